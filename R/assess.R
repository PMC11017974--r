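#' Assess division-of-labor patterns in one colony
#'
#' The central entry point: enriches the colony's records with derived
#' morphometrics, runs the two-branch size designation (normality test,
#' histogram-trough bimodality detection, class assignment), then the full
#' pattern battery (volume, reproduction, morphology, pharynx, %small,
#' distribution, activity, attacks) and the large-pharynx Tukey-fence
#' screen. Behavioural patterns (activity, attacks) are only computed for
#' saline-dissected colonies unless `config$behavior_saline_only` is
#' `FALSE`, because osmotic stress in water dissections suppresses
#' behaviour.
#'
#' @param colony a [redia_colony()].
#' @param config a [dol_config()].
#' @return An object of class `dol_assessment`: the classified colony,
#'   the normality/bimodality results, and a named list of
#'   `pattern_result`s.
#' @examples
#' set.seed(1)
#' sim <- simulate_colony(colony_sim_config(n_rediae = 120, seed = 1))
#' a <- assess_dol(sim$colony)
#' summary(a)
#' @export
assess_dol <- function(colony, config = dol_config()) {
  stopifnot(inherits(colony, "redia_colony"), inherits(config, "dol_config"))
  colony <- add_morphometrics(colony)
  r <- analysis_records(colony)
  vols <- r$body_volume_um3

  normality <- if (length(vols) >= 3 && stats::sd(log(vols)) > 0) {
    log_volume_normality(vols)
  } else NULL
  bimod <- detect_bimodality(vols, config, normality = normality,
                             colony_id = colony$colony_id)
  classes <- assign_size_classes(vols, bimod)
  colony$records$size_class <- "unassigned"
  colony$records$size_class[match(r$redia_id, colony$records$redia_id)] <- classes

  vol_code <- if (is.null(normality)) "NA" else
    volume_pattern_code(normality, bimod, config$alpha)
  patterns <- list(
    volume = pattern_result("volume", vol_code,
                            statistics = list(
                              shapiro_p = if (is.null(normality)) NA_real_ else normality$p_value,
                              method = bimod$method,
                              cutoff_volume_um3 = bimod$cutoff_volume_um3)),
    reproduction = reproduction_code(colony$scores),
    morphology = appendage_pattern(colony$scores, config),
    pharynx = pharynx_pattern(colony, config),
    pct_small = percent_small(colony, vol_code),
    distribution = spatial_distribution(colony, config)
  )

  behavior_ok <- !config$behavior_saline_only ||
    identical(colony$dissection_medium, "saline")
  patterns$activity <- if (behavior_ok) {
    activity_comparison(colony$activity, config)
  } else {
    pattern_result("activity", "NA",
                   notes = "water dissection: behaviour suppressed by osmotic stress")
  }
  patterns$attacks <- if (behavior_ok) {
    attack_summary(colony$attacks)
  } else {
    pattern_result("attacks", "NA",
                   notes = "water dissection: behaviour suppressed by osmotic stress")
  }

  ph <- r$pharynx_um[!is.na(r$pharynx_um)]
  outliers <- if (length(ph) >= 4) {
    pharynx_outliers(r$pharynx_um, k = config$outlier_fence_k, ids = r$redia_id)
  } else NULL
  patterns$large_pharynx <- if (!is.null(outliers)) {
    large_pharynx_flag(outliers, config$large_pharynx_min_fraction)
  } else {
    pattern_result("large_pharynx", "NA", notes = "fewer than 4 pharynx measurements")
  }

  structure(list(colony = colony, config = config, normality = normality,
                 bimodality = bimod, patterns = patterns,
                 outliers = outliers),
            class = "dol_assessment")
}

#' @export
print.dol_assessment <- function(x, ...) {
  cat(sprintf("Division-of-labor assessment: colony %s (%s)\n",
              x$colony$colony_id, x$colony$dissection_medium))
  r <- analysis_records(x$colony)
  tab <- table(factor(r$size_class,
                      c("small", "intermediate", "large", "unassigned")))
  cat(sprintf("  %d rediae: %d small / %d intermediate / %d large (%s)\n",
              nrow(r), tab["small"], tab["intermediate"], tab["large"],
              x$bimodality$method))
  for (p in x$patterns) print(p)
  invisible(x)
}

#' @export
summary.dol_assessment <- function(object, ...) {
  summarize_colony(object)
}

#' Plot the log-volume histogram behind a size designation
#'
#' Shows the default-bin histogram of log10 body volumes with the
#' detected peak bins, trough bin and cutoff marked, the visual the
#' histogram-trough rule formalizes.
#'
#' @param x a `dol_assessment`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.dol_assessment <- function(x, ...) {
  r <- analysis_records(x$colony)
  lv <- log10(r$body_volume_um3)
  b <- x$bimodality
  breaks <- if (!is.null(b$histogram_breaks)) b$histogram_breaks else "Sturges"
  graphics::hist(lv, breaks = breaks, right = TRUE, include.lowest = TRUE,
                 main = sprintf("Colony %s: log10 body volume", x$colony$colony_id),
                 xlab = expression(log[10] ~ "volume (" * mu * m^3 * ")"), ...)
  if (isTRUE(b$is_bimodal) && !is.null(b$cutoff_volume_um3)) {
    graphics::abline(v = log10(b$cutoff_volume_um3), lty = 2, col = "red")
  }
  invisible(x)
}

#' Assess a set of colonies
#'
#' @param colonies list of [redia_colony()] objects.
#' @param config a [dol_config()].
#' @return List of `dol_assessment`s, named by colony id.
#' @export
assess_colonies <- function(colonies, config = dol_config()) {
  out <- lapply(colonies, assess_dol, config = config)
  names(out) <- vapply(colonies, function(co) co$colony_id, character(1))
  out
}
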