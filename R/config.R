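#' Analysis configuration
#'
#' Bundles every tunable threshold used by the pattern battery and the
#' size-designation procedure. Defaults follow the conventions of the
#' field: a 0.05 significance level with no multiple-testing adjustment,
#' a 95% COI identity threshold for species grouping, and the standard
#' 1.5 x IQR Tukey fence for large-pharynx screening.
#'
#' @param alpha significance level for every hypothesis test (strictly
#'   `p < alpha` counts as significant). Default 0.05.
#' @param identity_threshold_pct percent identity at or above which two COI
#'   sequences are placed in the same putative species. Default 95.
#' @param outlier_fence_k multiplier on the IQR for the upper Tukey fence
#'   used in large-pharynx screening. Default 1.5.
#' @param min_n minimum colony size for the histogram-trough bimodality
#'   rule; smaller colonies fall back to the quartile branch. Default 20.
#' @param min_peak_count minimum count for a histogram bin to qualify as a
#'   peak. Default 3.
#' @param trough_ratio a candidate trough bin must have count at most
#'   `trough_ratio` times the smaller of the two peak counts. Default 0.75.
#' @param manual_cutoff optional named numeric vector of per-colony volume
#'   cutoffs (um^3) overriding the automatic bimodality rule.
#' @param exact_n_max largest combined sample size for which rank-sum
#'   p-values are computed by exhaustive enumeration. Default 12.
#' @param ci_level confidence level for section proportions. Default 0.95.
#' @param ci_method label recorded with every proportion interval; only
#'   `"clopper-pearson"` is implemented.
#' @param large_pharynx_min_fraction minimum outlier fraction for a colony
#'   to be flagged as carrying a large-pharynx subpopulation (inclusive).
#'   Default 0.05.
#' @param behavior_saline_only if `TRUE` (default) activity and attack
#'   patterns are only computed for saline-dissected colonies; osmotic
#'   stress in water dissections suppresses behaviour.
#' @param rng_seed integer seed recorded for reproducibility.
#'
#' @return An object of class `dol_config` (a validated list).
#' @seealso [write_config()], [read_config()]
#' @export
dol_config <- function(alpha = 0.05,
                       identity_threshold_pct = 95,
                       outlier_fence_k = 1.5,
                       min_n = 20,
                       min_peak_count = 3,
                       trough_ratio = 0.75,
                       manual_cutoff = NULL,
                       exact_n_max = 12,
                       ci_level = 0.95,
                       ci_method = "clopper-pearson",
                       large_pharynx_min_fraction = 0.05,
                       behavior_saline_only = TRUE,
                       rng_seed = 1L) {
  cfg <- list(
    alpha = alpha,
    identity_threshold_pct = identity_threshold_pct,
    outlier_fence_k = outlier_fence_k,
    min_n = min_n,
    min_peak_count = min_peak_count,
    trough_ratio = trough_ratio,
    manual_cutoff = manual_cutoff,
    exact_n_max = exact_n_max,
    ci_level = ci_level,
    ci_method = ci_method,
    large_pharynx_min_fraction = large_pharynx_min_fraction,
    behavior_saline_only = behavior_saline_only,
    rng_seed = as.integer(rng_seed)
  )
  validate_dol_config(cfg)
  structure(cfg, class = "dol_config")
}

validate_dol_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$alpha), length(cfg$alpha) == 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$identity_threshold_pct > 0, cfg$identity_threshold_pct <= 100,
    cfg$outlier_fence_k > 0,
    cfg$min_n >= 1,
    cfg$min_peak_count >= 1,
    cfg$trough_ratio > 0,
    cfg$exact_n_max >= 2,
    cfg$ci_level > 0, cfg$ci_level < 1,
    cfg$large_pharynx_min_fraction >= 0, cfg$large_pharynx_min_fraction <= 1
  )
  if (!is.null(cfg$manual_cutoff)) {
    stopifnot(is.numeric(cfg$manual_cutoff), all(cfg$manual_cutoff > 0),
              !is.null(names(cfg$manual_cutoff)))
  }
  invisible(cfg)
}

#' @export
print.dol_config <- function(x, ...) {
  cat("Division-of-labor analysis configuration\n")
  cat(sprintf("  alpha: %g (no multiple-testing adjustment)\n", x$alpha))
  cat(sprintf("  COI identity threshold: %g%%\n", x$identity_threshold_pct))
  cat(sprintf("  Tukey fence: Q3 + %g*IQR\n", x$outlier_fence_k))
  cat(sprintf("  bimodality: min_n=%d, min_peak_count=%d, trough_ratio=%g\n",
              x$min_n, x$min_peak_count, x$trough_ratio))
  cat(sprintf("  rank-sum exact enumeration up to n1+n2 = %d\n", x$exact_n_max))
  cat(sprintf("  proportion CI: %g%% %s\n", 100 * x$ci_level, x$ci_method))
  invisible(x)
}

#' Write / read an analysis configuration as JSON
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` reproduces
#' every field.
#'
#' @param config a [dol_config()] object.
#' @param path file path for the JSON document.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `dol_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dol_config"))
  payload <- unclass(config)
  if (!is.null(payload$manual_cutoff)) {
    # keep the per-colony names through auto_unbox
    payload$manual_cutoff <- as.list(payload$manual_cutoff)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$manual_cutoff)) {
    if (length(raw$manual_cutoff) == 0) {
      raw$manual_cutoff <- NULL
    } else {
      raw$manual_cutoff <- unlist(raw$manual_cutoff)
    }
  }
  do.call(dol_config, raw)
}
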