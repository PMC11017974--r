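#' @title Per-colony pattern tests
#' @description Each pattern test returns a `pattern_result`: the pattern
#'   name, a code from that pattern's closed vocabulary, a named list of
#'   supporting statistics, and free-text notes. Codes follow the summary
#'   table conventions of the field's soldier-redia literature: `Y` marks
#'   a result consistent with division of labor, `N` / `N*` / `O` / `NS`
#'   its graded alternatives, `NA` insufficient data.
#' @name pattern_battery
NULL

pattern_result <- function(pattern, code, statistics = list(), notes = NULL) {
  structure(list(pattern = pattern, code = code,
                 statistics = statistics, notes = notes),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("[%s] %s", x$pattern, x$code))
  if (!is.null(x$statistics$p_value)) {
    cat(sprintf(" (p = %.4g)", x$statistics$p_value))
  }
  if (!is.null(x$notes)) cat(" -", x$notes)
  cat("\n")
  invisible(x)
}

#' Relative-pharynx pattern
#'
#' One-tailed rank-sum test of whether small rediae have larger pharynges
#' relative to their body volume than large rediae (`Y` if p < alpha,
#' `N` otherwise, `NA` if either size class has no relative-pharynx
#' measurement). The companion test on absolute pharynx volume (large >
#' small) is returned in `statistics$abs_pharynx`.
#'
#' @param colony a [redia_colony()] with morphometrics and size classes
#'   assigned (see [add_morphometrics()], [assign_size_classes()]).
#' @param config a [dol_config()].
#' @return A `pattern_result` with code in `{Y, N, NA}`.
#' @export
pharynx_pattern <- function(colony, config = dol_config()) {
  r <- analysis_records(colony)
  small <- r$relative_pharynx[r$size_class == "small"]
  large <- r$relative_pharynx[r$size_class == "large"]
  small <- small[!is.na(small)]; large <- large[!is.na(large)]
  if (length(small) == 0 || length(large) == 0) {
    return(pattern_result("pharynx", "NA",
                          notes = "a size class has no relative-pharynx measurements"))
  }
  rel <- rank_sum(small, large, "greater", config$exact_n_max)
  abs_small <- r$pharynx_volume_um3[r$size_class == "small"]
  abs_large <- r$pharynx_volume_um3[r$size_class == "large"]
  abs_small <- abs_small[!is.na(abs_small)]; abs_large <- abs_large[!is.na(abs_large)]
  abs_test <- if (length(abs_small) && length(abs_large)) {
    rank_sum(abs_large, abs_small, "greater", config$exact_n_max)
  } else NULL
  code <- if (rel$p_value < config$alpha) "Y" else "N"
  pattern_result("pharynx", code,
                 statistics = list(p_value = rel$p_value, U = rel$U,
                                   n_small = length(small), n_large = length(large),
                                   abs_pharynx = abs_test))
}

#' Appendage (morphology) pattern
#'
#' Two one-tailed rank-sum tests on the ordinal presence scores of the
#' five smallest vs five largest rediae: one for the anterior
#' appendage/collar, one for the posterior appendages, each with the
#' alternative that the smallest five score higher. `Y` if both are
#' significant, `O` if exactly one, `N` if neither; `NA` if either
#' extremum group is missing.
#'
#' @param scores the colony's presence-score table.
#' @param config a [dol_config()].
#' @return A `pattern_result` with code in `{Y, O, N, NA}`.
#' @export
appendage_pattern <- function(scores, config = dol_config()) {
  if (is.null(scores) || !nrow(scores) ||
      !all(c("smallest5", "largest5") %in% scores$extremum)) {
    return(pattern_result("morphology", "NA",
                          notes = "missing smallest5 or largest5 score group"))
  }
  test_one <- function(col) {
    s <- scores[[col]][scores$extremum == "smallest5"]
    l <- scores[[col]][scores$extremum == "largest5"]
    s <- s[!is.na(s)]; l <- l[!is.na(l)]
    if (!length(s) || !length(l)) return(NULL)
    rank_sum(s, l, "greater", config$exact_n_max)
  }
  ant <- test_one("anterior_score")
  post <- test_one("posterior_score")
  if (is.null(ant) || is.null(post)) {
    return(pattern_result("morphology", "NA",
                          notes = "insufficient scored rediae for one appendage"))
  }
  sig <- c(ant$p_value < config$alpha, post$p_value < config$alpha)
  code <- c("N", "O", "Y")[sum(sig) + 1]
  pattern_result("morphology", code,
                 statistics = list(anterior_p = ant$p_value,
                                   posterior_p = post$p_value))
}

#' Reproduction code
#'
#' The maximum embryo presence score over the five smallest rediae codes
#' the reproductive potential of the small caste: 4 (embryos definitely
#' present) gives `Y`, 3 `Y?`, 2 `U`, and 0-1 `N` (soldier-consistent:
#' no embryos in small rediae).
#'
#' @param scores the colony's presence-score table.
#' @return A `pattern_result` with code in `{Y, Y?, U, N, NA}`.
#' @export
reproduction_code <- function(scores) {
  if (is.null(scores) || !any(scores$extremum == "smallest5")) {
    return(pattern_result("reproduction", "NA",
                          notes = "no smallest5 embryo scores"))
  }
  emb <- scores$embryo_score[scores$extremum == "smallest5"]
  emb <- emb[!is.na(emb)]
  if (!length(emb)) {
    return(pattern_result("reproduction", "NA",
                          notes = "no smallest5 embryo scores"))
  }
  m <- max(emb)
  code <- if (m == 4) "Y" else if (m == 3) "Y?" else if (m == 2) "U" else "N"
  pattern_result("reproduction", code,
                 statistics = list(max_embryo_score = m, n_scored = length(emb)))
}

#' Percentage of small rediae
#'
#' Reported only for colonies whose volume distribution is bimodal
#' (volume code `Y`); other colonies are `NA` because small/large is then
#' a quartile construct, not a caste count.
#'
#' @param colony a classified [redia_colony()].
#' @param volume_code the colony's volume pattern code.
#' @return A `pattern_result` whose code is the integer percentage (as a
#'   string) or `"NA"`; `statistics$pct_small` holds the exact value.
#' @export
percent_small <- function(colony, volume_code) {
  r <- analysis_records(colony)
  n_small <- sum(r$size_class == "small")
  n_large <- sum(r$size_class == "large")
  if (!identical(volume_code, "Y")) {
    return(pattern_result("pct_small", "NA", notes = "volume not bimodal"))
  }
  if (n_small + n_large == 0) stop("no classified rediae")
  pct <- 100 * n_small / (n_small + n_large)
  if (n_small == 0) warning("bimodal colony with zero small rediae")
  pattern_result("pct_small", sprintf("%d%%", round(pct)),
                 statistics = list(pct_small = pct, n_small = n_small,
                                   n_large = n_large))
}

#' Exact binomial proportion confidence interval
#'
#' Clopper-Pearson interval from beta quantiles; the interval always
#' contains the point estimate.
#'
#' @param successes,trials nonnegative integers, successes <= trials > 0.
#' @param level confidence level (default 0.95).
#' @return List of class `proportion_ci`: `successes`, `trials`, `point`,
#'   `lo`, `hi`, `level`, `method`.
#' @export
proportion_ci <- function(successes, trials, level = 0.95) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            level > 0, level < 1)
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else
    stats::qbeta(1 - a, successes + 1, trials - successes)
  structure(list(successes = successes, trials = trials,
                 point = successes / trials, lo = lo, hi = hi,
                 level = level, method = "clopper-pearson"),
            class = "proportion_ci")
}

#' Spatial distribution of castes across snail body sections
#'
#' For each body section, the proportion of classified rediae
#' (intermediates excluded) that are small, with an exact binomial CI.
#' The anterior section is the head/foot, or the mid section when the
#' foot holds no classified rediae. `Y` = small rediae are
#' proportionally more common anteriorly than in the apical
#' (gonad/digestive) region and the CIs are disjoint; `O` = the CIs
#' overlap; `N` = the apical proportion is higher with disjoint CIs;
#' `NA` = sections unavailable.
#'
#' @param colony a classified [redia_colony()].
#' @param config a [dol_config()].
#' @return A `pattern_result` with code in `{Y, O, N, NA}` and per-section
#'   CIs in `statistics$sections`.
#' @export
spatial_distribution <- function(colony, config = dol_config()) {
  r <- analysis_records(colony)
  r <- r[r$size_class %in% c("small", "large"), , drop = FALSE]
  r <- r[r$section %in% c("apical", "mid", "foot"), , drop = FALSE]
  secs <- unique(r$section)
  if (!"apical" %in% secs || length(secs) < 2) {
    return(pattern_result("distribution", "NA",
                          notes = "data from multiple body sections not available"))
  }
  ci_for <- function(sec) {
    sub <- r[r$section == sec, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    proportion_ci(sum(sub$size_class == "small"), nrow(sub), config$ci_level)
  }
  cis <- Filter(Negate(is.null),
                stats::setNames(lapply(c("apical", "mid", "foot"), ci_for),
                                c("apical", "mid", "foot")))
  anterior_name <- if (!is.null(cis$foot)) "foot" else "mid"
  ant <- cis[[anterior_name]]
  api <- cis$apical
  if (is.null(ant) || is.null(api)) {
    return(pattern_result("distribution", "NA",
                          notes = "anterior or apical section empty",
                          statistics = list(sections = cis)))
  }
  disjoint <- ant$lo > api$hi || api$lo > ant$hi
  code <- if (!disjoint) "O"
          else if (ant$point > api$point) "Y"
          else "N"
  pattern_result("distribution", code,
                 statistics = list(sections = cis,
                                   anterior_section = anterior_name,
                                   anterior_point = ant$point,
                                   apical_point = api$point))
}

#' Activity pattern
#'
#' Per redia, the 2-second movement distance is the mean of the available
#' 0- and 15-minute measurements; the relative distance is that divided
#' by body length. Small vs large relative distances are compared with a
#' two-tailed rank-sum test (`S` if p < alpha, else `NS`; `NA` when a
#' size label is absent). The companion two-tailed test on absolute
#' distance is reported in `statistics$abs_distance`, and the observed
#' direction (which group moved relatively further) in
#' `statistics$direction`; the division-of-labor prediction is that small
#' rediae are the more active.
#'
#' @param activity the colony's activity table.
#' @param config a [dol_config()].
#' @return A `pattern_result` with code in `{S, NS, NA}`.
#' @export
activity_comparison <- function(activity, config = dol_config()) {
  if (is.null(activity) || !nrow(activity) ||
      !all(c("small", "large") %in% activity$size_label)) {
    return(pattern_result("activity", "NA",
                          notes = "a size label is absent from activity trials"))
  }
  dist <- rowMeans(cbind(activity$distance_t0_um, activity$distance_t15_um),
                   na.rm = TRUE)
  rel <- dist / activity$body_length_um
  small_rel <- rel[activity$size_label == "small"]
  large_rel <- rel[activity$size_label == "large"]
  if (length(small_rel) < 2 || length(large_rel) < 2) {
    return(pattern_result("activity", "NA",
                          notes = "need at least 2 rediae per size label"))
  }
  test <- rank_sum(small_rel, large_rel, "two_sided", config$exact_n_max)
  small_abs <- dist[activity$size_label == "small"]
  large_abs <- dist[activity$size_label == "large"]
  abs_test <- rank_sum(small_abs, large_abs, "two_sided", config$exact_n_max)
  direction <- if (stats::median(small_rel) > stats::median(large_rel))
    "small_more_active" else "large_more_active"
  code <- if (test$p_value < config$alpha) "S" else "NS"
  pattern_result("activity", code,
                 statistics = list(p_value = test$p_value,
                                   abs_distance = abs_test,
                                   direction = direction,
                                   dol_prediction = "small_more_active"))
}

#' Attack pattern
#'
#' Totals observed attacks by attacker size: `Y` when small rediae
#' out-attack large rediae, `N` otherwise, `NA` with no trials. Per
#' target-type totals are kept in the statistics.
#'
#' @param attacks the colony's attack-trial table.
#' @return A `pattern_result` with code in `{Y, N, NA}`.
#' @export
attack_summary <- function(attacks) {
  if (is.null(attacks) || !nrow(attacks)) {
    return(pattern_result("attacks", "NA", notes = "no attack trials"))
  }
  totals <- tapply(attacks$n_attacks_observed, attacks$attacker_size, sum)
  n_small <- if ("small" %in% names(totals)) totals[["small"]] else 0L
  n_large <- if ("large" %in% names(totals)) totals[["large"]] else 0L
  by_target <- tapply(attacks$n_attacks_observed,
                      list(attacks$attacker_size, attacks$target_type), sum)
  code <- if (n_small > n_large) "Y" else "N"
  pattern_result("attacks", code,
                 statistics = list(attacks_small = n_small,
                                   attacks_large = n_large,
                                   by_target = by_target))
}

#' Tukey-fence pharynx outlier screen
#'
#' Quartiles use linear interpolation at index (n-1)p + 1; outliers lie
#' strictly above Q3 + k*IQR. The screened variable is pharynx diameter
#' (um) as measured.
#'
#' @param pharynx_um numeric vector of pharynx diameters (>= 4 values).
#' @param k fence multiplier (default 1.5).
#' @param ids optional identifiers parallel to `pharynx_um`.
#' @return List of class `outlier_result`: `q1`, `q3`, `iqr`,
#'   `upper_fence`, `outlier_ids`, `outlier_values`, `outlier_fraction`,
#'   `n`.
#' @export
pharynx_outliers <- function(pharynx_um, k = 1.5, ids = NULL) {
  keep <- !is.na(pharynx_um)
  x <- pharynx_um[keep]
  if (is.null(ids)) ids <- as.character(seq_along(pharynx_um))
  ids <- ids[keep]
  if (length(x) < 4) {
    stop("insufficient data: need at least 4 pharynx measurements, got ",
         length(x))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- q[2] + k * iqr
  out <- x > fence
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, upper_fence = fence,
                 outlier_ids = ids[out], outlier_values = x[out],
                 outlier_fraction = mean(out), n = length(x)),
            class = "outlier_result")
}

#' Large-pharynx subpopulation flag
#'
#' A colony is flagged as carrying a large-pharynx subpopulation when the
#' Tukey-fence outlier fraction reaches `min_fraction` (inclusive);
#' colonies with such subpopulations typically show outlier fractions of
#' roughly 5-15%.
#'
#' @param outlier_result a [pharynx_outliers()] result.
#' @param min_fraction flag threshold (default 0.05).
#' @return A `pattern_result` with code `"flagged"` / `"not_flagged"` and
#'   the fraction in `statistics`.
#' @export
large_pharynx_flag <- function(outlier_result, min_fraction = 0.05) {
  stopifnot(inherits(outlier_result, "outlier_result"))
  flagged <- outlier_result$outlier_fraction >= min_fraction
  pattern_result("large_pharynx",
                 if (flagged) "flagged" else "not_flagged",
                 statistics = list(outlier_fraction = outlier_result$outlier_fraction,
                                   upper_fence = outlier_result$upper_fence,
                                   n = outlier_result$n))
}

#' Growth trend of cultured rediae
#'
#' Ordinary least squares of mean redia length on day, with a two-sided
#' t-test on the slope, for culture monitoring data.
#'
#' @param day numeric time in days (>= 3 distinct timepoints).
#' @param mean_length_um mean redia length per timepoint (um).
#' @return A `pattern_result` with the slope (um/day) and its p-value.
#' @export
growth_trend <- function(day, mean_length_um) {
  stopifnot(length(day) == length(mean_length_um))
  keep <- !is.na(day) & !is.na(mean_length_um)
  day <- day[keep]; mean_length_um <- mean_length_um[keep]
  if (length(unique(day)) < 3) {
    stop("insufficient data: need at least 3 timepoints")
  }
  fit <- stats::lm(mean_length_um ~ day)
  slope <- unname(stats::coef(fit)[2])
  res_sd <- stats::sd(stats::residuals(fit))
  notes <- NULL
  if (isTRUE(all.equal(res_sd, 0)) || res_sd < 1e-12) {
    if (abs(slope) < 1e-12) {
      p <- NA_real_
      notes <- "constant lengths: slope exactly 0, no residual variance"
    } else {
      p <- .Machine$double.eps
      notes <- "perfect linear fit: p below machine tolerance"
    }
  } else {
    p <- summary(fit)$coefficients[2, 4]
  }
  pattern_result("growth", if (!is.na(p) && p < 0.05) "significant" else "flat",
                 statistics = list(slope_um_per_day = slope, p_value = p,
                                   n_timepoints = length(unique(day))),
                 notes = notes)
}
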