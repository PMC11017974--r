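#' Shapiro-Wilk normality of log body volumes
#'
#' A bimodal caste structure shows up as non-normal log volumes, so the
#' size-designation procedure first tests normality of the natural-log
#' volumes (the test is scale-invariant, so the log base is cosmetic).
#'
#' @param volumes positive body volumes (um^3), length 3..5000.
#' @return List of class `normality_result`: `W`, `p_value`, `n`.
#' @export
log_volume_normality <- function(volumes) {
  volumes <- volumes[!is.na(volumes)]
  if (length(volumes) < 3) {
    stop("insufficient data: need at least 3 volumes, got ", length(volumes))
  }
  if (any(volumes <= 0)) stop("volumes must be positive")
  lv <- log(volumes)
  if (stats::sd(lv) == 0) stop("degenerate input: all volumes identical")
  sw <- stats::shapiro.test(lv)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value,
                 n = length(volumes)),
            class = "normality_result")
}

#' Default histogram break points
#'
#' Reproduces the default binning of `hist()`: the number of classes comes
#' from Sturges' formula, ceiling(log2(n)) + 1, and the break points are
#' placed at "nice" numbers (1, 2 or 5 times a power of ten) covering the
#' data range. Bins are right-closed with the lowest bin closed on both
#' ends, so every value falls in exactly one bin.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return Strictly increasing numeric vector of break points.
#' @export
default_histogram_breaks <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || length(unique(values)) < 2) {
    stop("degenerate input: need at least 2 distinct finite values")
  }
  pretty(range(values), n = nclass.Sturges(values))
}

bin_counts <- function(values, breaks) {
  idx <- .bincode(values, breaks, right = TRUE, include.lowest = TRUE)
  tabulate(idx, nbins = length(breaks) - 1)
}

#' Histogram-trough bimodality detection
#'
#' The visual "two distinct peaks" judgement is replaced by an explicit
#' rule on the default histogram of log10 volumes: the distribution is
#' called bimodal when two local-maximum bins exist, each with count at
#' least `min_peak_count`, and the minimum-count bin strictly between them
#' has count at most `trough_ratio` times the smaller peak count. The
#' trough is the minimum-count bin between the two highest qualifying
#' peaks (ties broken toward the midpoint of the peaks, then toward the
#' lower index) and the size cutoff is the back-transformed midpoint of
#' the trough bin.
#'
#' Colonies whose log volumes do not reject normality at `config$alpha`,
#' or with fewer than `config$min_n` rediae, are not inspected: the result
#' carries `method = "quartile_fallback"` and `is_bimodal = FALSE`. A
#' per-colony `manual_cutoff` in the configuration short-circuits the rule
#' (`method = "manual_override"`).
#'
#' @param volumes positive body volumes (um^3).
#' @param config a [dol_config()].
#' @param normality optional pre-computed [log_volume_normality()] result.
#' @param colony_id optional id used to look up `config$manual_cutoff`.
#' @return List of class `bimodality_result`: `is_bimodal`,
#'   `histogram_breaks` (log10 um^3), `bin_counts`, `peak_bins`,
#'   `trough_bin`, `cutoff_volume_um3`, `method`.
#' @export
detect_bimodality <- function(volumes, config = dol_config(),
                              normality = NULL, colony_id = NULL) {
  volumes <- volumes[!is.na(volumes)]
  if (length(volumes) == 0) stop("no volumes supplied")
  if (any(volumes <= 0)) stop("volumes must be positive")

  if (!is.null(colony_id) && !is.null(config$manual_cutoff) &&
      colony_id %in% names(config$manual_cutoff)) {
    cutoff <- unname(config$manual_cutoff[[colony_id]])
    lv <- log10(volumes)
    breaks <- if (length(unique(lv)) >= 2) default_histogram_breaks(lv) else NULL
    return(structure(list(
      is_bimodal = TRUE, histogram_breaks = breaks,
      bin_counts = if (is.null(breaks)) NULL else bin_counts(lv, breaks),
      peak_bins = integer(0), trough_bin = NA_integer_,
      cutoff_volume_um3 = cutoff, method = "manual_override"),
      class = "bimodality_result"))
  }

  fallback <- structure(list(
    is_bimodal = FALSE, histogram_breaks = NULL, bin_counts = NULL,
    peak_bins = integer(0), trough_bin = NA_integer_,
    cutoff_volume_um3 = NULL, method = "quartile_fallback"),
    class = "bimodality_result")

  if (length(volumes) < config$min_n) return(fallback)
  if (is.null(normality)) {
    if (length(volumes) < 3 || stats::sd(log(volumes)) == 0) return(fallback)
    normality <- log_volume_normality(volumes)
  }
  if (normality$p_value >= config$alpha) return(fallback)

  lv <- log10(volumes)
  if (length(unique(lv)) < 2) return(fallback)
  breaks <- default_histogram_breaks(lv)
  counts <- bin_counts(lv, breaks)
  peaks <- local_maxima(counts)
  peaks <- peaks[counts[peaks] >= config$min_peak_count]

  result <- fallback
  result$histogram_breaks <- breaks
  result$bin_counts <- counts
  result$method <- "histogram_trough"

  if (length(peaks) >= 2) {
    # candidate peaks ranked by count (desc), then index; first qualifying
    # pair in that order is "the two highest such peaks"
    ord <- peaks[order(-counts[peaks], peaks)]
    chosen <- NULL
    for (i in seq_along(ord)) {
      for (j in seq_along(ord)) {
        if (j <= i) next
        p1 <- min(ord[i], ord[j]); p2 <- max(ord[i], ord[j])
        if (p2 - p1 < 2) next  # need a bin strictly between the peaks
        between <- counts[(p1 + 1):(p2 - 1)]
        smaller_peak <- min(counts[p1], counts[p2])
        if (min(between) <= config$trough_ratio * smaller_peak) {
          chosen <- c(p1, p2); break
        }
      }
      if (!is.null(chosen)) break
    }
    if (!is.null(chosen)) {
      p1 <- chosen[1]; p2 <- chosen[2]
      between_idx <- (p1 + 1):(p2 - 1)
      cand <- between_idx[counts[between_idx] == min(counts[between_idx])]
      mid <- (p1 + p2) / 2
      cand <- cand[abs(cand - mid) == min(abs(cand - mid))]
      trough <- min(cand)
      result$is_bimodal <- TRUE
      result$peak_bins <- c(p1, p2)
      result$trough_bin <- trough
      result$cutoff_volume_um3 <- 10^((breaks[trough] + breaks[trough + 1]) / 2)
    } else {
      result$peak_bins <- ord[1:2]
    }
  }
  result
}

# Indices of local-maximum runs in a count vector; a plateau counts once
# (its first bin). A run is a local maximum if it exceeds both adjacent
# runs (boundary runs only need to exceed their single neighbour).
local_maxima <- function(counts) {
  r <- rle(counts)
  vals <- r$values
  k <- length(vals)
  starts <- cumsum(c(1, r$lengths[-k]))
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1 || vals[i] > vals[i - 1]
    right_ok <- i == k || vals[i] > vals[i + 1]
    left_ok && right_ok
  }, logical(1))
  starts[is_max]
}

#' Assign small/intermediate/large size classes
#'
#' Two branches mirror the two-branch designation procedure. When a
#' histogram-trough (or manual) cutoff is available, every redia at or
#' below the cutoff volume is `small` and every other redia `large` (no
#' intermediates). In the quartile fallback the smallest 25% of volumes
#' are `small`, the largest 25% `large`, and the rest `intermediate`;
#' quartiles use linear interpolation at index (n-1)p + 1 with boundary
#' values inclusive.
#'
#' @param volumes positive body volumes (um^3), `NA` allowed (stays
#'   `unassigned`).
#' @param bimodality a [detect_bimodality()] result.
#' @return Character vector of labels `"small"`, `"intermediate"`,
#'   `"large"`, `"unassigned"`.
#' @export
assign_size_classes <- function(volumes, bimodality) {
  if (length(volumes) == 0) stop("no volumes supplied")
  stopifnot(inherits(bimodality, "bimodality_result"))
  labels <- rep("unassigned", length(volumes))
  ok <- !is.na(volumes)
  v <- volumes[ok]
  if (!length(v)) return(labels)
  if (length(unique(v)) == 1) {
    warning("all volumes identical; every redia labelled 'small'")
    labels[ok] <- "small"
    return(labels)
  }
  if (bimodality$is_bimodal) {
    cutoff <- bimodality$cutoff_volume_um3
    labels[ok] <- ifelse(v <= cutoff, "small", "large")
  } else {
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    labels[ok] <- ifelse(v <= q[1], "small",
                         ifelse(v >= q[2], "large", "intermediate"))
  }
  labels
}

#' Volume pattern code
#'
#' Codes the volume column: `"Y"` = non-normal and bimodal, `"N*"` =
#' non-normal but not bimodal, `"N"` = consistent with a (log)normal
#' distribution.
#'
#' @param normality a [log_volume_normality()] result.
#' @param bimodality a [detect_bimodality()] result.
#' @param alpha significance level.
#' @return `"Y"`, `"N*"` or `"N"`.
#' @export
volume_pattern_code <- function(normality, bimodality, alpha = 0.05) {
  stopifnot(inherits(normality, "normality_result"),
            inherits(bimodality, "bimodality_result"))
  if (normality$p_value >= alpha) return("N")
  if (bimodality$is_bimodal) "Y" else "N*"
}
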