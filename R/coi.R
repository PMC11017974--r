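#' Global nucleotide alignment
#'
#' Needleman-Wunsch dynamic programming under linear gap scoring, giving
#' the pipeline a self-contained aligner for unaligned COI barcodes.
#' Tie-breaking in the traceback is deterministic: diagonal is preferred
#' over a gap in the second sequence, which is preferred over a gap in
#' the first. An empty sequence yields the degenerate all-gap alignment
#' (score `gap * length` of the other sequence), not an error.
#'
#' @param seq_a,seq_b nucleotide strings over `{A, C, G, T, N}`
#'   (case-insensitive).
#' @param match,mismatch,gap scoring parameters (defaults 1, -1, -1).
#' @return List of class `global_alignment`: `a`, `b` (gapped strings of
#'   equal length) and `score`.
#' @examples
#' global_align("ACGT", "ACGT")$score  # 4
#' @export
global_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -1) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (s in c(seq_a, seq_b)) {
    if (nchar(s) && grepl("[^ACGTN]", s)) {
      stop("invalid character in sequence (alphabet is A/C/G/T/N)")
    }
  }
  res <- .nw_align(seq_a, seq_b, match, mismatch, gap)
  structure(list(a = res$a, b = res$b, score = res$score),
            class = "global_alignment")
}

#' Percent identity of an aligned pair
#'
#' PI = 100 x matches / comparable columns, where a column is comparable
#' when neither sequence carries a gap and neither carries `N`.
#' Divergence is `100 - PI`.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return Percent identity in \[0, 100\], with the number of comparable
#'   columns as attribute `n_compared`.
#' @export
pairwise_identity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length")
  }
  cnt <- .pi_counts(c(toupper(aligned_a), toupper(aligned_b)))
  nc <- cnt$comparable[1, 2]
  if (nc == 0) stop("undefined identity: zero comparable columns")
  pi_val <- 100 * cnt$matches[1, 2] / nc
  attr(pi_val, "n_compared") <- nc
  pi_val
}

#' Percent-identity matrix for a sequence set
#'
#' For pre-aligned input (`aligned = TRUE`, or sequences of equal length
#' containing gaps) identities are computed column-wise directly;
#' otherwise every pair is globally aligned first with [global_align()].
#' Columns with a gap or `N` in either sequence of a pair are excluded
#' from both numerator and denominator; this convention is recorded in
#' the result.
#'
#' @param seqs named character vector of sequences.
#' @param aligned treat input as already aligned (default: auto-detected
#'   as "all equal lengths").
#' @return List of class `identity_matrix`: `ids`, `pi` (symmetric,
#'   diagonal 100), `n_compared_columns`, `convention`.
#' @export
identity_matrix <- function(seqs, aligned = NULL) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  k <- length(seqs)
  if (k == 0) stop("no sequences supplied")
  seqs <- toupper(seqs)
  if (is.null(aligned)) aligned <- length(unique(nchar(seqs))) == 1
  ids <- names(seqs)
  if (aligned) {
    cnt <- .pi_counts(unname(seqs))
    nc <- cnt$comparable
    if (k > 1 && any(nc[upper.tri(nc)] == 0)) {
      stop("undefined identity: a pair has zero comparable columns")
    }
    pi_mat <- ifelse(nc > 0, 100 * cnt$matches / nc, NA_real_)
  } else {
    pi_mat <- matrix(NA_real_, k, k)
    nc <- matrix(0L, k, k)
    if (k > 1) {
      for (i in 1:(k - 1)) {
        for (j in (i + 1):k) {
          aln <- global_align(seqs[[i]], seqs[[j]])
          p <- pairwise_identity(aln$a, aln$b)
          pi_mat[i, j] <- pi_mat[j, i] <- as.numeric(p)
          nc[i, j] <- nc[j, i] <- attr(p, "n_compared")
        }
      }
    }
  }
  diag(pi_mat) <- 100
  diag(nc) <- nchar(seqs)
  dimnames(pi_mat) <- dimnames(nc) <- list(ids, ids)
  structure(list(ids = ids, pi = pi_mat, n_compared_columns = nc,
                 convention = "gap and N columns excluded from PI"),
            class = "identity_matrix")
}

#' Threshold clustering into putative COI species
#'
#' Single-linkage connected components over the graph whose edges join
#' sequence pairs with percent identity at or above the threshold
#' (equivalently, divergence below 100 - threshold; the boundary is
#' inclusive). Single linkage matches the practice of merging on any
#' qualifying similarity, so chained groups whose extreme members fall
#' below the threshold stay together. Cluster labels are deterministic:
#' each cluster is named after its lexicographically smallest member,
#' which is also the representative.
#'
#' @param im an [identity_matrix()] (or a plain symmetric PI matrix with
#'   dimnames).
#' @param threshold percent identity threshold (default 95, inclusive).
#' @return Data frame with columns `sequence_id`, `cluster_id`,
#'   `representative_id`, sorted by cluster then member id; the number of
#'   clusters is `length(unique(cluster_id))`.
#' @export
cluster_species <- function(im, threshold = 95) {
  if (inherits(im, "identity_matrix")) {
    pi_mat <- im$pi; ids <- im$ids
  } else {
    pi_mat <- as.matrix(im); ids <- rownames(pi_mat)
  }
  k <- length(ids)
  if (k == 0) {
    return(data.frame(sequence_id = character(0), cluster_id = character(0),
                      representative_id = character(0)))
  }
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (!is.na(pi_mat[i, j]) && pi_mat[i, j] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  rep_id <- vapply(split(ids, roots), function(m) sort(m)[1], character(1))
  cluster_id <- rep_id[as.character(roots)]
  out <- data.frame(sequence_id = ids, cluster_id = unname(cluster_id),
                    representative_id = unname(cluster_id),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster COI sequences from a FASTA file
#'
#' Convenience wrapper: reads the FASTA (aligned or unaligned), builds
#' the percent-identity matrix and clusters at the configured threshold.
#'
#' @param path FASTA file path.
#' @param threshold percent identity threshold (default 95).
#' @return The [cluster_species()] data frame, with the identity matrix
#'   attached as attribute `identity_matrix`.
#' @export
cluster_coi <- function(path, threshold = 95) {
  seqs <- read_fasta(path)
  im <- identity_matrix(seqs)
  out <- cluster_species(im, threshold)
  attr(out, "identity_matrix") <- im
  out
}
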