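# Shared fixture builders and independent oracles.

# A small hand-built colony: 8 measured rediae across three sections,
# with size classes assignable and pharynx measurements present.
make_tiny_colony <- function(medium = "saline") {
  records <- data.frame(
    redia_id = sprintf("r%d", 1:8),
    section = c("foot", "foot", "mid", "apical", "apical", "apical", "mid", "foot"),
    length_um = c(120, 130, 300, 600, 650, 700, 350, 110),
    width_um = c(30, 32, 75, 150, 160, 170, 80, 28),
    pharynx_um = c(14, 15, 18, 22, 23, 24, 19, 13),
    stringsAsFactors = FALSE
  )
  scores <- data.frame(
    redia_id = c(sprintf("r%d", c(8, 1, 2)), sprintf("r%d", c(6, 5, 4))),
    extremum = c(rep("smallest5", 3), rep("largest5", 3)),
    anterior_score = c(4, 4, 3, 1, 0, 1),
    posterior_score = c(4, 3, 4, 0, 1, 0),
    embryo_score = c(0, 1, 0, 4, 4, 4),
    stringsAsFactors = FALSE
  )
  activity <- data.frame(
    redia_id = sprintf("a%d", 1:6),
    size_label = rep(c("small", "large"), each = 3),
    distance_t0_um = c(20, 25, 22, 10, 9, 12),
    distance_t15_um = c(24, 21, NA, 8, 11, 10),
    body_length_um = c(120, 130, 110, 620, 640, 660),
    stringsAsFactors = FALSE
  )
  attacks <- data.frame(
    trial_id = sprintf("t%d", 1:4),
    attacker_size = c("small", "small", "large", "large"),
    target_type = c("heterospecific", "conspecific", "heterospecific", "colony_mate"),
    n_attacks_observed = c(3, 1, 0, 1),
    n_rediae = c(10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
  redia_colony("TINY1", records, scores = scores, activity = activity,
               attacks = attacks, dissection_medium = medium)
}

write_measurement_fixture <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# Independent rank-sum oracle: proportion of all permutations of the
# pooled values for which the group-one rank sum reaches the observed
# one. Enumerates full permutations (feasible to n = 7), a different
# route than the package's combination enumeration.
perm_rank_sum_p <- function(x, y, alternative = "greater") {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[seq_len(n1)])
  perms <- gtools_permutations(n)
  stats_all <- apply(perms, 1, function(idx) {
    sum(rank(pooled[idx])[seq_len(n1)])
  })
  pg <- mean(stats_all >= obs - 1e-9)
  pl <- mean(stats_all <= obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * factorial(n - 1) + 1):(i * factorial(n - 1))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

# Brute-force global alignment score by recursive enumeration of all
# alignments (feasible for sequences up to length ~7).
brute_force_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Quantile oracle: direct linear interpolation at index (n - 1) * p + 1
# on the sorted sample.
interp_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
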