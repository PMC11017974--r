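test_that("log-volume normality matches an independent Shapiro-Wilk implementation", {
  # frozen cross-check values computed with scipy.stats.shapiro on the
  # natural-log volumes of this seeded lognormal draw
  v <- c(363806.7524, 616292.5898, 295089.4157, 503135.9422, 533098.522,
         894821.7116, 641313.6395, 413477.927, 766980.7434, 386947.5299)
  res <- log_volume_normality(v)
  expect_equal(res$W, 0.9801449779, tolerance = 1e-6)
  expect_equal(res$p_value, 0.9659392221, tolerance = 1e-6)
  expect_equal(res$n, 10)
})

test_that("normality test rejects degenerate and undersized inputs", {
  expect_error(log_volume_normality(rep(5, 10)), "degenerate")
  expect_error(log_volume_normality(c(1, 2)), "insufficient")
  expect_error(log_volume_normality(c(-1, 2, 3)), "positive")
})

test_that("default histogram breaks reproduce hist()'s nice-number rule", {
  x30 <- seq(0.3, 9.7, length.out = 30)
  expect_equal(default_histogram_breaks(x30), c(0, 2, 4, 6, 8, 10))
  expect_error(default_histogram_breaks(rep(1, 5)), "degenerate")
  b <- default_histogram_breaks(c(0.1, 0.9))
  expect_true(min(b) <= 0.1 && max(b) >= 0.9)
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(10:500, 1), sd = runif(1, 0.1, 100))
    expect_equal(default_histogram_breaks(x),
                 hist(x, plot = FALSE)$breaks)
  }
})

test_that("histogram-trough rule detects a well-separated mixture and places the trough at the scan minimum", {
  set.seed(11)
  lv <- c(rnorm(50, 1, 0.15), rnorm(50, 2, 0.15))
  vols <- 10^lv
  res <- detect_bimodality(vols, dol_config())
  expect_true(res$is_bimodal)
  expect_identical(res$method, "histogram_trough")
  expect_gt(res$cutoff_volume_um3, 10^1)
  expect_lt(res$cutoff_volume_um3, 10^2)
  # exhaustive scan: the trough bin is a minimum-count bin strictly
  # between the two peak bins
  counts <- res$bin_counts
  p <- res$peak_bins
  between <- (p[1] + 1):(p[2] - 1)
  expect_true(res$trough_bin %in% between)
  expect_equal(counts[res$trough_bin], min(counts[between]))
  expect_equal(sum(counts), 100)
  expect_true(all(diff(res$histogram_breaks) > 0))
})

test_that("a single lognormal component is rarely called bimodal", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    vols <- 10^rnorm(100, 1.5, 0.2)
    res <- detect_bimodality(vols, dol_config())
    if (res$is_bimodal) hits <- hits + 1
  }
  expect_lte(hits, 10)
})

test_that("small colonies fall back to the quartile branch", {
  set.seed(3)
  vols <- 10^c(rnorm(5, 1, 0.1), rnorm(5, 2, 0.1))
  res <- detect_bimodality(vols, dol_config())
  expect_identical(res$method, "quartile_fallback")
  expect_false(res$is_bimodal)
})

test_that("manual cutoff overrides the automatic rule", {
  cfg <- dol_config(manual_cutoff = c(C1 = 500))
  res <- detect_bimodality(c(100, 200, 900, 1000), cfg, colony_id = "C1")
  expect_identical(res$method, "manual_override")
  expect_true(res$is_bimodal)
  expect_equal(res$cutoff_volume_um3, 500)
  labels <- assign_size_classes(c(100, 200, 900, 1000), res)
  expect_equal(labels, c("small", "small", "large", "large"))
})

test_that("quartile fallback assigns interpolated-quantile classes", {
  fallback <- detect_bimodality(10^rnorm(10, 1.5, 0.2), dol_config())
  expect_identical(fallback$method, "quartile_fallback")
  labels <- assign_size_classes(1:8, fallback)
  # Q1 = 2.75, Q3 = 6.25 under the (n-1)p + 1 convention
  expect_equal(interp_quantile(1:8, 0.25), 2.75)
  expect_equal(interp_quantile(1:8, 0.75), 6.25)
  expect_equal(labels, c("small", "small", rep("intermediate", 4),
                         "large", "large"))
})

test_that("trough-mode classification splits at the cutoff with no intermediates", {
  bim <- structure(list(is_bimodal = TRUE, cutoff_volume_um3 = 31.6,
                        method = "histogram_trough"),
                   class = "bimodality_result")
  expect_equal(assign_size_classes(c(10, 20, 100), bim),
               c("small", "small", "large"))
})

test_that("identical volumes label everything small with a warning", {
  bim <- detect_bimodality(10^rnorm(30, 1.5, 0.2), dol_config())
  expect_warning(labels <- assign_size_classes(rep(5, 6), bim), "identical")
  expect_equal(labels, rep("small", 6))
})

test_that("class labels always partition the colony and respect volume order", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(c(25, 60, 120), 1)
    sep <- sample(c(0, 1), 1)
    vols <- 10^c(rnorm(ceiling(n / 2), 5.5, 0.25), rnorm(floor(n / 2), 5.5 + sep, 0.25))
    res <- detect_bimodality(vols, dol_config())
    labels <- assign_size_classes(vols, res)
    expect_equal(length(labels), n)
    expect_true(all(labels %in% c("small", "intermediate", "large")))
    smalls <- vols[labels == "small"]; larges <- vols[labels == "large"]
    if (length(smalls) && length(larges)) expect_lt(max(smalls), min(larges))
  }
})

test_that("the volume code combines normality and bimodality as Y / N* / N", {
  norm_rej <- structure(list(W = 0.8, p_value = 0.001, n = 50),
                        class = "normality_result")
  norm_ok <- structure(list(W = 0.99, p_value = 0.30, n = 50),
                       class = "normality_result")
  bim_yes <- structure(list(is_bimodal = TRUE), class = "bimodality_result")
  bim_no <- structure(list(is_bimodal = FALSE), class = "bimodality_result")
  expect_identical(volume_pattern_code(norm_rej, bim_yes), "Y")
  expect_identical(volume_pattern_code(norm_rej, bim_no), "N*")
  expect_identical(volume_pattern_code(norm_ok, bim_yes), "N")
  expect_identical(volume_pattern_code(norm_ok, bim_no), "N")
})
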