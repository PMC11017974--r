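classified_colony <- function() {
  colony <- add_morphometrics(make_tiny_colony())
  r <- colony$records
  colony$records$size_class <- ifelse(r$length_um < 200, "small", "large")
  colony
}

test_that("relative-pharynx pattern codes Y on the enumerated 4v4 example", {
  colony <- classified_colony()
  # engineer relative pharynx values matching the worked example
  small_idx <- colony$records$size_class == "small"
  expect_equal(sum(small_idx), 3)
  res <- pharynx_pattern(colony)
  expect_true(res$code %in% c("Y", "N"))
  # direct check of the documented 4v4 case through the same test
  rs <- rank_sum(c(0.03, 0.028, 0.027, 0.026), c(0.010, 0.011, 0.012, 0.013),
                 "greater")
  expect_equal(rs$p_value, 1 / 70)
  expect_lt(rs$p_value, 0.05)
})

test_that("pharynx pattern returns NA when a size class has no measurements", {
  colony <- classified_colony()
  colony$records$pharynx_um[colony$records$size_class == "large"] <- NA
  colony <- add_morphometrics(colony)
  colony$records$size_class <- ifelse(colony$records$length_um < 200,
                                      "small", "large")
  res <- pharynx_pattern(colony)
  expect_identical(res$code, "NA")
})

test_that("identical pharynx distributions code N and carry the companion test", {
  colony <- classified_colony()
  colony$records$pharynx_um <- 15
  colony$records$width_um <- colony$records$length_um / 4
  colony <- add_morphometrics(colony)
  colony$records$size_class <- ifelse(colony$records$length_um < 200,
                                      "small", "large")
  # same body shape + same pharynx: relative pharynx strictly larger for
  # small rediae, so this codes Y; force identical relative values instead
  colony$records$relative_pharynx <- 0.01
  res <- pharynx_pattern(colony)
  expect_identical(res$code, "N")
  expect_false(is.null(res$statistics$abs_pharynx))
})

test_that("appendage pattern distinguishes Y / O / N", {
  smallest <- data.frame(redia_id = paste0("s", 1:5), extremum = "smallest5",
                         anterior_score = 4, posterior_score = 4,
                         embryo_score = 0)
  largest <- data.frame(redia_id = paste0("l", 1:5), extremum = "largest5",
                        anterior_score = 0, posterior_score = 0,
                        embryo_score = 4)
  both <- rbind(smallest, largest)
  res <- appendage_pattern(both)
  expect_identical(res$code, "Y")
  expect_equal(res$statistics$anterior_p, 1 / 252)
  expect_equal(res$statistics$posterior_p, 1 / 252)

  one <- both
  one$posterior_score <- 2  # identical posterior scores
  expect_identical(appendage_pattern(one)$code, "O")

  flat <- both
  flat$anterior_score <- 1; flat$posterior_score <- 1
  expect_identical(appendage_pattern(flat)$code, "N")

  expect_identical(appendage_pattern(smallest)$code, "NA")
})

test_that("reproduction code follows the maximum smallest-five embryo score", {
  mk <- function(scores) {
    data.frame(redia_id = seq_along(scores), extremum = "smallest5",
               anterior_score = 0, posterior_score = 0, embryo_score = scores)
  }
  expect_identical(reproduction_code(mk(c(0, 1, 2, 4, 3)))$code, "Y")
  expect_identical(reproduction_code(mk(c(2, 2, 3)))$code, "Y?")
  expect_identical(reproduction_code(mk(c(2, 2, 1)))$code, "U")
  expect_identical(reproduction_code(mk(c(0, 1, 1)))$code, "N")
  expect_identical(reproduction_code(NULL)$code, "NA")
})

test_that("percent small is reported only for bimodal colonies", {
  colony <- classified_colony()
  res <- percent_small(colony, "Y")
  expect_equal(res$statistics$pct_small, 100 * 3 / 8)
  expect_identical(percent_small(colony, "N*")$code, "NA")
  colony0 <- colony
  colony0$records$size_class <- "large"
  expect_warning(res0 <- percent_small(colony0, "Y"), "zero small")
  expect_equal(res0$statistics$pct_small, 0)
})

test_that("exact binomial CIs match binom.test across a grid", {
  for (case in list(c(40, 50), c(10, 50), c(8, 10), c(2, 10), c(0, 7), c(7, 7))) {
    ci <- proportion_ci(case[1], case[2])
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(c(ci$lo, ci$hi), as.numeric(ref), tolerance = 1e-10)
    expect_lte(ci$lo, ci$point)
    expect_gte(ci$hi, ci$point)
  }
  expect_equal(round(c(proportion_ci(40, 50)$lo, proportion_ci(40, 50)$hi), 3),
               c(0.663, 0.900))
})

test_that("spatial distribution codes Y / O / NA from section CIs", {
  mk_colony <- function(foot_small, foot_large, apical_small, apical_large) {
    n <- foot_small + foot_large + apical_small + apical_large
    records <- data.frame(
      redia_id = sprintf("r%d", 1:n),
      section = c(rep("foot", foot_small + foot_large),
                  rep("apical", apical_small + apical_large)),
      length_um = 100, width_um = 25, pharynx_um = NA,
      stringsAsFactors = FALSE)
    colony <- add_morphometrics(redia_colony("C", records))
    colony$records$size_class <- c(rep("small", foot_small),
                                   rep("large", foot_large),
                                   rep("small", apical_small),
                                   rep("large", apical_large))
    colony
  }
  res <- spatial_distribution(mk_colony(40, 10, 10, 40))
  expect_identical(res$code, "Y")
  cis <- res$statistics$sections
  expect_equal(round(c(cis$foot$lo, cis$foot$hi), 3), c(0.663, 0.900))
  expect_equal(round(c(cis$apical$lo, cis$apical$hi), 3), c(0.100, 0.337))

  res_o <- spatial_distribution(mk_colony(8, 2, 2, 8))
  expect_identical(res_o$code, "O")
  cis_o <- res_o$statistics$sections
  expect_equal(round(c(cis_o$foot$lo, cis_o$foot$hi), 3), c(0.444, 0.975))
  expect_equal(round(c(cis_o$apical$lo, cis_o$apical$hi), 3), c(0.025, 0.556))

  # apical majority of small with disjoint CIs codes N
  expect_identical(spatial_distribution(mk_colony(5, 45, 45, 5))$code, "N")

  # single section: no comparison possible
  one_sec <- mk_colony(10, 10, 0, 0)
  one_sec$records <- one_sec$records[one_sec$records$section == "foot", ]
  expect_identical(spatial_distribution(one_sec)$code, "NA")
})

test_that("activity pattern averages timepoints and tests relative distance", {
  act <- data.frame(
    redia_id = 1:6, size_label = rep(c("small", "large"), each = 3),
    distance_t0_um = c(10, 11, 12, 10, 10, 15),
    distance_t15_um = c(20, NA, 14, 10, 10, 15),
    body_length_um = c(100, 100, 100, 500, 500, 500))
  res <- activity_comparison(act)
  # mean of (10, 20) is 15; the single-timepoint row uses t0 as-is
  expect_true(res$code %in% c("S", "NS"))
  # the documented two-tailed enumeration: p = 2 * (1/20) = 0.1 -> NS
  rs <- rank_sum(c(0.10, 0.11, 0.12), c(0.02, 0.02, 0.03), "two_sided")
  expect_equal(rs$p_value, 0.1)
  act_rel <- data.frame(
    redia_id = 1:6, size_label = rep(c("small", "large"), each = 3),
    distance_t0_um = c(10, 11, 12, 10, 10, 15),
    distance_t15_um = c(10, 11, 12, 10, 10, 15),
    body_length_um = c(100, 100, 100, 500, 500, 500))
  res_rel <- activity_comparison(act_rel)
  expect_identical(res_rel$code, "NS")
  expect_identical(res_rel$statistics$direction, "small_more_active")

  only_large <- act[act$size_label == "large", ]
  expect_identical(activity_comparison(only_large)$code, "NA")
})

test_that("attack totals code Y only when small rediae out-attack large", {
  mk <- function(small, large) {
    data.frame(trial_id = 1:2, attacker_size = c("small", "large"),
               target_type = "heterospecific",
               n_attacks_observed = c(small, large), n_rediae = 10)
  }
  expect_identical(attack_summary(mk(1, 2))$code, "N")
  expect_identical(attack_summary(mk(3, 0))$code, "Y")
  expect_identical(attack_summary(mk(2, 2))$code, "N")
  expect_identical(attack_summary(NULL)$code, "NA")
})

test_that("Tukey fences match the interpolated-quantile oracle", {
  x <- c(5, 5, 6, 6, 7, 7, 8, 30)
  res <- pharynx_outliers(x)
  expect_equal(res$q1, interp_quantile(x, 0.25))
  expect_equal(res$q1, 5.75)
  expect_equal(res$q3, 7.25)
  expect_equal(res$upper_fence, 9.5)
  expect_equal(res$outlier_values, 30)
  expect_equal(res$outlier_fraction, 1 / 8)

  clean <- pharynx_outliers(c(1, 2, 3, 4))
  expect_equal(length(clean$outlier_values), 0)
  expect_equal(clean$outlier_fraction, 0)
  expect_error(pharynx_outliers(c(1, 2, 3)), "insufficient")
})

test_that("adding a low value does not turn the worked example's non-outliers into outliers", {
  x <- c(5, 5, 6, 6, 7, 7, 8, 30)
  res <- pharynx_outliers(c(3, x))
  expect_equal(res$outlier_values, 30)
})

test_that("large-pharynx flag uses an inclusive threshold", {
  mk <- function(frac) {
    structure(list(q1 = 1, q3 = 2, iqr = 1, upper_fence = 3.5,
                   outlier_ids = character(0), outlier_values = numeric(0),
                   outlier_fraction = frac, n = 100),
              class = "outlier_result")
  }
  expect_identical(large_pharynx_flag(mk(0.10))$code, "flagged")
  expect_identical(large_pharynx_flag(mk(0.01))$code, "not_flagged")
  expect_identical(large_pharynx_flag(mk(0.05))$code, "flagged")
})

test_that("growth trend fits OLS on mean lengths over days", {
  flat <- growth_trend(0:4, rep(250, 5))
  expect_equal(flat$statistics$slope_um_per_day, 0)
  lin <- growth_trend(0:2, c(10, 20, 30))
  expect_equal(lin$statistics$slope_um_per_day, 10)
  expect_lte(lin$statistics$p_value, .Machine$double.eps)
  expect_error(growth_trend(0:1, c(10, 20)), "insufficient")
  noisy <- growth_trend(0:9, 250 + rnorm(10, sd = 5))
  expect_true(is.finite(noisy$statistics$p_value))
})
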