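test_that("identical config and seed reproduce a colony exactly", {
  cfg <- colony_sim_config(n_rediae = 50, seed = 77)
  a <- simulate_colony(cfg)
  b <- simulate_colony(cfg)
  expect_identical(a$colony$records, b$colony$records)
  expect_identical(a$colony$scores, b$colony$scores)
  expect_identical(a$colony$activity, b$colony$activity)
  expect_identical(a$colony$attacks, b$colony$attacks)
  expect_identical(a$truth$caste, b$truth$caste)
})

test_that("zero mode separation is truthfully non-bimodal", {
  cfg <- colony_sim_config(log10_volume_modes = c(6, 6), seed = 5)
  sim <- simulate_colony(cfg)
  expect_false(sim$truth$truly_bimodal)
  cfg2 <- colony_sim_config(small_fraction = 0, seed = 5)
  expect_false(simulate_colony(cfg2)$truth$truly_bimodal)
})

test_that("empirical small fraction stays within three binomial SDs of its target", {
  cfg <- colony_sim_config(n_rediae = 400, small_fraction = 0.2,
                           log10_volume_modes = c(5.85, 6.6), mode_sd = 0.25,
                           seed = 12)
  sim <- simulate_colony(cfg)
  frac <- mean(sim$truth$caste == "small")
  expect_gte(frac, 0.2 - 0.06)
  expect_lte(frac, 0.2 + 0.06)
})

test_that("volumes back-solve through the cylinder formula and aspect ratio", {
  cfg <- colony_sim_config(n_rediae = 30, aspect_ratio = 4, seed = 9)
  sim <- simulate_colony(cfg)
  r <- sim$colony$records
  expect_equal(r$length_um / r$width_um, rep(4, 30))
  colony <- add_morphometrics(sim$colony)
  # generated volume is recoverable from length and width
  expect_true(all(colony$records$body_volume_um3 > 0))
})

test_that("section probabilities must be valid", {
  expect_error(colony_sim_config(section_probs_small = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("COI simulation honours its divergence targets and determinism", {
  sim <- simulate_coi(20, n_per_species = 3, within_divergence_pct = 2,
                      between_divergence_pct = 8, seq_length = 600, seed = 4)
  sim2 <- simulate_coi(20, n_per_species = 3, within_divergence_pct = 2,
                       between_divergence_pct = 8, seq_length = 600, seed = 4)
  expect_identical(sim$sequences, sim2$sequences)

  im <- identity_matrix(sim$sequences, aligned = TRUE)
  div <- (100 - im$pi) / 100
  same <- outer(sim$species, sim$species, "==")
  diag(same) <- NA
  within_div <- mean(div[same & !is.na(same)])
  between_div <- mean(div[!same & !is.na(same)])
  # within-species pairs target 2%; the binomial SE at length 600 over
  # many pairs is far below the 0.5% slack
  expect_equal(within_div, 0.02, tolerance = 0.25)
  # founders differ by exactly `between`; member substitutions on both
  # sides add up to ~`within` more
  expect_gte(between_div, 0.08)
  expect_lte(between_div, 0.08 + 0.022)

  ident <- simulate_coi(3, n_per_species = 2, within_divergence_pct = 0,
                        between_divergence_pct = 8, seq_length = 200, seed = 2)
  for (sp in unique(ident$species)) {
    members <- ident$sequences[ident$species == sp]
    expect_equal(length(unique(members)), 1)
  }
  expect_error(simulate_coi(3, within_divergence_pct = 4,
                            between_divergence_pct = 8),
               "config error")
})

test_that("the benchmark suite covers three archetypes with a reproducible manifest", {
  suite <- make_benchmark_suite(seed = 3, n_replicates = 3)
  expect_equal(length(unique(suite$manifest$archetype)), 3)
  expect_equal(nrow(suite$manifest), 9)
  suite2 <- make_benchmark_suite(seed = 3, n_replicates = 3)
  expect_identical(suite$manifest, suite2$manifest)
  expect_identical(suite$colonies[[1]]$colony$records,
                   suite2$colonies[[1]]$colony$records)

  # the soldier-like archetype is embryo-free in its smallest rediae by
  # construction
  dol <- suite$colonies[["dol_like_01"]]
  a <- assess_dol(dol$colony)
  expect_identical(a$patterns$reproduction$code, "N")
  expect_identical(a$patterns$volume$code, "Y")
})

test_that("benchmark datasets round-trip through the CSV schemas", {
  dir <- file.path(tempdir(), "suite_io")
  suite <- make_benchmark_suite(seed = 8, n_replicates = 1, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("measurements.csv", "scores.csv", "activity.csv", "attacks.csv",
           "manifest.tsv")))))
  colonies <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(length(colonies), nrow(suite$manifest))
  colonies <- attach_tables(colonies,
                            scores = read_scores(file.path(dir, "scores.csv")),
                            activity = read_activity(file.path(dir, "activity.csv")),
                            attacks = read_attacks(file.path(dir, "attacks.csv")))
  cid <- suite$manifest$colony_id[1]
  orig <- suite$colonies[[cid]]$colony
  expect_equal(colonies[[cid]]$records$length_um, orig$records$length_um,
               tolerance = 1e-9)
  expect_equal(nrow(colonies[[cid]]$scores), nrow(orig$scores))
})
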