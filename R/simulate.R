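#' Synthetic colony configuration
#'
#' Encodes the generative structure the pattern battery assumes: a
#' two-component lognormal body-volume mixture (bimodal when the modes
#' are separated), power-law pharynx allometry with lognormal noise,
#' caste-biased multinomial placement across three snail body sections,
#' latent-logistic ordinal presence scores, lognormal 2-second movement
#' distances with a dissection-medium effect, Bernoulli attack outcomes,
#' and an optional large-pharynx subpopulation among the large caste.
#'
#' Defaults describe a typical freshwater colony: ~100 measured rediae,
#' log10 volume modes 5.6 and 6.6 (a small redia of roughly 400,000 um^3
#' and a large one of 4,000,000 um^3) with mode SD 0.25 (a 4-sigma
#' separation, clearly bimodal), 20% small caste, pharynx allometric
#' exponent 0.75 (small rediae carry relatively larger pharynges, the
#' commonly observed direction), aspect ratio 4 (length = 4 x width),
#' reproducing small rediae (embryo probability 0.9), appendages present
#' in both castes, mild anterior bias of the small caste, and 2-second
#' movement medians of 7 um (small) and 15 um (large) in water, doubled
#' in dilute saline. The movement scales are proportional to the caste
#' body-length ratio, so absolute distance differs by caste while
#' relative distance (distance / body length) does not - the typical
#' freshwater observation.
#'
#' @param n_rediae number of measured rediae (default 100).
#' @param log10_volume_modes means (log10 um^3) of the small and large
#'   mixture components, `c(mu1, mu2)` with `mu1 <= mu2`.
#' @param mode_sd common SD of the components (log10 scale).
#' @param small_fraction mixture weight of the small component.
#' @param allometric_exponent exponent b in pharynx diameter
#'   = a * length^b; b < 1 gives small rediae relatively larger
#'   pharynges, b = 1 is isometry.
#' @param allometric_intercept coefficient a (um^(1-b)); the default
#'   puts a ~20 um pharynx on a 500 um redia at b = 0.75.
#' @param pharynx_noise_sd SD of lognormal noise on pharynx diameter
#'   (natural-log scale).
#' @param aspect_ratio body length / width.
#' @param large_pharynx_fraction fraction of large-caste rediae whose
#'   pharynx diameter is multiplied by `large_pharynx_multiplier`.
#' @param large_pharynx_multiplier multiplier (> 1) for that subset.
#' @param section_probs_small,section_probs_large placement probabilities
#'   over `c(apical, mid, foot)` for each caste.
#' @param embryo_prob_small,embryo_prob_large probability that embryos
#'   are truly present/visible in a redia of each caste.
#' @param anterior_prob_small,anterior_prob_large,posterior_prob_small,posterior_prob_large
#'   analogous visibility probabilities for the appendages.
#' @param score_noise SD multiplier of the latent logistic blur behind
#'   the ordinal presence scores.
#' @param n_activity number of rediae per size label in activity trials.
#' @param activity_scale_small,activity_scale_large median 2-s movement
#'   distance (um) per caste in water.
#' @param activity_sdlog lognormal SD of movement distances.
#' @param saline_activity_multiplier factor applied to movement scales
#'   when the colony is dissected in dilute saline.
#' @param attack_prob_small,attack_prob_large per-redia attack
#'   probability in a trial, by attacker caste.
#' @param medium dissection medium, `"water"` or `"saline"`.
#' @param seed integer seed; identical config + seed reproduces the
#'   colony byte for byte.
#'
#' @return An object of class `colony_sim_config`.
#' @export
colony_sim_config <- function(n_rediae = 100,
                              log10_volume_modes = c(5.6, 6.6),
                              mode_sd = 0.25,
                              small_fraction = 0.2,
                              allometric_exponent = 0.75,
                              allometric_intercept = 20 / 500^0.75,
                              pharynx_noise_sd = 0.1,
                              aspect_ratio = 4,
                              large_pharynx_fraction = 0,
                              large_pharynx_multiplier = 2,
                              section_probs_small = c(0.2, 0.3, 0.5),
                              section_probs_large = c(0.6, 0.3, 0.1),
                              embryo_prob_small = 0.9,
                              embryo_prob_large = 0.98,
                              anterior_prob_small = 0.8,
                              anterior_prob_large = 0.8,
                              posterior_prob_small = 0.8,
                              posterior_prob_large = 0.8,
                              score_noise = 0.5,
                              n_activity = 10,
                              activity_scale_small = 7,
                              activity_scale_large = 15,
                              activity_sdlog = 0.5,
                              saline_activity_multiplier = 2,
                              attack_prob_small = 0.05,
                              attack_prob_large = 0.05,
                              medium = c("water", "saline"),
                              seed = 1L) {
  medium <- match.arg(medium)
  cfg <- as.list(environment())
  probs_ok <- function(p) length(p) == 3 && all(p >= 0) &&
    isTRUE(all.equal(sum(p), 1))
  if (!probs_ok(section_probs_small) || !probs_ok(section_probs_large)) {
    stop("section probabilities must be length-3 and sum to 1")
  }
  stopifnot(n_rediae >= 1,
            length(log10_volume_modes) == 2,
            log10_volume_modes[1] <= log10_volume_modes[2],
            mode_sd > 0,
            small_fraction >= 0, small_fraction <= 1,
            allometric_exponent > 0, allometric_intercept > 0,
            pharynx_noise_sd >= 0, aspect_ratio > 0,
            large_pharynx_fraction >= 0, large_pharynx_fraction <= 1,
            large_pharynx_multiplier > 1,
            score_noise >= 0,
            activity_scale_small > 0, activity_scale_large > 0,
            saline_activity_multiplier > 0,
            attack_prob_small >= 0, attack_prob_small <= 1,
            attack_prob_large >= 0, attack_prob_large <= 1)
  for (p in c("embryo_prob_small", "embryo_prob_large", "anterior_prob_small",
              "anterior_prob_large", "posterior_prob_small",
              "posterior_prob_large")) {
    stopifnot(cfg[[p]] >= 0, cfg[[p]] <= 1)
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "colony_sim_config")
}

# Ordinal 0-4 presence score from a latent logistic variable: the latent
# visibility is logit(p_true) plus logistic blur; fixed thresholds map it
# to the five categories.
ordinal_score <- function(p_true, score_noise, n) {
  p_true <- min(max(p_true, 1e-6), 1 - 1e-6)
  latent <- stats::qlogis(p_true) + score_noise * stats::rlogis(n)
  findInterval(latent, c(-2, -1, 1, 2))
}

#' Simulate one redia colony with ground truth
#'
#' Draws log10 body volumes from the two-component normal mixture,
#' back-solves length and width from volume via the cylinder formula and
#' the fixed aspect ratio, attaches pharynx diameters from the allometric
#' power law with lognormal noise (inflated for the large-pharynx subset
#' of large-caste rediae), places rediae in body sections per caste,
#' scores the five smallest and five largest for appendages and embryos,
#' and generates activity and attack-trial tables. The returned truth
#' carries the generating caste of every redia and colony-level flags.
#'
#' @param config a [colony_sim_config()].
#' @param colony_id identifier for the simulated colony.
#' @return List with `colony` (a [redia_colony()]) and `truth` (class
#'   `sim_truth`: `caste` named by redia id, `truly_bimodal`,
#'   `has_large_pharynx_subpop`, `large_pharynx_ids`, `config`).
#' @export
simulate_colony <- function(config = colony_sim_config(), colony_id = "SIM1") {
  stopifnot(inherits(config, "colony_sim_config"))
  set.seed(config$seed)
  n <- config$n_rediae
  caste <- ifelse(stats::runif(n) < config$small_fraction, "small", "large")
  mu <- ifelse(caste == "small", config$log10_volume_modes[1],
               config$log10_volume_modes[2])
  log10_vol <- stats::rnorm(n, mu, config$mode_sd)
  volume <- 10^log10_vol
  # V = pi * (w/2)^2 * L with w = L / aspect  =>  L = (4 a^2 V / pi)^(1/3)
  length_um <- (4 * config$aspect_ratio^2 * volume / pi)^(1 / 3)
  width_um <- length_um / config$aspect_ratio

  pharynx <- config$allometric_intercept * length_um^config$allometric_exponent *
    exp(stats::rnorm(n, 0, config$pharynx_noise_sd))
  lp_ids <- character(0)
  if (config$large_pharynx_fraction > 0) {
    large_idx <- which(caste == "large")
    n_lp <- round(config$large_pharynx_fraction * length(large_idx))
    if (n_lp > 0) {
      pick <- sample(large_idx, n_lp)
      pharynx[pick] <- pharynx[pick] * config$large_pharynx_multiplier
      lp_ids <- sprintf("%s_r%03d", colony_id, pick)
    }
  }

  sections <- c("apical", "mid", "foot")
  section <- character(n)
  is_small <- caste == "small"
  section[is_small] <- sample(sections, sum(is_small), replace = TRUE,
                              prob = config$section_probs_small)
  section[!is_small] <- sample(sections, sum(!is_small), replace = TRUE,
                               prob = config$section_probs_large)

  redia_id <- sprintf("%s_r%03d", colony_id, seq_len(n))
  records <- data.frame(redia_id = redia_id, section = section,
                        length_um = length_um, width_um = width_um,
                        pharynx_um = pharynx, stringsAsFactors = FALSE)

  ord <- order(volume)
  smallest5 <- ord[seq_len(min(5, n))]
  largest5 <- rev(ord)[seq_len(min(5, n))]
  score_group <- function(idx, tag) {
    caste_p <- function(p_small, p_large) {
      ifelse(caste[idx] == "small", p_small, p_large)
    }
    data.frame(
      redia_id = redia_id[idx], extremum = tag,
      anterior_score = vapply(caste_p(config$anterior_prob_small,
                                      config$anterior_prob_large),
                              ordinal_score, integer(1),
                              score_noise = config$score_noise, n = 1),
      posterior_score = vapply(caste_p(config$posterior_prob_small,
                                       config$posterior_prob_large),
                               ordinal_score, integer(1),
                               score_noise = config$score_noise, n = 1),
      embryo_score = vapply(caste_p(config$embryo_prob_small,
                                    config$embryo_prob_large),
                            ordinal_score, integer(1),
                            score_noise = config$score_noise, n = 1),
      stringsAsFactors = FALSE)
  }
  scores <- rbind(score_group(smallest5, "smallest5"),
                  score_group(largest5, "largest5"))

  mult <- if (config$medium == "saline") config$saline_activity_multiplier else 1
  act_one <- function(label, scale, body_mu) {
    k <- config$n_activity
    data.frame(
      redia_id = sprintf("%s_act_%s%02d", colony_id, label, seq_len(k)),
      size_label = label,
      distance_t0_um = stats::rlnorm(k, log(scale * mult), config$activity_sdlog),
      distance_t15_um = stats::rlnorm(k, log(scale * mult), config$activity_sdlog),
      body_length_um = stats::rlnorm(k, log(body_mu), config$mode_sd * log(10) / 3),
      stringsAsFactors = FALSE)
  }
  body_len_small <- (4 * config$aspect_ratio^2 *
                       10^config$log10_volume_modes[1] / pi)^(1 / 3)
  body_len_large <- (4 * config$aspect_ratio^2 *
                       10^config$log10_volume_modes[2] / pi)^(1 / 3)
  activity <- rbind(act_one("small", config$activity_scale_small, body_len_small),
                    act_one("large", config$activity_scale_large, body_len_large))

  targets <- c("colony_mate", "conspecific", "heterospecific")
  attack_rows <- expand.grid(attacker_size = c("small", "large"),
                             target_type = targets,
                             stringsAsFactors = FALSE)
  attack_rows$trial_id <- sprintf("%s_t%02d", colony_id, seq_len(nrow(attack_rows)))
  attack_rows$n_rediae <- 10L
  p_attack <- ifelse(attack_rows$attacker_size == "small",
                     config$attack_prob_small, config$attack_prob_large)
  attack_rows$n_attacks_observed <- stats::rbinom(nrow(attack_rows), 10L, p_attack)

  colony <- redia_colony(colony_id, records, scores = scores,
                         activity = activity,
                         attacks = attack_rows[c("trial_id", "attacker_size",
                                                 "target_type",
                                                 "n_attacks_observed",
                                                 "n_rediae")],
                         dissection_medium = config$medium)
  truth <- structure(list(
    caste = stats::setNames(caste, redia_id),
    truly_bimodal = diff(config$log10_volume_modes) > 0 &&
      config$small_fraction > 0 && config$small_fraction < 1,
    has_large_pharynx_subpop = config$large_pharynx_fraction > 0,
    large_pharynx_ids = lp_ids,
    config = config), class = "sim_truth")
  list(colony = colony, truth = truth)
}

#' Simulate COI barcode sets with known species structure
#'
#' One random ancestor is drawn per run; each species founder carries a
#' fixed number of substitutions, `round(between/2/100 * L)`, at
#' diagnostic sites drawn without replacement from a shared site pool so
#' the substitutions of different species are disjoint while the pool
#' lasts. Every member sequence then accumulates
#' Binomial(L, within/2/100) substitutions at uniformly random sites.
#' Under this model the observed pairwise divergence is approximately
#' `within_divergence_pct` inside a species and
#' `between_divergence_pct + within_divergence_pct` across species
#' (founders differ by `between_divergence_pct` exactly, and the member
#' substitutions on both sides add on top). Substitutions are uniform
#' over the three alternative bases.
#'
#' @param n_species number of species.
#' @param n_per_species member sequences per species.
#' @param within_divergence_pct target pairwise divergence within a
#'   species (percent).
#' @param between_divergence_pct target pairwise divergence between
#'   species founders (percent); must exceed twice the within divergence.
#' @param seq_length sequence length (>= 100).
#' @param seed integer seed.
#' @return List with `sequences` (named character vector, ids
#'   `SPP<species>_<member>`) and `species` (named character vector of
#'   true species labels).
#' @export
simulate_coi <- function(n_species, n_per_species = 3,
                         within_divergence_pct = 2,
                         between_divergence_pct = 8,
                         seq_length = 600, seed = 1L) {
  if (between_divergence_pct <= 2 * within_divergence_pct) {
    stop("config error: between divergence must exceed twice the within divergence")
  }
  stopifnot(seq_length >= 100, n_species >= 1, n_per_species >= 1)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, seq_length, replace = TRUE)
  mutate_at <- function(seq, sites) {
    for (s in sites) {
      seq[s] <- sample(setdiff(bases, seq[s]), 1)
    }
    seq
  }
  m_founder <- round(between_divergence_pct / 2 / 100 * seq_length)
  pool <- sample(seq_length)  # shared diagnostic-site pool
  sequences <- character(0)
  species <- character(0)
  used <- 0
  for (sp in seq_len(n_species)) {
    if (used + m_founder <= seq_length) {
      sites <- pool[(used + 1):(used + m_founder)]
      used <- used + m_founder
    } else {
      sites <- sample(seq_length, m_founder)
    }
    founder <- mutate_at(ancestor, sites)
    for (mem in seq_len(n_per_species)) {
      k <- stats::rbinom(1, seq_length, within_divergence_pct / 2 / 100)
      member <- mutate_at(founder, sample(seq_length, k))
      id <- sprintf("SPP%02d_%02d", sp, mem)
      sequences[id] <- paste(member, collapse = "")
      species[id] <- sprintf("SPP%02d", sp)
    }
  }
  list(sequences = sequences, species = species)
}

#' Generate the benchmark battery of archetype colonies
#'
#' Three archetypes, each replicated with distinct seeds and full ground
#' truth, spanning the qualitative outcomes the battery distinguishes:
#'
#' * `dol_like` - marine-soldier-like: strongly bimodal volumes,
#'   embryo-free small caste with pronounced appendages and relatively
#'   large pharynges, small rediae concentrated in the head/foot, more
#'   active and more aggressive; expected codes Volume=Y, Reproduction=N,
#'   Morphology=Y.
#' * `freshwater_like` - overlapping sizes (non-normal but not clearly
#'   bimodal), reproducing small rediae, appendages in both castes,
#'   relative-pharynx advantage for small rediae, and a 10% large-pharynx
#'   subpopulation.
#' * `null_colony` - a single lognormal component, isometric pharynges,
#'   no caste structure at all.
#'
#' @param seed integer master seed; replicate seeds derive from it.
#' @param n_replicates replicates per archetype (default 10).
#' @param dir optional directory; when given, measurement/score/activity/
#'   attack CSVs and a manifest TSV are written there.
#' @return List of class `benchmark_suite`: `colonies` (list of
#'   simulate_colony outputs), `manifest` (data frame with archetype,
#'   colony id, seed, expected codes).
#' @export
make_benchmark_suite <- function(seed = 1L, n_replicates = 10, dir = NULL) {
  stopifnot(n_replicates >= 1)
  base <- as.integer(seed)
  archetypes <- list(
    dol_like = list(
      config = function(s) colony_sim_config(
        n_rediae = 150, log10_volume_modes = c(5.4, 6.8), mode_sd = 0.2,
        small_fraction = 0.3, allometric_exponent = 0.7,
        embryo_prob_small = 0.02, embryo_prob_large = 0.98,
        anterior_prob_small = 0.95, anterior_prob_large = 0.05,
        posterior_prob_small = 0.95, posterior_prob_large = 0.05,
        section_probs_small = c(0.1, 0.3, 0.6),
        section_probs_large = c(0.7, 0.2, 0.1),
        activity_scale_small = 20, activity_scale_large = 5,
        attack_prob_small = 0.4, attack_prob_large = 0.02,
        medium = "saline", seed = s),
      expected = c(Volume = "Y", Reproduction = "N", Morphology = "Y",
                   Pharynx = "Y")),
    freshwater_like = list(
      config = function(s) colony_sim_config(
        n_rediae = 100, log10_volume_modes = c(5.8, 6.4), mode_sd = 0.25,
        small_fraction = 0.35, allometric_exponent = 0.75,
        embryo_prob_small = 0.9, embryo_prob_large = 0.98,
        large_pharynx_fraction = 0.1, large_pharynx_multiplier = 2,
        medium = "saline", seed = s),
      expected = c(Reproduction = "Y", Morphology = "N", Pharynx = "Y",
                   LargePharynx = "flagged")),
    null_colony = list(
      config = function(s) colony_sim_config(
        n_rediae = 100, log10_volume_modes = c(6.1, 6.1), mode_sd = 0.25,
        small_fraction = 0, allometric_exponent = 1,
        section_probs_small = c(1 / 3, 1 / 3, 1 / 3),
        section_probs_large = c(1 / 3, 1 / 3, 1 / 3),
        medium = "saline", seed = s),
      expected = c(Volume = "N", Pharynx = "N"))
  )
  colonies <- list()
  manifest <- list()
  k <- 0
  for (arch in names(archetypes)) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1
      s <- base + 1000L * k
      cid <- sprintf("%s_%02d", arch, rep_i)
      sim <- simulate_colony(archetypes[[arch]]$config(s), colony_id = cid)
      colonies[[cid]] <- sim
      manifest[[cid]] <- data.frame(
        colony_id = cid, archetype = arch, seed = s,
        expected = paste(names(archetypes[[arch]]$expected),
                         archetypes[[arch]]$expected,
                         sep = "=", collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  suite <- structure(list(colonies = colonies, manifest = manifest,
                          master_seed = base),
                     class = "benchmark_suite")
  if (!is.null(dir)) write_benchmark_suite(suite, dir)
  suite
}

write_benchmark_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bind_with_id <- function(field) {
    do.call(rbind, lapply(suite$colonies, function(sim) {
      tab <- sim$colony[[field]]
      if (is.null(tab)) return(NULL)
      cbind(colony_id = sim$colony$colony_id, tab)
    }))
  }
  meas <- do.call(rbind, lapply(suite$colonies, function(sim) {
    r <- sim$colony$records[c("redia_id", "section", "length_um", "width_um",
                              "pharynx_um")]
    cbind(colony_id = sim$colony$colony_id,
          dissection_medium = sim$colony$dissection_medium, r)
  }))
  utils::write.csv(meas, file.path(dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(bind_with_id("scores"), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_with_id("activity"), file.path(dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_with_id("attacks"), file.path(dir, "attacks.csv"),
                   row.names = FALSE)
  utils::write.table(suite$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
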