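#' Colony container
#'
#' A `redia_colony` holds every observation made on the clonal trematode
#' population of one infected snail: per-redia measurements, ordinal
#' presence scores for the five smallest and five largest rediae, paired
#' 2-second movement distances, and attack-trial counts. All linear
#' dimensions are micrometres; volumes are cubic micrometres.
#'
#' @param colony_id unique colony identifier (character scalar).
#' @param records data frame of per-redia measurements with columns
#'   `redia_id`, `section` (one of `"apical"`, `"mid"`, `"foot"`,
#'   `"unknown"`), `length_um`, `width_um`, `pharynx_um` (NA allowed),
#'   and optionally `excluded` (logical) and `exclusion_reason`.
#' @param scores optional data frame with columns `redia_id`, `extremum`
#'   (`"smallest5"` or `"largest5"`), `anterior_score`, `posterior_score`,
#'   `embryo_score` (integers 0-4, NA allowed).
#' @param activity optional data frame with columns `redia_id`,
#'   `size_label` (`"small"`/`"large"`), `distance_t0_um`,
#'   `distance_t15_um` (NA allowed), `body_length_um`.
#' @param attacks optional data frame with columns `trial_id`,
#'   `attacker_size` (`"small"`/`"large"`), `target_type` (`"colony_mate"`,
#'   `"conspecific"`, `"heterospecific"`), `n_attacks_observed`, `n_rediae`.
#' @param coi_species optional species label from COI clustering.
#' @param snail_family optional snail host family.
#' @param dissection_medium `"water"` or `"saline"`.
#'
#' @return An object of class `redia_colony`.
#' @export
redia_colony <- function(colony_id, records,
                         scores = NULL, activity = NULL, attacks = NULL,
                         coi_species = NA_character_,
                         snail_family = NA_character_,
                         dissection_medium = c("water", "saline")) {
  dissection_medium <- match.arg(dissection_medium)
  stopifnot(is.character(colony_id), length(colony_id) == 1, nzchar(colony_id))
  records <- normalize_records(records)
  if (!is.null(scores)) scores <- normalize_scores(scores)
  if (!is.null(activity)) activity <- normalize_activity(activity)
  if (!is.null(attacks)) attacks <- normalize_attacks(attacks)
  fam_levels <- c("Hydrobiidae", "Physidae", "Planorbidae", "Viviparidae",
                  "Lymnaidae", "Valvatidae")
  if (!is.na(snail_family) && !snail_family %in% fam_levels) {
    stop("unknown snail_family: ", snail_family)
  }
  structure(
    list(colony_id = colony_id, coi_species = coi_species,
         snail_family = snail_family, dissection_medium = dissection_medium,
         records = records, scores = scores, activity = activity,
         attacks = attacks),
    class = "redia_colony"
  )
}

section_levels <- function() c("apical", "mid", "foot", "unknown")

normalize_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("redia_id", "section", "length_um", "width_um", "pharynx_um")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$redia_id <- as.character(records$redia_id)
  # "gonad" is the digestive-gland region; accepted as an alias of apical
  records$section <- ifelse(records$section %in% c("gonad", "Gonad"),
                            "apical", as.character(records$section))
  records$section[is.na(records$section) | records$section == ""] <- "unknown"
  bad <- !records$section %in% section_levels()
  if (any(bad)) {
    stop("unknown section value(s): ",
         paste(unique(records$section[bad]), collapse = ", "))
  }
  for (col in c("length_um", "width_um", "pharynx_um")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (is.null(records$excluded)) records$excluded <- FALSE
  records$excluded <- isTRUE_vec(records$excluded)
  if (is.null(records$exclusion_reason)) {
    records$exclusion_reason <- NA_character_
  }
  if (any(records$excluded & is.na(records$exclusion_reason))) {
    records$exclusion_reason[records$excluded &
                               is.na(records$exclusion_reason)] <- "unspecified"
  }
  ok <- !records$excluded
  if (any(ok & (!is.na(records$length_um) & records$length_um <= 0), na.rm = TRUE) ||
      any(ok & (!is.na(records$width_um) & records$width_um <= 0), na.rm = TRUE)) {
    stop("length_um and width_um must be positive for non-excluded records")
  }
  if (any(!is.na(records$pharynx_um) & records$pharynx_um <= 0)) {
    stop("pharynx_um must be positive when present")
  }
  if (anyDuplicated(records$redia_id)) {
    stop("duplicate redia_id in records: ",
         records$redia_id[duplicated(records$redia_id)][1])
  }
  if (is.null(records$size_class)) records$size_class <- "unassigned"
  rownames(records) <- NULL
  records
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y")
}

normalize_scores <- function(scores) {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  required <- c("redia_id", "extremum", "anterior_score", "posterior_score",
                "embryo_score")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols)) {
    stop("scores missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(scores$extremum %in% c("smallest5", "largest5")))
  for (col in c("anterior_score", "posterior_score", "embryo_score")) {
    scores[[col]] <- as.integer(scores[[col]])
    bad <- !is.na(scores[[col]]) & !scores[[col]] %in% 0:4
    if (any(bad)) stop(col, " must be an integer 0-4")
  }
  rownames(scores) <- NULL
  scores
}

normalize_activity <- function(activity) {
  activity <- as.data.frame(activity, stringsAsFactors = FALSE)
  required <- c("redia_id", "size_label", "distance_t0_um", "distance_t15_um",
                "body_length_um")
  missing_cols <- setdiff(required, names(activity))
  if (length(missing_cols)) {
    stop("activity missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(activity$size_label %in% c("small", "large")))
  for (col in c("distance_t0_um", "distance_t15_um", "body_length_um")) {
    activity[[col]] <- as.numeric(activity[[col]])
  }
  if (any(activity$distance_t0_um < 0, na.rm = TRUE) ||
      any(activity$distance_t15_um < 0, na.rm = TRUE)) {
    stop("movement distances must be nonnegative")
  }
  if (any(is.na(activity$body_length_um) | activity$body_length_um <= 0)) {
    stop("body_length_um must be positive")
  }
  rownames(activity) <- NULL
  activity
}

normalize_attacks <- function(attacks) {
  attacks <- as.data.frame(attacks, stringsAsFactors = FALSE)
  required <- c("trial_id", "attacker_size", "target_type",
                "n_attacks_observed", "n_rediae")
  missing_cols <- setdiff(required, names(attacks))
  if (length(missing_cols)) {
    stop("attacks missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(attacks$attacker_size %in% c("small", "large")),
            all(attacks$target_type %in%
                  c("colony_mate", "conspecific", "heterospecific")))
  attacks$n_attacks_observed <- as.integer(attacks$n_attacks_observed)
  attacks$n_rediae <- as.integer(attacks$n_rediae)
  if (any(attacks$n_attacks_observed < 0) || any(attacks$n_rediae <= 0)) {
    stop("attack counts must be nonnegative and n_rediae positive")
  }
  if (any(attacks$n_attacks_observed > attacks$n_rediae)) {
    stop("n_attacks_observed cannot exceed n_rediae")
  }
  rownames(attacks) <- NULL
  attacks
}

#' @export
print.redia_colony <- function(x, ...) {
  cat(sprintf("<redia_colony> %s (%s dissection)\n",
              x$colony_id, x$dissection_medium))
  if (!is.na(x$coi_species)) cat("  COI species:", x$coi_species, "\n")
  n_ex <- sum(x$records$excluded)
  cat(sprintf("  %d rediae measured (%d excluded)\n", nrow(x$records), n_ex))
  if (!is.null(x$scores)) cat(sprintf("  %d presence-score rows\n", nrow(x$scores)))
  if (!is.null(x$activity)) cat(sprintf("  %d activity rows\n", nrow(x$activity)))
  if (!is.null(x$attacks)) cat(sprintf("  %d attack trials\n", nrow(x$attacks)))
  invisible(x)
}

# Records usable for analysis: measured and not excluded.
analysis_records <- function(colony) {
  r <- colony$records
  r[!r$excluded & !is.na(r$length_um) & !is.na(r$width_um), , drop = FALSE]
}
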