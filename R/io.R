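#' Read a per-redia measurement CSV into colonies
#'
#' The file must be comma-separated UTF-8 with a header containing at
#' least `colony_id`, `redia_id`, `section`, `length_um`, `width_um`,
#' `pharynx_um`. Optional columns: `excluded` (logical), `exclusion_reason`,
#' `dissection_medium`, `snail_family`, `coi_species`. Missing values are
#' empty cells, never 0 or -1; a blank `pharynx_um` loads as `NA`.
#' `"gonad"` is accepted as an alias for the `apical` section. Rows are
#' never silently dropped: excluded rows load with `excluded = TRUE`.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping the required
#'   canonical names to the file's actual column names, e.g.
#'   `c(length_um = "Length")`, for externally deposited tables whose
#'   headers differ.
#' @return Named list of [redia_colony()] objects, one per distinct
#'   `colony_id`, in file order of first appearance.
#' @export
read_measurements <- function(path, column_map = NULL) {
  df <- read_checked_csv(path)
  df <- apply_column_map(df, column_map)
  required <- c("colony_id", "redia_id", "section", "length_um", "width_um",
                "pharynx_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("measurement file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("length_um", "width_um", "pharynx_um")) {
    df[[col]] <- parse_numeric_column(df[[col]], col)
  }
  split_colonies(df)
}

read_checked_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("empty file: ", path)
  df
}

apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  stopifnot(!is.null(names(column_map)))
  for (canonical in names(column_map)) {
    actual <- column_map[[canonical]]
    if (!actual %in% names(df)) {
      stop("column_map names missing column '", actual, "' in file")
    }
    names(df)[names(df) == actual] <- canonical
  }
  df
}

parse_numeric_column <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column %s at row %d",
                 x[bad[1]], col, bad[1]))
  }
  out
}

split_colonies <- function(df) {
  ids <- unique(df$colony_id)
  out <- lapply(ids, function(cid) {
    sub <- df[df$colony_id == cid, , drop = FALSE]
    medium <- if ("dissection_medium" %in% names(sub) &&
                  !is.na(sub$dissection_medium[1])) {
      sub$dissection_medium[1]
    } else "water"
    fam <- if ("snail_family" %in% names(sub)) sub$snail_family[1] else NA_character_
    sp <- if ("coi_species" %in% names(sub)) sub$coi_species[1] else NA_character_
    keep <- setdiff(names(sub), c("colony_id", "dissection_medium",
                                  "snail_family", "coi_species"))
    redia_colony(as.character(cid), sub[keep],
                 coi_species = sp, snail_family = fam,
                 dissection_medium = medium)
  })
  names(out) <- as.character(ids)
  out
}

#' Read presence-score, activity and attack CSVs
#'
#' Companion tables keyed by `colony_id`; see [redia_colony()] for the
#' required columns of each. Each reader returns a named list of data
#' frames, one per colony.
#'
#' @param path CSV file path.
#' @return Named list of data frames keyed by colony id.
#' @export
read_scores <- function(path) {
  df <- read_checked_csv(path)
  need <- c("colony_id", "redia_id", "extremum", "anterior_score",
            "posterior_score", "embryo_score")
  check_columns(df, need, path)
  split(df[setdiff(names(df), "colony_id")], df$colony_id)
}

#' @rdname read_scores
#' @export
read_activity <- function(path) {
  df <- read_checked_csv(path)
  need <- c("colony_id", "redia_id", "size_label", "distance_t0_um",
            "distance_t15_um", "body_length_um")
  check_columns(df, need, path)
  for (col in c("distance_t0_um", "distance_t15_um", "body_length_um")) {
    df[[col]] <- parse_numeric_column(df[[col]], col)
  }
  split(df[setdiff(names(df), "colony_id")], df$colony_id)
}

#' @rdname read_scores
#' @export
read_attacks <- function(path) {
  df <- read_checked_csv(path)
  need <- c("colony_id", "trial_id", "attacker_size", "target_type",
            "n_attacks_observed", "n_rediae")
  check_columns(df, need, path)
  split(df[setdiff(names(df), "colony_id")], df$colony_id)
}

check_columns <- function(df, need, path) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(basename(path), " missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

#' Attach companion tables to colonies
#'
#' @param colonies named list of [redia_colony()]s.
#' @param scores,activity,attacks named lists of data frames keyed by
#'   colony id, as returned by the companion readers.
#' @return The colonies with tables attached where ids match.
#' @export
attach_tables <- function(colonies, scores = NULL, activity = NULL,
                          attacks = NULL) {
  for (cid in names(colonies)) {
    if (!is.null(scores) && cid %in% names(scores)) {
      colonies[[cid]]$scores <- normalize_scores(scores[[cid]])
    }
    if (!is.null(activity) && cid %in% names(activity)) {
      colonies[[cid]]$activity <- normalize_activity(activity[[cid]])
    }
    if (!is.null(attacks) && cid %in% names(attacks)) {
      colonies[[cid]]$attacks <- normalize_attacks(attacks[[cid]])
    }
  }
  colonies
}

#' Read / write nucleotide FASTA
#'
#' Thin wrappers around Biostrings that preserve file order, uppercase
#' the sequences, retain gap characters (aligned FASTA is allowed) and
#' reject duplicate identifiers. The alphabet is `{A, C, G, T, N, -}`.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of uppercased
#'   sequences in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) && !startsWith(trimws(first), ">")) {
    stop("FASTA format error: sequence data before any '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("invalid character in sequence '", ids[bad][1],
         "' (alphabet is A/C/G/T/N/-)")
  }
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
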