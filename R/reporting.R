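#' Summarize a colony assessment into one report row
#'
#' One row with the colony's code for each of the eight pattern columns
#' (Volume, Reproduction, Morphology, Pharynx, %Small, Distribution,
#' Activity, Attacks). `%Small` is rendered as an integer percent or NA.
#'
#' @param assessment a [assess_dol()] result, or a named list of
#'   `pattern_result`s covering every pattern.
#' @return A one-row data frame of class `colony_summary`.
#' @export
summarize_colony <- function(assessment) {
  if (inherits(assessment, "dol_assessment")) {
    patterns <- assessment$patterns
    colony <- assessment$colony
    meta <- data.frame(colony_id = colony$colony_id,
                       coi_species = colony$coi_species,
                       dissection_medium = colony$dissection_medium,
                       stringsAsFactors = FALSE)
  } else {
    patterns <- assessment
    meta <- data.frame(colony_id = NA_character_,
                       coi_species = NA_character_,
                       dissection_medium = NA_character_,
                       stringsAsFactors = FALSE)
  }
  needed <- c("volume", "reproduction", "morphology", "pharynx",
              "pct_small", "distribution", "activity", "attacks")
  for (p in needed) {
    if (is.null(patterns[[p]])) stop("missing pattern result: ", p)
  }
  codes <- vapply(needed, function(p) patterns[[p]]$code, character(1))
  row <- cbind(meta, as.data.frame(as.list(codes), stringsAsFactors = FALSE))
  names(row) <- c("colony_id", "coi_species", "dissection_medium",
                  "Volume", "Reproduction", "Morphology", "Pharynx",
                  "PctSmall", "Distribution", "Activity", "Attacks")
  class(row) <- c("colony_summary", "data.frame")
  row
}

#' Summarize many assessments
#'
#' @param assessments list of [assess_dol()] results.
#' @return Data frame with one row per colony.
#' @export
summarize_colonies <- function(assessments) {
  rows <- lapply(assessments, summarize_colony)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pattern_columns <- function() {
  c("Volume", "Reproduction", "Morphology", "Pharynx", "PctSmall",
    "Distribution", "Activity", "Attacks")
}

code_vocabulary <- function() {
  list(Volume = c("Y", "N*", "N", "NA"),
       Reproduction = c("Y", "Y?", "U", "N", "NA"),
       Morphology = c("Y", "O", "N", "NA"),
       Pharynx = c("Y", "N", "NA"),
       Distribution = c("Y", "O", "N", "NA"),
       Activity = c("S", "NS", "NA"),
       Attacks = c("Y", "N", "NA"))
}

format_code_counts <- function(codes, vocab) {
  codes[is.na(codes)] <- "NA"
  counts <- table(factor(codes, levels = vocab))
  parts <- sprintf("%d%s", counts, names(counts))[counts > 0]
  paste(parts, collapse = "/")
}

format_pct_range <- function(pcts) {
  vals <- suppressWarnings(as.numeric(sub("%", "", pcts)))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return("NA")
  lo <- round(min(vals)); hi <- round(max(vals))
  if (lo == hi) sprintf("%d%%", lo) else sprintf("%d-%d%%", lo, hi)
}

#' Aggregate colony summaries into species and overall rows
#'
#' Per group (COI species x dissection medium, plus an overall `All`
#' row), counts of each code per pattern column are formatted as
#' `"4Y"` / `"1Y/2N*"` strings in fixed vocabulary order, omitting
#' zero-count codes; the `%Small` column is aggregated as a percent
#' range. Column-wise counts in every row sum to the group size.
#'
#' @param summaries data frame from [summarize_colonies()].
#' @param group_by `"species_medium"` (default) or `"all"`.
#' @return Data frame with `group_label`, `n_colonies` and one count
#'   string per pattern column.
#' @export
aggregate_summaries <- function(summaries, group_by = c("species_medium", "all")) {
  group_by <- match.arg(group_by)
  stopifnot(nrow(summaries) >= 1)
  vocab <- code_vocabulary()
  make_row <- function(label, sub) {
    counts <- lapply(pattern_columns(), function(col) {
      if (col == "PctSmall") format_pct_range(sub[[col]])
      else format_code_counts(sub[[col]], vocab[[col]])
    })
    out <- data.frame(group_label = label, n_colonies = nrow(sub),
                      stringsAsFactors = FALSE)
    out[pattern_columns()] <- counts
    out
  }
  rows <- list()
  if (group_by == "species_medium") {
    sp <- ifelse(is.na(summaries$coi_species), "Unknown", summaries$coi_species)
    med <- substr(summaries$dissection_medium, 1, 1)
    key <- sprintf("%s (%s)", sp, med)
    for (k in unique(key)) {
      rows[[k]] <- make_row(k, summaries[key == k, , drop = FALSE])
    }
  }
  rows[["All"]] <- make_row("All", summaries)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the pattern report TSV
#'
#' One row per colony followed by per-(species x medium) aggregate rows
#' and an `All` row, with a fixed column order. `read_report()` is the
#' round-trip companion.
#'
#' @param summaries data frame from [summarize_colonies()] (may have zero
#'   rows, giving a header-only colony section).
#' @param path output TSV path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a list with `colonies` and `aggregates` data frames.
#' @export
write_report <- function(summaries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("colony_id", "coi_species", "dissection_medium", pattern_columns())
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(summaries)) {
    body <- summaries[cols]
    body[] <- lapply(body, function(x) ifelse(is.na(x), "NA", as.character(x)))
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    agg <- aggregate_summaries(summaries)
    writeLines("", con)
    agg_cols <- c("group_label", "n_colonies", pattern_columns())
    writeLines(paste(agg_cols, collapse = "\t"), con)
    utils::write.table(agg[agg_cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")
  parse_block <- function(block_lines) {
    if (length(block_lines) < 1) return(NULL)
    utils::read.delim(text = paste(block_lines, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = character(0))
  }
  if (length(blank)) {
    colonies <- parse_block(lines[1:(blank[1] - 1)])
    aggregates <- parse_block(lines[(blank[1] + 1):length(lines)])
  } else {
    colonies <- parse_block(lines)
    aggregates <- NULL
  }
  list(colonies = colonies, aggregates = aggregates)
}

#' Serialize assessments to a machine-readable JSON bundle
#'
#' Per colony and per pattern: the code, the stored p-values and
#' supporting statistics.
#'
#' @param assessments list of [assess_dol()] results.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(assessments, path) {
  payload <- lapply(assessments, function(a) {
    pats <- lapply(a$patterns, function(p) {
      stats <- p$statistics
      stats <- stats[!vapply(stats, is.list, logical(1))]
      stats <- stats[!vapply(stats, function(s) inherits(s, "rank_sum_result"),
                             logical(1))]
      list(code = p$code, statistics = stats, notes = p$notes)
    })
    list(colony_id = a$colony$colony_id,
         dissection_medium = a$colony$dissection_medium,
         size_designation_method = a$bimodality$method,
         patterns = pats)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
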