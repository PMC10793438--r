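# Tab-separated table formats and schema validation.
#
# Count tables are TSV with the columns below, UTF-8, "." for missing.

count_table_columns <- c("library_id", "replicate_id", "residue_index",
                         "ref_aa", "alt_aa", "count_day9", "count_confluent",
                         "day_confluent")

#' Write / read a variant count table (TSV)
#'
#' Schema: `library_id`, `replicate_id`, `residue_index`, `ref_aa`,
#' `alt_aa`, `count_day9`, `count_confluent`, `day_confluent`; missing
#' values written as ".".  Reading validates types and content and reports
#' offending rows; duplicate (library, replicate, variant) rows are
#' rejected.
#'
#' @param counts Count-table tibble.
#' @param path File path.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` the validated tibble (empty, with a warning, for
#'   an empty file).
#' @export
write_count_table <- function(counts, path) {
  check_columns(counts, count_table_columns)
  readr::write_tsv(counts[, count_table_columns], path, na = ".")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(
    path, na = ".", show_col_types = FALSE,
    col_types = readr::cols(
      library_id = readr::col_character(),
      replicate_id = readr::col_integer(),
      residue_index = readr::col_integer(),
      ref_aa = readr::col_character(),
      alt_aa = readr::col_character(),
      count_day9 = readr::col_double(),
      count_confluent = readr::col_double(),
      day_confluent = readr::col_integer()
    ))
  if (nrow(x) == 0L) {
    warn(sprintf("empty count table: %s", path))
    return(x)
  }
  check_columns(x, count_table_columns, "count table")
  bad <- which(is.na(x$count_day9) | is.na(x$count_confluent) |
                 x$count_day9 < 0 | x$count_confluent < 0)
  if (length(bad) > 0L) {
    abort(sprintf("negative or missing count(s) at row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  bad_aa <- which(!is.na(x$residue_index) &
                    (!x$ref_aa %in% AA20 | !x$alt_aa %in% AA20))
  if (length(bad_aa) > 0L) {
    abort(sprintf("malformed amino-acid code(s) at row(s): %s",
                  paste(head(bad_aa, 5L), collapse = ", ")))
  }
  dup <- duplicated(x[, c("library_id", "replicate_id", "residue_index",
                          "alt_aa")])
  if (any(dup)) {
    abort(sprintf("duplicate (library, replicate, variant) row(s): %s",
                  paste(head(which(dup), 5L), collapse = ", ")))
  }
  x
}

#' Write classification results as TSV
#'
#' Flattens the per-replicate p-value list column into `p_rep1..k` columns.
#'
#' @param results Tibble from [classify_variants()] (optionally joined with
#'   fold-change results).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  out <- results
  if ("p_replicates" %in% names(out)) {
    kmax <- max(lengths(out$p_replicates))
    for (i in seq_len(kmax)) {
      out[[sprintf("p_rep%d", i)]] <-
        map_dbl(out$p_replicates, function(p) {
          if (length(p) >= i) p[i] else NA_real_
        })
    }
    out$p_replicates <- NULL
  }
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a predictor score table (TSV)
#'
#' Columns: `variant`, `predictor`, and `score` and/or `category`.
#'
#' @param path File path.
#' @return Tibble suitable for [binarize_scores()].
#' @export
read_predictor_table <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  check_columns(x, c("variant", "predictor"), "predictor table")
  if (!any(c("score", "category") %in% names(x))) {
    abort("predictor table needs a `score` and/or `category` column.")
  }
  x
}
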