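# Readers and writers for the tab-separated exchange formats.
#
# Two dialects are supported: a plain TSV (header row = sample IDs, first
# column = feature IDs) and the GEO series-matrix layout, where the data
# table sits between "!series_matrix_table_begin" / "!series_matrix_table_end"
# marker lines and all other "!"-prefixed lines are metadata to be skipped.

SERIES_BEGIN <- "!series_matrix_table_begin"
SERIES_END <- "!series_matrix_table_end"

strip_quotes <- function(x) {
  q <- nchar(x) >= 2L & substr(x, 1L, 1L) == '"' &
    substr(x, nchar(x), nchar(x)) == '"'
  x[q] <- substr(x[q], 2L, nchar(x[q]) - 1L)
  x
}

#' Read an expression matrix from TSV
#'
#' @param path Path to a tab-separated file.
#' @param format `"auto"` detects the series-matrix dialect from the marker
#'   line; `"series_matrix_tsv"` and `"plain_tsv"` force a dialect.
#' @return An [expression_matrix()].
#' @details Non-numeric cells and duplicate feature/sample IDs are hard
#'   errors naming the offending cell or ID.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "series_matrix_tsv",
                                              "plain_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_series <- any(lines == SERIES_BEGIN)
  if (format == "series_matrix_tsv" && !is_series) {
    stop2("no '", SERIES_BEGIN, "' marker found in ", path)
  }
  if (format == "auto") format <- if (is_series) "series_matrix_tsv" else "plain_tsv"
  if (format == "series_matrix_tsv") {
    b <- which(lines == SERIES_BEGIN)[1]
    e <- which(lines == SERIES_END)
    e <- e[e > b][1]
    if (is.na(e)) stop2("unterminated series-matrix table in ", path)
    lines <- lines[(b + 1L):(e - 1L)]
  }
  lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop2("no data rows in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- strip_quotes(cells[[1]])
  sample_ids <- header[-1]
  n_col <- length(header)
  body <- cells[-1]
  feature_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col) {
      stop2("row ", i + 1L, " has ", length(row), " fields, expected ", n_col)
    }
    row <- strip_quotes(row)
    feature_ids[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop2("non-numeric value '", row[j + 1L], "' at feature '", row[1],
            "', sample '", sample_ids[j], "'")
    }
    values[i, ] <- v
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop2("duplicate feature ID: ", dup[1])
  expression_matrix(values, feature_ids, sample_ids)
}

#' Write an expression matrix as plain TSV
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces them bit-exactly.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @param comment Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, comment = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("feature_id", matrix$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_along(matrix$feature_ids), function(i) {
    paste(c(matrix$feature_ids[i], num_chr(matrix$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read cohort labels from a two-column TSV
#'
#' Column 1 = sample ID, column 2 = status (0 = control, 1 = case).  A header
#' line is detected (and skipped) when the second field is not 0/1.
#'
#' @param path Path to the label file.
#' @return A [cohort_labels()] object.
#' @export
read_cohort_labels <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 2L)
  if (length(bad)) stop2("line ", bad[1], " has fewer than 2 fields")
  if (length(cells) && !cells[[1]][2] %in% c("0", "1")) cells <- cells[-1]
  if (!length(cells)) stop2("no label rows in ", path)
  ids <- vapply(cells, `[`, character(1), 1L)
  st <- vapply(cells, `[`, character(1), 2L)
  if (!all(st %in% c("0", "1"))) {
    stop2("invalid status '", st[!st %in% c("0", "1")][1],
          "' (expected 0 or 1)")
  }
  cohort_labels(ids, as.integer(st))
}

#' Write cohort labels as a two-column TSV
#' @param labels A [cohort_labels()] object.
#' @param path Output path.
#' @param comment Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_cohort_labels <- function(labels, path, comment = NULL) {
  stopifnot(inherits(labels, "cohort_labels"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines("sample_id\tstatus", con)
  writeLines(paste(labels$sample_ids, labels$status, sep = "\t"), con)
  invisible(path)
}
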