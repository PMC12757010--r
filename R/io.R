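#' Read a feature table from TSV/CSV
#'
#' Parses a delimited abundance table with one ID axis per dimension:
#' samples in rows by default, with `orientation = "features_rows"` to
#' transpose tables stored the other way around.  The delimiter is
#' inferred from the file extension (`.csv` = comma, otherwise tab)
#' unless given.  Values must be non-negative numbers with no empty
#' cells; violations are reported with the offending cell and line.
#'
#' @param path File path.
#' @param orientation `"samples_rows"` (default) or `"features_rows"`.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return Numeric matrix, samples in rows, with sample/feature IDs as
#'   dimnames.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_rows",
                                               "features_rows"),
                               sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("table needs an ID column plus at least one value column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- colnames(df)[-1]
  if (anyDuplicated(cols)) {
    stop("duplicate column IDs: ", paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(vals) | raw == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or empty cell at line %d (row '%s', column '%s')",
                 bad[1, 1] + 1L, ids[bad[1, 1]], cols[bad[1, 2]]))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative abundance %g at line %d (row '%s', column '%s')",
                 vals[neg[1, 1], neg[1, 2]], neg[1, 1] + 1L,
                 ids[neg[1, 1]], cols[neg[1, 2]]))
  }
  dimnames(vals) <- list(ids, cols)
  if (orientation == "features_rows") vals <- t(vals)
  vals
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: sample IDs in the first column,
#' one feature per remaining column, full numeric precision.
#'
#' @param x Numeric matrix, samples in rows.
#' @param path Output path.
#' @param id_column Header of the ID column (default `"sample_id"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "sample_id") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  df <- data.frame(rownames(x), format(x, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an anomaly-score report as TSV
#'
#' Columns `sample_id`, `mean_depth`, `anomaly_score`, `flagged`; numeric
#' columns are printed with 12 significant digits so scores round-trip.
#'
#' @param report A `kadaif` fit or the data frame from
#'   [as.data.frame.kadaif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(report, path) {
  if (inherits(report, "kadaif")) report <- as.data.frame(report)
  stopifnot(all(c("sample_id", "mean_depth", "anomaly_score", "flagged")
                %in% colnames(report)))
  out <- data.frame(
    sample_id = report$sample_id,
    mean_depth = format(report$mean_depth, digits = 12, trim = TRUE),
    anomaly_score = format(report$anomaly_score, digits = 12, trim = TRUE),
    flagged = tolower(as.character(report$flagged)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score report written by [write_scores()]
#'
#' @param path File path.
#' @return Data frame with the report columns, `flagged` as logical.
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  df$flagged <- df$flagged == "true"
  df
}
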