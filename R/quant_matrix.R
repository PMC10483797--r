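## matrix_io: quantification matrices and run metadata ------------------

QUANT_UNITS <- c("iBAQ", "FOT", "copies_per_cell", "arbitrary")

REQUIRED_META_COLS <- c("run_id", "group_label", "replicate_index",
                        "experiment_id")
OPTIONAL_META_COLS <- c(site_id = "S1", instrument_id = "unknown",
                        injection_index = NA, month = 1L,
                        material_form = "peptide")

#' Construct a validated quantification matrix
#'
#' A `quant_matrix` is a numeric matrix of non-negative protein
#' abundances with proteins as rows and MS runs as columns. Missing
#' entries are `NA` — explicitly distinct from zero — and the abundance
#' unit travels with the object.
#'
#' @param values numeric matrix with unique rownames (protein ids) and
#'   unique colnames (run ids). `NA` marks a missing (not identified)
#'   entry.
#' @param unit one of `"iBAQ"`, `"FOT"`, `"copies_per_cell"`,
#'   `"arbitrary"`.
#' @return the matrix with class `quant_matrix` and a `unit` attribute.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("r1", "r2")))
#' qm <- quant_matrix(m, unit = "iBAQ")
#' quant_unit(qm)
#' @export
quant_matrix <- function(values, unit = "arbitrary") {
  unit <- match.arg(unit, QUANT_UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    pqc_stop("'values' must be a numeric matrix", "proteoqc_format_error")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    pqc_stop("quant_matrix requires protein rownames and run colnames",
             "proteoqc_format_error")
  dup_p <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_p))
    pqc_stop(sprintf("duplicate protein identifier(s): %s",
                     paste(unique(dup_p), collapse = ", ")),
             "proteoqc_format_error")
  dup_r <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_r))
    pqc_stop(sprintf("duplicate run identifier(s): %s",
                     paste(unique(dup_r), collapse = ", ")),
             "proteoqc_format_error")
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg))
    pqc_stop(sprintf("negative abundance at protein '%s', run '%s'",
                     rownames(values)[neg[1, 1]],
                     colnames(values)[neg[1, 2]]),
             "proteoqc_validation_error")
  structure(values, unit = unit, class = c("quant_matrix", class(values)))
}

#' @rdname quant_matrix
#' @param x a `quant_matrix`.
#' @export
quant_unit <- function(x) attr(x, "unit") %||% "arbitrary"

`%||%` <- function(a, b) if (is.null(a)) b else a

set_quant_unit <- function(x, unit) {
  attr(x, "unit") <- match.arg(unit, QUANT_UNITS)
  x
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d runs [%s], %d missing\n",
              nrow(x), ncol(x), quant_unit(x), sum(is.na(x))))
  invisible(x)
}

#' Read a quantification matrix from TSV/CSV
#'
#' Expected layout: optional `#`-prefixed comment lines (a line of the
#' form `# unit: FOT` restores the unit), then a header row whose first
#' column holds protein identifiers and whose remaining columns are runs.
#' Empty cells and `NA` denote missing values.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param unit abundance unit; overridden by a `# unit:` header if present.
#' @return a [quant_matrix].
#' @export
read_quant_matrix <- function(path, dialect = c("tsv", "csv"),
                              unit = "arbitrary") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    pqc_stop(sprintf("file not found: %s", path), "proteoqc_io_error")
  header <- grep("^#", readLines(path, n = 20L), value = TRUE)
  u <- sub("^#\\s*unit:\\s*", "", grep("^#\\s*unit:", header, value = TRUE))
  if (length(u) == 1L && u %in% QUANT_UNITS) unit <- u
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"")
  if (ncol(df) < 2L)
    pqc_stop("matrix file needs an identifier column plus >= 1 run column",
             "proteoqc_format_error")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    pqc_stop(sprintf("duplicate protein identifier(s) in %s: %s",
                     path, paste(unique(dup), collapse = ", ")),
             "proteoqc_format_error")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  quant_matrix(vals, unit = unit)
}

#' Write a quantification matrix to TSV/CSV
#'
#' Missing values are written as `NA`; numbers keep full precision
#' (up to 17 significant digits) so a read/write round trip is lossless
#' for representable decimals. The unit is recorded in a `# unit:`
#' comment line.
#'
#' @param x a [quant_matrix].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "quant_matrix"))
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", quant_unit(x)), con)
  writeLines(paste(c("protein_id", colnames(x)), collapse = sep), con)
  if (nrow(x)) {
    txt <- vapply(as.vector(x), function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, trim = TRUE)
    }, character(1))
    txt <- matrix(txt, nrow = nrow(x))
    writeLines(paste(rownames(x), apply(txt, 1L, paste, collapse = sep),
                     sep = sep), con)
  }
  invisible(path)
}

#' Construct validated run metadata
#'
#' @param df data.frame with columns `run_id`, `group_label`,
#'   `replicate_index`, `experiment_id` and optionally `site_id`,
#'   `instrument_id`, `injection_index`, `month`, `material_form`.
#'   Missing optional columns are filled with documented defaults
#'   (`month = 1` triggers a warning, since stability analyses depend
#'   on it).
#' @return data.frame of class `run_metadata`.
#' @export
run_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_req <- setdiff(REQUIRED_META_COLS, names(df))
  if (length(missing_req))
    pqc_stop(sprintf("metadata missing required column(s): %s",
                     paste(missing_req, collapse = ", ")),
             "proteoqc_format_error")
  if (!"month" %in% names(df)) {
    pqc_warn("metadata has no 'month' column; defaulting to month = 1")
  }
  for (col in names(OPTIONAL_META_COLS)) {
    if (!col %in% names(df)) df[[col]] <- OPTIONAL_META_COLS[[col]]
  }
  df$run_id <- as.character(df$run_id)
  df$group_label <- as.character(df$group_label)
  df$experiment_id <- as.character(df$experiment_id)
  df$replicate_index <- as.integer(df$replicate_index)
  df$month <- as.integer(df$month)
  df$material_form <- tolower(as.character(df$material_form))
  dup <- df$run_id[duplicated(df$run_id)]
  if (length(dup))
    pqc_stop(sprintf("duplicate run_id(s): %s",
                     paste(unique(dup), collapse = ", ")),
             "proteoqc_format_error")
  if (any(df$replicate_index < 1L))
    pqc_stop("replicate_index must be >= 1", "proteoqc_validation_error")
  if (any(!is.na(df$month) & df$month < 1L))
    pqc_stop("month must be >= 1", "proteoqc_validation_error")
  key <- paste(df$experiment_id, df$group_label, df$replicate_index)
  if (anyDuplicated(key))
    pqc_stop("(experiment_id, group_label, replicate_index) must be unique",
             "proteoqc_validation_error")
  class(df) <- c("run_metadata", "data.frame")
  df
}

#' Read run metadata from TSV/CSV
#'
#' @inheritParams read_quant_matrix
#' @return a [run_metadata] data.frame.
#' @export
read_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    pqc_stop(sprintf("file not found: %s", path), "proteoqc_io_error")
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  run_metadata(df)
}

#' Check that a matrix and metadata describe the same runs
#'
#' @param x a [quant_matrix].
#' @param metadata a [run_metadata].
#' @return invisibly `TRUE`; otherwise an error listing the symmetric
#'   difference of run identifiers.
#' @export
check_pairing <- function(x, metadata) {
  only_m <- setdiff(colnames(x), metadata$run_id)
  only_d <- setdiff(metadata$run_id, colnames(x))
  if (length(only_m) || length(only_d))
    pqc_stop(sprintf(
      "matrix/metadata run mismatch; only in matrix: [%s]; only in metadata: [%s]",
      paste(only_m, collapse = ", "), paste(only_d, collapse = ", ")),
      "proteoqc_validation_error")
  invisible(TRUE)
}

# runs of one experiment, in matrix column order
experiment_runs <- function(metadata, experiment_id) {
  runs <- metadata$run_id[metadata$experiment_id == experiment_id]
  if (!length(runs))
    pqc_stop(sprintf("no runs for experiment '%s'", experiment_id),
             "proteoqc_validation_error")
  runs
}
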