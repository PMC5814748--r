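# Readers and writers for the package's on-disk formats: dense TSV/CSV
# expression tables (genes in rows, first column = gene ids, header = cell
# ids), MatrixMarket triplets (.mtx + genes.txt + cells.txt), two-column
# label TSVs, and JSON run reports. Gene identifier matching against the
# network is exact-string; symbol/Ensembl mismatches should be resolved by
# the user with a mapping table before smoothing, never by fuzzy matching.

#' Read an expression matrix
#'
#' Reads either a dense delimited table (TSV/CSV; first column gene ids,
#' header cell ids) or a MatrixMarket file accompanied by gene and cell id
#' files (one id per line). Data stored cells-in-rows can be transposed on
#' read with the orientation flag. Duplicate identifiers and negative
#' values are errors.
#'
#' @param path path to the table or `.mtx` file.
#' @param orientation "genes_in_rows" (default) or "cells_in_rows".
#' @param genes_file,cells_file id files for the MatrixMarket layout;
#'   default to `genes.txt` / `cells.txt` next to the `.mtx` file.
#' @return validated genes-by-cells numeric matrix.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "cells_in_rows"),
                            genes_file = NULL, cells_file = NULL) {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_file))
      genes_file <- file.path(dirname(path), "genes.txt")
    if (is.null(cells_file))
      cells_file <- file.path(dirname(path), "cells.txt")
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(genes_file)
    cols <- readLines(cells_file)
    if (length(rows) != nrow(m))
      stop(sprintf("'%s' has %d ids but the matrix has %d rows",
                   genes_file, length(rows), nrow(m)))
    if (length(cols) != ncol(m))
      stop(sprintf("'%s' has %d ids but the matrix has %d columns",
                   cells_file, length(cols), ncol(m)))
    dimnames(m) <- list(rows, cols)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  if (orientation == "cells_in_rows") m <- t(m)
  validate_expression(m)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `format = "tsv"`/`"csv"` writes a dense
#' table with a `gene_id` first column; `format = "mtx"` writes a
#' MatrixMarket file plus `genes.txt` and `cells.txt` beside it.
#'
#' @param expr genes-by-cells matrix.
#' @param path output path.
#' @param format "tsv", "csv" or "mtx" (default: inferred from `path`).
#' @export
write_expression <- function(expr, path, format = NULL) {
  expr <- validate_expression(expr)
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(expr, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(expr), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(expr), file.path(dirname(path), "cells.txt"))
  } else {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  }
  invisible(path)
}

#' Read per-cell labels from a two-column TSV
#'
#' @param path TSV with columns cell_id and label (header optional, detected
#'   by whether the first row's second field is the literal "label").
#' @return named character vector (NA for the literal "NA" label).
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = "auto", colClasses = "character",
                          data.table = FALSE)
  if (ncol(dt) != 2L)
    stop(sprintf("label file '%s' must have exactly 2 columns", path))
  labs <- dt[[2]]
  labs[labs == "NA"] <- NA_character_
  stats::setNames(labs, dt[[1]])
}

#' Write per-cell labels as a two-column TSV
#'
#' @param labels named vector (names = cell ids); NA written as "NA".
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(
    data.frame(cell_id = names(labels),
               label = ifelse(is.na(labels), "NA", as.character(labels)),
               stringsAsFactors = FALSE),
    path, sep = "\t")
  invisible(path)
}

#' Assemble a machine-readable run report
#'
#' Collects package version, the configuration, per-stage summaries and
#' wall times into a list serializable as JSON, so every run is
#' reproducible from its report's config block alone.
#'
#' @param command the command or function that ran.
#' @param config named list of configuration values (seeds included).
#' @param stages named list of per-stage summaries (counts, choices,
#'   timings).
#' @param path optional path; when given, the report is also written as
#'   pretty-printed JSON.
#' @return the report list, invisibly when written to `path`.
#' @export
run_report <- function(command, config, stages = list(), path = NULL) {
  report <- list(
    tool = "rwrsmooth",
    version = as.character(utils::packageVersion("rwrsmooth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    config = config,
    stages = stages)
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    return(invisible(report))
  }
  report
}
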