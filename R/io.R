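# Readers and writers for the delimited / Matrix Market interchange formats.

#' Read a cells-by-features matrix
#'
#' Delimited input (`tsv`/`csv`) expects a header row of feature IDs and a
#' first column of cell IDs. Matrix Market input (`mtx`) expects the common
#' single-cell convention of a features-by-cells sparse matrix with sidecar
#' `barcodes` and `features` ID files (one ID per line); the orientation is
#' checked against the sidecar lengths and the matrix is returned as cells
#' by features. `format = "h5ad"` is recognized but requires an HDF5 reader,
#' which this package does not bundle.
#'
#' @param path Matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`, `"h5ad"`; default guessed
#'   from the file extension.
#' @param transpose Flip the parsed orientation (for delimited files whose
#'   rows are features).
#' @param barcodes,features Sidecar ID files for `mtx` (defaults:
#'   `barcodes.tsv` / `features.tsv` next to the matrix).
#' @return Dense numeric matrix, cells in rows, with unique dimnames.
#' @export
read_matrix <- function(path, format = NULL, transpose = FALSE,
                        barcodes = NULL, features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     h5ad = "h5ad",
                     stop("cannot guess the format of ", path))
  }
  m <- switch(format,
    tsv = read_delim_matrix(path, "\t"),
    csv = read_delim_matrix(path, ","),
    mtx = read_mtx_matrix(path, barcodes, features),
    h5ad = stop("reading .h5ad requires an HDF5 reader, which is not ",
                "available; export the matrix as MTX or TSV instead"),
    stop("unknown format: ", format))
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate cell IDs in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate feature IDs in ", path)
  m
}

read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          colClasses = NA)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric entries in column '%s' of %s",
                 colnames(df)[bad[1L]], path))
  }
  as.matrix(df)
}

read_mtx_matrix <- function(path, barcodes, features) {
  if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
  if (is.null(features)) features <- file.path(dirname(path), "features.tsv")
  for (f in c(barcodes, features)) {
    if (!file.exists(f)) stop("missing MTX sidecar file: ", f)
  }
  m <- as.matrix(Matrix::readMM(path))
  bc <- readLines(barcodes)
  ft <- readLines(features)
  if (nrow(m) == length(ft) && ncol(m) == length(bc)) {
    m <- t(m)  # stored features x cells, the common convention
  } else if (!(nrow(m) == length(bc) && ncol(m) == length(ft))) {
    stop(sprintf(
      "MTX shape %dx%d matches neither %d barcodes x %d features nor its transpose",
      nrow(m), ncol(m), length(bc), length(ft)))
  }
  dimnames(m) <- list(bc, ft)
  m
}

#' Write a cells-by-features matrix as TSV
#'
#' Values are written at full precision so that
#' `read_matrix(write_matrix(m))` round-trips exactly.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("cell_%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("feature_%d", seq_len(ncol(m)))
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  con <- file(path, "wb")  # binary mode forces UNIX newlines
  on.exit(close(con))
  writeLines(paste(c("cell_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read per-cell time labels
#'
#' Expects a two-column delimited file (`cell_id`, `time`), with or without a
#' header. When `cell_ids` is given, the labels are aligned to that order and
#' missing or unmatched cells are reported by ID.
#'
#' @param path Label file (tab- or comma-delimited).
#' @param cell_ids Optional cell ID vector to align against.
#' @param ordinal Map non-numeric stage labels to ranks 1..D (in sorted
#'   stage order), with a message describing the mapping.
#' @return Named numeric vector of times.
#' @export
read_labels <- function(path, cell_ids = NULL, ordinal = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  # treat line 1 as a header when its first field looks like a column name
  has_header <- grepl("^(cell[_ ]?id|id|cell|barcode)$",
                      strsplit(first, sep)[[1L]][1L], ignore.case = TRUE)
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character",
                          skip = if (has_header) 1L else 0L)
  if (ncol(df) < 2L) stop("label file must have two columns (cell_id, time)")
  ids <- df[[1L]]
  raw <- df[[2L]]
  tm <- suppressWarnings(as.numeric(raw))
  if (anyNA(tm)) {
    if (!ordinal) {
      stop("non-numeric time labels; supply numeric times or use ordinal = TRUE")
    }
    stages <- sort(unique(raw))
    tm <- match(raw, stages)
    message("ordinal stage mapping: ",
            paste(sprintf("%s=%d", stages, seq_along(stages)),
                  collapse = ", "))
  }
  names(tm) <- ids
  if (!is.null(cell_ids)) {
    miss <- setdiff(cell_ids, ids)
    if (length(miss) > 0L) {
      stop("cells missing a time label: ", paste(miss, collapse = ", "))
    }
    tm <- tm[cell_ids]
  }
  tm
}

#' Write a two-column (cell_id, value) TSV
#'
#' @param values Named numeric vector.
#' @param path Output file.
#' @param col_name Header name of the value column.
#' @param digits Significant digits (default 6; use `NA` for full precision).
#' @return `path`, invisibly.
#' @export
write_values <- function(values, path, col_name = "value", digits = 6L) {
  ids <- names(values)
  if (is.null(ids)) ids <- sprintf("cell_%d", seq_along(values))
  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste("cell_id", col_name, sep = "\t"), con)
  writeLines(paste(ids, sprintf(fmt, values), sep = "\t"), con)
  invisible(path)
}
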