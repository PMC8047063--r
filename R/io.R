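#' Read a labelled matrix from a delimited text file
#'
#' Reads a dense matrix stored as TSV or CSV with a header row of column
#' identifiers and a first column of row identifiers.  The delimiter is
#' auto-detected from the header line (tab wins over comma when both occur).
#' Identifiers are kept as opaque strings in file order.
#'
#' @param path Path to the file.
#' @param expect_square If \code{TRUE}, require the matrix to be square
#'   (side networks); a non-square input is an error.
#' @param binary If \code{TRUE}, require every entry to be 0 or 1
#'   (association matrices); anything else is an error, never coerced.
#' @return A numeric matrix with \code{dimnames} set from the file.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, expect_square = FALSE, binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("parse error: no data columns in ", path, call. = FALSE)
  row_ids <- as.character(df[[1L]])
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(row_ids))
    stop("identifier error: duplicate row ids in ", path, call. = FALSE)
  if (anyDuplicated(col_ids))
    stop("identifier error: duplicate column ids in ", path, call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals))
      stop("parse error: non-numeric cells in ", path, call. = FALSE)
  }
  if (anyNA(vals))
    stop("parse error: missing values in ", path, call. = FALSE)
  dimnames(vals) <- list(row_ids, col_ids)
  if (expect_square && nrow(vals) != ncol(vals))
    stop(sprintf("shape error: expected square matrix, got %d x %d",
                 nrow(vals), ncol(vals)), call. = FALSE)
  if (binary) assert_binary(vals)
  vals
}

assert_binary <- function(Y) {
  if (!all(Y == 0 | Y == 1))
    stop("domain error: association matrix entries must be 0 or 1",
         call. = FALSE)
  invisible(Y)
}

#' Write a labelled matrix to a delimited text file
#'
#' Inverse of [read_matrix()]: the header row holds column identifiers and
#' the first field of every data row holds the row identifier.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have row and column names", call. = FALSE)
  header <- paste(c("id", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = sep),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Align an association matrix with its side networks
#'
#' Re-indexes every side network to the identifiers of the association
#' matrix.  Entities present in the association matrix but absent from a
#' side network cause that axis to be restricted to the intersection (the
#' dropped entities are reported in a warning); entities only in a side
#' network are silently dropped from it.
#'
#' @param Y Binary association matrix (rows = one entity class, columns =
#'   the other) with dimnames.
#' @param drug_nets Named or unnamed list of square matrices over the row
#'   entities, with dimnames.
#' @param met_nets List of square matrices over the column entities.
#' @return List with elements \code{Y}, \code{drug_nets}, \code{met_nets},
#'   all indexed consistently in the (possibly restricted) order of
#'   \code{Y}'s identifiers.
#' @export
align_inputs <- function(Y, drug_nets = list(), met_nets = list()) {
  assert_binary(Y)
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop("association matrix must have row and column names", call. = FALSE)
  row_ids <- rownames(Y)
  col_ids <- colnames(Y)
  for (net in drug_nets) row_ids <- intersect(row_ids, rownames(net))
  for (net in met_nets)  col_ids <- intersect(col_ids, rownames(net))
  if (length(row_ids) == 0L || length(col_ids) == 0L)
    stop("alignment error: empty identifier intersection", call. = FALSE)
  dropped <- (nrow(Y) - length(row_ids)) + (ncol(Y) - length(col_ids))
  if (dropped > 0L)
    warning(sprintf("align_inputs: dropped %d entities absent from a side network",
                    dropped), call. = FALSE)
  list(
    Y = Y[row_ids, col_ids, drop = FALSE],
    drug_nets = lapply(drug_nets, function(net) net[row_ids, row_ids, drop = FALSE]),
    met_nets  = lapply(met_nets,  function(net) net[col_ids, col_ids, drop = FALSE])
  )
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of [ilmf_config()] fields; unspecified
#' fields keep their defaults.  Files ending in \code{.json} are parsed as
#' JSON, everything else as YAML (requires the \pkg{yaml} package).
#'
#' @param path Path to the configuration file.
#' @return An \code{ilmf_config} object.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  }
  do.call(ilmf_config, as.list(vals))
}
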