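# Plain-text I/O: response matrices and Q-matrices as CSV, with positional
# error reporting.  No missing-data handling: incomplete files are rejected.

#' Read a binary response matrix from CSV
#'
#' Expects a header row of item identifiers and one row per examinee with
#' cells in `{0, 1}`.  An optional first column named `id` (or any
#' non-numeric first column) is treated as examinee identifiers.  Missing
#' or non-binary cells are an error naming the location.
#'
#' @param path CSV file path.
#' @return Integer matrix with item names as columns and examinee ids (if
#'   present) as row names.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) >= 2L &&
      (tolower(names(df)[1]) == "id" || !is.numeric(df[[1L]]))) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else ids <- NULL
  m <- as.matrix(df)
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (NROW(bad))
    stop(sprintf("non-binary or missing cell in %s at row %d, column '%s'",
                 path, bad[1L, 1L], colnames(m)[bad[1L, 2L]]))
  storage.mode(m) <- "integer"
  if (!is.null(ids)) rownames(m) <- ids
  m
}

#' Write a binary response matrix to CSV
#'
#' @param responses Binary matrix.
#' @param path Output path.
#' @export
write_responses <- function(responses, path) {
  m <- as.matrix(responses)
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a Q-matrix from CSV
#'
#' Header row of attribute names, one row per item, integer entries
#' validated against the attribute levels: `0 <= q_jk < M_k`, and no
#' all-zero rows.
#'
#' @param path CSV file path.
#' @param levels Integer vector of attribute level counts, or an
#'   [attribute_spec()].
#' @return Integer Q-matrix.
#' @export
read_qmatrix <- function(path, levels) {
  spec <- if (inherits(levels, "attr_spec")) levels else
    attribute_spec(levels)
  Q <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (ncol(Q) != spec$K)
    stop(sprintf("%s has %d columns; expected %d attributes",
                 path, ncol(Q), spec$K))
  if (any(is.na(Q)) || any(Q != round(Q)))
    stop("Q-matrix entries must be integers")
  storage.mode(Q) <- "integer"
  oor <- which(Q < 0L | Q >= matrix(spec$levels, nrow(Q), spec$K,
                                    byrow = TRUE), arr.ind = TRUE)
  if (NROW(oor))
    stop(sprintf(
      "Q-matrix entry out of range in %s at row %d, column '%s' (M_k = %d)",
      path, oor[1L, 1L], colnames(Q)[oor[1L, 2L]],
      spec$levels[oor[1L, 2L]]))
  zr <- which(rowSums(Q > 0L) == 0L)
  if (length(zr))
    stop(sprintf("all-zero Q-matrix row(s) in %s: %s", path,
                 paste(zr, collapse = ", ")))
  rownames(Q) <- NULL
  Q
}

#' Write a Q-matrix to CSV
#'
#' @param Q Q-matrix.
#' @param path Output path.
#' @export
write_qmatrix <- function(Q, path) {
  m <- as.matrix(Q)
  if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
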