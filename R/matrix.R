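#' Coerce tabular input to a numeric data matrix
#'
#' All user-facing functions in netcure accept either a numeric matrix or a
#' data frame / tibble whose first column may carry row identifiers (time
#' points, sample names). This helper normalises both shapes into a numeric
#' matrix with unique row and column names; missing cells are carried as
#' `NA`.
#'
#' @param x A numeric matrix or a data frame. In a data frame, a leading
#'   non-numeric column is interpreted as row identifiers.
#' @param require_complete Reject input containing missing cells.
#' @param min_rows,min_cols Minimal admissible dimensions.
#' @return A numeric matrix with `rownames` and `colnames` set.
#' @examples
#' as_curation_matrix(data.frame(id = c("t1", "t2", "t3"),
#'                               a = 1:3, b = c(2, NA, 6)))
#' @export
as_curation_matrix <- function(x, require_complete = FALSE,
                               min_rows = 1L, min_cols = 1L) {
  if (is.data.frame(x)) {
    rn <- NULL
    if (ncol(x) >= 2L && !is.numeric(x[[1L]])) {
      rn <- as.character(x[[1L]])
      x <- x[, -1L, drop = FALSE]
    }
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad) > 0L) {
      abort(paste0("non-numeric data column(s): ", toString(bad)))
    }
    m <- as.matrix(x)
    if (!is.null(rn)) rownames(m) <- rn
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else {
    abort("`x` must be a numeric matrix or a data frame")
  }
  if (!is.numeric(m)) abort("`x` must be numeric")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) abort("duplicated row identifiers")
  if (anyDuplicated(colnames(m))) abort("duplicated column identifiers")
  if (nrow(m) < min_rows || ncol(m) < min_cols) {
    abort(sprintf("need at least %d rows and %d columns, got %d x %d",
                  min_rows, min_cols, nrow(m), ncol(m)))
  }
  m[is.nan(m)] <- NA_real_
  if (require_complete && anyNA(m)) {
    abort("matrix contains missing cells; impute or cure it first")
  }
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    abort(paste0("column(s) entirely missing: ",
                 toString(colnames(m)[all_na])))
  }
  m
}

#' Convert a data matrix to a tibble
#'
#' @param m A numeric matrix with dimnames.
#' @param row_col Name of the identifier column in the output.
#' @return A tibble with one row per matrix row.
#' @export
matrix_tbl <- function(m, row_col = ".row") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!row_col := rownames(m) %||%
                                   as.character(seq_len(nrow(m)))), out)
  out
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed leaves the global stream untouched.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
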