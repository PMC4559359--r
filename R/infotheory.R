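#' Equal-frequency discretisation
#'
#' Bins a numeric series into (approximately) equal-count bins using
#' quantile edges; duplicated quantiles from heavily tied data collapse
#' into fewer bins. A constant series yields a single bin.
#'
#' @param x Numeric vector.
#' @param bins Target number of bins; default `min(10, ceiling(sqrt(n)/2))`.
#' @return Integer vector of bin indices (1-based).
#' @export
discretize_ef <- function(x, bins = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  bins <- as.integer(bins %||% default_bins(n))
  if (bins < 1L) abort("`bins` must be >= 1")
  if (bins == 1L) return(rep(1L, n))
  xs <- sort.int(x, method = "quick")
  # interior type-7 quantile edges; right-closed bins as cut() would give
  h <- (n - 1) * (seq_len(bins - 1L) / bins) + 1
  lo <- floor(h)
  edges <- unique(xs[lo] + (h - lo) * (xs[pmin(lo + 1L, n)] - xs[lo]))
  findInterval(x, edges, left.open = TRUE) + 1L
}

default_bins <- function(n) max(2L, min(10L, ceiling(sqrt(n) / 2)))

# joint plug-in entropy (bits) of pre-discretised integer columns,
# mixed-radix encoded so the joint cells can be tabulated directly
.entropy_binned <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, ncol = 1L)
  key <- codes[, 1L]
  if (ncol(codes) > 1L) {
    for (j in 2L:ncol(codes)) {
      key <- (key - 1L) * max(codes[, j]) + codes[, j]
    }
  }
  p <- tabulate(key)
  p <- p[p > 0L] / nrow(codes)
  -sum(p * log2(p))
}

#' Shannon entropy (plug-in, bits)
#'
#' Plug-in entropy `H = -sum p log2 p` over equal-frequency bins, with
#' `0 * log 0 := 0`. For a matrix, columns are discretised independently
#' and the joint entropy of the bin tuples is returned. A constant series
#' has zero entropy.
#'
#' @param x Numeric vector, or matrix whose columns form a joint sample
#'   (at most 4 dimensions).
#' @param bins Bins per dimension; default `min(10, ceiling(sqrt(n)/2))`.
#' @return Entropy in bits (non-negative).
#' @examples
#' shannon_entropy(rep(c(0, 1), 50), bins = 2)  # 1 bit
#' @export
shannon_entropy <- function(x, bins = NULL) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (ncol(x) > 4L) abort("joint entropy limited to 4 dimensions")
  if (nrow(x) < 2L) abort("need at least 2 samples")
  codes <- vapply(seq_len(ncol(x)), function(j) discretize_ef(x[, j], bins),
                  integer(nrow(x)))
  .entropy_binned(codes)
}

#' Conditional entropy (bits)
#'
#' `H(Y | X) = H(X, Y) - H(X)` computed from joint histograms over
#' equal-frequency bins; at most three conditioning series (histograms of
#' higher order are too sparse to estimate).
#'
#' @param y Numeric response series.
#' @param conditioners Numeric vector or matrix of 1-3 conditioning series,
#'   aligned with `y`.
#' @param bins Bins per dimension.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(y, conditioners, bins = NULL) {
  if (is.null(dim(conditioners))) {
    conditioners <- matrix(as.numeric(conditioners), ncol = 1L)
  }
  if (ncol(conditioners) > 3L) {
    abort("at most 3 conditioning series (third-order conditional entropy)")
  }
  if (nrow(conditioners) != length(y)) abort("series must be aligned")
  cy <- discretize_ef(y, bins)
  cx <- vapply(seq_len(ncol(conditioners)),
               function(j) discretize_ef(conditioners[, j], bins),
               integer(length(y)))
  .entropy_binned(cbind(cx, cy)) - .entropy_binned(cx)
}

#' Mutual information (bits)
#'
#' `I(X, Y) = H(X) + H(Y) - H(X, Y)` on equal-frequency bins, clipping the
#' tiny negative values that finite-sample plug-in estimates can produce.
#' With `lag > 0`, `x[t]` is paired with `y[t + lag]`, so a positive value
#' at lag `tau` means the past of `x` is informative about the future of
#' `y`. Symmetric in its arguments at `lag = 0`.
#'
#' @param x,y Numeric series of equal length.
#' @param lag Non-negative integer shift of `y` relative to `x`.
#' @param bins Bins per dimension.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y, lag = 0L, bins = NULL) {
  lag <- as.integer(lag)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (lag < 0L) abort("`lag` must be >= 0")
  if (n < lag + 10L) abort("series too short for this lag")
  xs <- x[seq_len(n - lag)]
  ys <- y[seq_len(n - lag) + lag]
  cx <- discretize_ef(xs, bins)
  cy <- discretize_ef(ys, bins)
  max(0, .entropy_binned(cx) + .entropy_binned(cy) -
        .entropy_binned(cbind(cx, cy)))
}

#' Transfer entropy (bits)
#'
#' Directional information flow from `x` to `y` at lag `tau`:
#' `T(X -> Y) = H(Y_t | Y_{t-tau}) - H(Y_t | Y_{t-tau}, X_{t-tau})`,
#' i.e. the reduction of the uncertainty of `y`'s present given its own
#' past once `x`'s past is also known. Non-negative after clipping.
#'
#' @param x,y Numeric series of equal length.
#' @param lag Positive integer lag `tau`.
#' @param bins Bins per dimension.
#' @return Transfer entropy in bits (non-negative).
#' @export
transfer_entropy <- function(x, y, lag = 1L, bins = NULL) {
  lag <- as.integer(lag)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (lag < 1L) abort("`lag` must be >= 1")
  if (n < lag + 10L) abort("series too short for this lag")
  cx <- discretize_ef(x, bins)
  cy <- discretize_ef(y, bins)
  idx <- seq_len(n - lag)
  yt <- cy[idx + lag]
  ylag <- cy[idx]
  xlag <- cx[idx]
  h_y_ypast <- .entropy_binned(cbind(ylag, yt)) - .entropy_binned(ylag)
  h_y_both <- .entropy_binned(cbind(ylag, xlag, yt)) -
    .entropy_binned(cbind(ylag, xlag))
  max(0, h_y_ypast - h_y_both)
}
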