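#' Fit a principal component analysis model
#'
#' Decomposes a complete data matrix as `X = 1 m' + T P' + E`: the column
#' means `m`, scores `T` (projections of the observations onto the latent
#' subspace), orthonormal loadings `P` (right singular vectors of the
#' centred matrix, ordered by singular value) and residuals `E`. The score
#' variances `lambda[a] = d[a]^2 / (n - 1)` are the diagonal of the score
#' covariance matrix and feed the Hotelling T2 statistic.
#'
#' For reproducibility each loading column is sign-fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param x Complete numeric matrix or data frame (observations x
#'   variables); at least 3 rows and 2 columns.
#' @param ncomp Number of components `A`, `1 <= A <= min(n - 1, p)`.
#' @param scale Autoscale columns to unit variance before the decomposition
#'   (in addition to mean centring, which is always applied).
#' @return An object of class `pca_model`: a list with elements `center`,
#'   `scale`, `loadings` (p x A), `scores` (n x A), `score_variances`,
#'   `residuals` (n x p), `ncomp`, `eigenvalues` (all `min(n - 1, p)`
#'   variances of the decomposition) and `explained_variance` (cumulative
#'   fraction per component).
#' @seealso [hotelling_t2()], [spe()], [spe_contributions()],
#'   [n_components_variance()], [n_components_eigenvalue()]
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' fit <- pca_fit(x, ncomp = 2)
#' glance(fit)
#' @export
pca_fit <- function(x, ncomp, scale = FALSE) {
  m <- as_curation_matrix(x, require_complete = TRUE,
                          min_rows = 3L, min_cols = 2L)
  n <- nrow(m)
  p <- ncol(m)
  amax <- min(n - 1L, p)
  ncomp <- as.integer(ncomp)
  if (length(ncomp) != 1L || is.na(ncomp) || ncomp < 1L || ncomp > amax) {
    abort(sprintf("`ncomp` must be in 1..%d", amax))
  }
  ctr <- colMeans(m)
  scl <- rep(1, p)
  if (isTRUE(scale)) {
    scl <- apply(m, 2L, sd)
    if (any(scl == 0)) {
      abort(paste0("constant column(s), autoscaling undefined: ",
                   toString(colnames(m)[scl == 0])))
    }
  }
  xc <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  if (all(abs(xc) < .Machine$double.eps * 1e3)) {
    abort("matrix has zero variance; no principal components exist")
  }
  sv <- svd(xc, nu = amax, nv = amax)
  d <- sv$d[seq_len(amax)]
  # sign convention: largest |loading| entry positive per component
  flip <- vapply(seq_len(amax), function(a) {
    v <- sv$v[, a]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v, 2L, flip, "*")
  scores_full <- sweep(sv$u, 2L, flip * d, "*")
  eig <- d^2 / (n - 1)
  tot <- sum(eig)
  P <- loadings[, seq_len(ncomp), drop = FALSE]
  T_ <- scores_full[, seq_len(ncomp), drop = FALSE]
  dimnames(P) <- list(colnames(m), paste0("PC", seq_len(ncomp)))
  dimnames(T_) <- list(rownames(m), paste0("PC", seq_len(ncomp)))
  res <- xc - T_ %*% t(P)
  structure(list(
    center = ctr,
    scale = scl,
    scaled = isTRUE(scale),
    loadings = P,
    scores = T_,
    score_variances = eig[seq_len(ncomp)],
    residuals = res,
    ncomp = ncomp,
    eigenvalues = eig,
    explained_variance = cumsum(eig) / tot,
    n = n
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d observations, %d variables, %d component%s\n",
              x$n, length(x$center), x$ncomp, if (x$ncomp > 1) "s" else ""))
  cat(sprintf("  cumulative explained variance: %.1f %%\n",
              100 * x$explained_variance[x$ncomp]))
  invisible(x)
}

# project new observations into the model's (centred, scaled) space
.pca_preprocess <- function(model, newdata) {
  p <- length(model$center)
  if (is.null(newdata)) {
    xc <- model$scores %*% t(model$loadings) + model$residuals
    return(xc)
  }
  if (is.vector(newdata) && is.numeric(newdata)) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  m <- as_curation_matrix(newdata, require_complete = TRUE)
  if (ncol(m) != p) {
    abort(sprintf("newdata has %d columns, model expects %d", ncol(m), p))
  }
  sweep(sweep(m, 2L, model$center), 2L, model$scale, "/")
}

#' Hotelling T-squared statistic
#'
#' The estimated Mahalanobis distance of an observation's projection from
#' the centre of the latent subspace, `T2 = sum_a t[a]^2 / lambda[a]`.
#' Large values flag observations far from the centre yet still coherent
#' with the correlation structure.
#'
#' @param model A [pca_fit()] model.
#' @param newdata Optional matrix / data frame / single numeric vector of
#'   new observations; default: the training rows.
#' @return Named numeric vector of non-negative T2 values.
#' @export
hotelling_t2 <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (any(model$score_variances <= max(model$score_variances) * 1e-12)) {
    abort("degenerate component: a score variance is (numerically) zero")
  }
  if (is.null(newdata)) {
    scores <- model$scores
  } else {
    scores <- .pca_preprocess(model, newdata) %*% model$loadings
  }
  drop(rowSums(sweep(scores^2, 2L, model$score_variances, "/")))
}

#' Square prediction error (SPE)
#'
#' The squared Euclidean (perpendicular) distance of an observation from
#' the A-dimensional latent subspace: `SPE = e' e` with `e` the residual of
#' the observation after projection. Breaks in the correlation structure of
#' the data inflate this statistic.
#'
#' @inheritParams hotelling_t2
#' @return Named numeric vector of non-negative SPE values.
#' @export
spe <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(newdata)) {
    return(drop(rowSums(model$residuals^2)))
  }
  drop(rowSums(.pca_residuals(model, newdata)^2))
}

.pca_residuals <- function(model, newdata) {
  xc <- .pca_preprocess(model, newdata)
  xc - (xc %*% model$loadings) %*% t(model$loadings)
}

#' Per-variable SPE contributions
#'
#' Decomposes each observation's SPE into per-variable squared residuals
#' `e[i, k]^2`; the variable with the highest contribution is the usual
#' suspect when diagnosing which measurement broke the correlation
#' structure (contribution analysis).
#'
#' @inheritParams hotelling_t2
#' @return Numeric matrix (observations x variables); each row sums to that
#'   observation's SPE.
#' @export
spe_contributions <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(newdata)) model$residuals^2 else .pca_residuals(model, newdata)^2
}

#' Number of components explaining a variance fraction
#'
#' Smallest `A` whose cumulative explained variance of the centred matrix
#' reaches `fraction` (default 90 %), truncated at `cap`. This is the rule
#' used on the imputation path, where the model must capture most of the
#' systematic variability to reconstruct missing cells.
#'
#' @param x Complete numeric matrix or data frame.
#' @param fraction Target cumulative fraction in (0, 1].
#' @param cap Upper bound on `A`; defaults to `min(n - 1, p, 50)` (large
#'   matrices are truncated at 50 components to keep the iteration cheap).
#' @param scale Autoscale before the decomposition (default `FALSE`: the
#'   imputation path centres only).
#' @return Integer component count, at least 1.
#' @export
n_components_variance <- function(x, fraction = 0.9, cap = NULL,
                                  scale = FALSE) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  m <- as_curation_matrix(x, require_complete = TRUE,
                          min_rows = 3L, min_cols = 2L)
  amax <- min(nrow(m) - 1L, ncol(m))
  cap <- min(amax, cap %||% min(amax, 50L))
  fit <- pca_fit(m, ncomp = 1L, scale = scale)
  cum <- fit$explained_variance
  a <- which(cum >= fraction - 1e-12)[1L]
  if (is.na(a)) a <- amax
  max(1L, min(as.integer(a), as.integer(cap)))
}

#' Number of components by the eigenvalue-greater-than-one rule
#'
#' Counts the eigenvalues of the correlation structure (PCA of the
#' autoscaled matrix) strictly greater than 1, with a floor of one
#' component. On autoscaled data each original variable carries unit
#' variance, so a component with eigenvalue above 1 summarises more than a
#' single variable's worth of information (Kaiser-type rule). This is the
#' rule used on the outlier-monitoring path, where only the dominant
#' directions of variability should enter the model.
#'
#' @param x Complete numeric matrix or data frame; constant columns are
#'   rejected (autoscaling undefined).
#' @return Integer component count, at least 1.
#' @export
n_components_eigenvalue <- function(x) {
  m <- as_curation_matrix(x, require_complete = TRUE,
                          min_rows = 3L, min_cols = 2L)
  fit <- pca_fit(m, ncomp = 1L, scale = TRUE)
  max(1L, sum(fit$eigenvalues > 1 + 1e-12))
}

#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = matrix_tbl(x$scores, row_col = "row") |>
      tidyr::pivot_longer(-"row", names_to = "component",
                          values_to = "score"),
    loadings = matrix_tbl(x$loadings, row_col = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "component",
                          values_to = "loading"),
    eigenvalues = tibble(
      component = paste0("PC", seq_along(x$eigenvalues)),
      eigenvalue = x$eigenvalues,
      cumulative = x$explained_variance
    )
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(
    n = x$n,
    p = length(x$center),
    ncomp = x$ncomp,
    scaled = x$scaled,
    explained_variance = x$explained_variance[x$ncomp]
  )
}

#' @export
augment.pca_model <- function(x, ...) {
  tibble(
    row = rownames(x$scores) %||% as.character(seq_len(x$n)),
    t2 = hotelling_t2(x),
    spe = spe(x)
  )
}

#' @rdname autoplot_netcure
#' @export
autoplot.pca_model <- function(object, ...) {
  dat <- augment(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t2, y = .data$spe)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hotelling T²", y = "SPE",
                  title = "PCA monitoring statistics") +
    ggplot2::theme_minimal()
}

#' Serialise / restore a PCA model as JSON
#'
#' Writes the model's mean, scale, loadings, score variances and component
#' count to a JSON sidecar so a fit can be audited or reused.
#'
#' @param model A `pca_model`.
#' @param path File path to write to.
#' @return `path`, invisibly (`pca_write_json`); a list (`pca_read_json`).
#' @export
pca_write_json <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  obj <- list(
    center = unname(model$center),
    scale = unname(model$scale),
    scaled = model$scaled,
    loadings = unname(model$loadings),
    score_variances = unname(model$score_variances),
    ncomp = model$ncomp,
    variables = colnames(model$loadings) %||% NULL,
    variable_names = names(model$center)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pca_write_json
#' @export
pca_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- as.matrix(obj$loadings)
  obj
}
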