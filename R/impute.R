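#' Impute missing values in a data matrix
#'
#' Front door to the six imputation methods of the comparative framework:
#'
#' * `"tsr"` — trimmed scores regression: iterative PCA in which each
#'   incomplete row's missing part is regressed on the scores of a PCA
#'   restricted to that row's observed columns (the recommended method);
#' * `"ia"` — iterative algorithm: iterative PCA replacing missing cells
#'   with the full model's reconstruction;
#' * `"cc"` — complete-case analysis: drop incomplete rows;
#' * `"mean"` (alias `"mi"`) — unconditional mean imputation;
#' * `"li"` — linear interpolation along the row (time) order;
#' * `"nn"` — nearest-neighbour imputation.
#'
#' Every method leaves originally observed cells bit-identical and returns
#' a completed matrix free of missing markers (for `"cc"`, the retained
#' complete rows).
#'
#' @param x Numeric matrix or data frame with missing cells marked `NA`.
#' @param method One of `"tsr"`, `"ia"`, `"cc"`, `"mean"` (`"mi"`), `"li"`,
#'   `"nn"`.
#' @param ... Passed to the method-specific function.
#' @return An [imputation result][impute_tsr] object.
#' @examples
#' x <- matrix(c(1, 2, NA, 2, 4, 6), 3, 2)
#' impute(x, "mean")$completed
#' @export
impute <- function(x, method = c("tsr", "ia", "cc", "mean", "mi", "li", "nn"),
                   ...) {
  method <- match.arg(method)
  switch(method,
    tsr = impute_tsr(x, ...),
    ia = impute_ia(x, ...),
    cc = impute_cc(x, ...),
    mean = ,
    mi = impute_mean(x, ...),
    li = impute_li(x, ...),
    nn = impute_nn(x, ...)
  )
}

new_imputation_result <- function(x, completed, method, ncomp = NA_integer_,
                                  iterations = 0L, converged = TRUE,
                                  dropped_rows = integer()) {
  miss <- which(is.na(x), arr.ind = TRUE)
  cells <- if (method == "cc" || nrow(miss) == 0L) {
    tibble(row = integer(), col = integer(),
           row_id = character(), variable = character(), value = numeric())
  } else {
    tibble(
      row = as.integer(miss[, 1L]),
      col = as.integer(miss[, 2L]),
      row_id = rownames(x)[miss[, 1L]],
      variable = colnames(x)[miss[, 2L]],
      value = completed[miss]
    ) |> dplyr::arrange(.data$row, .data$col)
  }
  structure(list(
    completed = completed,
    method = method,
    n_components = ncomp,
    iterations = iterations,
    converged = converged,
    imputed_cells = cells,
    dropped_rows = dropped_rows
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method %s: %d cell%s imputed",
              toupper(x$method), nrow(x$imputed_cells),
              if (nrow(x$imputed_cells) == 1) "" else "s"))
  if (length(x$dropped_rows)) {
    cat(sprintf(", %d row(s) dropped", length(x$dropped_rows)))
  }
  if (x$iterations > 0L) {
    cat(sprintf(" (%d iterations, %sconverged, A = %d)",
                x$iterations, if (x$converged) "" else "NOT ",
                x$n_components))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.imputation_result <- function(x, ...) x$imputed_cells

#' @export
glance.imputation_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_imputed = nrow(x$imputed_cells),
    n_dropped = length(x$dropped_rows),
    n_components = x$n_components,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
augment.imputation_result <- function(x, ...) matrix_tbl(x$completed, "row")

# shared validation: rows/columns must retain at least one observed cell
.check_imputable <- function(m) {
  empty_rows <- rowSums(!is.na(m)) == 0L
  if (any(empty_rows)) {
    abort(paste0("row(s) entirely missing, nothing to condition on: ",
                 toString(rownames(m)[empty_rows])))
  }
  invisible(m)
}

# One PCA-based imputation pass shared by TSR and IA. `impute_step` maps
# (xc [centred, current matrix], miss [logical mask], ncomp) to a full
# matrix of predictions on the centred scale.
.impute_pca_loop <- function(x, method, fraction, tol, max_iter, ncomp, cap) {
  m <- as_curation_matrix(x, min_rows = 3L, min_cols = 2L)
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(m, m, method, iterations = 0L))
  }
  .check_imputable(m)
  tol <- tol %||% (1e-9 * sd(m[!miss]))
  if (!is.finite(tol) || tol <= 0) tol <- 1e-9

  work <- m
  work[miss] <- 0
  patterns <- NULL
  if (method == "tsr") {
    key <- apply(miss, 1L, function(r) paste(which(r), collapse = ","))
    rows_with <- which(rowSums(miss) > 0L)
    patterns <- split(rows_with, key[rows_with])
  }

  a_used <- NA_integer_
  converged <- FALSE
  it <- 0L
  prev_delta <- Inf
  prev_rho <- NA_real_
  prev_step <- NULL
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(work)
    xc <- sweep(work, 2L, mu)
    a_used <- if (!is.null(ncomp)) as.integer(ncomp) else
      n_components_variance(work, fraction = fraction, cap = cap)
    pred <- if (method == "tsr") {
      .tsr_predict(xc, miss, patterns, a_used)
    } else {
      .ia_predict(xc, a_used)
    }
    new_vals <- pred[miss] + rep(mu, each = nrow(m))[miss]
    step <- new_vals - work[miss]
    delta <- mean(abs(step))
    work[miss] <- new_vals
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # Aitken extrapolation: the update is (asymptotically) a linear
    # fixed-point iteration, so once the contraction rate rho stabilises
    # the remaining error is ~ step * rho / (1 - rho); jumping there keeps
    # the same fixed point while collapsing slow geometric tails
    rho <- delta / prev_delta
    if (it %% 5L == 0L && is.finite(rho) && !is.na(prev_rho) &&
        rho > 0.3 && rho < 0.9999 && abs(rho - prev_rho) < 0.05 * rho &&
        !is.null(prev_step)) {
      work[miss] <- work[miss] + step * rho / (1 - rho)
    }
    prev_rho <- rho
    prev_delta <- delta
    prev_step <- step
  }
  if (!converged) {
    warn(sprintf("%s imputation did not converge in %d iterations",
                 toupper(method), max_iter))
  }
  out <- m
  out[miss] <- work[miss]
  new_imputation_result(m, out, method, ncomp = a_used, iterations = it,
                        converged = converged)
}

# TSR step: for each missing pattern, PCA on the observed-column submatrix
# (all rows, current imputations), then least squares of the missing
# columns on those scores; predictions for the pattern's rows.
.tsr_predict <- function(xc, miss, patterns, ncomp) {
  n <- nrow(xc)
  pred <- xc
  for (rows in patterns) {
    mis <- which(miss[rows[1L], ])
    obs <- which(!miss[rows[1L], ])
    if (length(obs) == 0L) next  # guarded earlier
    xobs <- xc[, obs, drop = FALSE]
    a_sub <- min(ncomp, length(obs), n - 1L)
    sv <- svd(xobs, nu = 0L, nv = a_sub)
    tstar <- xobs %*% sv$v[, seq_len(a_sub), drop = FALSE]
    g <- crossprod(tstar)
    rhs <- crossprod(tstar, xc[, mis, drop = FALSE])
    beta <- tryCatch(solve(g, rhs), error = function(e) {
      solve(g + diag(1e-8 * sum(diag(g)) / nrow(g), nrow(g)), rhs)
    })
    pred[rows, mis] <- tstar[rows, , drop = FALSE] %*% beta
  }
  pred
}

# IA step: reconstruction from the full-data PCA model.
.ia_predict <- function(xc, ncomp) {
  a <- min(ncomp, nrow(xc) - 1L, ncol(xc))
  sv <- svd(xc, nu = a, nv = a)
  sweep(sv$u, 2L, sv$d[seq_len(a)], "*") %*% t(sv$v)
}

#' Trimmed scores regression (TSR) imputation
#'
#' Iterative latent-structure imputation. Starting from zeros in the holes,
#' each pass centres the data, selects the number of components needed to
#' explain `fraction` of the variance (recomputed every pass, capped at
#' `cap`), and for every missing-data pattern regresses the missing columns
#' on the scores of a PCA restricted to that pattern's observed columns —
#' so each row's holes are predicted from the latent directions its own
#' observed part can see. Iteration stops when the mean absolute change of
#' the imputed values falls below `tol`.
#'
#' @param x Numeric matrix or data frame with `NA` holes; every row and
#'   column must retain at least one observed cell.
#' @param fraction Target explained-variance fraction for the component
#'   count (default 0.90).
#' @param tol Convergence threshold on the mean absolute change of imputed
#'   values; default `1e-6` times the standard deviation of the observed
#'   cells.
#' @param max_iter Iteration cap (default 500); on hitting it the result is
#'   returned with `converged = FALSE` and a warning.
#' @param ncomp Fixed component count overriding the variance rule.
#' @param cap Component cap passed to [n_components_variance()] (default
#'   50).
#' @return An object of class `imputation_result` with elements
#'   `completed` (numeric matrix), `method`, `n_components`, `iterations`,
#'   `converged`, `imputed_cells` (tibble: row, col, row_id, variable,
#'   value) and `dropped_rows`. `tidy()` returns the imputed cells,
#'   `glance()` the method metadata, `augment()` the completed matrix as a
#'   tibble.
#' @export
impute_tsr <- function(x, fraction = 0.9, tol = NULL, max_iter = 5000L,
                       ncomp = NULL, cap = 50L) {
  .impute_pca_loop(x, "tsr", fraction, tol, max_iter, ncomp, cap)
}

#' Iterative algorithm (IA) imputation
#'
#' Iterative PCA imputation that differs from [impute_tsr()] only in the
#' imputation step: missing cells are replaced by the reconstruction
#' `mean + T P'` of the PCA model fitted on all (currently completed)
#' data, with no per-pattern regression.
#'
#' @inheritParams impute_tsr
#' @inherit impute_tsr return
#' @export
impute_ia <- function(x, fraction = 0.9, tol = NULL, max_iter = 5000L,
                      ncomp = NULL, cap = 50L) {
  .impute_pca_loop(x, "ia", fraction, tol, max_iter, ncomp, cap)
}

#' Complete-case analysis
#'
#' Drops every row containing a missing cell. Wasteful — it is included as
#' the baseline practitioners reach for first — and inapplicable when no
#' row is complete.
#'
#' @inheritParams impute_tsr
#' @inherit impute_tsr return
#' @export
impute_cc <- function(x) {
  m <- as_curation_matrix(x)
  keep <- rowSums(is.na(m)) == 0L
  if (!any(keep)) {
    abort("CC not applicable: every row contains missing values")
  }
  new_imputation_result(m, m[keep, , drop = FALSE], "cc",
                        dropped_rows = unname(which(!keep)))
}

#' Unconditional mean imputation
#'
#' Replaces each missing cell by the mean of the observed values in its
#' column. Fast, but it flattens the correlation structure the latent
#' methods try to preserve.
#'
#' @inheritParams impute_tsr
#' @inherit impute_tsr return
#' @export
impute_mean <- function(x) {
  m <- as_curation_matrix(x)
  out <- m
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  out[idx] <- mu[idx[, 2L]]
  new_imputation_result(m, out, "mean")
}

#' Linear interpolation along the time order
#'
#' Treats the row order as consecutive time points and fills each hole by
#' linear interpolation between the nearest preceding and following
#' observed values of the same column; holes at the boundaries carry the
#' nearest observed value.
#'
#' @inheritParams impute_tsr
#' @inherit impute_tsr return
#' @export
impute_li <- function(x) {
  m <- as_curation_matrix(x)
  out <- m
  short <- colSums(!is.na(m)) < 2L & colSums(is.na(m)) > 0L
  if (any(short)) {
    abort(paste0("LI needs >= 2 observed values per column; offending: ",
                 toString(colnames(m)[short])))
  }
  t_ <- seq_len(nrow(m))
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (!any(nas)) next
    out[nas, j] <- approx(t_[!nas], m[!nas, j], xout = t_[nas],
                          method = "linear", rule = 2)$y
  }
  new_imputation_result(m, out, "li")
}

#' Nearest-neighbour imputation
#'
#' Fills the holes of each incomplete row with the values of its nearest
#' neighbour among the rows observed on all the needed columns. Distance is
#' the root mean squared difference over the mutually observed columns
#' (scaling by the overlap size keeps rows with different numbers of shared
#' columns comparable). Ties go to the lowest row index; `k > 1` averages
#' the `k` nearest donors.
#'
#' @inheritParams impute_tsr
#' @param k Number of neighbours to average (default 1).
#' @inherit impute_tsr return
#' @export
impute_nn <- function(x, k = 1L) {
  m <- as_curation_matrix(x)
  out <- m
  obs <- !is.na(m)
  incomplete <- which(rowSums(!obs) > 0L)
  for (i in incomplete) {
    need <- which(!obs[i, ])
    donors <- which(seq_len(nrow(m)) != i &
                      rowSums(!obs[, need, drop = FALSE]) == 0L)
    d <- vapply(donors, function(j) {
      shared <- obs[i, ] & obs[j, ]
      if (!any(shared)) return(NA_real_)
      sqrt(mean((m[i, shared] - m[j, shared])^2))
    }, numeric(1))
    donors <- donors[!is.na(d)]
    d <- d[!is.na(d)]
    if (length(donors) == 0L) {
      abort(sprintf("NN not applicable: no eligible neighbour for row %d", i))
    }
    ord <- order(d, donors)  # distance, then lowest row index
    use <- donors[ord][seq_len(min(k, length(donors)))]
    out[i, need] <- colMeans(m[use, need, drop = FALSE])
  }
  new_imputation_result(m, out, "nn")
}
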