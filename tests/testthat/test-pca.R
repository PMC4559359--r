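test_that("rank-1 data is explained fully by one component", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = 2 * c(1, 2, 3, 4, 5))
  fit <- pca_fit(x, ncomp = 1)
  expect_equal(fit$explained_variance[1], 1)
  expect_lt(max(abs(fit$residuals)), 1e-12)
})

test_that("full-rank reconstruction mean + T P' is exact", {
  x <- rank_factor_matrix(10, 4, 4, scales = c(3, 2, 1.5, 1), seed = 3)
  fit <- pca_fit(x, ncomp = 4)
  rec <- sweep(fit$scores %*% t(fit$loadings), 2, fit$center, "+")
  expect_equal(unname(rec), unname(x), tolerance = 1e-10)
})

test_that("fit matches an eigendecomposition oracle up to column sign", {
  x <- rank_factor_matrix(20, 6, 6, scales = 6:1, noise_sd = 0.5, seed = 7)
  fit <- pca_fit(x, ncomp = 3)
  eo <- eigen(cov(x), symmetric = TRUE)
  expect_equal(fit$score_variances, eo$values[1:3], tolerance = 1e-8)
  expect_equal(abs(unname(fit$loadings)), abs(eo$vectors[, 1:3]),
               tolerance = 1e-8)
  xc <- sweep(x, 2, colMeans(x))
  res_oracle <- xc - xc %*% eo$vectors[, 1:3] %*% t(eo$vectors[, 1:3])
  expect_equal(abs(unname(fit$residuals)), abs(unname(res_oracle)),
               tolerance = 1e-8)
})

test_that("model satisfies orthonormality, score decorrelation and ordering", {
  x <- rank_factor_matrix(30, 8, 8, scales = 8:1, noise_sd = 0.2, seed = 11)
  fit <- pca_fit(x, ncomp = 5)
  expect_lt(max(abs(crossprod(fit$loadings) - diag(5))), 1e-8)
  cc <- cov(fit$scores)
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-8)
  expect_true(all(diff(fit$score_variances) <= 1e-12))
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("monitoring statistics match their defining formulas", {
  x <- rank_factor_matrix(25, 6, 6, scales = 6:1, noise_sd = 0.4, seed = 5)
  fit <- pca_fit(x, ncomp = 3)
  # Mahalanobis distance in score space, explicit loop
  t2_oracle <- sapply(seq_len(nrow(x)), function(i) {
    sum(fit$scores[i, ]^2 / fit$score_variances)
  })
  expect_equal(unname(hotelling_t2(fit)), t2_oracle, tolerance = 1e-10)
  # SPE as squared residual norm; contributions as squared residuals
  expect_equal(unname(spe(fit)), unname(rowSums(fit$residuals^2)),
               tolerance = 1e-12)
  contrib <- spe_contributions(fit)
  expect_equal(unname(rowSums(contrib)), unname(spe(fit)), tolerance = 1e-10)
  for (i in c(1, 9, 25)) {
    expect_identical(which.max(contrib[i, ]),
                     which.max(abs(fit$residuals[i, ])))
  }
  # batch and row-wise computation agree
  expect_equal(unname(hotelling_t2(fit, x[4, ])),
               unname(hotelling_t2(fit))[4], tolerance = 1e-10)
  expect_equal(unname(spe(fit, x[4, ])), unname(spe(fit))[4],
               tolerance = 1e-10)
})

test_that("the model centre has zero T2 and subspace points zero SPE", {
  x <- rank_factor_matrix(20, 5, 5, scales = 5:1, noise_sd = 0.3, seed = 2)
  fit <- pca_fit(x, ncomp = 2)
  expect_equal(unname(hotelling_t2(fit, fit$center)), 0, tolerance = 1e-20)
  in_plane <- fit$center + drop(fit$loadings %*% c(1.3, -0.7))
  expect_lt(spe(fit, in_plane), 1e-16)
})

test_that("invalid inputs are rejected", {
  x <- rank_factor_matrix(10, 4, 4, scales = 4:1, seed = 1)
  xm <- x; xm[2, 2] <- NA
  expect_error(pca_fit(xm, 2), "missing")
  expect_error(pca_fit(x, 0), "ncomp")
  expect_error(pca_fit(x, 5), "ncomp")
  expect_error(pca_fit(matrix(1, 5, 3), 1), "zero variance")
  # components beyond the rank are degenerate for T2
  fit <- pca_fit(rank_factor_matrix(10, 4, 2, scales = c(2, 1), seed = 9), 4)
  expect_error(hotelling_t2(fit), "degenerate")
  expect_error(spe(fit, rnorm(3)), "columns")
})

test_that("variance rule selects the smallest A reaching the target", {
  x1 <- cbind(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4))
  expect_identical(n_components_variance(x1), 1L)
  x <- shared_variance_matrix(40, 7, shares = c(0.80, 0.15, 0.05), seed = 4)
  expect_identical(n_components_variance(x, 0.90), 2L)
  expect_identical(n_components_variance(x, 0.96), 3L)
  expect_identical(n_components_variance(x, 0.90, cap = 1), 1L)
  expect_error(n_components_variance(matrix(2, 6, 3)), "zero variance")
})

test_that("eigenvalue rule counts correlation eigenvalues above one", {
  z <- orthonormal_columns(50, 2, seed = 6)
  # duplicated variable plus an uncorrelated one: eigenvalues {2, 1, 0}
  x <- cbind(z[, 1], z[, 1], z[, 2])
  expect_identical(n_components_eigenvalue(x), 1L)
  # four perfectly collinear variables: eigenvalues {4, 0, 0, 0}
  x4 <- cbind(z[, 1], 2 * z[, 1], -z[, 1], 0.5 * z[, 1])
  expect_identical(n_components_eigenvalue(x4), 1L)
  # exactly uncorrelated variables: all eigenvalues 1, floor applies
  expect_identical(n_components_eigenvalue(orthonormal_columns(60, 5)), 1L)
  expect_error(n_components_eigenvalue(cbind(z[, 1], rep(2, 50))),
               "constant")
})

test_that("explained variance is non-decreasing and reaches 1 at the rank", {
  x <- rank_factor_matrix(30, 6, 3, seed = 12)
  fit <- pca_fit(x, ncomp = 3)
  expect_true(all(diff(fit$explained_variance) >= -1e-12))
  expect_equal(fit$explained_variance[3], 1, tolerance = 1e-10)
})

test_that("broom methods and JSON round trip expose the fit", {
  x <- rank_factor_matrix(15, 4, 4, scales = 4:1, seed = 8)
  fit <- pca_fit(x, ncomp = 2)
  expect_named(glance(fit),
               c("n", "p", "ncomp", "scaled", "explained_variance"))
  expect_identical(nrow(tidy(fit, "loadings")), 8L)
  expect_named(augment(fit), c("row", "t2", "spe"))
  path <- withr::local_tempfile(fileext = ".json")
  pca_write_json(fit, path)
  back <- pca_read_json(path)
  expect_equal(back$center, unname(fit$center))
  expect_equal(unname(back$loadings), unname(fit$loadings))
  expect_identical(back$ncomp, fit$ncomp)
})
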