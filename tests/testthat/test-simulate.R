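test_that("the chain generator is reproducible and standardised", {
  a <- generate_chain_timeseries(seed = 5)
  b <- generate_chain_timeseries(seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(dim(a$data), c(200L, 4L))
  expect_equal(unname(colMeans(a$data)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(a$data, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_identical(sort(a$truth$edges$target), c("X", "Y", "Z"))
})

test_that("the W-Y reaction is the weakest lagged coupling", {
  weaker <- sapply(1:10, function(s) {
    x <- generate_chain_timeseries(seed = s)$data
    n <- nrow(x)
    r <- function(a, b) abs(cor(x[-n, a], x[-1, b]))
    r("W", "Y") < r("Y", "X") & r("W", "Y") < r("X", "Z")
  })
  expect_true(all(weaker))
})

test_that("zero coupling produces independent columns", {
  top <- chain_topology(weak = 0, strong = 0)
  x <- generate_chain_timeseries(120, top, seed = 2)$data
  cors <- cor(x)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.25)
})

test_that("unstable topologies are rejected", {
  cyc <- tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                        weight = c(1.2, 1.2), lag = 1L)
  expect_error(generate_chain_timeseries(topology = cyc), "unstable")
  stable_cycle <- tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                                 weight = c(0.5, 0.5), lag = 1L)
  expect_silent(generate_chain_timeseries(topology = stable_cycle, seed = 1))
})

test_that("MCAR injection deletes the exact count and keeps rows/columns", {
  x <- matrix(rnorm(100), 10, 10)
  xm <- inject_missing_mcar(x, 5, seed = 3)
  expect_identical(sum(is.na(xm)), 5L)
  mask <- attr(xm, "mask")
  expect_identical(sort(which(is.na(xm))),
                   sort(mask[, "row"] + (mask[, "col"] - 1L) * 10L))
  expect_true(all(rowSums(!is.na(xm)) >= 1))
  expect_true(all(colSums(!is.na(xm)) >= 1))
  expect_identical(inject_missing_mcar(x, 5, seed = 3), xm)
  # a percentage rounding to zero cells is the identity
  x2 <- matrix(rnorm(9), 3, 3)
  expect_identical(sum(is.na(inject_missing_mcar(x2, 4, seed = 1))), 0L)
  expect_error(inject_missing_mcar(x, 45, min_observed = 8), "infeasible")
  xm2 <- inject_missing_mcar(x, 30, seed = 9, min_observed = 4)
  expect_true(all(rowSums(!is.na(xm2)) >= 4))
})

test_that("univariate injection lands beyond the box-plot fences", {
  x <- rank_factor_matrix(57, 6, 2, scales = c(2, 1), noise_sd = 0.5,
                          seed = 5)
  out <- inject_univariate_outliers(x, pct = 1, seed = 2)
  expect_identical(nrow(out$cells), 2L)  # 1 % of 57 rows, minimum of 2
  for (k in seq_len(nrow(out$cells))) {
    j <- out$cells$col[k]
    q <- quantile(x[, j], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    v <- out$cells$value[k]
    expect_true(v > q[2] + 3 * iqr || v < q[1] - 3 * iqr)
  }
  # quartiles 0 and 1: a high injection must exceed the fence at 4
  xq <- cbind(rep(c(0, 0, 1, 1), 10), rep(2, 40))  # col 2 has zero IQR
  out2 <- inject_univariate_outliers(xq, pct = 5, seed = 4)
  expect_true(all(out2$cells$col == 1L))  # zero-IQR column is redrawn
  # fences sit at -3 and 4; injections land half an IQR beyond them
  expect_true(all(out2$cells$value %in% c(4.5, -3.5)))
})

test_that("multivariate injection reflects eligible cells across the mean", {
  x <- rank_factor_matrix(80, 6, 2, scales = c(2, 1), noise_sd = 0.5,
                          seed = 9)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  out <- inject_multivariate_outliers(x, pct = 5, seed = 6)
  cells <- out$cells
  expect_identical(nrow(cells), 4L)  # 5 % of 80
  expect_equal(cells$value, 2 * mu[cells$col] - cells$original,
               ignore_attr = TRUE)
  expect_true(all(abs(cells$original - mu[cells$col]) >
                    1.5 * sdv[cells$col]))
  # reflecting twice restores the original exactly
  expect_equal(2 * mu[cells$col] - cells$value, cells$original,
               ignore_attr = TRUE)
  # reflected values stay inside the univariate fences of Gaussian columns
  for (k in seq_len(nrow(cells))) {
    j <- cells$col[k]
    q <- quantile(x[, j], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    expect_true(cells$value[k] <= q[2] + 3 * iqr &&
                  cells$value[k] >= q[1] - 3 * iqr)
  }
})

test_that("a small study is reproducible and fully scored", {
  cfg <- list(
    corruption = "mcar", methods = c("mean", "li"), percentages = 10,
    n_reps = 2, seed = 7, generator = list(n_timepoints = 60),
    infer_args = list(max_lag = 2, n_perm = 10)
  )
  s1 <- do.call(run_study, cfg)
  s2 <- do.call(run_study, cfg)
  expect_identical(s1$results, s2$results)
  expect_identical(nrow(s1$results), 4L)
  expect_named(s1$results, c("corruption", "method", "pct", "rep", "tp",
                             "fp", "fn", "precision", "recall", "note"))
  expect_true(all(!is.na(s1$results$precision)))
  expect_identical(sort(unique(s1$comparisons$metric)),
                   c("precision", "recall"))
  g <- glance(s1)
  expect_identical(nrow(g), 2L)
})

test_that("methods that cannot run record missing entries, not zeros", {
  # 10-species chain at 35 % missing: no complete rows, so CC must fail
  chain10 <- tibble::tibble(source = paste0("S", 1:9),
                            target = paste0("S", 2:10),
                            weight = 1, lag = 1L)
  st <- run_study(
    corruption = "mcar", methods = c("cc", "mean"), percentages = 35,
    n_reps = 1, seed = 2,
    generator = list(n_timepoints = 40, topology = chain10),
    infer_args = list(max_lag = 1, n_perm = 5)
  )
  cc_row <- st$results[st$results$method == "cc", ]
  expect_true(is.na(cc_row$precision))
  expect_match(cc_row$note, "CC not applicable")
  expect_false(is.na(st$results[st$results$method == "mean", ]$precision))
})
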