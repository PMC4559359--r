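test_that("degenerate resampling reproduces the full-sample quantile", {
  set.seed(1)
  v <- rchisq(50, df = 4)
  lim <- spe_control_limit(v, subset_fraction = 1, n_subsets = 20, seed = 1)
  q95 <- unname(quantile(v, 0.95, type = 7))
  expect_identical(lim$limit, q95)
  expect_true(all(lim$per_subset_limits == q95))
})

test_that("resampled limit tracks the analytic quantile of a chi-square", {
  set.seed(42)
  v <- rchisq(1000, df = 5)
  lim <- spe_control_limit(v, seed = 7)
  expect_lt(abs(lim$limit - qchisq(0.95, 5)) / qchisq(0.95, 5), 0.05)
})

test_that("the limit is deterministic under a fixed seed", {
  v <- rchisq(100, df = 3)
  a <- spe_control_limit(v, seed = 11)
  b <- spe_control_limit(v, seed = 11)
  expect_identical(a$per_subset_limits, b$per_subset_limits)
  expect_identical(a$limit, b$limit)
  expect_error(spe_control_limit(rchisq(5, 2)), "at least 10")
})

test_that("classification applies the two extremeness rules and excusal", {
  # 2x rule: 25 extreme; 11 a false alarm; 9 in control
  cls <- classify_extreme(c(25, 11, 9), limit = 10, alpha = 0.05)
  expect_identical(cls$status, c("extreme", "excused", "in_control"))
  expect_identical(cls$rule[1], "above_2x_limit")
  # distance rule: gap to limit 6 > 10 * (10.5 - 10)
  cls2 <- classify_extreme(c(rep(4, 10), 10.5, 16), limit = 10)
  expect_identical(cls2$status[12], "extreme")
  expect_identical(cls2$rule[12], "distance_10x_false_alarm")
  expect_identical(cls2$status[11], "excused")
  # nothing above the limit
  cls3 <- classify_extreme(c(1, 2, 3), limit = 10)
  expect_true(all(cls3$status == "in_control"))
})

test_that("excusal quota is granted smallest-first and overflow flagged", {
  v <- c(rep(5, 16), 10.5, 11, 12, 25)  # n = 20, quota = 1
  cls <- classify_extreme(v, limit = 10, alpha = 0.05)
  expect_identical(cls$status[20], "extreme")     # 25 > 2 * limit
  expect_identical(cls$status[17], "excused")     # most marginal point
  expect_identical(cls$status[18:19], c("extreme", "extreme"))
  expect_true(all(cls$rule[18:19] == "beyond_false_alarm_quota"))
})

test_that("faulty-variable isolation takes the largest contribution", {
  expect_identical(isolate_faulty_variable(c(1, 9, 4)), 2L)
  expect_identical(isolate_faulty_variable(c(4, 4)), 1L)
  expect_error(isolate_faulty_variable(c(0, 0, 0)), "zero")
  set.seed(3)
  for (k in 1:10) {
    e <- rnorm(7)
    expect_identical(isolate_faulty_variable(e^2), which.max(abs(e)))
  }
})

test_that("cure detects a reflected multivariate outlier and repairs it", {
  x <- rank_factor_matrix(100, 8, 3, scales = c(4, 2, 1), noise_sd = 0.3,
                          seed = 7)
  out <- inject_multivariate_outliers(x, pct = 5, seed = 3)
  cu <- suppressWarnings(cure(out$data, seed = 11))
  idx <- cbind(out$cells$row, out$cells$col)
  expect_true(all(out$cells$row %in% cu$report$records$row))
  expect_lt(mean(abs(cu$data[idx] - x[idx])),
            mean(abs(out$data[idx] - x[idx])))
})

test_that("cure detects a fence-violating univariate outlier", {
  x <- rank_factor_matrix(80, 6, 2, scales = c(3, 1.5), noise_sd = 0.3,
                          seed = 15)
  out <- inject_univariate_outliers(x, pct = 2, seed = 5)
  cu <- suppressWarnings(cure(out$data, seed = 9))
  expect_true(all(out$cells$row %in% cu$report$records$row))
  # after repair the injected rows are no longer extreme outliers
  a <- n_components_eigenvalue(cu$data)
  fit <- pca_fit(cu$data, a, scale = TRUE)
  cls <- classify_extreme(spe(fit), cu$report$limits[[cu$report$rounds]])
  expect_true(all(cls$status[out$cells$row] != "extreme"))
})

test_that("only reported cells differ between input and cured output", {
  x <- rank_factor_matrix(60, 6, 2, scales = c(3, 1.5), noise_sd = 0.3,
                          seed = 21)
  out <- inject_multivariate_outliers(x, pct = 5, seed = 2)
  cu <- suppressWarnings(cure(out$data, seed = 4))
  rec <- cu$report$records
  changed <- which(cu$data != out$data, arr.ind = TRUE)
  expect_setequal(paste(changed[, 1], changed[, 2]),
                  paste(rec$row, rec$col))
  expect_true(all(rec$rule %in% c("above_2x_limit",
                                  "distance_10x_false_alarm",
                                  "beyond_false_alarm_quota")))
  expect_true(all(rec$spe > rec$limit))
  expect_true(all(diff(rec$spe) <= 0))  # sorted by decreasing SPE
})

test_that("cure is deterministic and TSR-imputes missing cells first", {
  x <- rank_factor_matrix(50, 6, 2, scales = c(3, 1.5), noise_sd = 0.3,
                          seed = 30)
  xm <- x
  xm[4, 2] <- NA
  a <- suppressWarnings(cure(xm, seed = 5))
  b <- suppressWarnings(cure(xm, seed = 5))
  expect_identical(a$data, b$data)
  expect_identical(a$report$records, b$report$records)
  expect_identical(a$report$n_missing_imputed, 1L)
  expect_false(anyNA(a$data))
})

test_that("curation tidiers summarise the report", {
  x <- rank_factor_matrix(60, 6, 2, scales = c(3, 1.5), noise_sd = 0.3,
                          seed = 33)
  out <- inject_multivariate_outliers(x, pct = 5, seed = 8)
  cu <- suppressWarnings(cure(out$data, seed = 6))
  expect_identical(tidy(cu), cu$report$records)
  g <- glance(cu)
  expect_identical(g$n_corrected, nrow(cu$report$records))
  expect_gt(g$final_limit, 0)
  expect_identical(nrow(augment(cu)), 60L)
})
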