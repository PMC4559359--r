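#' Resampled upper control limit for a monitoring statistic
#'
#' Real data rarely satisfy the distributional assumptions behind
#' theoretical SPE limits, so the 95 % limit is estimated empirically by
#' resampling: `n_subsets` random subsets of the SPE values (drawn without
#' replacement, size `ceiling(subset_fraction * n)`) each yield their
#' empirical `1 - alpha` quantile — a "real" limit leaving a fraction
#' `alpha` of the subset above it — and the final limit is the median of
#' the per-subset limits.
#'
#' @param values Numeric vector of non-negative statistic values (one per
#'   observation); at least 10.
#' @param alpha False-alarm rate (default 0.05, i.e. a 95 % limit).
#' @param n_subsets Number of resampled subsets (default 1000).
#' @param subset_fraction Fraction of observations per subset (default
#'   0.8); at 1.0 the limit degenerates to the full-sample quantile.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Object of class `control_limit` with fields `limit`,
#'   `per_subset_limits`, `statistic`, `alpha`, `n_subsets`,
#'   `subset_fraction` and `seed`.
#' @export
spe_control_limit <- function(values, alpha = 0.05, n_subsets = 1000L,
                              subset_fraction = 0.8, seed = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 10L) abort("need at least 10 values to estimate a control limit")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (subset_fraction <= 0 || subset_fraction > 1) {
    abort("`subset_fraction` must be in (0, 1]")
  }
  size <- ceiling(subset_fraction * n)
  lims <- with_seed_opt(seed, {
    vapply(seq_len(n_subsets), function(b) {
      idx <- if (size == n) seq_len(n) else sample.int(n, size)
      unname(quantile(values[idx], probs = 1 - alpha, type = 7))
    }, numeric(1))
  })
  structure(list(
    statistic = "SPE",
    alpha = alpha,
    n_subsets = as.integer(n_subsets),
    subset_fraction = subset_fraction,
    per_subset_limits = lims,
    limit = median(lims),
    seed = seed
  ), class = "control_limit")
}

#' @export
print.control_limit <- function(x, ...) {
  cat(sprintf("<control_limit> %s %.0f %% limit = %.4g (median of %d resampled quantiles)\n",
              x$statistic, 100 * (1 - x$alpha), x$limit, x$n_subsets))
  invisible(x)
}

#' Classify observations above a control limit
#'
#' A limit at confidence `1 - alpha` carries an intrinsic false-alarm rate:
#' about `alpha * n` observations are expected above it without being
#' faulty. Candidates above the limit are therefore ordered by decreasing
#' statistic and split by two extremeness rules that are never excusable:
#'
#' * `above_2x_limit` — the value exceeds twice the limit;
#' * `distance_10x_false_alarm` — its distance to the limit exceeds 10
#'   times the distance between the lowest above-limit value and the limit.
#'
#' Remaining above-limit points are excused as admissible false alarms,
#' smallest first, up to `ceiling(alpha * n)`; any left beyond that quota
#' are flagged `beyond_false_alarm_quota`.
#'
#' @param values Numeric statistic vector (one value per observation).
#' @param limit A [spe_control_limit()] object or a single number.
#' @param alpha False-alarm rate used for the excusal quota; defaults to
#'   the limit object's `alpha` (0.05 for a plain number).
#' @return A tibble with one row per observation, in original order:
#'   `row`, `value`, `status` in `in_control` / `excused` / `extreme`, and
#'   `rule` (NA unless extreme).
#' @export
classify_extreme <- function(values, limit, alpha = NULL) {
  lim <- if (inherits(limit, "control_limit")) limit$limit else as.numeric(limit)
  alpha <- alpha %||%
    (if (inherits(limit, "control_limit")) limit$alpha else 0.05)
  values <- as.numeric(values)
  n <- length(values)
  status <- rep("in_control", n)
  rule <- rep(NA_character_, n)
  above <- which(values > lim)
  if (length(above) > 0L) {
    lowest_gap <- min(values[above]) - lim
    r1 <- values[above] > 2 * lim
    r2 <- (values[above] - lim) > 10 * lowest_gap
    status[above[r1 | r2]] <- "extreme"
    rule[above[r1]] <- "above_2x_limit"
    rule[above[r2 & !r1]] <- "distance_10x_false_alarm"
    quota <- ceiling(alpha * n)
    rest <- above[!(r1 | r2)]
    rest <- rest[order(values[rest])]  # most marginal excused first
    exc <- head(rest, quota)
    status[exc] <- "excused"
    over <- setdiff(rest, exc)
    status[over] <- "extreme"
    rule[over] <- "beyond_false_alarm_quota"
  }
  tibble(row = seq_len(n), value = values, status = status, rule = rule)
}

#' Isolate the variable responsible for an extreme observation
#'
#' Returns the column with the largest SPE contribution (squared residual)
#' for a flagged row; ties are broken by the lowest column index.
#'
#' @param contributions Numeric vector of per-variable squared residuals
#'   for one observation (a row of [spe_contributions()]).
#' @return Integer column index.
#' @export
isolate_faulty_variable <- function(contributions) {
  contributions <- as.numeric(contributions)
  if (all(contributions == 0)) {
    abort("all contributions are zero; cannot isolate a faulty variable")
  }
  which.max(contributions)  # which.max takes the first (lowest) index on ties
}

#' Detect and correct extreme outliers in a data matrix
#'
#' The curation pipeline for faulty measurements. Missing cells, if any,
#' are first imputed by TSR. Then, per round: the matrix is autoscaled and
#' a PCA model is fitted with the eigenvalue-greater-than-one rule; each
#' row's SPE is compared against a resampled 95 % control limit
#' ([spe_control_limit()]); above-limit rows are classified by
#' [classify_extreme()]; for each extreme row the variable with the highest
#' SPE contribution is declared faulty, that single cell is replaced by a
#' missing value, and the punctured matrix is re-imputed by TSR so the
#' replacement is coherent with the latent structure of the remaining
#' data. Rounds repeat until no extreme outlier remains or `max_rounds` is
#' reached (rows corrupted in several variables need one round per
#' variable). Hotelling T2 is reported for audit but triggers no
#' correction: T2 outliers are extreme yet coherent with the correlation
#' structure, while SPE outliers break it and are the ones to fix.
#'
#' @param x Numeric matrix or data frame; `NA` cells allowed.
#' @param alpha False-alarm rate of the limit (default 0.05).
#' @param n_subsets,subset_fraction Resampling settings for
#'   [spe_control_limit()].
#' @param max_rounds Detection/correction rounds cap (default 5).
#' @param fraction Explained-variance target of the TSR imputations.
#' @param seed Optional integer seed driving all resampling.
#' @return Object of class `curation_result`: list with `data` (the cured
#'   numeric matrix) and `report` (class `curation_report`) holding
#'   `records` (tibble of corrections sorted by decreasing SPE: row,
#'   row_id, variable, col, spe, rule, limit, round, original, corrected),
#'   `limits` (per-round `control_limit`s), `model_components` (per-round
#'   A), `n_excused` (per-round counts), `rounds`,
#'   `n_missing_imputed`, and `exhausted` (TRUE when `max_rounds` ended the
#'   loop with extremes still present).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 50, 6) %*% matrix(rnorm(36), 6, 6)
#' cure(x)$report
#' @export
cure <- function(x, alpha = 0.05, n_subsets = 1000L, subset_fraction = 0.8,
                 max_rounds = 5L, fraction = 0.9, seed = NULL) {
  m <- as_curation_matrix(x, min_rows = 10L, min_cols = 2L)
  n_missing <- sum(is.na(m))
  if (n_missing > 0L) {
    m <- impute_tsr(m, fraction = fraction)$completed
  }
  records <- list()
  limits <- list()
  comps <- integer()
  excused <- integer()
  exhausted <- FALSE
  round <- 0L
  repeat {
    round <- round + 1L
    a <- n_components_eigenvalue(m)
    fit <- pca_fit(m, ncomp = a, scale = TRUE)
    s <- spe(fit)
    lim <- spe_control_limit(
      s, alpha = alpha, n_subsets = n_subsets,
      subset_fraction = subset_fraction,
      seed = if (is.null(seed)) NULL else seed + round - 1L
    )
    cls <- classify_extreme(s, lim)
    limits[[round]] <- lim
    comps[round] <- a
    excused[round] <- sum(cls$status == "excused")
    ext <- cls$row[cls$status == "extreme"]
    if (length(ext) == 0L) break
    contrib <- spe_contributions(fit)
    punctured <- m
    recs <- lapply(ext, function(i) {
      j <- isolate_faulty_variable(contrib[i, ])
      punctured[i, j] <<- NA_real_
      tibble(row = i, row_id = rownames(m)[i], variable = colnames(m)[j],
             col = j, spe = s[[i]], rule = cls$rule[[i]],
             limit = lim$limit, round = round, original = m[i, j])
    })
    fixed <- impute_tsr(punctured, fraction = fraction)$completed
    recs <- dplyr::bind_rows(recs)
    recs$corrected <- fixed[cbind(recs$row, recs$col)]
    records[[round]] <- recs
    m <- fixed
    if (round >= max_rounds) {
      exhausted <- TRUE
      warn(sprintf("cure: max_rounds = %d exhausted with extreme outliers remaining",
                   max_rounds))
      break
    }
  }
  records <- if (length(records)) {
    dplyr::arrange(dplyr::bind_rows(records), dplyr::desc(.data$spe))
  } else {
    tibble(row = integer(), row_id = character(), variable = character(),
           col = integer(), spe = numeric(), rule = character(),
           limit = numeric(), round = integer(), original = numeric(),
           corrected = numeric())
  }
  report <- structure(list(
    records = records,
    limits = limits,
    model_components = comps,
    n_excused = excused,
    rounds = round,
    n_missing_imputed = n_missing,
    exhausted = exhausted
  ), class = "curation_report")
  structure(list(data = m, report = report), class = "curation_result")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d correction%s in %d round%s (final SPE limit %.4g)\n",
              nrow(x$records), if (nrow(x$records) == 1) "" else "s",
              x$rounds, if (x$rounds == 1) "" else "s",
              x$limits[[x$rounds]]$limit))
  if (x$n_missing_imputed > 0L) {
    cat(sprintf("  %d missing cell(s) TSR-imputed before monitoring\n",
                x$n_missing_imputed))
  }
  if (nrow(x$records) > 0L) print(x$records)
  invisible(x)
}

#' @export
print.curation_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
tidy.curation_report <- function(x, ...) x$records

#' @export
tidy.curation_result <- function(x, ...) tidy(x$report)

#' @export
glance.curation_report <- function(x, ...) {
  tibble(
    n_corrected = nrow(x$records),
    rounds = x$rounds,
    final_limit = x$limits[[x$rounds]]$limit,
    n_excused_final = x$n_excused[x$rounds],
    n_missing_imputed = x$n_missing_imputed,
    exhausted = x$exhausted
  )
}

#' @export
glance.curation_result <- function(x, ...) glance(x$report)

#' @export
augment.curation_result <- function(x, ...) matrix_tbl(x$data, "row")

#' Diagnostic plots for netcure result objects
#'
#' `autoplot.curation_result` shows each observation's SPE in the final
#' monitoring round against the resampled control limit, highlighting the
#' corrected rows. `autoplot.pca_model` draws the T2/SPE monitoring plane.
#' `autoplot.inferred_network` sketches the inferred links on a circular
#' layout. `autoplot.curation_study` maps mean precision and recall by
#' method and corruption level.
#'
#' @param object A netcure result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_netcure
NULL

#' @rdname autoplot_netcure
#' @export
autoplot.curation_result <- function(object, ...) {
  rep_ <- object$report
  a <- n_components_eigenvalue(object$data)
  fit <- pca_fit(object$data, ncomp = a, scale = TRUE)
  dat <- tibble(
    row = seq_len(nrow(object$data)),
    spe = spe(fit),
    corrected = seq_len(nrow(object$data)) %in% rep_$records$row
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$row, y = .data$spe)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$row, yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$corrected)) +
    ggplot2::geom_hline(yintercept = rep_$limits[[rep_$rounds]]$limit,
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "observation", y = "SPE (after curation)",
                  colour = "corrected") +
    ggplot2::theme_minimal()
}
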