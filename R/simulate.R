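#' Default four-species chain topology
#'
#' A small chain of three reactions between four species, W -> Y -> X -> Z,
#' with the W-Y coupling much weaker than the other two. Weights are the
#' coefficients of the lagged linear dynamics in
#' [generate_chain_timeseries()].
#'
#' @param weak,strong Coupling weights for the weak (W -> Y) and strong
#'   (Y -> X, X -> Z) reactions.
#' @return A tibble with columns `source`, `target`, `weight`, `lag`.
#' @export
chain_topology <- function(weak = 0.8, strong = 2) {
  tibble(
    source = c("W", "Y", "X"),
    target = c("Y", "X", "Z"),
    weight = c(weak, strong, strong),
    lag = c(1L, 1L, 1L)
  )
}

#' Simulate a lagged linear stochastic network
#'
#' Generates multivariate time series from the linear lagged process
#' `x_j(t) = sum_parents w * x_parent(t - lag) + eps`, with Gaussian
#' innovations of standard deviation `noise_sd`, a burn-in of 100 steps,
#' and standardised columns. The default topology is the weak-link chain of
#' [chain_topology()]. Cyclic topologies are admitted as a vector
#' autoregression and rejected when unstable (companion spectral radius
#' >= 1).
#'
#' @param n_timepoints Number of retained time points (>= 30; default 200).
#' @param topology Edge tibble as produced by [chain_topology()].
#' @param noise_sd Innovation standard deviation (default 1).
#' @param seed Optional integer seed.
#' @return A list with `data` (n x p standardised numeric matrix, columns
#'   named by species) and `truth` (the generating network as an
#'   `inferred_network`).
#' @export
generate_chain_timeseries <- function(n_timepoints = 200L,
                                      topology = chain_topology(),
                                      noise_sd = 1, seed = NULL) {
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 30L) abort("`n_timepoints` must be >= 30")
  topology <- as_tibble(topology)
  if (!all(is.finite(topology$weight))) abort("weights must be finite")
  vars <- sort(unique(c(topology$source, topology$target)))
  p <- length(vars)
  maxlag <- max(topology$lag, 1L)

  # stability: spectral radius of the VAR companion matrix
  comp <- matrix(0, p * maxlag, p * maxlag)
  for (k in seq_len(nrow(topology))) {
    i <- match(topology$target[k], vars)
    j <- match(topology$source[k], vars)
    comp[i, (topology$lag[k] - 1L) * p + j] <- topology$weight[k]
  }
  if (maxlag > 1L) {
    comp[(p + 1L):(p * maxlag), seq_len(p * (maxlag - 1L))] <-
      diag(p * (maxlag - 1L))
  }
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1 - 1e-10) {
    abort("unstable topology: companion spectral radius >= 1")
  }

  burn <- 100L
  total <- n_timepoints + burn
  x <- with_seed_opt(seed, {
    xm <- matrix(rnorm(total * p, sd = noise_sd), total, p,
                 dimnames = list(NULL, vars))
    for (t_ in (maxlag + 1L):total) {
      for (k in seq_len(nrow(topology))) {
        i <- match(topology$target[k], vars)
        j <- match(topology$source[k], vars)
        xm[t_, i] <- xm[t_, i] +
          topology$weight[k] * xm[t_ - topology$lag[k], j]
      }
    }
    xm
  })
  x <- x[(burn + 1L):total, , drop = FALSE]
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  rownames(x) <- as.character(seq_len(n_timepoints))
  # reciprocal couplings collapse to one undirected truth edge
  et <- tibble(source = topology$source, target = topology$target,
               strength = abs(topology$weight) / max(abs(topology$weight)),
               direction = "directed", lag = as.integer(topology$lag))
  key <- paste(pmin(et$source, et$target), pmax(et$source, et$target))
  if (anyDuplicated(key)) {
    et <- et |>
      dplyr::mutate(.key = key) |>
      dplyr::group_by(.data$.key) |>
      dplyr::summarise(
        .s = min(.data$source[1], .data$target[1]),
        .t = max(.data$source[1], .data$target[1]),
        strength = max(.data$strength),
        direction = if (dplyr::n() > 1) "undirected" else .data$direction[1],
        lag = min(.data$lag),
        .groups = "drop"
      ) |>
      dplyr::transmute(source = .data$.s, target = .data$.t,
                       strength = .data$strength,
                       direction = .data$direction, lag = .data$lag)
  }
  truth <- as_network(et, variables = vars)
  list(data = x, truth = truth)
}

#' Inject missing-completely-at-random holes
#'
#' Sets exactly `round(pct / 100 * n * p)` cells to `NA`, uniformly at
#' random, redrawing the mask until every row and column keeps at least
#' one observed cell (so latent-structure imputation stays feasible).
#'
#' @param x Complete numeric matrix or data frame.
#' @param pct Percentage of cells to delete, in (0, 50) (the comparative
#'   grid runs 5-35 %); a percentage rounding to zero cells returns the
#'   input unchanged.
#' @param seed Optional integer seed.
#' @param min_observed Minimum observed cells guaranteed per row (default
#'   1). Exact low-rank recovery additionally needs every row to keep at
#'   least as many observed cells as the data rank, so recovery studies on
#'   rank-A data should set `min_observed = A`.
#' @return The matrix with `NA` holes; the deleted cells are recorded in
#'   attribute `"mask"` (two-column index matrix).
#' @export
inject_missing_mcar <- function(x, pct, seed = NULL, min_observed = 1L) {
  m <- as_curation_matrix(x, require_complete = TRUE)
  if (pct < 0 || pct >= 50) abort("`pct` must be in [0, 50)")
  n <- nrow(m)
  p <- ncol(m)
  min_observed <- max(1L, as.integer(min_observed))
  count <- round(pct / 100 * n * p)
  if (count == 0L) {
    attr(m, "mask") <- cbind(row = integer(), col = integer())
    return(m)
  }
  if (count > min(n * (p - min_observed), (n - 1L) * p)) {
    abort("`pct` infeasible: cannot keep every row and column observed")
  }
  with_seed_opt(seed, {
    for (try_ in seq_len(1000L)) {
      cells <- sample.int(n * p, count)
      rows <- ((cells - 1L) %% n) + 1L
      cols <- ((cells - 1L) %/% n) + 1L
      ok_rows <- all(tabulate(rows, n) <= p - min_observed)
      ok_cols <- all(tabulate(cols, p) < n)
      if (ok_rows && ok_cols) {
        out <- m
        out[cbind(rows, cols)] <- NA_real_
        attr(out, "mask") <- cbind(row = rows, col = cols)
        return(out)
      }
    }
    abort("could not draw a feasible MCAR mask in 1000 attempts")
  })
}

.n_outliers <- function(pct, n, min_count) max(min_count, round(pct / 100 * n))

#' Inject univariate outliers
#'
#' Corrupts `max(min_count, round(pct/100 * n))` distinct rows; in each, a
#' randomly chosen variable (with non-zero interquartile range) is replaced
#' by a value beyond the usual box-plot fences — half an IQR past
#' `Q3 + 3 IQR` (or below `Q1 - 3 IQR`; side at random) — so every
#' injected value is an outlier in the classical univariate sense.
#'
#' @param x Complete numeric matrix or data frame.
#' @param pct Percentage of rows to corrupt (the study grid uses 1, 5,
#'   10 %).
#' @param seed Optional integer seed.
#' @param min_count Minimum number of corrupted rows (default 2).
#' @return A list with `data` (corrupted matrix) and `cells` (tibble:
#'   `row`, `col`, `original`, `value`).
#' @export
inject_univariate_outliers <- function(x, pct = 1, seed = NULL,
                                       min_count = 2L) {
  m <- as_curation_matrix(x, require_complete = TRUE)
  n <- nrow(m)
  k <- .n_outliers(pct, n, min_count)
  if (k > n) abort("more outliers requested than rows available")
  q1 <- apply(m, 2L, quantile, 0.25, names = FALSE)
  q3 <- apply(m, 2L, quantile, 0.75, names = FALSE)
  iqr <- q3 - q1
  if (all(iqr == 0)) abort("all columns have zero interquartile range")
  with_seed_opt(seed, {
    rows <- sample.int(n, k)
    cells <- lapply(rows, function(i) {
      repeat {
        j <- sample.int(ncol(m), 1L)
        if (iqr[j] > 0) break
      }
      hi <- runif(1) < 0.5
      val <- if (hi) q3[j] + 3.5 * iqr[j] else q1[j] - 3.5 * iqr[j]
      tibble(row = i, col = j, original = m[i, j], value = val)
    })
    cells <- dplyr::bind_rows(cells)
    out <- m
    out[cbind(cells$row, cells$col)] <- cells$value
    list(data = out, cells = cells)
  })
}

#' Inject multivariate outliers
#'
#' Corrupts rows by reflecting one cell across its column mean: a cell
#' whose value lies more than 1.5 standard deviations from the column mean
#' (e.g. 2 in a standardised column) is moved to the other side of the
#' mean (to -2). The reflected value keeps the same univariate magnitude —
#' it is not a box-plot outlier — but it breaks the correlation structure,
#' so only a multivariate monitoring statistic can catch it. Rows without
#' an eligible cell are redrawn.
#'
#' @inheritParams inject_univariate_outliers
#' @inherit inject_univariate_outliers return
#' @export
inject_multivariate_outliers <- function(x, pct = 1, seed = NULL,
                                         min_count = 2L) {
  m <- as_curation_matrix(x, require_complete = TRUE)
  n <- nrow(m)
  k <- .n_outliers(pct, n, min_count)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, sd)
  eligible <- abs(sweep(m, 2L, mu)) > 1.5 * rep(sdv, each = n)
  ok_rows <- which(rowSums(eligible) > 0L)
  if (length(ok_rows) < k) {
    abort("not enough rows with a cell beyond 1.5 SD to inject outliers")
  }
  with_seed_opt(seed, {
    rows <- sample(ok_rows, k)
    cells <- lapply(rows, function(i) {
      js <- which(eligible[i, ])
      j <- if (length(js) == 1L) js else sample(js, 1L)
      tibble(row = i, col = j, original = m[i, j],
             value = 2 * mu[j] - m[i, j])
    })
    cells <- dplyr::bind_rows(cells)
    out <- m
    out[cbind(cells$row, cells$col)] <- cells$value
    list(data = out, cells = cells)
  })
}

#' Run a curation-benchmark study
#'
#' Reproduces the experimental design of the comparative studies: for each
#' repetition a dataset is simulated, a reference network is inferred from
#' the clean data, the data are corrupted (MCAR holes or injected
#' outliers), each curation method repairs them, the network is re-inferred
#' and scored by [precision_recall()] against the reference. The reference
#' is the clean-data inference by default — the question answered is how
#' much of the attainable reconstruction survives corruption — with the
#' generator's ground truth available via `reference = "truth"`. Methods
#' that cannot handle a corruption level (complete-case or
#' nearest-neighbour with every row incomplete) record missing precision
#' and recall for that cell of the design.
#'
#' @param corruption `"mcar"`, `"univariate"` or `"multivariate"`.
#' @param methods Curation methods: any of `"tsr"`, `"ia"`, `"cc"`,
#'   `"mean"`, `"li"`, `"nn"` (imputation; MCAR study) or `"none"`,
#'   `"cure"` (outlier studies).
#' @param percentages Corruption grid; defaults to 5-35 % in steps of 5 for
#'   `"mcar"`, `c(1, 5, 10)` otherwise.
#' @param n_reps Simulated datasets per percentage (the studies use 100).
#' @param seed Master seed; every repetition derives its own seeds from it.
#' @param reference `"clean"` (default) or `"truth"`.
#' @param generator Arguments for [generate_chain_timeseries()].
#' @param infer_args Arguments for [infer_network()].
#' @param alpha Type-I risk of the paired comparisons (default 0.05).
#' @return Object of class `curation_study`: list with `results` (long
#'   tibble: corruption, method, pct, rep, tp, fp, fn, precision, recall,
#'   note) and `comparisons` (paired t-tests of the first listed method
#'   against each other method on precision and recall). `tidy()` returns
#'   `results`, `glance()` per-method/percentage means, `autoplot()` the
#'   mean precision/recall maps.
#' @export
run_study <- function(corruption = c("mcar", "univariate", "multivariate"),
                      methods = c("tsr", "ia", "cc", "mean", "li", "nn"),
                      percentages = NULL,
                      n_reps = 100L,
                      seed = 1L,
                      reference = c("clean", "truth"),
                      generator = list(),
                      infer_args = list(),
                      alpha = 0.05) {
  corruption <- match.arg(corruption)
  reference <- match.arg(reference)
  percentages <- percentages %||%
    if (corruption == "mcar") seq(5, 35, by = 5) else c(1, 5, 10)
  outlier_study <- corruption != "mcar"
  ok_methods <- if (outlier_study) c("none", "cure") else
    c("tsr", "ia", "cc", "mean", "mi", "li", "nn")
  bad <- setdiff(methods, ok_methods)
  if (length(bad)) {
    abort(paste0("method(s) not applicable to a ", corruption, " study: ",
                 toString(bad)))
  }
  seed <- as.integer(seed)

  rows <- list()
  for (rep_ in seq_len(n_reps)) {
    seed_rep <- (seed + 7919L * rep_) %% .Machine$integer.max
    sim <- do.call(generate_chain_timeseries,
                   c(generator, list(seed = seed_rep)))
    ref <- if (reference == "truth") sim$truth else
      do.call(infer_network,
              c(list(sim$data, seed = seed_rep), infer_args))
    for (pct in percentages) {
      seed_pct <- (seed_rep + round(1000 * pct)) %% .Machine$integer.max
      corrupted <- switch(corruption,
        mcar = inject_missing_mcar(sim$data, pct, seed = seed_pct),
        univariate = inject_univariate_outliers(sim$data, pct,
                                                seed = seed_pct)$data,
        multivariate = inject_multivariate_outliers(sim$data, pct,
                                                    seed = seed_pct)$data
      )
      for (method in methods) {
        res <- tryCatch({
          completed <- if (outlier_study) {
            if (method == "none") corrupted else
              cure(corrupted, seed = seed_pct)$data
          } else {
            impute(corrupted, method)$completed
          }
          net <- do.call(infer_network,
                         c(list(completed, seed = seed_pct), infer_args))
          pr <- precision_recall(net, ref)
          dplyr::mutate(pr, note = NA_character_)
        }, error = function(e) {
          tibble(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                 precision = NA_real_, recall = NA_real_,
                 note = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(corruption = corruption, method = method, pct = pct,
                 rep = rep_), res)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  comparisons <- .paired_comparisons(results, methods, alpha)
  structure(list(results = results, comparisons = comparisons,
                 reference = reference, alpha = alpha),
            class = "curation_study")
}

# one-sided paired t-tests of the first method against each competitor,
# per percentage and metric, on the repetitions where both produced values
.paired_comparisons <- function(results, methods, alpha) {
  base <- methods[1L]
  others <- setdiff(methods, base)
  grid <- expand.grid(method = others, pct = unique(results$pct),
                      metric = c("precision", "recall"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    mth <- grid$method[k]
    pct <- grid$pct[k]
    metric <- grid$metric[k]
    a <- results[results$method == base & results$pct == pct, ]
    b <- results[results$method == mth & results$pct == pct, ]
    a <- a[order(a$rep), ][[metric]]
    b <- b[order(b$rep), ][[metric]]
    keep <- !is.na(a) & !is.na(b)
    d <- a[keep] - b[keep]
    if (sum(keep) < 3L || sd(d) == 0) {
      return(tibble(method = mth, pct = pct, metric = metric,
                    n = sum(keep), mean_diff = mean(d),
                    p_value = NA_real_, better = NA))
    }
    tt <- t.test(d, alternative = "greater")
    tibble(method = mth, pct = pct, metric = metric, n = sum(keep),
           mean_diff = mean(d), p_value = tt$p.value,
           better = tt$p.value < alpha)
  })
  dplyr::bind_rows(out)
}

#' @export
print.curation_study <- function(x, ...) {
  cat(sprintf("<curation_study> %s corruption, %d method(s), %d repetition(s)\n",
              x$results$corruption[1L], length(unique(x$results$method)),
              max(x$results$rep)))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.curation_study <- function(x, ...) x$results

#' @export
glance.curation_study <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$method, .data$pct),
    precision = mean(.data$precision, na.rm = TRUE),
    recall = mean(.data$recall, na.rm = TRUE),
    n_failed = sum(is.na(.data$precision)),
    .groups = "drop"
  )
}

#' @rdname autoplot_netcure
#' @export
autoplot.curation_study <- function(object, ...) {
  dat <- glance(object) |>
    tidyr::pivot_longer(c("precision", "recall"), names_to = "metric")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$pct), y = .data$method,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "% corrupted", y = NULL, fill = "mean") +
    ggplot2::theme_minimal()
}
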