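new_inferred_network <- function(edges, variables, settings = list()) {
  structure(list(edges = edges, variables = variables, settings = settings),
            class = "inferred_network")
}

empty_edges <- function() {
  tibble(source = character(), target = character(), strength = numeric(),
         direction = character(), lag = integer())
}

#' Build a network object from an edge table
#'
#' @param edges Data frame with columns `source` and `target`; optional
#'   `strength`, `direction` (`"directed"` / `"undirected"`) and `lag`.
#' @param variables Character vector of node labels; defaults to the labels
#'   appearing in `edges`.
#' @return An `inferred_network` object.
#' @export
as_network <- function(edges, variables = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    abort("`edges` needs `source` and `target` columns")
  }
  if (any(edges$source == edges$target)) abort("self-edges are not allowed")
  if (!"strength" %in% names(edges)) edges$strength <- NA_real_
  if (!"direction" %in% names(edges)) edges$direction <- "directed"
  if (!"lag" %in% names(edges)) edges$lag <- NA_integer_
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target))
  if (anyDuplicated(key)) abort("at most one edge per unordered pair")
  variables <- variables %||% sort(unique(c(edges$source, edges$target)))
  new_inferred_network(edges[, c("source", "target", "strength",
                                 "direction", "lag")], variables)
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("<inferred_network> %d variables, %d edge%s\n",
              length(x$variables), nrow(x$edges),
              if (nrow(x$edges) == 1) "" else "s"))
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

#' @export
tidy.inferred_network <- function(x, ...) x$edges

#' @export
glance.inferred_network <- function(x, ...) {
  tibble(n_variables = length(x$variables), n_edges = nrow(x$edges),
         n_directed = sum(x$edges$direction == "directed"))
}

#' @rdname autoplot_netcure
#' @export
autoplot.inferred_network <- function(object, ...) {
  v <- object$variables
  ang <- seq(0, 2 * pi, length.out = length(v) + 1L)[seq_along(v)]
  nodes <- tibble(name = v, x = cos(ang), y = sin(ang))
  e <- object$edges
  seg <- dplyr::left_join(e, nodes, by = c(source = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(target = "name")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$strength,
                   linetype = .data$direction),
      arrow = grid::arrow(length = grid::unit(0.12, "in"), type = "closed"),
      colour = "grey40"
    ) + ggplot2::scale_linewidth(range = c(0.2, 1.4), limits = c(0, 1))
  }
  p +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}

# time-lagged MI of a -> b at lag tau over a lag grid; returns best
.best_lag_mi <- function(a, b, max_lag, bins) {
  lags <- 0:max_lag
  mis <- vapply(lags, function(tau) mutual_information(a, b, tau, bins),
                numeric(1))
  k <- which.max(mis)
  list(lag = lags[k], mi = mis[k])
}

# circular-shift null of the same statistic used for candidate selection:
# the max of MI over the lag grid and both orientations
.null_mi_scan <- function(a, b, max_lag, bins, n_perm) {
  n <- length(a)
  shifts <- sample(seq(floor(n / 4), floor(3 * n / 4)), n_perm,
                   replace = TRUE)
  vapply(shifts, function(s) {
    ash <- a[((seq_len(n) - 1L + s) %% n) + 1L]
    max(.best_lag_mi(ash, b, max_lag, bins)$mi,
        .best_lag_mi(b, ash, max_lag, bins)$mi)
  }, numeric(1))
}

#' Infer an interaction network by entropy reduction
#'
#' A minimal information-theoretic inference engine, used here to evaluate
#' data curation end to end. For each pair of variables the time-lagged
#' mutual information is scanned over lags `0..max_lag` (both
#' orientations) and the pair becomes a candidate link when its best MI
#' exceeds a permutation null (mean + 3 SD of the max-over-lags MI under
#' `n_perm` circular shifts of one series). Candidate links are then pruned
#' by conditional entropy: a link source -> target is indirect, and
#' dropped, when conditioning on one or two other linked variables leaves
#' less than `prune_tol` relative reduction of the target's entropy.
#' Surviving links carry `strength = (H(target) - H(target | source)) /
#' H(target)`, clipped to \[0, 1\], and a direction chosen by the larger of
#' the two transfer entropies at the selected lag; near-symmetric transfer
#' (difference below 5 % of the mean) leaves the link undirected.
#'
#' @param x Complete numeric matrix or data frame (time points x
#'   variables); missing cells are rejected — impute or cure first.
#' @param max_lag Largest time lag scanned (default 5 samples).
#' @param bins Histogram bins per dimension; default
#'   `min(10, ceiling(sqrt(n)/2))`.
#' @param threshold Absolute MI threshold (bits) overriding the permutation
#'   null.
#' @param n_perm Circular-shift permutations for the null (default 30).
#' @param prune_tol Relative entropy-reduction tolerance below which a
#'   conditioned link is declared indirect (default 0.01).
#' @param direction_tol Relative transfer-entropy asymmetry below which a
#'   link stays undirected (default 0.05).
#' @param seed Optional integer seed for the permutation null.
#' @return An `inferred_network` object; `tidy()` returns the edge tibble
#'   (source, target, strength, direction, lag).
#' @export
infer_network <- function(x, max_lag = 5L, bins = NULL, threshold = NULL,
                          n_perm = 30L, prune_tol = 0.01,
                          direction_tol = 0.05, seed = NULL) {
  m <- as_curation_matrix(x, min_rows = 3L, min_cols = 2L)
  if (anyNA(m)) {
    abort("matrix has missing cells; run impute() or cure() first")
  }
  n <- nrow(m)
  p <- ncol(m)
  vars <- colnames(m)
  bins <- bins %||% default_bins(n)
  max_lag <- min(as.integer(max_lag), n - 10L)

  cand <- with_seed_opt(seed, {
    # step 1: best lagged MI per ordered pair, candidate links vs a
    # circular-shift null at the selected lag
    cand <- list()
    for (i in seq_len(p - 1L)) {
      for (j in seq((i + 1L), p)) {
        fwd <- .best_lag_mi(m[, i], m[, j], max_lag, bins)
        bwd <- .best_lag_mi(m[, j], m[, i], max_lag, bins)
        if (fwd$mi >= bwd$mi) {
          src <- i; tgt <- j; best <- fwd
        } else {
          src <- j; tgt <- i; best <- bwd
        }
        thr <- threshold
        if (is.null(thr)) {
          null_mi <- .null_mi_scan(m[, i], m[, j], max_lag, bins, n_perm)
          thr <- mean(null_mi) + 3 * sd(null_mi)
        }
        if (best$mi > thr) {
          cand[[length(cand) + 1L]] <- list(src = src, tgt = tgt,
                                            lag = best$lag, mi = best$mi)
        }
      }
    }
    if (length(cand) == 0L) {
      cand
    } else {
    # step 2: prune indirect links by first/second-order conditioning.
    # Plug-in conditional entropies in 3-4 dimensions carry a sparsity
    # bias that makes any added variable look informative, so the raw
    # reduction is judged against its own circular-shift null: the link is
    # kept only when the bias-corrected excess reduction exceeds
    # `prune_tol` of the target's entropy and the null's 3-sigma band.
    adj <- lapply(seq_len(p), function(i) integer())
    for (cd in cand) {
      adj[[cd$src]] <- union(adj[[cd$src]], cd$tgt)
      adj[[cd$tgt]] <- union(adj[[cd$tgt]], cd$src)
    }
    # each conditioner enters at its own most informative lag to the target
    cond_lag <- function(z, tgt) .best_lag_mi(m[, z], m[, tgt], max_lag,
                                              bins)$lag
    keep <- vapply(cand, function(cd) {
      others <- setdiff(union(adj[[cd$src]], adj[[cd$tgt]]),
                        c(cd$src, cd$tgt))
      if (length(others) == 0L) return(TRUE)
      tau <- cd$lag
      zlags <- vapply(others, cond_lag, integer(1), tgt = cd$tgt)
      sets <- c(as.list(seq_along(others)),
                if (length(others) >= 2L) utils::combn(seq_along(others), 2L,
                                                       simplify = FALSE))
      for (s_ in sets) {
        tmax <- max(tau, zlags[s_])
        idx <- seq_len(n - tmax)
        tgt_t <- m[idx + tmax, cd$tgt]
        src_l <- m[idx + tmax - tau, cd$src]
        z <- vapply(s_, function(k) m[idx + tmax - zlags[k], others[k]],
                    numeric(length(idx)))
        nloc <- length(idx)
        # keep the joint histogram populated: n >= 10 * bins^d
        d_ <- 2L + length(s_)
        bprune <- min(bins, max(2L, round((nloc / 5)^(1 / d_))))
        h_t <- shannon_entropy(tgt_t, bprune)
        if (h_t <= 0) return(FALSE)
        h_cond <- conditional_entropy(tgt_t, z, bprune)
        red <- h_cond - conditional_entropy(tgt_t, cbind(z, src_l), bprune)
        shifts <- sample(seq(floor(nloc / 4), floor(3 * nloc / 4)), n_perm,
                         replace = TRUE)
        null_red <- vapply(shifts, function(s) {
          sh <- src_l[((seq_len(nloc) - 1L + s) %% nloc) + 1L]
          h_cond - conditional_entropy(tgt_t, cbind(z, sh), bprune)
        }, numeric(1))
        excess <- red - (mean(null_red) + 3 * sd(null_red))
        if (excess <= 0 || (red - mean(null_red)) / h_t < prune_tol) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    cand[keep]
    }
  })
  if (length(cand) == 0L) {
    return(new_inferred_network(empty_edges(), vars,
                                list(bins = bins, max_lag = max_lag,
                                     n_perm = n_perm, seed = seed)))
  }

  # steps 3-4: strength as relative entropy reduction, direction by TE
  edges <- lapply(cand, function(cd) {
    a <- m[, cd$src]
    b <- m[, cd$tgt]
    tau <- cd$lag
    idx <- seq_len(n - tau)
    h_b <- shannon_entropy(b[idx + tau], bins)
    red <- if (h_b > 0) {
      (h_b - conditional_entropy(b[idx + tau], a[idx], bins)) / h_b
    } else 0
    tau_te <- max(tau, 1L)
    t_ab <- transfer_entropy(a, b, tau_te, bins)
    t_ba <- transfer_entropy(b, a, tau_te, bins)
    avg <- (t_ab + t_ba) / 2
    if (avg <= 0 || abs(t_ab - t_ba) < direction_tol * avg) {
      i2 <- min(cd$src, cd$tgt); j2 <- max(cd$src, cd$tgt)
      tibble(source = vars[i2], target = vars[j2],
             strength = min(max(red, 0), 1),
             direction = "undirected", lag = as.integer(tau))
    } else if (t_ab >= t_ba) {
      tibble(source = vars[cd$src], target = vars[cd$tgt],
             strength = min(max(red, 0), 1),
             direction = "directed", lag = as.integer(tau))
    } else {
      tibble(source = vars[cd$tgt], target = vars[cd$src],
             strength = min(max(red, 0), 1),
             direction = "directed", lag = as.integer(tau))
    }
  })
  edges <- dplyr::arrange(dplyr::bind_rows(edges), .data$source, .data$target)
  new_inferred_network(edges, vars, list(bins = bins, max_lag = max_lag,
                                         n_perm = n_perm,
                                         threshold = threshold, seed = seed))
}

#' Precision and recall of an inferred network
#'
#' Compares the links of an inferred network against a reference by set
#' comparison: `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. Links are
#' matched as unordered pairs by default (link recovery); with
#' `directed = TRUE` a true positive requires the orientation to match
#' (undirected edges match either orientation). An undefined ratio (0 / 0)
#' is reported as `NA`, not 0.
#'
#' @param inferred,reference `inferred_network` objects (or edge data
#'   frames) over overlapping variable sets.
#' @param directed Compare orientations as well as adjacency.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
precision_recall <- function(inferred, reference, directed = FALSE) {
  ekey <- function(net) {
    e <- if (inherits(net, "inferred_network")) net$edges else
      as_network(net)$edges
    if (nrow(e) == 0L) return(character())
    if (directed) {
      unlist(lapply(seq_len(nrow(e)), function(k) {
        if (identical(e$direction[k], "undirected")) {
          paste(pmin(e$source[k], e$target[k]),
                pmax(e$source[k], e$target[k]), sep = "~")
        } else {
          paste(e$source[k], e$target[k], sep = ">")
        }
      }))
    } else {
      unique(paste(pmin(e$source, e$target), pmax(e$source, e$target),
                   sep = "~"))
    }
  }
  vi <- if (inherits(inferred, "inferred_network")) inferred$variables else
    unique(unlist(inferred[c("source", "target")]))
  vr <- if (inherits(reference, "inferred_network")) reference$variables else
    unique(unlist(reference[c("source", "target")]))
  if (length(intersect(vi, vr)) == 0L) {
    abort("inferred and reference networks share no variables")
  }
  a <- ekey(inferred)
  b <- ekey(reference)
  if (directed) {
    # adjacency key, orientation forgotten
    und <- function(k) vapply(strsplit(k, "[>~]"), function(s)
      paste(sort(s), collapse = "~"), character(1))
    is_und <- function(k) grepl("~", k, fixed = TRUE)
    # a directed key matches an identically oriented key; an undirected key
    # on either side matches on adjacency alone
    matched_a <- a %in% b |
      (is_und(a) & und(a) %in% und(b)) |
      und(a) %in% und(b[is_und(b)])
    matched_b <- b %in% a |
      (is_und(b) & und(b) %in% und(a)) |
      und(b) %in% und(a[is_und(a)])
    tp <- sum(matched_a)
    fp <- sum(!matched_a)
    fn <- sum(!matched_b)
    return(tibble(
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
      recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
    ))
  }
  tp <- length(intersect(a, b))
  fp <- length(a) - tp
  fn <- length(b) - tp
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  )
}
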