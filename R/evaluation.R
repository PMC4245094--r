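#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling, as used to relate MR fat
#' fractions to the histology percentage.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A value in `[-1, 1]`, or `NA` with a warning when either vector
#'   is constant.
#' @export
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("Spearman correlation is undefined for a constant vector; returning NA.")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

new_roc_result <- function(points, auc, smoothed) {
  structure(list(points = points, auc = auc, smoothed = smoothed),
            class = "hepafat_roc")
}

#' @export
print.hepafat_roc <- function(x, ...) {
  cat(sprintf("<roc%s> AUC = %.4f (%d operating points)\n",
              if (x$smoothed) " (smoothed)" else "", x$auc, nrow(x$points)))
  invisible(x)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' The empirical ROC over all observed thresholds, predicting positive when
#' `score >= threshold`. The trapezoidal area equals the Mann-Whitney
#' concordance probability, with ties counting one half.
#'
#' @param scores Numeric marker values.
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return A `hepafat_roc`: a `points` tibble (`threshold`, `fpr`, `tpr`)
#'   and the `auc`.
#' @export
#' @examples
#' roc_empirical(c(3, 1, 2, 4), c(0, 0, 1, 1))
roc_empirical <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) abort("Lengths differ.")
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(scores >= c & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(c) sum(scores >= c & labels == 0) / n_neg,
                numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                           tpr = c(0, tpr))
  # trapezoid over the staircase == Mann-Whitney with half-weight ties
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  new_roc_result(points, auc, smoothed = FALSE)
}

#' Kernel-smoothed (robust) ROC curve
#'
#' Scores are rank-transformed (the robust step: the curve depends on the
#' data only through ranks), each class's distribution is smoothed with a
#' Gaussian kernel (Silverman's rule bandwidth per class unless supplied),
#' and the ROC is traced over a fine threshold grid. Thresholds are mapped
#' back to the original score scale, so Youden cutoffs stay in marker units.
#'
#' @param scores Numeric marker values.
#' @param labels 0/1 labels, at least 5 per class.
#' @param bandwidth Optional common kernel bandwidth on the rank scale.
#' @param n_grid Number of threshold grid points.
#' @return A `hepafat_roc` with `smoothed = TRUE`.
#' @export
roc_smoothed <- function(scores, labels, bandwidth = NULL, n_grid = 512) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  if (min(table(labels)) < 5) abort("Need at least 5 subjects per class.")
  r <- rank(scores, ties.method = "average")
  r0 <- r[labels == 0]; r1 <- r[labels == 1]
  if (is.null(bandwidth)) {
    bw0 <- bw.nrd0(r0); bw1 <- bw.nrd0(r1)
  } else {
    if (bandwidth <= 0) abort("`bandwidth` must be positive.")
    bw0 <- bw1 <- bandwidth
  }
  grid <- seq(min(r) - 4 * max(bw0, bw1), max(r) + 4 * max(bw0, bw1),
              length.out = n_grid)
  surv <- function(x, bw, c) mean(pnorm((x - c) / bw))
  tpr <- vapply(grid, function(c) surv(r1, bw1, c), numeric(1))
  fpr <- vapply(grid, function(c) surv(r0, bw0, c), numeric(1))
  # rank-scale grid -> original score scale by interpolation
  ord <- order(r)
  thr <- approx(x = r[ord], y = scores[ord], xout = grid, rule = 2,
                ties = "ordered")$y
  points <- tibble::tibble(threshold = rev(thr), fpr = rev(fpr), tpr = rev(tpr))
  o <- order(points$fpr, points$tpr)
  auc <- {
    p <- points[o, ]
    sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
  }
  new_roc_result(points, min(max(auc, 0), 1), smoothed = TRUE)
}

#' Youden-optimal decision threshold
#'
#' Maximises `J = sensitivity + specificity - 1` over the operating points
#' of a ROC curve; ties resolve to the lowest threshold.
#'
#' @param roc A `hepafat_roc` from [roc_empirical()] or [roc_smoothed()].
#' @return A list of class `threshold_result` with `threshold`,
#'   `sensitivity`, `specificity` and `youden_j`.
#' @export
youden_threshold <- function(roc) {
  p <- roc$points[is.finite(roc$points$threshold), ]
  if (nrow(p) == 0) abort("ROC has no finite-threshold operating points.")
  j <- p$tpr - p$fpr
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(p$threshold[best])]
  structure(
    list(threshold = p$threshold[pick], sensitivity = p$tpr[pick],
         specificity = 1 - p$fpr[pick], youden_j = p$tpr[pick] - p$fpr[pick]),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> cutoff %.4g: sens %.3f, spec %.3f, J = %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Compare two paired ROC curves (DeLong test)
#'
#' Two-sided test of equal AUC for two markers measured on the same
#' subjects, using DeLong's structural-components covariance for correlated
#' ROC curves. Identical markers (zero variance of the AUC difference and
#' zero difference) return p = 1.
#'
#' @param scores_a,scores_b Marker values on the same subjects.
#' @param labels Shared 0/1 labels.
#' @return A list with `auc_a`, `auc_b`, `statistic` and `p_value`.
#' @export
compare_roc_paired <- function(scores_a, scores_b, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("Both score vectors must match the labels in length.")
  }
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  # a class with a single member contributes no estimable variance
  s10 <- if (m >= 2) stats::var(cbind(ca$v10, cb$v10)) else matrix(0, 2, 2)
  s01 <- if (n >= 2) stats::var(cbind(ca$v01, cb$v01)) else matrix(0, 2, 2)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 1e-16) {
    p <- if (abs(d) < 1e-12) 1 else 0
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, statistic = z,
       p_value = max(min(p, 1), .Machine$double.xmin))
}

# mean placement of each member of level s among level t (> counts 1, = 0.5)
placements_vs <- function(vals_s, vals_t) {
  st <- sort(vals_t)
  n_t <- length(st)
  below <- findInterval(vals_s, st, left.open = TRUE)   # strictly smaller
  below_eq <- findInterval(vals_s, st)                  # smaller or equal
  (below + 0.5 * (below_eq - below)) / n_t
}

#' Obuchowski AUC for an ordinal gold standard
#'
#' Generalises the two-class AUC to an ordinal truth with three or more
#' levels: the weighted average of all pairwise between-level AUCs, each
#' pair weighted by its number of subject pairs. The standard error is the
#' leave-one-subject-out jackknife. With exactly two levels the estimate
#' reduces to the ordinary empirical AUC.
#'
#' @param predictions Numeric predictions (higher = more severe).
#' @param ordinal_truth Ordinal truth labels (factor or numeric) with at
#'   least two distinct levels.
#' @return A list with `auc`, `se`, `n_levels` and the `pairwise` tibble of
#'   per-pair AUCs and weights.
#' @export
obuchowski_auc <- function(predictions, ordinal_truth) {
  truth <- if (is.factor(ordinal_truth)) {
    as.integer(droplevels(as.factor(ordinal_truth)))
  } else as.integer(as.factor(ordinal_truth))
  if (length(predictions) != length(truth)) abort("Lengths differ.")
  levels_present <- sort(unique(truth))
  L <- length(levels_present)
  if (L < 2) abort("Need at least 2 distinct truth levels.")
  by_level <- split(predictions, truth)
  counts <- vapply(by_level, length, integer(1))

  pairs <- utils::combn(L, 2)
  # per-subject mean placements against every other level, for the jackknife
  V <- lapply(seq_len(L), function(s) {
    lapply(seq_len(L), function(t) {
      if (s == t) return(NULL)
      p <- placements_vs(by_level[[s]], by_level[[t]])
      if (s < t) 1 - p else p   # concordance: higher level should score higher
    })
  })
  A <- matrix(NA_real_, L, L)
  for (k in seq_len(ncol(pairs))) {
    s <- pairs[1, k]; t <- pairs[2, k]
    A[s, t] <- mean(V[[s]][[t]])
  }
  theta_from <- function(cnt, Amat) {
    w <- outer(cnt, cnt)
    tot <- 0; denom <- 0
    for (k in seq_len(ncol(pairs))) {
      s <- pairs[1, k]; t <- pairs[2, k]
      tot <- tot + w[s, t] * Amat[s, t]
      denom <- denom + w[s, t]
    }
    tot / denom
  }
  theta <- theta_from(counts, A)

  # jackknife: removing subject i of level u updates only the (u, t) AUCs
  n <- length(predictions)
  theta_loo <- numeric(n)
  idx <- 0
  for (u in seq_len(L)) {
    for (i in seq_len(counts[u])) {
      idx <- idx + 1
      cnt <- counts; cnt[u] <- cnt[u] - 1L
      Amat <- A
      for (t in seq_len(L)) {
        if (t == u) next
        s <- min(u, t); tt <- max(u, t)
        Amat[s, tt] <- (counts[u] * A[s, tt] - V[[u]][[t]][i]) / cnt[u]
      }
      theta_loo[idx] <- if (any(cnt == 0)) NA_real_ else theta_from(cnt, Amat)
    }
  }
  theta_loo <- theta_loo[is.finite(theta_loo)]
  se <- if (length(theta_loo) > 1) {
    sqrt((length(theta_loo) - 1) / length(theta_loo) *
           sum((theta_loo - mean(theta_loo))^2))
  } else NA_real_

  pairwise <- tibble::tibble(
    lower_level = pairs[1, ], upper_level = pairs[2, ],
    auc = A[cbind(pairs[1, ], pairs[2, ])],
    weight = counts[pairs[1, ]] * counts[pairs[2, ]] /
      sum(counts[pairs[1, ]] * counts[pairs[2, ]])
  )
  list(auc = theta, se = se, n_levels = L, pairwise = pairwise)
}

#' Grade-wise medians and interquartile ranges
#'
#' Per-grade summaries of a measurement column, with linear-interpolation
#' (type 7) quantiles.
#'
#' @param cohort A cohort tibble.
#' @param value Column name (string) to summarise.
#' @param by Grouping column name (default `"grade"`).
#' @return A tibble with `n`, `median`, `q25`, `q75` per group.
#' @export
group_summaries <- function(cohort, value, by = "grade") {
  if (!value %in% names(cohort)) abort(sprintf("No column '%s'.", value))
  cohort |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[value]]),
      q25 = quantile(.data[[value]], 0.25, type = 7, names = FALSE),
      q75 = quantile(.data[[value]], 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon rank-sum test between two groups of measurements, the
#' pairwise test used to compare grade groups.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return The two-sided p-value.
#' @export
group_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  suppressWarnings(wilcox.test(values_a, values_b,
                               alternative = "two.sided")$p.value)
}
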