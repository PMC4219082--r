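#' Normality gate
#'
#' Shapiro-Wilk test deciding between the parametric and nonparametric
#' branches of the cohort analysis; the nonparametric path is taken whenever
#' `p < 0.05`.
#'
#' @param x Numeric sample of at least 3 non-identical values.
#' @return One-row tibble: `w`, `p`, `verdict` (`"normal"`/`"non_normal"`).
#' @export
shapiro_wilk_gate <- function(x) {
  if (length(x) < 3L) {
    ctces_abort("Shapiro-Wilk needs at least 3 values.", "ctces_error_sample_size")
  }
  if (length(unique(x)) == 1L) {
    ctces_abort("Sample is constant; normality is undefined.",
                "ctces_error_degenerate")
  }
  if (length(x) > 5000L) x <- sample(x, 5000L)
  fit <- stats::shapiro.test(x)
  tibble(w = unname(fit$statistic), p = fit$p.value,
         verdict = ifelse(fit$p.value < 0.05, "non_normal", "normal"))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' the combined sample size is at most 12 and there are no ties; otherwise
#' the tie-corrected normal approximation (with continuity correction)
#' applies. `u` is the U statistic of the first sample, so swapping the
#' samples maps `u` to `n_a * n_b - u` with the same p-value.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `u`, `p`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    ctces_abort("Both samples must be non-empty.", "ctces_error_sample_size")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble(u = unname(fit$statistic), p = fit$p.value,
         method = ifelse(exact, "exact", "normal_approx"))
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution.
#'
#' @param groups List of at least two non-empty numeric samples.
#' @return One-row tibble: `h`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    ctces_abort("Need at least two non-empty groups.", "ctces_error_sample_size")
  }
  fit <- stats::kruskal.test(groups)
  tibble(h = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
}

#' Per-bin nonparametric scan of two group distributions
#'
#' For each HU value 0--79, compares the per-subject proportions of the two
#' groups with [mann_whitney()]; discriminative bands are the maximal
#' contiguous runs of bins with `p < alpha`. No multiple-testing correction
#' is applied by default, matching the original per-bin practice; Holm
#' correction is available behind `p_adjust`.
#'
#' @param group_a,group_b Subjects x 80 matrices of per-HU proportions (as
#'   produced by [group_distribution()]), at least 2 subjects each.
#' @param alpha Per-bin significance level.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A `band_scan`: `p_values` tibble (hu, p), `bands` tibble (lo, hi,
#'   width, min_p), `alpha`.
#' @export
per_bin_scan <- function(group_a, group_b, alpha = 0.05,
                         p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    ctces_abort("Each group needs at least 2 subjects.", "ctces_error_sample_size")
  }
  stopifnot(ncol(group_a) == 80L, ncol(group_b) == 80L)
  p <- vapply(1:80, function(j) mann_whitney(group_a[, j], group_b[, j])$p,
              numeric(1))
  if (p_adjust == "holm") p <- stats::p.adjust(p, "holm")
  sig <- p < alpha
  bands <- band_runs(sig, p)
  structure(list(p_values = tibble(hu = 0:79, p = p),
                 bands = bands, alpha = alpha, p_adjust = p_adjust),
            class = "band_scan")
}

band_runs <- function(sig, p) {
  if (!any(sig)) {
    return(tibble(lo = integer(), hi = integer(), width = integer(),
                  min_p = numeric()))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(lo = starts[keep] - 1L, hi = ends[keep] - 1L,
         width = r$lengths[keep],
         min_p = vapply(keep, function(k) min(p[starts[k]:ends[k]]), numeric(1)))
}

#' The discriminative band of a scan
#'
#' The maximal significant run containing the most significant bin -- the
#' range the analysis reports as *the* source of the group difference.
#' Returns a zero-row tibble when no bin is significant.
#'
#' @param scan A `band_scan`.
#' @return One-row tibble (lo, hi, width, min_p), or zero rows.
#' @export
primary_band <- function(scan) {
  stopifnot(inherits(scan, "band_scan"))
  if (nrow(scan$bands) == 0L) return(scan$bands)
  scan$bands[which.min(scan$bands$min_p), ]
}

#' @export
print.band_scan <- function(x, ...) {
  cat(sprintf("<band_scan> alpha = %g (%s): %d significant band(s)\n",
              x$alpha, x$p_adjust, nrow(x$bands)))
  if (nrow(x$bands) > 0) {
    for (i in seq_len(nrow(x$bands))) {
      cat(sprintf("  HU %d-%d (min p = %.3g)\n",
                  x$bands$lo[i], x$bands$hi[i], x$bands$min_p[i]))
    }
  }
  invisible(x)
}

#' Empirical ROC curve
#'
#' Evaluates the classifier `score >= threshold -> positive` at every
#' distinct score; the area under the curve is computed by the trapezoid
#' rule and equals the concordance probability (ties counted half).
#'
#' @param scores Numeric per-subject scores.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive class.
#' @return A `ces_roc`: `points` tibble (threshold, fpr, tpr, sensitivity,
#'   specificity), `auc`, class counts, and the raw data for cutoff
#'   selection.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)),
            !any(is.na(labels)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    ctces_abort("Both classes must be present for a ROC curve.",
                "ctces_error_single_class")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble(threshold = thr, fpr = fpr, tpr = tpr,
                                 sensitivity = tpr, specificity = 1 - fpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "ces_roc")
}

#' Select the operating cutoff on a ROC curve
#'
#' The cutoff with the highest predictive power, operationalised as Youden's
#' `J = sensitivity + specificity - 1` (default) or the point closest to the
#' (0, 1) corner. Ties break towards higher specificity, then towards the
#' lower cutoff; only attainable cutoffs (observed scores) are candidates.
#'
#' @param roc A `ces_roc` from [roc_curve()].
#' @param criterion `"youden"` or `"closest"`.
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
select_cutoff <- function(roc, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  pts <- roc$points[is.finite(roc$points$threshold), ]
  score <- if (criterion == "youden") {
    pts$sensitivity + pts$specificity - 1
  } else {
    -sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  }
  # round the keys so float noise cannot defeat the documented tie-breaks
  ord <- order(-round(score, 9), -round(pts$specificity, 9), pts$threshold)
  best <- pts[ord[1], ]
  tibble(cutoff = best$threshold, sensitivity = best$sensitivity,
         specificity = best$specificity,
         j = best$sensitivity + best$specificity - 1)
}

#' Confusion counts and predictive values at a cutoff
#'
#' Applies `score >= cutoff -> positive` and tallies the confusion matrix.
#' Predictive values are `NA` (flagged, not an error) when their denominator
#' is zero.
#'
#' @param scores,labels As in [roc_curve()].
#' @param cutoff Decision threshold.
#' @return One-row tibble: tp, fp, tn, fn, sensitivity, specificity, ppv, npv.
#' @export
predictive_values <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    ctces_abort("Both classes must be present.", "ctces_error_single_class")
  }
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
         npv = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_))
}

#' Categorical association test
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' Pearson's chi-square (without continuity correction, so the statistic
#' matches the classical formula).
#'
#' @param table Matrix of non-negative integer counts (2x2 or r x c).
#' @return One-row tibble: `statistic` (NA for Fisher), `p`, `method`.
#' @export
categorical_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    ctces_abort("Counts must be non-negative integers.", "ctces_error_format")
  }
  if (sum(table) == 0) {
    ctces_abort("All-zero table has no association to test.",
                "ctces_error_degenerate")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    fit <- stats::fisher.test(table)
    tibble(statistic = NA_real_, p = fit$p.value, method = "fisher")
  } else {
    fit <- stats::chisq.test(table, correct = FALSE)
    tibble(statistic = unname(fit$statistic), p = fit$p.value,
           method = "chi_square")
  }
}
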