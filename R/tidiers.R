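#' Tidiers for fitted result objects
#'
#' `tidy()` returns the per-observation table of a result (per-HU p-values
#' for a band scan, curve points for a ROC); `glance()` returns a one-row
#' summary.
#'
#' @param x A `band_scan`, `ces_roc` or `group_distribution`.
#' @param ... Unused.
#' @return A tibble.
#' @name ctces-tidiers
NULL

#' @rdname ctces-tidiers
#' @export
tidy.band_scan <- function(x, ...) {
  dplyr::mutate(x$p_values, significant = .data$p < x$alpha)
}

#' @rdname ctces-tidiers
#' @export
glance.band_scan <- function(x, ...) {
  tibble(alpha = x$alpha, n_bands = nrow(x$bands),
         widest_lo = if (nrow(x$bands)) x$bands$lo[which.max(x$bands$width)] else NA_integer_,
         widest_hi = if (nrow(x$bands)) x$bands$hi[which.max(x$bands$width)] else NA_integer_,
         min_p = min(x$p_values$p))
}

#' @rdname ctces-tidiers
#' @export
tidy.ces_roc <- function(x, ...) x$points

#' @rdname ctces-tidiers
#' @export
glance.ces_roc <- function(x, ...) {
  best <- select_cutoff(x)
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         cutoff = best$cutoff, sensitivity = best$sensitivity,
         specificity = best$specificity, j = best$j)
}

#' @rdname ctces-tidiers
#' @export
tidy.group_distribution <- function(x, ...) {
  as_tibble(x$subjects, rownames = "subject_id") |>
    tidyr::pivot_longer(-"subject_id", names_to = "hu",
                        values_to = "proportion") |>
    dplyr::mutate(hu = as.integer(.data$hu))
}

#' @rdname ctces-tidiers
#' @export
glance.group_distribution <- function(x, ...) {
  tibble(n_subjects = nrow(x$subjects),
         ces = compute_ces(x$distribution),
         mces = compute_mces(x$distribution))
}

#' @param object A result object.
#' @rdname ctces-tidiers
#' @export
autoplot.band_scan <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hu, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = "Hounsfield Units", y = expression(-log[10](p)),
                  colour = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal()
  if (nrow(object$bands) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$bands, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$lo - 0.5, xmax = .data$hi + 0.5,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' @rdname ctces-tidiers
#' @export
autoplot.ces_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Empirical ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
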