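#' Hounsfield-Unit density distributions
#'
#' A `density_distribution` is a tibble with one row per integer HU value
#' 0--79 and a `proportion` column in percent summing to 100. Attributes
#' record the `level` (slice, series or group), the number of images averaged
#' and the number of retained pixels contributing.
#'
#' @param proportions Numeric length-80 vector of percentages for HU 0..79.
#' @param level One of `"slice"`, `"series"`, `"group"`.
#' @param n_images Number of CT images averaged.
#' @param n_pixels Total retained pixels contributing.
#' @return A tibble of class `density_distribution` with columns `hu`,
#'   `proportion`.
#' @export
new_density_distribution <- function(proportions, level, n_images, n_pixels) {
  level <- match.arg(level, c("slice", "series", "group"))
  if (length(proportions) != 80L || any(proportions < -1e-9) ||
      abs(sum(proportions) - 100) > 1e-6) {
    ctces_abort("A density distribution needs 80 non-negative proportions summing to 100.",
                "ctces_error_format")
  }
  out <- tibble(hu = 0:79, proportion = as.numeric(proportions))
  class(out) <- c("density_distribution", class(out))
  attr(out, "level") <- level
  attr(out, "n_images") <- as.integer(n_images)
  attr(out, "n_pixels") <- as.integer(n_pixels)
  out
}

dist_level <- function(dist) attr(dist, "level")

#' Distribution of a retained pixel multiset
#'
#' Convenience constructor: tabulates integer HU values already inside the
#' 0--79 boundary condition into a slice-level distribution.
#'
#' @param values Integer HU values in `[0, 79]`.
#' @return A `density_distribution` (level `"slice"`).
#' @export
distribution_from_pixels <- function(values) {
  if (length(values) == 0L) {
    ctces_abort("Empty pixel set has no distribution.", "ctces_error_empty_region")
  }
  if (any(values < 0L | values > 79L)) {
    ctces_abort("Pixels outside HU 0-79 must be removed before tabulation.",
                "ctces_error_bounds")
  }
  counts <- tabulate(as.integer(values) + 1L, 80L)
  new_density_distribution(100 * counts / sum(counts), "slice",
                           n_images = 1L, n_pixels = length(values))
}

#' Per-image density distribution
#'
#' The proportion of intracranial pixels at each HU value lambda in one CT
#' image: `lambda_p = 100 * count(HU == lambda) / count(retained)`.
#'
#' @param seg A `ct_segmentation` from [segment_slice()].
#' @return A `density_distribution` (level `"slice"`).
#' @export
slice_distribution <- function(seg) {
  stopifnot(inherits(seg, "ct_segmentation"))
  distribution_from_pixels(seg$retained_pixels)
}

#' Series-averaged density distribution
#'
#' Averages per-image proportions over the `n` images of an examination:
#' `(1/n) * sum_k lambda_p^k` per HU value, so every image contributes
#' equally regardless of its pixel count. A pooled-pixel alternative
#' (`method = "pooled"`, weighting images by retained pixels) is provided
#' for sensitivity analysis.
#'
#' @param dists List of slice-level `density_distribution`s, or a
#'   `ct_segmentation_series`.
#' @param method `"mean"` (default) or `"pooled"`.
#' @return A `density_distribution` (level `"series"`).
#' @export
series_distribution <- function(dists, method = c("mean", "pooled")) {
  method <- match.arg(method)
  if (inherits(dists, "ct_segmentation_series")) {
    dists <- lapply(dists$results, slice_distribution)
  }
  if (length(dists) == 0L) {
    ctces_abort("No slice distributions to average.", "ctces_error_empty_region")
  }
  stopifnot(all(vapply(dists, inherits, logical(1), "density_distribution")))
  mat <- vapply(dists, function(d) d$proportion, numeric(80))
  npx <- vapply(dists, function(d) attr(d, "n_pixels"), integer(1))
  prop <- if (method == "mean") {
    rowMeans(mat)
  } else {
    as.numeric(mat %*% (npx / sum(npx)))
  }
  new_density_distribution(prop, "series",
                           n_images = length(dists), n_pixels = sum(npx))
}

#' Group-averaged density distribution
#'
#' Per-HU mean over subjects' series distributions, keeping the per-subject
#' matrix for the statistical module.
#'
#' @param series_dists Named list of series-level `density_distribution`s
#'   (names are subject ids).
#' @return List of class `group_distribution`: `distribution` (level
#'   `"group"`) and `subjects`, a subjects x 80 matrix of per-HU proportions.
#' @export
group_distribution <- function(series_dists) {
  if (length(series_dists) == 0L) {
    ctces_abort("No subjects in group.", "ctces_error_empty_region")
  }
  stopifnot(all(vapply(series_dists, inherits, logical(1), "density_distribution")))
  mat <- t(vapply(series_dists, function(d) d$proportion, numeric(80)))
  colnames(mat) <- 0:79
  rownames(mat) <- names(series_dists) %||% as.character(seq_len(nrow(mat)))
  dist <- new_density_distribution(colMeans(mat), "group",
                                   n_images = length(series_dists),
                                   n_pixels = sum(vapply(series_dists, function(d)
                                     attr(d, "n_pixels"), integer(1))))
  structure(list(distribution = dist, subjects = mat),
            class = "group_distribution")
}

#' Band proportion HU(alpha..beta)
#'
#' The summed proportion of pixels with HU between `alpha` and `beta`,
#' inclusive on both ends.
#'
#' @param dist A `density_distribution`.
#' @param alpha,beta Integer HU bounds, `0 <= alpha <= beta <= 79`.
#' @return A percentage in `[0, 100]`.
#' @export
#' @examples
#' d <- distribution_from_pixels(rep(c(20L, 30L), each = 5))
#' band_proportion(d, 17, 24)  # 50
band_proportion <- function(dist, alpha, beta) {
  stopifnot(inherits(dist, "density_distribution"))
  if (!(alpha >= 0 && alpha <= beta && beta <= 79) ||
      alpha != round(alpha) || beta != round(beta)) {
    ctces_abort("Band must satisfy 0 <= alpha <= beta <= 79 (integers).",
                "ctces_error_bounds")
  }
  sum(dist$proportion[dist$hu >= alpha & dist$hu <= beta])
}

#' @export
autoplot.density_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble(hu = object$hu, proportion = object$proportion),
                  ggplot2::aes(x = .data$hu, y = .data$proportion)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "Hounsfield Units", y = "Proportion of pixels (%)",
                  title = sprintf("HU density distribution (%s level)",
                                  dist_level(object))) +
    ggplot2::theme_minimal()
}
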