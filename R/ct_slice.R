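#' CT slice and series containers
#'
#' A `ct_slice` holds one axial grid of integer Hounsfield-Unit (HU) values
#' together with its spacing metadata; a `ct_series` is an ordered stack of
#' slices (vertex to caudal) from one examination.
#'
#' HU values may be negative before segmentation (air is about -1000); the
#' 0--79 intracranial boundary condition is only applied by
#' [apply_hu_bounds()].
#'
#' @param pixels Integer matrix of HU values (rows x cols).
#' @param pixel_spacing Numeric length-2, mm per pixel (row, col).
#' @param slice_index 0-based ordinal position, vertex to caudal.
#' @param source_id Opaque provenance string.
#' @return An object of class `ct_slice`.
#' @export
#' @examples
#' s <- ct_slice(matrix(0L, 8, 8))
#' dim(s$pixels)
ct_slice <- function(pixels, pixel_spacing = c(0.5, 0.5), slice_index = 0L,
                     source_id = "unknown") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    ctces_abort("`pixels` must be a non-empty matrix.", "ctces_error_format")
  }
  if (any(!is.finite(pixels))) {
    ctces_abort("All HU values must be finite.", "ctces_error_format")
  }
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) {
      ctces_abort("HU values must be integer-valued; use to_hounsfield() to rescale.",
                  "ctces_error_format")
    }
    storage.mode(pixels) <- "integer"
  }
  structure(
    list(pixels = pixels,
         rows = nrow(pixels), cols = ncol(pixels),
         pixel_spacing = as.numeric(pixel_spacing),
         slice_index = as.integer(slice_index),
         source_id = as.character(source_id)),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, %.3g x %.3g mm/px, index %d (%s)\n",
              x$rows, x$cols, x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_index, x$source_id))
  cat(sprintf("  HU range: [%d, %d]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @param slices List of `ct_slice`, ordered vertex to caudal.
#' @param subject_id Subject identifier.
#' @rdname ct_slice
#' @export
ct_series <- function(slices, subject_id = "unknown") {
  if (length(slices) < 1L) {
    ctces_abort("A series needs at least one slice.", "ctces_error_format")
  }
  if (!all(vapply(slices, inherits, logical(1), "ct_slice"))) {
    ctces_abort("All elements must be ct_slice objects.", "ctces_error_format")
  }
  dims <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ctces_abort("All slices in a series must share grid dimensions.",
                "ctces_error_format")
  }
  structure(list(slices = slices, subject_id = as.character(subject_id),
                 n = length(slices)),
            class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  cat(sprintf("<ct_series> subject %s: n = %d slices of %d x %d px\n",
              x$subject_id, x$n, x$slices[[1]]$rows, x$slices[[1]]$cols))
  invisible(x)
}

#' Convert raw scanner values to Hounsfield Units
#'
#' Applies the standard CT linear rescale `HU = raw * slope + intercept`.
#' Results are rounded half-away-from-zero to integers, since densitometry
#' bins pixels by integer HU.
#'
#' @param raw Numeric matrix or vector of stored pixel values.
#' @param slope Rescale slope (must be non-zero).
#' @param intercept Rescale intercept.
#' @return Integer grid of HU values, same shape as `raw`.
#' @export
#' @examples
#' to_hounsfield(2000, 1, -1024)  # 976
to_hounsfield <- function(raw, slope, intercept) {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0) {
    ctces_abort("Rescale slope must be a single non-zero number.",
                "ctces_error_metadata")
  }
  x <- raw * slope + intercept
  out <- sign(x) * floor(abs(x) + 0.5)  # half-away-from-zero
  storage.mode(out) <- "integer"
  out
}
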