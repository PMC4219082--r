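#' Read and write CT series
#'
#' Two on-disk layouts are supported. The portable *fixture* format stores one
#' whitespace-delimited integer grid per slice (`slice_000.txt`, ...) plus a
#' `series.json` sidecar with subject id, pixel spacing and slice order; it
#' round-trips HU grids bit-exactly. Single-frame CT DICOM files are read via
#' [read_dicom_slice()], with the rescale to HU already applied and slices
#' ordered by slice-position metadata (ties broken by instance number).
#'
#' @param path Directory holding one series.
#' @param format `"fixture"` or `"dicom"`.
#' @return `read_series()` returns a [ct_series()]; `write_series()` returns
#'   `path` invisibly.
#' @export
read_series <- function(path, format = c("fixture", "dicom")) {
  format <- match.arg(format)
  if (!dir.exists(path)) {
    ctces_abort(paste0("Series directory not found: ", path), "ctces_error_io")
  }
  if (format == "fixture") {
    sidecar <- file.path(path, "series.json")
    if (!file.exists(sidecar)) {
      ctces_abort(paste0("Missing series.json sidecar in ", path),
                  "ctces_error_io")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    slices <- purrr::map2(meta$slice_files, seq_along(meta$slice_files) - 1L,
      function(f, idx) {
        fp <- file.path(path, f)
        if (!file.exists(fp)) {
          ctces_abort(paste0("Missing slice file: ", fp), "ctces_error_io")
        }
        g <- as.matrix(utils::read.table(fp, colClasses = "integer"))
        dimnames(g) <- NULL
        ct_slice(g, pixel_spacing = meta$pixel_spacing, slice_index = idx,
                 source_id = fp)
      })
  } else {
    files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
    if (length(files) == 0L) files <- list.files(path, full.names = TRUE)
    raw <- purrr::map(files, read_dicom_slice)
    loc <- vapply(raw, function(s) attr(s, "slice_location") %||% NA_real_,
                  numeric(1))
    inst <- vapply(raw, function(s) attr(s, "instance_number") %||% NA_real_,
                   numeric(1))
    ord <- order(loc, inst, na.last = TRUE)
    slices <- purrr::map2(raw[ord], seq_along(raw) - 1L, function(s, idx) {
      s$slice_index <- idx
      s
    })
  }
  dims <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ctces_abort("Mixed grid sizes in series.", "ctces_error_format")
  }
  meta_subject <- if (format == "fixture") meta$subject_id %||% basename(path) else basename(path)
  ct_series(slices, subject_id = meta_subject)
}

#' @param series A [ct_series()].
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "ct_series"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("slice_%03d.txt", seq_along(series$slices) - 1L)
  for (i in seq_along(series$slices)) {
    utils::write.table(series$slices[[i]]$pixels,
                       file.path(path, files[i]),
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(subject_id = series$subject_id,
         pixel_spacing = series$slices[[1]]$pixel_spacing,
         slice_files = files),
    file.path(path, "series.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a density distribution as CSV
#'
#' Writes/reads the 80-row `(hu, proportion)` table; proportions are in
#' percent and sum to 100.
#'
#' @param dist A [density_distribution] object (see [slice_distribution()]).
#' @param path File path.
#' @return `write_distribution()` returns `path` invisibly;
#'   `read_distribution()` returns a `density_distribution`.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "density_distribution"))
  # %.17g keeps doubles bit-exact across the round trip, so rank-based
  # analyses see identical ties whether they run from memory or from disk
  lines <- c("hu,proportion",
             sprintf("%d,%.17g", dist$hu, dist$proportion))
  tryCatch(writeLines(lines, path),
           error = function(e) ctces_abort(
             paste0("Cannot write distribution to ", path, ": ",
                    conditionMessage(e)), "ctces_error_io"))
  invisible(path)
}

#' @rdname write_distribution
#' @param level,n_images,n_pixels Metadata restored on read (the CSV itself
#'   carries only the 80 proportions).
#' @export
read_distribution <- function(path, level = "series", n_images = NA_integer_,
                              n_pixels = NA_integer_) {
  # base parser: correctly rounded doubles, so the round trip is bit-exact
  tab <- utils::read.csv(path)
  if (!all(c("hu", "proportion") %in% names(tab)) || nrow(tab) != 80L) {
    ctces_abort("Distribution file must have 80 rows of (hu, proportion).",
                "ctces_error_format")
  }
  tab <- tab[order(tab$hu), ]
  new_density_distribution(tab$proportion, level = level,
                           n_images = n_images, n_pixels = n_pixels)
}
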