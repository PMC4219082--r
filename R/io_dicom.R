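#' Read a single-frame CT DICOM image
#'
#' A compact reader for uncompressed single-frame CT images in the implicit or
#' explicit VR little-endian transfer syntaxes (the storage form of
#' conventional axial brain CT). Stored values are converted to Hounsfield
#' Units using the file's RescaleSlope/RescaleIntercept via [to_hounsfield()].
#' Only the elements densitometry needs are interpreted (Rows, Columns,
#' PixelSpacing, BitsAllocated, PixelRepresentation, rescale pair, slice
#' position, PixelData); everything else is skipped structurally.
#'
#' @param file Path to one DICOM file.
#' @return A [ct_slice()] with attributes `slice_location` and
#'   `instance_number` used for series ordering.
#' @export
read_dicom_slice <- function(file) {
  if (!file.exists(file)) {
    ctces_abort(paste0("DICOM file not found: ", file), "ctces_error_io")
  }
  bytes <- readBin(file, "raw", file.size(file))
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM") {
    ctces_abort(paste0("Not a DICOM part-10 file: ", file), "ctces_error_io")
  }
  pos <- 133L
  u16 <- function(i) readBin(bytes[i:(i + 1L)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3L)], "integer", size = 4,
                             endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  explicit <- TRUE  # file meta group is always explicit little-endian
  ts <- "1.2.840.10008.1.2.1"
  in_meta <- TRUE
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (in_meta && group != 0x0002) {
      # dataset begins; switch syntax if the meta header said implicit VR
      in_meta <- FALSE
      explicit <- !identical(ts, "1.2.840.10008.1.2")
      if (grepl("1.2.840.10008.1.2.4|1.2.840.10008.1.2.5", ts)) {
        ctces_abort(paste0("Compressed transfer syntax unsupported: ", ts),
                    "ctces_error_format")
      }
    }
    if (explicit || in_meta) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len < 0L) {
      ctces_abort("Undefined-length elements unsupported.", "ctces_error_format")
    }
    val_start <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    keep <- c("0002,0010", "0020,0013", "0020,1041", "0028,0010", "0028,0011",
              "0028,0030", "0028,0100", "0028,0103", "0028,1052", "0028,1053",
              "7fe0,0010")
    if (key %in% keep && len > 0L) {
      elems[[key]] <- bytes[val_start:(val_start + len - 1L)]
      if (key == "0002,0010") {
        ts <- sub("\\x00+$", "", rawToChar(elems[[key]]))
      }
    }
    pos <- val_start + len
    if (key == "7fe0,0010") break
  }
  num <- function(key, default = NULL) {
    v <- elems[[key]]
    if (is.null(v)) return(default)
    as.numeric(strsplit(trimws(rawToChar(v)), "\\\\")[[1]])
  }
  us <- function(key, default = NULL) {
    v <- elems[[key]]
    if (is.null(v)) return(default)
    readBin(v, "integer", size = 2, endian = "little", signed = FALSE)
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  px <- elems[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px)) {
    ctces_abort(paste0("DICOM file lacks image elements: ", file),
                "ctces_error_format")
  }
  bits <- us("0028,0100", 16L)
  if (bits != 16L) {
    ctces_abort("Only 16-bit CT pixel data is supported.", "ctces_error_format")
  }
  signed <- identical(us("0028,0103", 0L), 1L)
  raw_vals <- readBin(px, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = signed)
  if (!signed) raw_vals <- as.numeric(raw_vals)
  # DICOM pixel data is row-major
  grid <- matrix(raw_vals, nrow = rows, ncol = cols, byrow = TRUE)
  slope <- num("0028,1053", 1)[1]
  intercept <- num("0028,1052", 0)[1]
  hu <- to_hounsfield(grid, slope, intercept)
  spacing <- num("0028,0030", c(1, 1))
  out <- ct_slice(hu, pixel_spacing = spacing, source_id = file)
  attr(out, "slice_location") <- num("0020,1041", NA_real_)[1]
  attr(out, "instance_number") <- num("0020,0013", NA_real_)[1]
  out
}
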