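# Byte-level DICOM writer used only to build test fixtures; constructed
# directly from the part-10 encoding rules, independent of the reader.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcm_elem <- function(group, elem, vr, value, explicit = TRUE) {
  val <- switch(vr,
    US = dcm_u16(value),
    CS = dcm_str(value),
    UI = { r <- charToRaw(value); if (length(r) %% 2) c(r, as.raw(0)) else r },
    DS = dcm_str(paste(format(value), collapse = "\\")),
    IS = dcm_str(paste0(value)),
    OW = value)
  hdr <- c(dcm_u16(group), dcm_u16(elem))
  if (explicit) {
    if (vr == "OW") {
      c(hdr, charToRaw(vr), as.raw(c(0, 0)),
        writeBin(length(val), raw(), size = 4, endian = "little"), val)
    } else {
      c(hdr, charToRaw(vr), dcm_u16(length(val)), val)
    }
  } else {
    c(hdr, writeBin(length(val), raw(), size = 4, endian = "little"), val)
  }
}

# one single-frame CT slice; `raw_grid` holds stored (pre-rescale) values
write_test_dicom <- function(path, raw_grid, slope = 1, intercept = -1024,
                             slice_location = 0, instance = 1,
                             spacing = c(0.5, 0.5), signed = FALSE,
                             implicit = FALSE) {
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  px <- writeBin(as.integer(t(raw_grid)), raw(), size = 2, endian = "little")
  meta <- dcm_elem(0x0002, 0x0010, "UI", ts, explicit = TRUE)
  ex <- !implicit
  body <- c(
    dcm_elem(0x0020, 0x0013, "IS", instance, ex),
    dcm_elem(0x0020, 0x1041, "DS", slice_location, ex),
    dcm_elem(0x0028, 0x0002, "US", 1L, ex),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2", ex),
    dcm_elem(0x0028, 0x0010, "US", nrow(raw_grid), ex),
    dcm_elem(0x0028, 0x0011, "US", ncol(raw_grid), ex),
    dcm_elem(0x0028, 0x0030, "DS", spacing, ex),
    dcm_elem(0x0028, 0x0100, "US", 16L, ex),
    dcm_elem(0x0028, 0x0101, "US", 16L, ex),
    dcm_elem(0x0028, 0x0102, "US", 15L, ex),
    dcm_elem(0x0028, 0x0103, "US", as.integer(signed), ex),
    dcm_elem(0x0028, 0x1052, "DS", intercept, ex),
    dcm_elem(0x0028, 0x1053, "DS", slope, ex),
    dcm_elem(0x7FE0, 0x0010, "OW", px, ex))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}
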