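# Minimal DICOM I/O (single-frame CT, explicit VR little endian).
#
# The supported dependency set has no DICOM reader, so the package carries a
# deliberately small parser covering what the preprocessing front end needs:
# uncompressed single-frame images, explicit VR little endian transfer
# syntax, signed/unsigned 16-bit pixel data, with rescale slope/intercept,
# pixel spacing, slice thickness and image position. A matching writer is
# provided so the simulator and the test-suite can build series in code.

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

# VRs that use the 4-byte length form (2 reserved bytes + uint32 length).
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stopf("%s: missing DICM magic (only part-10 files are supported)", path)
  pos <- 133L
  out <- list()
  n <- length(raw)
  u16 <- function(p) readBin(raw[p:(p + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(p) readBin(raw[p:(p + 3L)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_long_vrs) {
      len <- u32(pos + 8L); body <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L); body <- pos + 8L
    } else {
      stopf("%s: implicit VR or unsupported element at byte %d", path, pos)
    }
    if (len < 0 || body + len - 1L > n)
      stopf("%s: element %s overruns file", path, dcm_tag(group, elem))
    bytes <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    key <- dcm_tag(group, elem)
    val <- switch(vr,
      US = readBin(bytes, "integer", n = len / 2, size = 2,
                   signed = FALSE, endian = "little"),
      UL = readBin(bytes, "integer", n = len / 4, size = 4,
                   endian = "little"),
      DS = as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
      IS = as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
      UI = ,
      LO = ,
      SH = ,
      PN = ,
      CS = trimws(rawToChar(bytes[bytes != as.raw(0)]), which = "right"),
      OW = bytes,
      OB = bytes,
      bytes)
    out[[key]] <- val
    pos <- body + len
  }
  rows <- out[[dcm_tag(0x0028, 0x0010)]]
  cols <- out[[dcm_tag(0x0028, 0x0011)]]
  px <- out[[dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stopf("%s: missing Rows/Columns/PixelData", path)
  signed <- identical(out[[dcm_tag(0x0028, 0x0103)]], 1L)
  stored <- readBin(px, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  slope <- (out[[dcm_tag(0x0028, 0x1053)]] %||% 1)[1]
  inter <- (out[[dcm_tag(0x0028, 0x1052)]] %||% 0)[1]
  hu <- stored * slope + inter
  ipp <- out[[dcm_tag(0x0020, 0x0032)]] %||% c(0, 0, 0)
  ps <- out[[dcm_tag(0x0028, 0x0030)]] %||% c(1, 1)
  thick <- (out[[dcm_tag(0x0018, 0x0050)]] %||% 1)[1]
  list(img = array(hu, dim = c(cols, rows)),   # [x, y]; stream is row-major
       z = ipp[3], pixel_spacing = ps, thickness = thick,
       rows = rows, cols = cols)
}

#' Write a minimal single-frame CT DICOM file
#'
#' Explicit VR little endian, signed 16-bit pixels. Used by the phantom
#' simulator and the test-suite to build series in code; it writes only the
#' attributes the package's own reader consumes.
#'
#' @param img 2D numeric matrix indexed `[x, y]` of values in HU (after
#'   rescale: stored value = (HU - intercept) / slope).
#' @param path Output file path.
#' @param z Image position z coordinate (mm).
#' @param pixel_spacing In-plane spacing (mm), length 2.
#' @param thickness Slice thickness (mm).
#' @param slope,intercept Rescale slope/intercept written to the file.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(img, path, z = 0, pixel_spacing = c(1, 1),
                              thickness = 3, slope = 1, intercept = -1024) {
  nx <- nrow(img); ny <- ncol(img)
  stored <- as.integer(round((as.vector(img) - intercept) / slope))
  if (any(stored < -32768 | stored > 32767))
    stopf("stored pixel values exceed int16 under slope=%g intercept=%g",
          slope, intercept)
  enc_short <- function(group, elem, vr, bytes) {
    if (length(bytes) %% 2 == 1)
      bytes <- c(bytes, as.raw(if (vr == "UI") 0x00 else 0x20))
    c(writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little"),
      charToRaw(vr),
      writeBin(length(bytes), raw(), size = 2, endian = "little"),
      bytes)
  }
  enc_long <- function(group, elem, vr, bytes) {
    c(writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little"),
      charToRaw(vr), raw(2),
      writeBin(length(bytes), raw(), size = 4, endian = "little"),
      bytes)
  }
  ds <- function(...) charToRaw(paste(format(c(...), trim = TRUE),
                                      collapse = "\\"))
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  body <- c(
    enc_short(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
    enc_short(0x0018, 0x0050, "DS", ds(thickness)),
    enc_short(0x0020, 0x0032, "DS", ds(0, 0, z)),
    enc_short(0x0028, 0x0002, "US", us(1)),
    enc_short(0x0028, 0x0010, "US", us(ny)),       # Rows
    enc_short(0x0028, 0x0011, "US", us(nx)),       # Columns
    enc_short(0x0028, 0x0030, "DS", ds(pixel_spacing[1], pixel_spacing[2])),
    enc_short(0x0028, 0x0100, "US", us(16)),
    enc_short(0x0028, 0x0101, "US", us(16)),
    enc_short(0x0028, 0x0103, "US", us(1)),        # signed
    enc_short(0x0028, 0x1052, "DS", ds(intercept)),
    enc_short(0x0028, 0x1053, "DS", ds(slope)),
    enc_long(0x7FE0, 0x0010, "OW",
             writeBin(stored, raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
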