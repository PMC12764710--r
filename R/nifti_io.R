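# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the supported dependency set, so the
# package carries a small reader/writer for the subset of NIfTI-1 it needs:
# single-file .nii / .nii.gz, little-endian, datatypes uint8 (2), int16 (4),
# int32 (8), float32 (16), float64 (64), spacing from pixdim, scl_slope /
# scl_inter applied on read. Orientation matrices (qform/sform) are neither
# read nor written; the package's own axial convention (index 1 = most
# superior) is documented in the sidecar JSON written next to exported
# volumes.

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "numeric", size = 4, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "numeric", size = 8, signed = TRUE,  bitpix = 64L))

#' Read a NIfTI-1 volume
#'
#' Minimal reader for single-file little-endian `.nii` / `.nii.gz` images
#' (see the package vignette for the supported subset). Returns the voxel
#' array with `scl_slope` / `scl_inter` applied and the (x, y, z) spacing
#' from `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `voxels` (3D array) and `spacing` (length-3, mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stopf("truncated NIfTI header in %s", path)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  if (rd(0, "integer", 1, 4) != 348L)
    stopf("%s: not a little-endian NIfTI-1 file", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("%s: bad NIfTI magic '%s'", path, magic)
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3) stopf("%s: expected a 3D image, got %d dims", path, ndim)
  dim3 <- dims[2:4]
  datatype <- rd(70, "integer", 1, 2)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stopf("%s: unsupported NIfTI datatype %d", path, datatype)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  n_vox <- prod(dim3)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) < n_vox) stopf("%s: truncated voxel data", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(voxels = array(vals, dim = dim3), spacing = abs(pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image (float32 by default).
#' Gzip compression is chosen from the file extension (`.nii.gz`).
#'
#' @param voxels 3D numeric array.
#' @param spacing Length-3 voxel spacing in mm.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI datatype code: 16 (float32, default), 4 (int16) or
#'   64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(voxels, spacing, path, datatype = 16L) {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt) || !datatype %in% c(4L, 16L, 64L))
    stopf("unsupported write datatype %s", datatype)
  hdr <- raw(348)
  put <- function(off, vals, size) {
    b <- writeBin(vals, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, 4)                                   # sizeof_hdr
  put(40, as.integer(c(3L, dim(voxels), 1L, 1L, 1L, 1L)), 2)  # dim
  put(70, as.integer(datatype), 2)                  # datatype
  put(72, dt$bitpix, 2)                             # bitpix
  put(76, as.numeric(c(1, spacing, 0, 0, 0, 0)), 4) # pixdim
  put(108, 352, 4)                                  # vox_offset
  put(112, c(1, 0), 4)                              # scl_slope, scl_inter
  hdr[345:348] <- as.raw(c(0x6e, 0x2b, 0x31, 0x00)) # "n+1\0"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                             # extension flag
  vals <- as.vector(voxels)
  if (datatype == 4L) {
    vals <- as.integer(round(pmin(pmax(vals, -32768), 32767)))
    writeBin(vals, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
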