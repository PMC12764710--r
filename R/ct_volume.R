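#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar field of CT intensities in Hounsfield
#' units together with its voxel spacing. The array is indexed
#' `[x, y, z]` with the axial (z) axis third; by package convention axial
#' index 1 is the most superior retained slice (apex-first ordering), so
#' increasing z walks toward the lung base.
#'
#' @param voxels 3D numeric array of intensities in Hounsfield units.
#' @param spacing Numeric length-3 vector, voxel spacing in mm along
#'   (x, y, z); all components must be strictly positive.
#' @param patient_id Opaque identifier carried through the pipeline.
#'
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `axial_order` (always `"apex-first"`) and `patient_id`.
#' @export
ct_volume <- function(voxels, spacing, patient_id = "anon") {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values (mm)")
  structure(
    list(voxels = voxels, spacing = spacing,
         axial_order = "apex-first", patient_id = as.character(patient_id)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume %s: %dx%dx%d voxels @ (%g, %g, %g) mm, HU range [%g, %g]>\n",
              x$patient_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary lung mask aligned with a CT volume
#'
#' @param mask 3D array coercible to logical; same shape as the volume it
#'   annotates.
#' @return An object of class `lung_mask` wrapping a logical array.
#' @export
lung_mask <- function(mask) {
  if (length(dim(mask)) != 3L) stopf("mask must be a 3D array")
  m <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(m)) stopf("mask must contain only 0/1 (or logical) values")
  structure(list(mask = m), class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<lung_mask %dx%dx%d, %d voxels set>\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$voxels), dim(mask$mask)))
    stopf("volume (%s) and mask (%s) shapes differ",
          paste(dim(vol$voxels), collapse = "x"),
          paste(dim(mask$mask), collapse = "x"))
  invisible(TRUE)
}

#' Slice stack ready for the 2D encoder
#'
#' Ordered, filtered, cropped and normalized axial slices, each resized to a
#' common square shape with intensities in \[0, 1\], plus each slice's
#' relative axial position (0 = most apical retained slice, 1 = most basal)
#' and its original axial index in the source volume.
#'
#' @param slices List of equal-shape 2D matrices with values in \[0, 1\].
#' @param relative_positions Numeric vector in \[0, 1\], nondecreasing; when
#'   more than one slice is present the first must be 0 and the last 1.
#' @param source_indices Integer vector of original axial indices.
#' @param patient_id Identifier carried along.
#' @return An object of class `slice_stack` with field `R` = slice count.
#' @export
slice_stack <- function(slices, relative_positions, source_indices,
                        patient_id = "anon") {
  R <- length(slices)
  if (R < 1L) stopf("a slice_stack needs at least one slice")
  shp <- dim(slices[[1]])
  for (s in slices)
    if (!identical(dim(s), shp)) stopf("all slices must share one shape")
  rp <- as.numeric(relative_positions)
  if (length(rp) != R || any(rp < 0) || any(rp > 1) || is.unsorted(rp))
    stopf("relative_positions must be nondecreasing in [0,1], length R")
  if (R > 1L && (abs(rp[1]) > 1e-12 || abs(rp[R] - 1) > 1e-12))
    stopf("relative_positions must start at 0 and end at 1 when R > 1")
  structure(
    list(slices = slices, relative_positions = rp,
         source_indices = as.integer(source_indices), R = R,
         patient_id = as.character(patient_id)),
    class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  shp <- dim(x$slices[[1]])
  cat(sprintf("<slice_stack %s: R=%d slices of %dx%d>\n",
              x$patient_id, x$R, shp[1], shp[2]))
  invisible(x)
}
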