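# CT preprocessing pipeline: load -> resample to (1,1,3) mm -> segment lungs
# -> drop slices with < 2% lung area -> crop the union lung bounding box ->
# resize each retained slice to 224x224 and window HU to [0,1].

#' Load a CT volume from disk
#'
#' Reads either a DICOM series directory (one single-frame file per axial
#' slice, explicit VR little endian) or a NIfTI volume. Intensities are
#' returned in Hounsfield units (rescale slope/intercept applied when
#' present) and slices are sorted superior-to-inferior (descending patient
#' z), so axial index 1 is the most superior slice.
#'
#' @param path Directory containing a DICOM series, or a `.nii`/`.nii.gz`
#'   file.
#' @param format `"dicom-series"` or `"nifti"`; the default guesses from
#'   `path`.
#' @param patient_id Identifier attached to the returned volume; defaults to
#'   the file/directory name.
#' @return A [ct_volume()].
#' @export
load_ct_volume <- function(path,
                           format = c("auto", "dicom-series", "nifti"),
                           patient_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom-series" else "nifti"
  pid <- patient_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  if (format == "nifti") {
    nii <- read_nifti(path)
    return(ct_volume(nii$voxels, nii$spacing, patient_id = pid))
  }
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) files <- list.files(path, full.names = TRUE)
  if (!length(files)) stopf("no DICOM files found in %s", path)
  slices <- lapply(sort(files), read_dicom_file)
  dims <- vapply(slices, function(s) c(s$cols, s$rows), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("inconsistent in-plane dimensions across series in %s", path)
  zs <- vapply(slices, function(s) s$z, numeric(1))
  ord <- order(zs, decreasing = TRUE)          # superior (largest z) first
  slices <- slices[ord]; zs <- zs[ord]
  if (length(zs) > 1L) {
    dz <- abs(diff(zs))
    step <- min(dz)
    if (step <= 0) stopf("duplicate slice positions in %s", path)
    gap <- which(dz > 1.5 * step)
    if (length(gap))
      stopf(paste0("missing or irregular slices in %s: spacing breaks after ",
                   "sorted slice %s (z = %s mm, expected step %.3f mm, got %.3f mm)"),
            path, gap[1], format(zs[gap[1]]), step, dz[gap[1]])
    z_spacing <- step
  } else {
    z_spacing <- slices[[1]]$thickness
  }
  ps <- slices[[1]]$pixel_spacing
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  vox <- array(0, dim = c(nx, ny, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$img
  ct_volume(vox, c(ps[2], ps[1], z_spacing), patient_id = pid)
}

#' Resample a CT volume to a target voxel spacing
#'
#' Trilinear interpolation on an index-aligned grid. The output shape per
#' axis is `round(extent_mm / target_spacing)` where `extent_mm = n *
#' spacing`.
#'
#' @param vol A [ct_volume()].
#' @param target_spacing Length-3 target spacing in mm; default `c(1, 1, 3)`.
#' @param nearest Use nearest-neighbour interpolation (for masks).
#' @return A resampled [ct_volume()].
#' @export
resample_volume <- function(vol, target_spacing = c(1, 1, 3),
                            nearest = FALSE) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stopf("target_spacing must be 3 strictly positive values")
  d <- dim(vol$voxels)
  outdim <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  ratio <- target_spacing / vol$spacing
  out <- .resample3d(as.vector(vol$voxels), as.integer(d), ratio,
                     outdim, nearest)
  ct_volume(array(out, dim = outdim), target_spacing,
            patient_id = vol$patient_id)
}

#' Resample a lung mask with nearest-neighbour interpolation
#'
#' @param mask A [lung_mask()].
#' @param spacing Current spacing of the mask's volume (mm).
#' @param target_spacing Target spacing (mm).
#' @return A resampled [lung_mask()].
#' @export
resample_mask <- function(mask, spacing, target_spacing = c(1, 1, 3)) {
  v <- ct_volume(array(as.numeric(mask$mask), dim = dim(mask$mask)), spacing)
  r <- resample_volume(v, target_spacing, nearest = TRUE)
  lung_mask(r$voxels > 0.5)
}

#' Rule-based threshold lung segmenter
#'
#' Default segmenter: voxels below `hu_threshold` are air candidates;
#' 6-connected components touching the x/y volume border are discarded as
#' outside air; the two largest remaining components are kept as the lungs;
#' a morphological closing (dilate then erode, 6-neighbourhood) fills small
#' internal gaps. Deterministic and dependency-free; a learned segmenter
#' can replace it through the `segmenter` argument of [segment_lungs()].
#'
#' @param vol A [ct_volume()] in HU.
#' @param hu_threshold Air/parenchyma threshold; default -320 HU.
#' @param closing_iterations Closing radius in voxels (0 disables).
#' @return A [lung_mask()]; carries attribute `n_components` (number of
#'   lung-like components found, 0, 1 or 2).
#' @export
threshold_segmenter <- function(vol, hu_threshold = -320,
                                closing_iterations = 1L) {
  d <- dim(vol$voxels)
  cand <- as.vector(vol$voxels < hu_threshold)
  lab <- .cc_label3d(cand, as.integer(d))
  ncomp <- attr(lab, "n_components")
  empty <- function() {
    m <- lung_mask(array(FALSE, dim = d))
    attr(m, "n_components") <- 0L
    m
  }
  if (ncomp == 0L) return(empty())
  lab_a <- array(lab, dim = d)
  border <- unique(c(lab_a[1, , ], lab_a[d[1], , ],
                     lab_a[, 1, ], lab_a[, d[2], ]))
  border <- setdiff(border, 0L)
  sizes <- tabulate(lab, nbins = ncomp)
  sizes[border] <- 0L
  keep <- order(sizes, decreasing = TRUE)
  keep <- keep[sizes[keep] > 0L]
  keep <- utils::head(keep, 2L)
  if (!length(keep)) return(empty())
  m <- array(lab %in% keep, dim = d)
  if (closing_iterations > 0L) {
    m <- .binary_dilate3d(as.vector(m), as.integer(d),
                          as.integer(closing_iterations))
    m <- .binary_erode3d(m, as.integer(d), as.integer(closing_iterations))
    m <- array(m, dim = d)
  }
  out <- lung_mask(m)
  attr(out, "n_components") <- length(keep)
  out
}

#' Segment the lungs of a CT volume
#'
#' Applies a pluggable segmenter (default: [threshold_segmenter()]). If no
#' lung-like component is found the empty mask is returned with a warning
#' and attribute `n_components = 0`, never silently.
#'
#' @param vol A [ct_volume()] in HU.
#' @param segmenter Function `(vol, ...) -> lung_mask`.
#' @param ... Passed on to the segmenter.
#' @return A [lung_mask()] aligned with `vol`.
#' @export
segment_lungs <- function(vol, segmenter = threshold_segmenter, ...) {
  mask <- segmenter(vol, ...)
  if (!inherits(mask, "lung_mask"))
    stopf("segmenter must return a lung_mask")
  check_aligned(vol, mask)
  if (!any(mask$mask))
    warnf("no lung-like component found for patient %s: empty mask",
          vol$patient_id)
  mask
}

#' Per-slice lung-area fractions
#'
#' @param mask A [lung_mask()].
#' @return Numeric vector, one value per axial slice: lung pixels divided by
#'   total pixels in that slice.
#' @export
lung_fraction_per_slice <- function(mask) {
  d <- dim(mask$mask)
  apply(mask$mask, 3L, sum) / (d[1] * d[2])
}

#' Select axial slices by minimum lung-area fraction
#'
#' Slices whose lung area is strictly below `min_fraction` of the slice area
#' are excluded (a fraction of exactly `min_fraction` is retained). By
#' default every sub-threshold slice is dropped, including interior ones;
#' `mode = "trim"` instead only trims sub-threshold runs at the apical and
#' basal ends, keeping interior gaps.
#'
#' @param vol A [ct_volume()] (used for the error message only).
#' @param mask Aligned [lung_mask()].
#' @param min_fraction Threshold fraction; default 0.02 (2%).
#' @param mode `"drop-all"` (default) or `"trim"`.
#' @return Integer vector of retained axial indices, in ascending order.
#' @export
filter_slices <- function(vol, mask, min_fraction = 0.02,
                          mode = c("drop-all", "trim")) {
  mode <- match.arg(mode)
  check_aligned(vol, mask)
  fr <- lung_fraction_per_slice(mask)
  ok <- fr >= min_fraction
  retained <- which(ok)
  if (!length(retained))
    stopf("no slice of patient %s reaches a lung fraction of %g",
          vol$patient_id, min_fraction)
  if (mode == "trim") retained <- seq(min(retained), max(retained))
  retained
}

#' Crop a volume to the union lung bounding box
#'
#' Computes one in-plane bounding box: the union over the retained slices of
#' each slice's lung bounding box, and applies that same box to every
#' retained slice; non-retained slices are dropped. The box is inclusive, so
#' no masked lung pixel of a retained slice is discarded.
#'
#' @param vol A [ct_volume()].
#' @param mask Aligned [lung_mask()].
#' @param retained Integer vector of retained axial indices.
#' @return A cropped [ct_volume()]; attribute `bbox` holds
#'   `c(x0, x1, y0, y1)` and attribute `source_indices` the retained
#'   indices.
#' @export
crop_roi <- function(vol, mask, retained) {
  check_aligned(vol, mask)
  if (!length(retained)) stopf("retained index set is empty")
  sub <- mask$mask[, , retained, drop = FALSE]
  if (!any(sub))
    stopf("mask is empty on all retained slices of patient %s",
          vol$patient_id)
  xs <- which(apply(sub, 1L, any))
  ys <- which(apply(sub, 2L, any))
  box <- c(min(xs), max(xs), min(ys), max(ys))
  out <- ct_volume(
    vol$voxels[box[1]:box[2], box[3]:box[4], retained, drop = FALSE],
    vol$spacing, patient_id = vol$patient_id)
  attr(out, "bbox") <- box
  attr(out, "source_indices") <- as.integer(retained)
  out
}

#' Resize retained slices and normalize intensities
#'
#' Each slice is resized to `out_size` x `out_size` pixels (bilinear, aspect
#' ratio not preserved), clipped to the HU window and mapped linearly to
#' \[0, 1\]. Relative axial positions are `(i - 1) / (R - 1)` over the
#' retained order (0 when `R = 1`).
#'
#' @param vol A cropped [ct_volume()] as returned by [crop_roi()].
#' @param out_size Output side length in pixels; default 224.
#' @param hu_window `c(low, high)` clipping window; default `c(-1000, 400)`.
#' @return A [slice_stack()].
#' @export
resize_and_normalize <- function(vol, out_size = 224L,
                                 hu_window = c(-1000, 400)) {
  if (out_size < 8L) stopf("out_size must be at least 8 pixels")
  if (hu_window[2] <= hu_window[1]) stopf("hu_window must be increasing")
  R <- dim(vol$voxels)[3]
  src <- attr(vol, "source_indices") %||% seq_len(R)
  lo <- hu_window[1]; hi <- hu_window[2]
  slices <- vector("list", R)
  for (i in seq_len(R)) {
    s <- .resize_bilinear(vol$voxels[, , i], as.integer(out_size),
                          as.integer(out_size))
    slices[[i]] <- (pmin(pmax(s, lo), hi) - lo) / (hi - lo)
  }
  rp <- if (R == 1L) 0 else (seq_len(R) - 1) / (R - 1)
  slice_stack(slices, rp, src, patient_id = vol$patient_id)
}

#' Training-time augmentation configuration
#'
#' @param apply_probability Probability that a slice is augmented at all;
#'   default 0.2.
#' @param rotation_range_degrees Rotation drawn uniformly in plus/minus this
#'   angle; default 20.
#' @param flip_probability Probability of a horizontal flip given that the
#'   slice is augmented; default 0.5.
#' @return An `augment_config` list.
#' @export
augment_config <- function(apply_probability = 0.2,
                           rotation_range_degrees = 20,
                           flip_probability = 0.5) {
  if (apply_probability < 0 || apply_probability > 1 ||
      flip_probability < 0 || flip_probability > 1)
    stopf("probabilities must lie in [0, 1]")
  if (rotation_range_degrees < 0) stopf("rotation range must be nonnegative")
  structure(list(apply_probability = apply_probability,
                 rotation_range_degrees = rotation_range_degrees,
                 flip_probability = flip_probability),
            class = "augment_config")
}

#' Randomly flip and rotate a slice
#'
#' With probability `cfg$apply_probability` the slice is (possibly) flipped
#' and rotated by an angle drawn uniformly in the configured range; rotation
#' uses bilinear interpolation with edge fill 0. Draws come from R's RNG, so
#' fixing the seed makes the output reproducible bit-for-bit.
#'
#' @param slice 2D numeric matrix.
#' @param cfg An [augment_config()].
#' @return The augmented 2D matrix.
#' @export
augment_slice <- function(slice, cfg = augment_config()) {
  if (stats::runif(1) >= cfg$apply_probability) return(slice)
  out <- slice
  if (stats::runif(1) < cfg$flip_probability)
    out <- out[nrow(out):1, , drop = FALSE]
  angle <- stats::runif(1, -cfg$rotation_range_degrees,
                        cfg$rotation_range_degrees)
  if (abs(angle) > 1e-12) out <- .rotate_bilinear(out, angle, 0)
  out
}

#' Run the full preprocessing pipeline on one volume
#'
#' Resample to `spacing`, segment the lungs, filter slices by lung-area
#' fraction, crop the union bounding box and produce the normalized slice
#' stack, together with the per-patient provenance the sidecar JSON records.
#'
#' @param vol A [ct_volume()] in HU.
#' @param spacing Target spacing; default `c(1, 1, 3)` mm.
#' @param min_fraction Lung-area threshold; default 0.02.
#' @param out_size Slice side length; default 224.
#' @param hu_window HU clipping window; default `c(-1000, 400)`.
#' @param segmenter Pluggable segmenter; default [threshold_segmenter()].
#' @param mask Optional precomputed [lung_mask()] aligned with `vol` (e.g.
#'   a ground-truth phantom mask); skips segmentation.
#' @return A list with `stack` ([slice_stack()]), `retained`, `fractions`,
#'   `bbox` and `spacing`.
#' @export
preprocess_volume <- function(vol, spacing = c(1, 1, 3),
                              min_fraction = 0.02, out_size = 224L,
                              hu_window = c(-1000, 400),
                              segmenter = threshold_segmenter,
                              mask = NULL) {
  rvol <- if (isTRUE(all.equal(vol$spacing, spacing))) vol
          else resample_volume(vol, spacing)
  if (is.null(mask)) {
    rmask <- segment_lungs(rvol, segmenter)
  } else {
    check_aligned(vol, mask)
    rmask <- if (identical(dim(mask$mask), dim(rvol$voxels))) mask
             else resample_mask(mask, vol$spacing, spacing)
  }
  fr <- lung_fraction_per_slice(rmask)
  retained <- filter_slices(rvol, rmask, min_fraction)
  cropped <- crop_roi(rvol, rmask, retained)
  stack <- resize_and_normalize(cropped, out_size, hu_window)
  list(stack = stack, retained = retained, fractions = fr,
       bbox = attr(cropped, "bbox"), spacing = spacing)
}
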