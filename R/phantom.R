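# Desk-scale thoracic phantom simulator with linked discrete-time survival.
#
# The phantom is a stated world, not an anatomical model: a soft-tissue body
# ellipsoid in an air background, two lung ellipsoids whose in-plane cross
# section tapers toward the apex and widens toward the base (so a slice's
# appearance carries usable depth information, as real thoracic anatomy
# does), and an optional spherical lesion whose realized volume and relative
# axial depth drive a constant per-month hazard through a logistic link.

#' Phantom geometry configuration
#'
#' @param grid Voxel grid `(nx, ny, nz)`; every axis at least 32.
#' @param spacing Voxel spacing in mm; default `c(1, 1, 3)`.
#' @param air_hu,lung_hu,body_hu,lesion_hu Intensity levels (HU). Must obey
#'   `air_hu < lung_hu < body_hu`; the default lesion contrast is +60 HU
#'   above lung parenchyma so that threshold segmentation keeps lesion
#'   voxels inside the lung mask.
#' @param lesion_present Whether to place a lesion.
#' @param lesion_radius_mm Lesion sphere radius (mm).
#' @param lesion_relative_depth Axial lesion position in `[0, 1]` relative
#'   to the lung extent (0 = apex, 1 = base).
#' @param lesion_side `"left"` or `"right"` lung.
#' @param noise_sd Gaussian intensity noise (HU); 0 disables.
#' @param shape_jitter Relative jitter applied to body/lung semi-axes per
#'   phantom (uniform in plus/minus this fraction).
#' @param seed Seed for noise and jitter.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid = c(96L, 96L, 44L), spacing = c(1, 1, 3),
                           air_hu = -1000, lung_hu = -800, body_hu = 40,
                           lesion_hu = -740, lesion_present = TRUE,
                           lesion_radius_mm = 6,
                           lesion_relative_depth = 0.5,
                           lesion_side = c("left", "right"),
                           noise_sd = 15, shape_jitter = 0.04, seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 32L))
    stopf("grid must be three integers, each at least 32")
  if (!(air_hu < lung_hu && lung_hu < body_hu))
    stopf("need air_hu < lung_hu < body_hu")
  if (lesion_relative_depth < 0 || lesion_relative_depth > 1)
    stopf("lesion_relative_depth must lie in [0, 1]")
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 air_hu = air_hu, lung_hu = lung_hu, body_hu = body_hu,
                 lesion_hu = lesion_hu, lesion_present = lesion_present,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_relative_depth = lesion_relative_depth,
                 lesion_side = match.arg(lesion_side),
                 noise_sd = noise_sd, shape_jitter = shape_jitter,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a thoracic phantom volume
#'
#' Builds the phantom described by `cfg` and returns the volume, the
#' ground-truth lung mask (lungs plus any lesion voxels inside them) and
#' the exact set of axial slices intersecting the lesion. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @param patient_id Identifier for the returned volume.
#' @return List with `volume` ([ct_volume()]), `mask` ([lung_mask()]),
#'   `lesion_slices` (integer vector, empty without a lesion) and
#'   `lesion_volume_cm3` (realized lesion volume after clipping to the
#'   lung interior).
#' @export
generate_phantom <- function(cfg = phantom_config(), patient_id = "phantom") {
  g <- cfg$grid; sp <- cfg$spacing
  ext <- g * sp
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] / 2
  with_seed(cfg$seed, {
    jit <- function() 1 + stats::runif(1, -cfg$shape_jitter, cfg$shape_jitter)
    # semi-axes chosen so the lungs stay strictly inside the body at every
    # 3 mm axial step even under worst-case shape jitter (no air leak from
    # the lung interior to the background, which would break the
    # border-connected-component rule of the segmenter)
    body_ax <- c(0.44 * ext[1] * jit(), 0.38 * ext[2] * jit(),
                 0.48 * ext[3] * jit())
    lung_ax <- c(0.12 * ext[1] * jit(), 0.24 * ext[2] * jit(),
                 0.33 * ext[3] * jit())
    lung_cx <- c(left = cx - 0.18 * ext[1], right = cx + 0.18 * ext[1])
    taper <- 0.25                         # base wider than apex
    xs <- (seq_len(g[1]) - 0.5) * sp[1]
    ys <- (seq_len(g[2]) - 0.5) * sp[2]
    zs <- (seq_len(g[3]) - 0.5) * sp[3]
    vox <- array(cfg$air_hu, dim = g)
    mask <- array(FALSE, dim = g)
    # axial index 1 is most superior: map z index -> superior..inferior
    # (z grows toward the base)
    dx2b <- outer(((xs - cx) / body_ax[1])^2,
                  ((ys - cy) / body_ax[2])^2, "+")
    for (iz in seq_len(g[3])) {
      znb <- (zs[iz] - cz) / body_ax[3]
      body <- dx2b + znb^2 <= 1
      sl <- matrix(cfg$air_hu, g[1], g[2])
      sl[body] <- cfg$body_hu
      znl <- (zs[iz] - cz) / lung_ax[3]
      if (abs(znl) < 1) {
        f <- max(1 + taper * znl, 0.3)
        msl <- matrix(FALSE, g[1], g[2])
        for (side in c("left", "right")) {
          d2 <- outer(((xs - lung_cx[side]) / (lung_ax[1] * f))^2,
                      ((ys - cy) / (lung_ax[2] * f))^2, "+")
          inl <- d2 + znl^2 <= 1
          sl[inl] <- cfg$lung_hu
          msl <- msl | inl
        }
        mask[, , iz] <- msl
      }
      vox[, , iz] <- sl
    }
    lesion_slices <- integer(0)
    lesion_volume_cm3 <- 0
    if (cfg$lesion_present) {
      d <- cfg$lesion_relative_depth
      lz <- cz + (2 * d - 1) * lung_ax[3]
      lcx <- lung_cx[cfg$lesion_side]
      # lesion centre must lie strictly inside the lung
      znl <- 2 * d - 1
      f <- max(1 + taper * znl, 0.3)
      if (abs(znl) >= 1)
        stopf("lesion depth %.2f places its centre outside the lung", d)
      r <- cfg$lesion_radius_mm
      zrange <- which(abs(zs - lz) <= r)
      for (iz in zrange) {
        rz2 <- r^2 - (zs[iz] - lz)^2
        if (rz2 <= 0) next
        d2 <- outer((xs - lcx)^2, (ys - cy)^2, "+")
        inles <- d2 <= rz2
        inles <- inles & mask[, , iz]     # clip to lung interior
        if (any(inles)) {
          sl <- vox[, , iz]
          sl[inles] <- cfg$lesion_hu
          vox[, , iz] <- sl
          lesion_slices <- c(lesion_slices, iz)
          lesion_volume_cm3 <- lesion_volume_cm3 +
            sum(inles) * prod(sp) / 1000
        }
      }
      if (!length(lesion_slices))
        stopf("lesion at depth %.2f, radius %.1f mm falls outside the lungs",
              d, r)
    }
    if (cfg$noise_sd > 0)
      vox <- vox + array(stats::rnorm(length(vox), sd = cfg$noise_sd),
                         dim = g)
    list(volume = ct_volume(vox, sp, patient_id = patient_id),
         mask = lung_mask(mask),
         lesion_slices = lesion_slices,
         lesion_volume_cm3 = lesion_volume_cm3)
  })
}

#' Hazard-model configuration for the synthetic cohort
#'
#' Each patient gets a constant per-month hazard
#' `h = plogis(beta0 + beta_size * lesion_volume_cm3 + beta_depth * depth)`
#' over a `t_max = 24` month horizon, with independent uniform censoring.
#' The default coefficients were calibrated once so that ranking patients
#' by their true hazard attains a time-dependent concordance of about 0.75
#' (the generator's discrimination ceiling) with roughly half the cohort
#' experiencing the event.
#'
#' @param beta0 Baseline log-odds of the monthly hazard.
#' @param beta_size Effect per cm^3 of lesion volume.
#' @param beta_depth Effect of relative lesion depth (basal lesions carry
#'   higher hazard).
#' @param censor_rate Probability of an independent uniform censoring time.
#' @param t_max Horizon in months; default 24.
#' @param lesion_prob Probability a patient carries a lesion.
#' @param radius_range Lesion radius range (mm), drawn uniformly.
#' @param depth_range Relative depth range within the lungs.
#' @param depth_shape `c(a, b)` of the Beta draw for depth inside
#'   `depth_range`; the default skews lesions basally.
#' @return A `hazard_config` list.
#' @export
hazard_config <- function(beta0 = -5.0, beta_size = 0.8, beta_depth = 1.2,
                          censor_rate = 0.3, t_max = 24L,
                          lesion_prob = 0.8, radius_range = c(4, 9),
                          depth_range = c(0.15, 0.85),
                          depth_shape = c(2, 1.2)) {
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  structure(list(beta0 = beta0, beta_size = beta_size,
                 beta_depth = beta_depth, censor_rate = censor_rate,
                 t_max = as.integer(t_max), lesion_prob = lesion_prob,
                 radius_range = radius_range, depth_range = depth_range,
                 depth_shape = depth_shape),
            class = "hazard_config")
}

#' Sample one survival record from a monthly hazard sequence
#'
#' The event month is the first Bernoulli success over `h_1..h_t_max`; an
#' independent censoring month, uniform on `1..t_max`, applies with
#' probability `censor_rate`. When censoring strikes first, or no event
#' occurs by the horizon, the record is censored (`k = 0`) at the earlier
#' of censoring time and `t_max`.
#'
#' @param h Per-month hazard: scalar (constant hazard) or length-`t_max`
#'   vector of probabilities.
#' @param censor_rate Censoring probability.
#' @param t_max Horizon in months.
#' @return List with integer `s` and `k`.
#' @export
sample_survival_record <- function(h, censor_rate = 0.3, t_max = 24L) {
  if (length(h) == 1L) h <- rep(h, t_max)
  if (length(h) != t_max || any(h < 0) || any(h > 1))
    stopf("h must be %d probabilities in [0, 1]", t_max)
  draws <- stats::runif(t_max) < h
  event <- if (any(draws)) which(draws)[1L] else Inf
  censor <- if (stats::runif(1) < censor_rate)
    sample.int(t_max, 1L) else Inf
  if (event <= censor && event <= t_max) {
    list(s = as.integer(event), k = 1L)
  } else {
    list(s = as.integer(min(censor, t_max)), k = 0L)
  }
}

#' Generate a synthetic phantom cohort
#'
#' Per patient: lesion presence, radius and depth are drawn from the hazard
#' configuration's distributions, a phantom volume is built, the full
#' preprocessing pipeline runs (resampling, rule-based lung segmentation,
#' slice filtering, cropping, resizing) and a survival record is sampled
#' from the patient's true hazard. Fully reproducible from `seed`.
#'
#' @param n Number of patients (at least 2).
#' @param phantom Template [phantom_config()]; lesion fields and seed are
#'   overridden per patient.
#' @param hazard A [hazard_config()].
#' @param seed Cohort seed; every per-patient stream derives from it.
#' @param keep What to retain per patient: `"features"` (default;
#'   block-pooled slice features ready for the encoder, memory-light),
#'   `"stack"` (adds the full [slice_stack()]) or `"none"` (records and
#'   ground truth only, no imaging — used for large statistical checks of
#'   the survival sampler).
#' @param encoder [encoder_config()] whose pooling grid is used for
#'   `keep = "features"`.
#' @param out_size Slice size for preprocessing; default 224.
#' @return An `attnsurv_cohort`: list of `patients` (each with
#'   `patient_id`, `s`, `k`, `truth`, and per-`keep` imaging payload),
#'   plus the configurations and seed.
#' @export
generate_cohort <- function(n, phantom = phantom_config(),
                            hazard = hazard_config(), seed = 11L,
                            keep = c("features", "stack", "none"),
                            encoder = encoder_config(), out_size = 224L) {
  keep <- match.arg(keep)
  if (n < 2L) stopf("a cohort needs at least 2 patients")
  draws <- with_seed(derive_seed(seed, "covariates"), {
    list(pres = stats::runif(n) < hazard$lesion_prob,
         radius = stats::runif(n, hazard$radius_range[1],
                               hazard$radius_range[2]),
         depth = hazard$depth_range[1] +
           diff(hazard$depth_range) *
             stats::rbeta(n, hazard$depth_shape[1], hazard$depth_shape[2]),
         side = ifelse(stats::runif(n) < 0.5, "left", "right"))
  })
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    pcfg <- phantom
    pcfg$lesion_present <- draws$pres[i]
    pcfg$lesion_radius_mm <- draws$radius[i]
    pcfg$lesion_relative_depth <- draws$depth[i]
    pcfg$lesion_side <- draws$side[i]
    pcfg$seed <- derive_seed(seed, paste0("phantom-", i))
    vol_cm3 <- 0; depth_i <- 0
    payload <- list()
    if (keep == "none") {
      # covariates without imaging: the unclipped sphere volume is a good
      # stand-in only when the sphere fits; reproduce the clipped volume
      # cheaply by building the phantom without noise? No: statistical
      # checks at keep="none" need only the hazard structure, so use the
      # analytic sphere volume.
      if (draws$pres[i]) {
        vol_cm3 <- 4 / 3 * pi * draws$radius[i]^3 / 1000
        depth_i <- draws$depth[i]
      }
    } else {
      ph <- generate_phantom(pcfg, patient_id = pid)
      if (draws$pres[i]) {
        vol_cm3 <- ph$lesion_volume_cm3
        depth_i <- draws$depth[i]
      }
      pre <- preprocess_volume(ph$volume, out_size = out_size)
      payload$relative_positions <- pre$stack$relative_positions
      payload$source_indices <- pre$stack$source_indices
      payload$lesion_slices <- ph$lesion_slices
      payload$pooled <- encoder_pool(pre$stack, encoder)
      if (keep == "stack") payload$stack <- pre$stack
    }
    h <- plogis(hazard$beta0 + hazard$beta_size * vol_cm3 +
                  hazard$beta_depth * depth_i)
    rec <- with_seed(derive_seed(seed, paste0("survival-", i)),
                     sample_survival_record(h, hazard$censor_rate,
                                            hazard$t_max))
    patients[[i]] <- c(
      list(patient_id = pid, s = rec$s, k = rec$k,
           truth = list(lesion_present = draws$pres[i],
                        radius_mm = draws$radius[i],
                        depth = depth_i, lesion_volume_cm3 = vol_cm3,
                        hazard = h)),
      payload)
  }
  structure(list(patients = patients, phantom = phantom, hazard = hazard,
                 seed = as.integer(seed), keep = keep,
                 encoder = encoder),
            class = "attnsurv_cohort")
}

#' @export
print.attnsurv_cohort <- function(x, ...) {
  rec <- cohort_records(x)
  cat(sprintf("<attnsurv_cohort: %d patients, %.0f%% events, seed %d, keep=%s>\n",
              nrow(rec), 100 * mean(rec$k), x$seed, x$keep))
  invisible(x)
}

#' Resample a cohort's survival records under a different hazard law
#'
#' Keeps every patient's imaging payload and lesion covariates and redraws
#' only the hazard and the survival record under `hazard`. Useful for
#' matched-world controls (e.g. a no-signal cohort with the lesion effects
#' zeroed) without regenerating the phantom volumes.
#'
#' @param cohort An `attnsurv_cohort`.
#' @param hazard A [hazard_config()].
#' @param seed Seed for the redrawn records; defaults to the cohort seed.
#' @return The cohort with updated `truth$hazard`, `s`, `k` and hazard
#'   configuration.
#' @export
resample_cohort_records <- function(cohort, hazard, seed = cohort$seed) {
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    h <- plogis(hazard$beta0 +
                  hazard$beta_size * p$truth$lesion_volume_cm3 +
                  hazard$beta_depth * p$truth$depth)
    rec <- with_seed(derive_seed(seed, paste0("resurvival-", i)),
                     sample_survival_record(h, hazard$censor_rate,
                                            hazard$t_max))
    p$truth$hazard <- h
    p$s <- rec$s
    p$k <- rec$k
    cohort$patients[[i]] <- p
  }
  cohort$hazard <- hazard
  cohort
}

#' Extract the survival records of a cohort
#'
#' @param cohort An `attnsurv_cohort`.
#' @return A [survival_records()] data frame aligned with the patients.
#' @export
cohort_records <- function(cohort) {
  survival_records(vapply(cohort$patients, `[[`, integer(1), "s"),
                   vapply(cohort$patients, `[[`, integer(1), "k"),
                   t_max = cohort$hazard$t_max)
}
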