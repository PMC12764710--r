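# Phantom geometry and the linked discrete-time survival generator.

test_that("generate_phantom places tissue, lungs and lesion as configured", {
  cfg <- small_phantom(seed = 2, lesion_relative_depth = 0.5)
  ph <- generate_phantom(cfg)
  v <- ph$volume$voxels
  # intensity modes at the configured levels
  expect_true(sum(abs(v - cfg$air_hu) < 1) > 0.2 * length(v))
  expect_true(sum(abs(v - cfg$body_hu) < 1) > 0.05 * length(v))
  expect_true(sum(abs(v - cfg$lung_hu) < 1) > 0.01 * length(v))
  # lesion slices sit around the configured depth
  nz <- dim(v)[3]
  expect_true(all(ph$lesion_slices >= nz * 0.3 &
                    ph$lesion_slices <= nz * 0.7))
  expect_gt(ph$lesion_volume_cm3, 0)

  none <- generate_phantom(small_phantom(seed = 2, lesion_present = FALSE))
  expect_length(none$lesion_slices, 0)
  expect_equal(none$lesion_volume_cm3, 0)

  # determinism under a fixed seed
  ph2 <- generate_phantom(cfg)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)

  expect_error(generate_phantom(small_phantom(lesion_relative_depth = 1)),
               "outside the lung|centre outside")
  expect_error(phantom_config(grid = c(16, 16, 16)), "at least 32")
  expect_error(phantom_config(air_hu = 0, lung_hu = -800), "air_hu <")
})

test_that("sample_survival_record covers the degenerate hazards", {
  set.seed(1)
  r1 <- sample_survival_record(rep(1, 24), censor_rate = 0)
  expect_equal(r1, list(s = 1L, k = 1L))
  r0 <- sample_survival_record(rep(0, 24), censor_rate = 0)
  expect_equal(r0, list(s = 24L, k = 0L))
  expect_error(sample_survival_record(rep(2, 24)), "probabilities")
})

test_that("event times under constant hazard follow a truncated geometric", {
  set.seed(99)
  h <- 0.1
  n <- 10000
  draws <- replicate(n, sample_survival_record(h, censor_rate = 0)$s)
  events <- replicate(n, sample_survival_record(h, censor_rate = 0)$k)
  # closed-form: P(s = m, event) = h (1-h)^(m-1); censored at 24 otherwise
  obs <- table(factor(draws, levels = 1:24))
  pmf <- h * (1 - h)^(0:22)
  p24 <- h * (1 - h)^23 + (1 - h)^24     # event at 24 or survived past it
  expected <- c(pmf, p24) * n
  chi <- sum((as.vector(obs) - expected)^2 / expected)
  expect_lt(chi, qchisq(0.99, df = 23))
})

test_that("generate_cohort is reproducible and honours its effects", {
  co1 <- generate_cohort(30, seed = 21, keep = "none")
  co2 <- generate_cohort(30, seed = 21, keep = "none")
  expect_identical(co1$patients, co2$patients)

  # beta_size > 0: larger lesions die stochastically earlier
  co <- generate_cohort(500, hazard = hazard_config(censor_rate = 0),
                        seed = 31, keep = "none")
  s <- vapply(co$patients, `[[`, integer(1), "s")
  vol <- vapply(co$patients, function(p) p$truth$lesion_volume_cm3,
                numeric(1))
  ct <- cor.test(vol, s, method = "spearman", alternative = "less",
                 exact = FALSE)
  expect_lt(ct$p.value, 0.01)

  # zero effects: event times independent of the lesion covariates
  co0 <- generate_cohort(500, hazard = hazard_config(beta_size = 0,
                                                     beta_depth = 0,
                                                     censor_rate = 0),
                         seed = 32, keep = "none")
  s0 <- vapply(co0$patients, `[[`, integer(1), "s")
  v0 <- vapply(co0$patients, function(p) p$truth$lesion_volume_cm3,
               numeric(1))
  expect_lt(abs(cor(v0, s0, method = "spearman")), 0.1)
})

test_that("resample_cohort_records keeps imaging and redraws outcomes", {
  co <- generate_cohort(20, seed = 81, keep = "none")
  co0 <- resample_cohort_records(co, hazard_config(beta0 = -3.4,
                                                   beta_size = 0,
                                                   beta_depth = 0))
  h0 <- vapply(co0$patients, function(p) p$truth$hazard, numeric(1))
  expect_true(all(abs(h0 - plogis(-3.4)) < 1e-12))
  # covariates untouched
  expect_identical(
    vapply(co$patients, function(p) p$truth$lesion_volume_cm3, numeric(1)),
    vapply(co0$patients, function(p) p$truth$lesion_volume_cm3, numeric(1)))
  # reproducible
  co0b <- resample_cohort_records(co, co0$hazard)
  expect_identical(vapply(co0$patients, `[[`, integer(1), "s"),
                   vapply(co0b$patients, `[[`, integer(1), "s"))
})

test_that("realized censoring fraction matches the generator's own law", {
  # Under the sampling rule, k = 1 iff the event strikes by the horizon and
  # not after the censoring clock:
  #   P(k=1) = (1-cr) P(E<=24) + cr sum_e P(E=e) P(C>=e),  C ~ U{1..24}.
  # The realized censored fraction therefore exceeds censor_rate by the
  # administrative-truncation mass at 24 months; the test checks the
  # generator against this closed form within 5 percentage points.
  co <- generate_cohort(1000, seed = 41, keep = "none")
  rec <- cohort_records(co)
  h <- vapply(co$patients, function(p) p$truth$hazard, numeric(1))
  cr <- co$hazard$censor_rate
  p_event <- vapply(h, function(hh) {
    pe <- hh * (1 - hh)^(0:23)
    (1 - cr) * sum(pe) + cr * sum(pe * (24 - (1:24) + 1) / 24)
  }, numeric(1))
  expect_lt(abs(mean(rec$k == 0L) - (1 - mean(p_event))), 0.05)
  # the independent clock itself fires at the configured rate
  expect_lt(abs(mean(rec$k == 0L & rec$s < 24L) -
                  mean(vapply(h, function(hh) {
                    pe <- hh * (1 - hh)^(0:23)
                    cr * sum((1 - cumsum(pe))[1:23] / 24)
                  }, numeric(1)))), 0.05)
})

test_that("ground-truth masks survive the preprocessing pipeline", {
  for (seed in c(51, 52)) {
    cfg <- small_phantom(seed = seed, lesion_relative_depth = 0.6,
                         noise_sd = 15)
    ph <- generate_phantom(cfg)
    pre <- preprocess_volume(ph$volume, out_size = 64L)
    expect_gte(mean(ph$lesion_slices %in% pre$retained), 0.95)
  }
})

test_that("survival sampling is consistent with the discrete likelihood", {
  # L1 at the true per-patient hazard distributions should approach the
  # entropy rate of the generator (uncensored world, horizon-free check)
  set.seed(61)
  n <- 400
  h <- runif(n, 0.05, 0.3)
  recs <- survival_records(
    vapply(h, function(hh) sample_survival_record(hh, censor_rate = 0)$s,
           integer(1)),
    rep(1L, n))
  y <- t(sapply(h, function(hh) {
    p <- hh * (1 - hh)^(0:23)
    p[24] <- p[24] + (1 - hh)^24          # fold tail mass into bin 24
    p
  }))
  # expected negative log-likelihood per patient under the truth
  nll <- loss_l1(y, recs) / n
  ent <- mean(vapply(h, function(hh) {
    p <- hh * (1 - hh)^(0:23); p[24] <- p[24] + (1 - hh)^24
    -sum(p * log(p))
  }, numeric(1)))
  expect_lt(abs(nll - ent), 0.15)
})
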