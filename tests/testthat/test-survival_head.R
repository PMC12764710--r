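# Risk network, CIF and the two-term loss.

test_that("forward_risk obeys the softmax output contract", {
  pars <- risk_params(8L, risk_config(), seed = 1)
  set.seed(2)
  x <- matrix(rnorm(5 * 8), 5, 8)
  y <- forward_risk(x, pars)
  expect_equal(dim(y), c(5L, 24L))
  expect_true(all(y >= 0))
  expect_equal(rowSums(y), rep(1, 5), tolerance = 1e-6)
  expect_identical(y, forward_risk(x, pars))   # no dropout in evaluation

  # zero output layer: uniform distribution over the 24 bins
  pars0 <- pars
  pars0$out$W[] <- 0; pars0$out$b[] <- 0
  expect_equal(as.vector(forward_risk(x[1, ], pars0)),
               rep(1 / 24, 24), tolerance = 1e-12)

  expect_error(forward_risk(rep(NA_real_, 8), pars), "non-finite")
  expect_error(forward_risk(rep(0, 5), pars), "dimension")
})

test_that("estimated_cif is the cumulative sum with F(0) = 0", {
  yu <- rep(1 / 24, 24)
  expect_equal(estimated_cif(yu, 12), 0.5)
  expect_equal(estimated_cif(yu, 0), 0)
  one <- rep(0, 24); one[5] <- 1
  expect_equal(estimated_cif(one, 4), 0)
  expect_equal(estimated_cif(one, 5), 1)
  set.seed(3)
  y <- as.vector(rand_y(1, seed = 3))
  cif <- estimated_cif(y, 0:24)
  expect_equal(cif, c(0, cumsum(y)))           # cumulative-sum oracle
  expect_true(all(diff(cif) >= 0))
  expect_equal(cif[25], 1, tolerance = 1e-12)
  expect_error(estimated_cif(y, 25), "0..24")
})

test_that("loss_l1 reproduces hand-computed values", {
  y <- matrix(1 / 24, 1, 24)
  y[1, ] <- 0; y[1, 3] <- 0.25; y[1, 10] <- 0.75
  expect_equal(loss_l1(y, survival_records(3, 1)), -log(0.25),
               tolerance = 1e-10)

  # censored at 3 with F(3) = 0.4
  y2 <- matrix(0, 1, 24); y2[1, 2] <- 0.4; y2[1, 20] <- 0.6
  expect_equal(loss_l1(y2, survival_records(3, 0)), -log(0.6),
               tolerance = 1e-10)

  # perfect prediction: zero loss
  y3 <- matrix(0, 1, 24); y3[1, 7] <- 1
  expect_equal(loss_l1(y3, survival_records(7, 1)), 0)

  expect_error(loss_l1(y, survival_records(25, 1)), NA) # remaps to censored 24
  expect_error(check_batch <- loss_l1(y, data.frame(s = 30L, k = 1L)),
               "outside")
})

test_that("loss_l2 reproduces the exponential ranking kernel", {
  # pair with equal CIFs at s_i: eta = exp(0) = 1
  y <- rbind(rand_y(1, seed = 4), rand_y(1, seed = 4))
  rec <- survival_records(c(3, 9), c(1, 0))
  expect_equal(loss_l2(y, rec), 1, tolerance = 1e-12)

  # CIF difference 0.1 at sigma 0.1: eta = exp(-1)
  y2 <- matrix(0, 2, 24)
  y2[1, 2] <- 0.5; y2[1, 20] <- 0.5     # F_1(2) = 0.5
  y2[2, 2] <- 0.4; y2[2, 20] <- 0.6     # F_2(2) = 0.4
  rec2 <- survival_records(c(2, 10), c(1, 1))
  expect_equal(loss_l2(y2, rec2), exp(-1), tolerance = 1e-10)

  # single patient: no pairs
  expect_equal(loss_l2(rand_y(1), survival_records(5, 1)), 0)

  # sum mode restores the plain sum over pairs
  y3 <- rand_y(3, seed = 5)
  rec3 <- survival_records(c(2, 5, 9), c(1, 1, 0))
  cfg_mean <- loss_config()
  cfg_sum <- loss_config(l2_normalize = "sum")
  np <- nrow(acceptable_pairs(rec3))
  expect_equal(loss_l2(y3, rec3, cfg_sum),
               np * loss_l2(y3, rec3, cfg_mean), tolerance = 1e-12)

  # duplicating the batch leaves the mean-normalized loss unchanged
  y6 <- rbind(y3, y3)
  rec6 <- survival_records(rep(rec3$s, 2), rep(rec3$k, 2))
  # duplicated batches add cross-copy pairs with the same eta values
  expect_equal(loss_l2(y6, rec6, cfg_mean), loss_l2(y3, rec3, cfg_mean),
               tolerance = 1e-12)
})

test_that("total_loss is the weighted sum of its terms", {
  y <- rand_y(4, seed = 6)
  rec <- rand_records(4, seed = 7)
  expect_equal(total_loss(y, rec, loss_config(alpha = 1, beta = 0)),
               loss_l1(y, rec), tolerance = 1e-12)
  expect_equal(total_loss(y, rec, loss_config(alpha = 0, beta = 1)),
               loss_l2(y, rec), tolerance = 1e-12)
  # worked single-patient cases at alpha = 0.5, beta = 0
  y1 <- matrix(0, 1, 24); y1[1, 3] <- 0.25; y1[1, 10] <- 0.75
  expect_equal(total_loss(y1, survival_records(3, 1),
                          loss_config(alpha = 0.5, beta = 0)),
               -log(0.25) / 2, tolerance = 1e-10)
})

test_that("likelihood monotonicity: mass on the true bin lowers L1", {
  rec <- survival_records(8, 1)
  l1 <- function(p) {
    y <- matrix((1 - p) / 23, 1, 24); y[1, 8] <- p
    loss_l1(y, rec)
  }
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(ps, l1, numeric(1))) < 0))

  # censored: moving mass beyond s never increases L1
  recc <- survival_records(8, 0)
  base <- matrix(1 / 24, 1, 24)
  shifted <- base
  shifted[1, 3] <- shifted[1, 3] - 0.02
  shifted[1, 20] <- shifted[1, 20] + 0.02
  expect_lte(loss_l1(shifted, recc), loss_l1(base, recc))
})

test_that("direct optimization drives L1 to the perfect-likelihood floor", {
  set.seed(8)
  rec <- survival_records(sample.int(20, 20, replace = TRUE),
                          rbinom(20, 1, 0.7))
  # free per-patient logits, optimized directly (no encoder)
  obj <- function(theta) {
    y <- softmax_rows_free(matrix(theta, 20, 24))
    loss_l1(y, rec)
  }
  softmax_rows_free <- function(o) {
    z <- exp(o - apply(o, 1, max)); z / rowSums(z)
  }
  opt <- optim(rep(0, 20 * 24), obj, method = "BFGS",
               control = list(maxit = 200))
  # empirical entropy of the observed time distribution (the floor for a
  # shared marginal predictor); per-patient free parameters must beat it
  tab <- table(factor(rec$s, levels = 1:24))
  p <- as.vector(tab / sum(tab))
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  expect_lt(opt$value / 20, entropy)
})

test_that("analytic gradients match numerical differentiation", {
  m <- attnsurv_model(seed = 3)
  batch <- toy_batch(c(3L, 4L, 2L), seed = 9)
  rec <- survival_records(c(5, 23, 24), c(1, 1, 0))
  set.seed(10)
  gc <- gradient_check(m, batch, rec, n_checks = 50)
  expect_lt(gc$max_rel_err, 1e-4)

  m2 <- attnsurv_model(aggregator = "average", seed = 4)
  set.seed(11)
  expect_lt(gradient_check(m2, batch, rec, n_checks = 30)$max_rel_err, 1e-4)

  m3 <- attnsurv_model(encoder = encoder_config(freeze_strategy =
                                                  "half_frozen"), seed = 5)
  set.seed(12)
  expect_lt(gradient_check(m3, batch, rec, n_checks = 30)$max_rel_err, 1e-4)
})
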