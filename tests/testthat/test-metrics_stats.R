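# Concordance, permutation comparison, exact Wilcoxon, effect size.

test_that("acceptable_pairs matches its definition and a brute force", {
  rec <- survival_records(c(2, 4), c(1, 0))
  expect_equal(acceptable_pairs(rec), cbind(i = 1L, j = 2L))
  expect_equal(nrow(acceptable_pairs(survival_records(c(3, 5, 9),
                                                      c(0, 0, 0)))), 0L)
  set.seed(1)
  for (rep in 1:10) {
    rec <- rand_records(5, seed = rep)
    got <- acceptable_pairs(rec)
    want <- NULL
    for (i in 1:5) for (j in 1:5)
      if (i != j && rec$k[i] == 1L && rec$s[i] < rec$s[j])
        want <- rbind(want, c(i, j))
    expect_equal(nrow(got), NROW(want))
    if (NROW(want))
      expect_setequal(paste(got[, 1], got[, 2]),
                      paste(want[, 1], want[, 2]))
  }
})

test_that("ctd_index: perfect, inverted, and hand-enumerated cases", {
  rec <- survival_records(c(2, 5, 7), c(1, 1, 1))
  # perfectly ordered CIFs: earlier death = higher CIF at every horizon
  risk <- c(0.9, 0.5, 0.2)
  y <- t(sapply(risk, function(r) { p <- rep((1 - r) / 23, 24); p[1] <- r; p }))
  expect_equal(ctd_index(y, rec), 1)
  expect_equal(ctd_index(y[3:1, ], survival_records(c(7, 5, 2), c(1, 1, 1))),
               1)  # reordering invariance
  yr <- y[c(3, 2, 1), ]                   # reversed assignment
  expect_equal(ctd_index(yr, rec), 0)

  # hand enumeration: F_A(2)=0.9, F_B(2)=0.3, F_C(2)=0.2, F_B(5)=0.4,
  # F_C(5)=0.6 -> pairs (A,B): 0.9>0.3 ok; (A,C): 0.9>0.2 ok; (B,C):
  # 0.4>0.6 wrong -> 2/3
  y3 <- matrix(0, 3, 24)
  y3[1, 1] <- 0.5; y3[1, 2] <- 0.4; y3[1, 24] <- 0.1       # F_A(2)=0.9
  y3[2, 2] <- 0.3; y3[2, 5] <- 0.1; y3[2, 24] <- 0.6       # F_B(2)=.3,F_B(5)=.4
  y3[3, 2] <- 0.2; y3[3, 5] <- 0.4; y3[3, 24] <- 0.4       # F_C(2)=.2,F_C(5)=.6
  expect_equal(ctd_index(y3, rec), 2 / 3, tolerance = 1e-12)

  expect_error(ctd_index(rand_y(3), survival_records(c(3, 3, 3), c(0, 0, 0))),
               "no acceptable pairs")
})

test_that("ctd_index equals the O(N^2) brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    rec <- rand_records(n, seed = 100 + rep)
    if (!nrow(acceptable_pairs(rec))) next
    y <- rand_y(n, seed = 200 + rep)
    expect_equal(ctd_index(y, rec), brute_ctd(y, rec), tolerance = 1e-12)
    expect_equal(ctd_index(y, rec, ties = "half"),
                 brute_ctd(y, rec, ties = "half"), tolerance = 1e-12)
  }
})

test_that("risk-complement concordances sum to one without ties", {
  # ranking by 1 - F reverses every strict comparison, so the two
  # concordances partition the acceptable pairs when no CIF ties occur
  n <- 20
  rec <- rand_records(n, seed = 7)
  y <- rand_y(n, seed = 8)        # continuous draws: ties have measure zero
  a <- ctd_index(y, rec)
  pairs <- acceptable_pairs(rec)
  cif <- cbind(0, t(apply(y, 1, cumsum)))
  si <- rec$s[pairs[, 1]]
  fi <- cif[cbind(pairs[, 1], si + 1L)]
  fj <- cif[cbind(pairs[, 2], si + 1L)]
  expect_equal(sum(fi == fj), 0L)
  b <- sum(fi < fj) / nrow(pairs) # concordance of the complemented risk
  expect_equal(a + b, 1, tolerance = 1e-12)
})

test_that("permutation_paired_test: degenerate, guarded and calibrated", {
  n <- 25
  rec <- rand_records(n, seed = 3)
  ya <- rand_y(n, seed = 4)
  pa <- model_predictions(ya, rec)
  pb <- model_predictions(ya, rec)
  set.seed(1)
  res <- permutation_paired_test(pa, pb, n_perm = 200)
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_value, 1)
  expect_error(permutation_paired_test(pa, pb, n_perm = 0), "at least 1")
  yb <- rand_y(n, seed = 5)
  pb2 <- model_predictions(yb, rand_records(n, seed = 99))
  expect_error(permutation_paired_test(pa, pb2), "same patients")
})

test_that("permutation p agrees with a high-repetition reference run", {
  n <- 30
  rec <- rand_records(n, seed = 11)
  ya <- rand_y(n, seed = 12)
  yb <- 0.7 * ya + 0.3 * rand_y(n, seed = 13)
  pa <- model_predictions(ya, rec)
  pb <- model_predictions(yb, rec)
  set.seed(2)
  p1 <- permutation_paired_test(pa, pb, n_perm = 2000)$p_value
  set.seed(3)
  p_ref <- permutation_paired_test(pa, pb, n_perm = 30000)$p_value
  expect_lt(abs(p1 - p_ref), 0.02)
})

test_that("wilcoxon_exact reproduces known and brute-force values", {
  # six one-signed differences: statistic 0, exact two-sided p = 0.03125
  w <- wilcoxon_exact(c(0.01, 0.05, 0.02, 0.08, 0.03, 0.04))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.03125, tolerance = 1e-12)

  # a single nonzero difference: p = 1 (2 equiprobable outcomes)
  w1 <- wilcoxon_exact(0.4)
  expect_equal(w1$statistic, 0)
  expect_equal(w1$p_value, 1)

  # mixed signs vs the exhaustive 2^n oracle
  for (d in list(c(1, -2, 3, -4, 5, -6),
                 c(0.3, 0.1, -0.2, 0.5, -0.4),
                 c(2, 2, -1, 3, -3, 1, 4))) {       # ties in |d|
    expect_equal(wilcoxon_exact(d)$p_value, brute_wilcoxon_p(d),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_exact(c(0, 0)), "undefined")
  # matches the exact null CDF for n = 6 at every attainable value
  null6 <- attnsurv:::signed_rank_null(2 * (1:6))
  expect_equal(sum(null6$prob), 1, tolerance = 1e-12)
  expect_equal(null6$prob[null6$support2 == 0], 1 / 64)
  probs <- vapply(0:21, function(v)
    sum(null6$prob[null6$support2 == 2 * v]), numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(probs[1 + 21], 1 / 64)     # all-positive assignment
  expect_equal(probs[1 + 1], 1 / 64)      # V = 1 reachable one way
})

test_that("effect_size_r matches the printed and hand-derived values", {
  expect_equal(round(effect_size_r(0, 6), 3), 0.899)
  expect_equal(effect_size_r(6 * 7 / 4, 6), 0)
  expect_equal(effect_size_r(1, 6),
               ((10.5 - 1) / sqrt(6 * 7 * 13 / 24)) / sqrt(6),
               tolerance = 1e-12)
})
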