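# Shared fixtures, all built in code at test time.

# A small slice stack with constant-valued slices (values in [0, 1]).
const_stack <- function(values, size = 32L) {
  R <- length(values)
  slice_stack(lapply(values, function(v) matrix(v, size, size)),
              if (R == 1L) 0 else (seq_len(R) - 1) / (R - 1),
              seq_len(R))
}

# Random slice embeddings matrix.
rand_emb <- function(R, d_e = 8L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(R * d_e), R, d_e)
}

# Random survival records with mixed censoring.
rand_records <- function(n, seed = 1L, t_max = 24L) {
  set.seed(seed)
  survival_records(sample.int(t_max, n, replace = TRUE),
                   rbinom(n, 1L, 0.6), t_max = t_max)
}

# Random predicted distributions (rows on the simplex).
rand_y <- function(n, seed = 1L, t_max = 24L) {
  set.seed(seed)
  y <- matrix(rexp(n * t_max), n, t_max)
  y / rowSums(y)
}

# Independent O(N^2) concordance oracle: explicit double loop over Eq.-style
# acceptable pairs with strict comparison at the earlier patient's time.
brute_ctd <- function(y, records, ties = "strict") {
  n <- nrow(records)
  conc <- 0; tot <- 0
  for (i in seq_len(n)) {
    if (records$k[i] != 1L) next
    for (j in seq_len(n)) {
      if (i == j || records$s[j] <= records$s[i]) next
      tot <- tot + 1
      fi <- sum(y[i, seq_len(records$s[i])])
      fj <- sum(y[j, seq_len(records$s[i])])
      if (fi > fj) conc <- conc + 1
      else if (ties == "half" && fi == fj) conc <- conc + 0.5
    }
  }
  conc / tot
}

# Exhaustive sign-flip oracle for the Wilcoxon signed-rank two-sided
# p-value: enumerates all 2^n assignments and counts statistics at least
# as extreme as the observed min rank sum.
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  count <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m)[1:n])
    wp <- sum(r[signs == 1L])
    if (min(wp, total - wp) <= obs + 1e-9) count <- count + 1L
  }
  count / 2^n
}

# Fast phantom configuration for pipeline tests (small grid, no noise).
small_phantom <- function(...) {
  args <- utils::modifyList(
    list(grid = c(64L, 64L, 32L), lesion_radius_mm = 4, noise_sd = 0),
    list(...))
  do.call(phantom_config, args)
}

# Deterministic slice-feature batch for model-level tests (matches the toy
# backbone's 32-feature slice stage).
toy_batch <- function(lens = c(3L, 5L, 4L), seed = 1L, p = 32L) {
  set.seed(seed)
  lapply(lens, function(R) matrix(runif(R * p), R, p))
}
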