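# Censoring-aware training loss: L = alpha * L1 + beta * L2, the
# discrete-time likelihood term plus the CIF ranking term.

#' Loss configuration
#'
#' Defaults follow the fixed values used with the risk network: equal
#' weights `alpha = beta = 0.5` on the likelihood and ranking terms, ranking
#' kernel scale `sigma = 0.1`, per-event ranking weight `theta = 1` (single
#' event), and a `1e-7` floor inside logarithms.
#'
#' @param alpha Weight of the likelihood term L1.
#' @param beta Weight of the ranking term L2.
#' @param sigma Ranking kernel scale in `eta(a, b) = exp(-(a - b) / sigma)`.
#' @param eps Log floor in `(0, 1e-4]`.
#' @param l2_normalize `"mean"` (default; mean over acceptable pairs, keeps
#'   the alpha/beta balance independent of batch size) or `"sum"` (the
#'   plain sum over pairs).
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, sigma = 0.1, eps = 1e-7,
                        l2_normalize = c("mean", "sum")) {
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be nonnegative")
  if (sigma <= 0) stopf("sigma must be positive")
  if (eps <= 0 || eps > 1e-4) stopf("eps must lie in (0, 1e-4]")
  structure(list(alpha = alpha, beta = beta, sigma = sigma, eps = eps,
                 l2_normalize = match.arg(l2_normalize), theta = 1),
            class = "loss_config")
}

check_batch <- function(y, records) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (nrow(y) != nrow(records))
    stopf("predictions (%d) and records (%d) differ in length",
          nrow(y), nrow(records))
  t_max <- ncol(y)
  if (any(records$s < 1L) || any(records$s > t_max))
    stopf("record time outside 1..%d", t_max)
  y
}

#' Likelihood loss L1
#'
#' `L1 = -sum_i [ 1(k_i = 1) log y_{i, s_i} + 1(k_i = 0) log(1 - F_hat(s_i)) ]`
#' with `eps` flooring inside the logarithms. For a patient censored at the
#' horizon `t_max`, `1 - F_hat(t_max)` is identically 0 under the softmax
#' parameterization; the flooring makes the contribution the finite
#' constant `-log(eps)`, whose gradient through the softmax is exactly
#' zero.
#'
#' @param y `N x t_max` matrix of predicted per-month distributions.
#' @param records [survival_records()] aligned with the rows of `y`.
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar.
#' @export
loss_l1 <- function(y, records, cfg = loss_config()) {
  y <- check_batch(y, records)
  cif <- cif_matrix(y)
  ev <- records$k == 1L
  terms <- numeric(nrow(y))
  if (any(ev))
    terms[ev] <- log(pmax(y[cbind(which(ev), records$s[ev])], cfg$eps))
  if (any(!ev)) {
    surv <- 1 - cif[cbind(which(!ev), records$s[!ev] + 1L)]
    terms[!ev] <- log(pmax(surv, cfg$eps))
  }
  -sum(terms)
}

#' Ranking loss L2
#'
#' Over acceptable pairs `(i, j)` with `k_i = 1` and `s_i < s_j`,
#' accumulates `eta(F_hat(s_i | x_i), F_hat(s_i | x_j))` with
#' `eta(a, b) = exp(-(a - b) / sigma)`; by default the mean over acceptable
#' pairs is returned (`l2_normalize = "sum"` restores the plain sum). Zero
#' when no acceptable pair exists.
#'
#' @inheritParams loss_l1
#' @return Nonnegative scalar.
#' @export
loss_l2 <- function(y, records, cfg = loss_config()) {
  y <- check_batch(y, records)
  pairs <- acceptable_pairs(records)
  if (!nrow(pairs)) return(0)
  cif <- cif_matrix(y)
  si <- records$s[pairs[, 1L]]
  a <- cif[cbind(pairs[, 1L], si + 1L)]
  b <- cif[cbind(pairs[, 2L], si + 1L)]
  eta <- exp(-(a - b) / cfg$sigma)
  tot <- cfg$theta * sum(eta)
  if (cfg$l2_normalize == "mean") tot / nrow(pairs) else tot
}

#' Total training loss
#'
#' `alpha * L1 + beta * L2`.
#'
#' @inheritParams loss_l1
#' @return Finite scalar.
#' @export
total_loss <- function(y, records, cfg = loss_config()) {
  cfg$alpha * loss_l1(y, records, cfg) + cfg$beta * loss_l2(y, records, cfg)
}

# Analytic gradient of total_loss with respect to the predicted
# distributions y (N x t_max). The CIF chain rule uses
# dF_hat(s)/dy_m = 1(m <= s).
grad_total_y <- function(y, records, cfg = loss_config()) {
  y <- check_batch(y, records)
  n <- nrow(y); t_max <- ncol(y)
  g <- matrix(0, n, t_max)
  cif <- cif_matrix(y)
  # L1, uncensored: -1 / y_{i, s_i}
  ev <- which(records$k == 1L)
  for (i in ev) {
    v <- y[i, records$s[i]]
    if (v > cfg$eps) g[i, records$s[i]] <- g[i, records$s[i]] -
        cfg$alpha / v
  }
  # L1, censored: +1 / (1 - F(s_i)) on bins m <= s_i
  for (i in which(records$k == 0L)) {
    v <- 1 - cif[i, records$s[i] + 1L]
    if (v > cfg$eps)
      g[i, seq_len(records$s[i])] <- g[i, seq_len(records$s[i])] +
        cfg$alpha / v
  }
  # L2 over acceptable pairs
  pairs <- acceptable_pairs(records)
  if (nrow(pairs) && cfg$beta > 0) {
    si <- records$s[pairs[, 1L]]
    a <- cif[cbind(pairs[, 1L], si + 1L)]
    b <- cif[cbind(pairs[, 2L], si + 1L)]
    eta <- exp(-(a - b) / cfg$sigma)
    scale <- cfg$beta * cfg$theta /
      (if (cfg$l2_normalize == "mean") nrow(pairs) else 1)
    for (p in seq_len(nrow(pairs))) {
      m <- seq_len(si[p])
      d <- scale * eta[p] / cfg$sigma
      g[pairs[p, 1L], m] <- g[pairs[p, 1L], m] - d
      g[pairs[p, 2L], m] <- g[pairs[p, 2L], m] + d
    }
  }
  g
}
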