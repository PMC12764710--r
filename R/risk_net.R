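# DeepHit-style risk-assessment network: a shared sub-network (SN) of fully
# connected ReLU layers, a single cause-specific sub-network (CSN) that
# consumes the pair (f_s(x), x) via concatenation (the residual input
# connection), and one softmax output layer over the 24 monthly bins.

#' Survival record
#'
#' Observed time and event indicator for one patient. Time is an integer
#' month in `1..t_max`; `k = 1` means death observed at `s`, `k = 0` means
#' censoring/truncation at `s`. A record at `s = 0` is remapped to month 1
#' with a warning (a first-hitting time of 0 is not representable in the
#' monthly softmax); times beyond `t_max` become censored at `t_max`.
#'
#' @param s Observed time(s) in months.
#' @param k Event indicator(s), 0 or 1.
#' @param t_max Horizon; default 24.
#' @return A `survival_records` data frame with columns `s`, `k`.
#' @export
survival_records <- function(s, k, t_max = 24L) {
  s <- as.integer(s); k <- as.integer(k)
  if (length(s) != length(k)) stopf("s and k must have equal length")
  if (any(!k %in% c(0L, 1L))) stopf("k must be 0 (censored) or 1 (death)")
  if (any(s < 0L)) stopf("negative survival time")
  if (any(s == 0L)) {
    warnf("%d record(s) at s = 0 remapped to month 1", sum(s == 0L))
    s[s == 0L] <- 1L
  }
  over <- s > t_max
  if (any(over)) {
    s[over] <- t_max
    k[over] <- 0L
  }
  structure(data.frame(s = s, k = k),
            t_max = as.integer(t_max), class = c("survival_records",
                                                 "data.frame"))
}

#' Risk-network configuration
#'
#' Defaults follow the fixed hyperparameters of the risk-assessment network:
#' 5 hidden layers of 100 ReLU units with dropout 0.2 for both the shared
#' and the cause-specific part, and 24 output bins.
#'
#' @param n_hidden_layers Hidden layers in the shared sub-network; default 5.
#' @param neurons_per_layer Units per hidden layer; default 100.
#' @param dropout Dropout rate in `[0, 1)`; default 0.2.
#' @param t_max Number of output time bins; default 24.
#' @return A `risk_config` list.
#' @export
risk_config <- function(n_hidden_layers = 5L, neurons_per_layer = 100L,
                        dropout = 0.2, t_max = 24L) {
  if (n_hidden_layers < 1L || neurons_per_layer < 1L)
    stopf("layer counts must be positive")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 dropout = dropout, t_max = as.integer(t_max)),
            class = "risk_config")
}

#' Initialize risk-network parameters
#'
#' @param d_e Input (volume-embedding) dimension.
#' @param cfg A [risk_config()].
#' @param seed Initialization seed.
#' @return Parameter list: `hidden` (list of `W`, `b`) and `out` (`W`, `b`
#'   over the concatenated `(f_s(x), x)` input).
#' @export
risk_params <- function(d_e, cfg = risk_config(), seed = 1L) {
  with_seed(seed, {
    dims <- c(d_e, rep(cfg$neurons_per_layer, cfg$n_hidden_layers))
    hidden <- lapply(seq_len(cfg$n_hidden_layers), function(i)
      list(W = he_init(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L])))
    # small-init output layer: the softmax starts near uniform whatever the
    # scale of the incoming representation
    out <- list(W = matrix(stats::rnorm((cfg$neurons_per_layer + d_e) *
                                          cfg$t_max, sd = 0.01),
                           cfg$neurons_per_layer + d_e, cfg$t_max),
                b = numeric(cfg$t_max))
    list(hidden = hidden, out = out, d_e = d_e, cfg = cfg)
  })
}

# Forward pass for a batch X (N x d_e). dropout_masks: optional list of
# per-layer inverted-dropout masks (NULL = evaluation mode). Returns y
# (N x t_max, rows summing to 1) plus the activation caches for backprop.
risknet_forward <- function(X, params, dropout_masks = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  acts <- vector("list", length(params$hidden) + 1L)
  acts[[1L]] <- X
  a <- X
  for (i in seq_along(params$hidden)) {
    a <- pmax(sweep(a %*% params$hidden[[i]]$W, 2L,
                    params$hidden[[i]]$b, "+"), 0)
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[i]]
    acts[[i + 1L]] <- a
  }
  z <- cbind(a, X)                       # residual input connection
  o <- sweep(z %*% params$out$W, 2L, params$out$b, "+")
  if (any(!is.finite(o))) stopf("non-finite activations in risk network")
  y <- softmax_rows(o)
  list(y = y, acts = acts, z = z)
}

# Backprop dL/dy through the softmax and the network. Returns parameter
# gradients and dL/dX (for the upstream attention/encoder).
risknet_backward <- function(fw, params, d_y, dropout_masks = NULL) {
  y <- fw$y
  d_o <- y * (d_y - rowSums(d_y * y))    # softmax Jacobian, row-wise
  grads <- list(hidden = vector("list", length(params$hidden)))
  grads$out <- list(W = crossprod(fw$z, d_o), b = colSums(d_o))
  d_z <- d_o %*% t(params$out$W)
  nh <- length(params$hidden)
  d_e <- params$d_e
  nn <- params$cfg$neurons_per_layer
  delta <- d_z[, seq_len(nn), drop = FALSE]
  d_x <- d_z[, nn + seq_len(d_e), drop = FALSE]   # residual branch
  for (i in nh:1) {
    if (!is.null(dropout_masks)) delta <- delta * dropout_masks[[i]]
    delta <- delta * (fw$acts[[i + 1L]] > 0)
    grads$hidden[[i]] <- list(W = crossprod(fw$acts[[i]], delta),
                              b = colSums(delta))
    delta <- delta %*% t(params$hidden[[i]]$W)
  }
  d_x <- d_x + delta
  list(grads = grads, d_x = d_x)
}

#' Predict the discrete survival distribution for volume embeddings
#'
#' Evaluation-mode forward pass (dropout disabled): each row of the output
#' is a probability vector over the `t_max` monthly bins, nonnegative and
#' summing to 1 (single softmax output).
#'
#' @param x Volume embedding (length `d_e` vector) or `N x d_e` matrix.
#' @param params [risk_params()].
#' @return `N x t_max` matrix of per-month event probabilities.
#' @export
forward_risk <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$d_e)
    stopf("embedding dimension %d does not match network input %d",
          ncol(x), params$d_e)
  if (any(!is.finite(x))) stopf("non-finite volume embedding")
  risknet_forward(x, params)$y
}

#' Estimated cumulative incidence function
#'
#' `F_hat(t | x) = sum_{m=1}^{t} y_m`: the probability that the event has
#' occurred by month `t`. `F_hat(0) = 0`; `F_hat(t_max) = 1` up to softmax
#' tolerance; nondecreasing in `t`.
#'
#' @param y Length-`t_max` probability vector (one predicted distribution).
#' @param t Month(s) in `0..t_max`; vectorized.
#' @return CIF value(s) in `[0, 1]`.
#' @export
estimated_cif <- function(y, t) {
  t_max <- length(y)
  t <- as.integer(t)
  if (any(t < 0L) || any(t > t_max))
    stopf("t must lie in 0..%d", t_max)
  cum <- c(0, cumsum(y))
  cum[t + 1L]
}

# N x (t_max + 1) matrix of CIF values, column t+1 = F_hat(t).
cif_matrix <- function(y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  cbind(0, t(apply(y, 1L, cumsum)))
}
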