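# Pluggable 2D slice encoders.
#
# The shipped default ("toy") plays the role of a pretrained backbone at
# desk scale without any weight download. Its fixed body is a deterministic
# per-slice feature stage -- a 24-bin intensity histogram plus
# band-occupancy spatial moments and intensity summaries (32 features) --
# chosen because, like features from a network pretrained on natural
# images, they are informative about generic structures without ever having
# seen the cohort; a frozen stack of random projections, in contrast, was
# measured to either destroy the recoverable signal (random ReLU layers) or
# pass through so much pixel-level noise that the risk network memorizes
# patients instead of learning (random linear layers). On top sits one
# trainable ReLU embedding head (d_e = 32). Under both freeze strategies
# the parameter-free feature stage is the frozen part and the head trains.

backbone_registry <- new.env(parent = emptyenv())

register_backbone <- function(name, spec) {
  assign(name, spec, envir = backbone_registry)
  invisible(name)
}

get_backbone <- function(name) {
  if (!exists(name, envir = backbone_registry))
    stopf("unknown backbone '%s'; registered: %s", name,
          paste(ls(backbone_registry), collapse = ", "))
  get(name, envir = backbone_registry)
}

#' List registered slice-encoder backbones
#' @return Character vector of backbone names.
#' @export
list_backbones <- function() ls(backbone_registry)

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

toy_spec <- list(
  dims = c(32L, 32L),              # feature stage -> one trainable head
  activations = "relu",
  d_e = 32L,
  n_hist_bins = 24L,
  # occupancy band sitting just above lung parenchyma in the package's HU
  # window ((-800+1000)/1400 ~ 0.14): picks up lesion-like soft structure
  band = c(0.17, 0.35),
  make_params = function(seed) {
    with_seed(seed, list(
      list(W = he_init(32L, 32L), b = numeric(32L), act = "relu")))
  })

register_backbone("toy", toy_spec)

#' Encoder configuration
#'
#' @param backbone Name of a registered backbone; default `"toy"`.
#' @param freeze_strategy `"feature_extractor"` (all layers frozen except the
#'   last) or `"half_frozen"` (first half of the layers, by layer count,
#'   frozen).
#' @param weights_seed Seed for the backbone's deterministic random
#'   initialization ("pretrained" weights at desk scale).
#' @return An `encoder_config` with the derived embedding size `d_e`.
#' @export
encoder_config <- function(backbone = "toy",
                           freeze_strategy = c("feature_extractor",
                                               "half_frozen"),
                           weights_seed = 42L) {
  freeze_strategy <- match.arg(freeze_strategy)
  spec <- get_backbone(backbone)
  structure(list(backbone = backbone, freeze_strategy = freeze_strategy,
                 weights_seed = as.integer(weights_seed), d_e = spec$d_e),
            class = "encoder_config")
}

encoder_params <- function(cfg) {
  get_backbone(cfg$backbone)$make_params(cfg$weights_seed)
}

# Number of leading frozen layers under a freeze strategy.
encoder_n_frozen <- function(cfg) {
  n_layers <- length(get_backbone(cfg$backbone)$dims) - 1L
  switch(cfg$freeze_strategy,
         feature_extractor = n_layers - 1L,
         half_frozen = n_layers %/% 2L)
}

# Fixed per-slice feature stage of the toy backbone: a 24-bin intensity
# histogram over [0, 1], occupancy/centroid/dispersion of the band just
# above lung parenchyma (lesion-like soft structure), and four intensity
# summaries. 32 features per slice; deterministic and parameter-free.
toy_slice_features <- function(sl, spec) {
  v <- as.vector(sl)
  nb <- spec$n_hist_bins
  hist <- tabulate(findInterval(v, seq(0, 1, length.out = nb + 1L),
                                rightmost.closed = TRUE), nb) / length(v)
  band <- sl >= spec$band[1] & sl <= spec$band[2]
  n_band <- sum(band)
  sp <- if (n_band > 0L) {
    rc <- which(band, arr.ind = TRUE)
    disp <- (stats::sd(rc[, 1]) + stats::sd(rc[, 2])) / nrow(sl)
    c(n_band / length(v), mean(rc[, 1]) / nrow(sl),
      mean(rc[, 2]) / ncol(sl), if (is.finite(disp)) disp else 0)
  } else c(0, 0.5, 0.5, 0)
  c(hist, sp, mean(v), stats::sd(v),
    stats::quantile(v, c(0.9, 0.99), names = FALSE))
}

# Per-slice features for a whole stack: R x 32 matrix.
encoder_pool <- function(stack, cfg) {
  spec <- get_backbone(cfg$backbone)
  t(vapply(stack$slices, toy_slice_features, numeric(spec$dims[1L]),
           spec = spec))
}

# Dense ReLU forward from pooled features; returns all activations
# (activations[[1]] = input, activations[[k+1]] = after layer k).
# `from_layer` > 1 resumes from a cached activation (the input is then the
# output of layer `from_layer - 1`; earlier slots stay NULL).
encoder_forward <- function(pooled, params, from_layer = 1L) {
  acts <- vector("list", length(params) + 1L)
  acts[[from_layer]] <- pooled
  a <- pooled
  for (k in seq(from_layer, length(params))) {
    a <- sweep(a %*% params[[k]]$W, 2L, params[[k]]$b, "+")
    if (!identical(params[[k]]$act, "linear")) a <- pmax(a, 0)
    acts[[k + 1L]] <- a
  }
  acts
}

# Backprop dL/d(embeddings) through the dense layers; returns gradients for
# layers > n_frozen (named grads[[k]]) and nothing upstream of the freeze
# boundary.
encoder_backward <- function(acts, params, d_emb, n_frozen) {
  n <- length(params)
  grads <- vector("list", n)
  delta <- d_emb
  for (k in n:1) {
    if (!identical(params[[k]]$act, "linear"))
      delta <- delta * (acts[[k + 1L]] > 0)   # ReLU gate
    if (k > n_frozen) {
      grads[[k]] <- list(W = crossprod(acts[[k]], delta),
                         b = colSums(delta))
    }
    if (k == n_frozen + 1L || k == 1L) break
    delta <- delta %*% t(params[[k]]$W)
  }
  grads
}

#' Encode the slices of a stack into per-slice embeddings
#'
#' Runs the configured backbone over each slice independently (no
#' cross-slice mixing); deterministic in evaluation mode.
#'
#' @param stack A [slice_stack()] whose slices match the backbone's expected
#'   input (any square size: the toy backbone block-pools to its own grid).
#' @param cfg An [encoder_config()].
#' @param params Optional explicit backbone parameters (defaults to the
#'   deterministic seeded initialization of `cfg`).
#' @return An `R x d_e` matrix of slice embeddings.
#' @export
encode_slices <- function(stack, cfg = encoder_config(), params = NULL) {
  if (is.null(params)) params <- encoder_params(cfg)
  pooled <- encoder_pool(stack, cfg)
  acts <- encoder_forward(pooled, params)
  emb <- acts[[length(acts)]]
  if (any(!is.finite(emb))) stopf("non-finite slice embeddings")
  emb
}
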