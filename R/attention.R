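# Slice-aggregation operators: the learned soft-attention pooling (the
# method), plain averaging and a self-attention block with a class token
# (the two ablation aggregators).

#' Soft-attention parameters
#'
#' One learnable linear scorer: a `1 x d_e` weight row `W` and a scalar bias
#' `b`; each slice embedding is scored `W s_j + b` and the scores pass
#' through a softmax.
#'
#' @param d_e Embedding dimension.
#' @param seed Seed for the small random initialization.
#' @return List with `W` (length `d_e`) and `b` (scalar).
#' @export
attention_params <- function(d_e, seed = 1L) {
  with_seed(seed, list(W = stats::rnorm(d_e, sd = 1 / sqrt(d_e)), b = 0))
}

#' Soft-attention weights over slices
#'
#' Computes `w_j = softmax(W s_j + b)` over the slices of a volume, with
#' max-subtraction for overflow safety. With a `mask`, the softmax runs over
#' the unmasked slices only and masked (padded) slots receive weight exactly
#' 0.
#'
#' @param emb `R x d_e` matrix of slice embeddings.
#' @param params [attention_params()].
#' @param mask Optional logical vector of length `R`; `FALSE` marks padded
#'   slots.
#' @return Numeric weight vector of length `R`: nonnegative, summing to 1.
#' @export
attention_weights <- function(emb, params, mask = NULL) {
  if (!nrow(emb)) stopf("empty slice embeddings")
  logits <- drop(emb %*% params$W) + params$b
  if (any(!is.finite(logits))) stopf("non-finite attention logits")
  if (is.null(mask)) return(softmax(logits))
  w <- numeric(length(logits))
  if (!any(mask)) stopf("all slices masked")
  w[mask] <- softmax(logits[mask])
  w
}

#' Fuse slice embeddings by soft attention
#'
#' `x = sum_j w_j s_j`: a convex combination of the slice embeddings, so
#' each coordinate of `x` lies between the corresponding slice-embedding
#' extrema.
#'
#' @param emb `R x d_e` matrix.
#' @param w Length-`R` weight vector from [attention_weights()].
#' @return Length-`d_e` volume embedding.
#' @export
aggregate_soft_attention <- function(emb, w) {
  if (length(w) != nrow(emb))
    stopf("weight length %d does not match slice count %d",
          length(w), nrow(emb))
  drop(crossprod(emb, w))
}

#' Fuse slice embeddings by unweighted averaging
#'
#' Ablation aggregator: the mean over slices, identical to soft attention
#' with uniform weights.
#'
#' @param emb `R x d_e` matrix.
#' @return Length-`d_e` volume embedding.
#' @export
aggregate_average <- function(emb) {
  if (!nrow(emb)) stopf("empty slice embeddings")
  colMeans(emb)
}

#' Self-attention class-token parameters
#'
#' One self-attention encoder block (default 4 heads, model width `d_e`, no
#' positional encoding) plus a learned class token. Deterministically
#' initialized from `seed`.
#'
#' @param d_e Embedding dimension; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads; default 4.
#' @param seed Initialization seed.
#' @return Parameter list with `token`, `Wq`, `Wk`, `Wv`, `Wo`, `n_heads`.
#' @export
ctk_params <- function(d_e, n_heads = 4L, seed = 1L) {
  if (d_e %% n_heads != 0L) stopf("d_e must be divisible by n_heads")
  with_seed(seed, {
    sd <- 1 / sqrt(d_e)
    list(token = stats::rnorm(d_e, sd = sd),
         Wq = matrix(stats::rnorm(d_e * d_e, sd = sd), d_e, d_e),
         Wk = matrix(stats::rnorm(d_e * d_e, sd = sd), d_e, d_e),
         Wv = matrix(stats::rnorm(d_e * d_e, sd = sd), d_e, d_e),
         Wo = matrix(stats::rnorm(d_e * d_e, sd = sd), d_e, d_e),
         n_heads = as.integer(n_heads))
  })
}

#' Fuse slice embeddings via self-attention with a class token
#'
#' Prepends the learned class token to the slice sequence, runs one
#' multi-head self-attention block (with residual connection, no positional
#' encoding) and returns the transformed class token. Without positional
#' encoding the output is invariant to slice-order permutations.
#'
#' @param emb `R x d_e` matrix.
#' @param params [ctk_params()].
#' @return Length-`d_e` volume embedding.
#' @export
aggregate_self_attention_ctk <- function(emb, params) {
  if (!nrow(emb)) stopf("empty slice embeddings")
  d_e <- ncol(emb)
  x0 <- rbind(params$token, emb)
  q <- x0 %*% params$Wq
  k <- x0 %*% params$Wk
  v <- x0 %*% params$Wv
  h <- params$n_heads
  dh <- d_e %/% h
  out <- matrix(0, nrow(x0), d_e)
  for (head in seq_len(h)) {
    cols <- ((head - 1L) * dh + 1L):(head * dh)
    scores <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dh)
    attn <- softmax_rows(scores)
    out[, cols] <- attn %*% v[, cols, drop = FALSE]
  }
  x1 <- x0 + out %*% params$Wo
  x1[1L, ]
}
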