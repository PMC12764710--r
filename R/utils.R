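# Internal helpers shared across modules.

# Numerically safe softmax (max-subtraction). Returns weights summing to 1.
softmax <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits in softmax")
  z <- exp(logits - max(logits))
  z / sum(z)
}

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  z <- exp(logits - m)
  z / rowSums(z)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards. All package randomness funnels through this,
#' so cohort generation, training and permutation draws are reproducible.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a labelled child seed
#'
#' Deterministically derives an independent child seed from a parent seed
#' and a stream label (cheap djb2-style string hash), keeping the result a
#' valid 32-bit integer. Used to give every random stream (folds,
#' initialization, dropout, survival sampling, ...) its own seed under one
#' configuration seed.
#'
#' @param seed Integer parent seed.
#' @param label Character stream label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 5381
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
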