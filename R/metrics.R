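# Evaluation and model-comparison statistics: time-dependent concordance,
# the permutation-based paired comparison, and the exact Wilcoxon
# signed-rank test with effect size r.

#' Bundle per-patient predictions with their survival records
#'
#' @param y `N x t_max` matrix of predicted per-month distributions.
#' @param records [survival_records()] aligned with the rows of `y`.
#' @param patient_id Unique patient identifiers; default `p1..pN`.
#' @return A `model_predictions` object.
#' @export
model_predictions <- function(y, records, patient_id = NULL) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (nrow(y) != nrow(records))
    stopf("y rows (%d) and records (%d) differ", nrow(y), nrow(records))
  patient_id <- patient_id %||% paste0("p", seq_len(nrow(y)))
  if (anyDuplicated(patient_id)) stopf("patient identifiers must be unique")
  structure(list(y = y, records = records,
                 patient_id = as.character(patient_id)),
            class = "model_predictions")
}

#' Acceptable (comparable) patient pairs
#'
#' A pair `(i, j)` is acceptable when patient `i` experienced the event
#' (`k_i = 1`) and `s_i < s_j`; `j` may be censored.
#'
#' @param records A [survival_records()] data frame.
#' @return Two-column integer matrix of ordered index pairs (columns `i`,
#'   `j`); zero rows when no pair qualifies.
#' @export
acceptable_pairs <- function(records) {
  if (!nrow(records)) stopf("records must be nonempty")
  ev <- which(records$k == 1L)
  out <- vector("list", length(ev))
  for (idx in seq_along(ev)) {
    i <- ev[idx]
    js <- which(records$s > records$s[i])
    if (length(js))
      out[[idx]] <- cbind(i = rep.int(i, length(js)), j = js)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  pairs
}

#' Time-dependent concordance index
#'
#' Over acceptable pairs, the fraction with
#' `F_hat(s_i | x_i) > F_hat(s_i | x_j)` (strict inequality: ties
#' contribute 0 by default; `ties = "half"` credits them 0.5).
#'
#' @param preds A [model_predictions()] object, or an `N x t_max` matrix of
#'   predicted distributions if `records` is supplied.
#' @param records [survival_records()]; ignored when `preds` is a
#'   `model_predictions`.
#' @param ties `"strict"` (default) or `"half"`.
#' @return Concordance value in `[0, 1]`.
#' @export
ctd_index <- function(preds, records = NULL, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  if (inherits(preds, "model_predictions")) {
    records <- preds$records
    y <- preds$y
  } else {
    if (is.null(records)) stopf("records required when preds is a matrix")
    y <- check_batch(preds, records)
  }
  pairs <- acceptable_pairs(records)
  if (!nrow(pairs))
    stopf("no acceptable pairs: need at least one event preceding another patient's time")
  cif <- cif_matrix(y)
  si <- records$s[pairs[, 1L]]
  a <- cif[cbind(pairs[, 1L], si + 1L)]
  b <- cif[cbind(pairs[, 2L], si + 1L)]
  conc <- sum(a > b)
  if (ties == "half") conc <- conc + 0.5 * sum(a == b)
  conc / nrow(pairs)
}

# Internal: C^td from a precomputed event-column matrix.
#   M: N x E matrix, M[j, e] = F_hat(s_e | x_j) for the e-th event patient;
#   ev_idx: row index of the e-th event patient; risk: N x E logical risk
#   set (s_j > s_e).
ctd_from_columns <- function(M, ev_idx, risk, ties = "strict") {
  v <- M[cbind(ev_idx, seq_along(ev_idx))]
  lt <- sweep(M, 2L, v, "<") & risk
  conc <- sum(lt)
  if (ties == "half") {
    eq <- sweep(M, 2L, v, "==") & risk
    conc <- conc + 0.5 * sum(eq)
  }
  conc / sum(risk)
}

#' Permutation-based paired model comparison
#'
#' Observed statistic: `ctd_index(a) - ctd_index(b)`. The null distribution
#' is built by randomly swapping (with probability 0.5) the two models'
#' predictions at the patient level, `n_perm` times; the two-sided p-value
#' uses add-one smoothing: `(1 + #{|perm diff| >= |observed|}) /
#' (n_perm + 1)`.
#'
#' @param preds_a,preds_b [model_predictions()] over the same patients (same
#'   identifiers, same records).
#' @param n_perm Number of permutations; default 5000.
#' @param ties Tie handling passed to the concordance computation.
#' @param statistic `"ctd_diff"` (default, the concordance difference) or
#'   `"t"` (a paired t-like statistic on per-pair concordance indicators).
#' @return List with `observed_diff`, `p_value`, `n_perm`, `ctd_a`, `ctd_b`.
#' @export
permutation_paired_test <- function(preds_a, preds_b, n_perm = 5000L,
                                    ties = c("strict", "half"),
                                    statistic = c("ctd_diff", "t")) {
  ties <- match.arg(ties)
  statistic <- match.arg(statistic)
  if (!inherits(preds_a, "model_predictions") ||
      !inherits(preds_b, "model_predictions"))
    stopf("preds_a and preds_b must be model_predictions objects")
  if (!identical(preds_a$patient_id, preds_b$patient_id) ||
      !identical(preds_a$records$s, preds_b$records$s) ||
      !identical(preds_a$records$k, preds_b$records$k))
    stopf("the two prediction sets must cover the same patients and records")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stopf("n_perm must be at least 1 (got %d)", n_perm)
  records <- preds_a$records
  n <- nrow(records)
  ev_idx <- which(records$k == 1L)
  if (!length(ev_idx)) stopf("no events: the concordance is undefined")
  se <- records$s[ev_idx]
  risk <- outer(records$s, se, ">")
  if (!any(risk)) stopf("no acceptable pairs in the records")
  ca <- cif_matrix(preds_a$y)
  cb <- cif_matrix(preds_b$y)
  Ma <- ca[, se + 1L, drop = FALSE]
  Mb <- cb[, se + 1L, drop = FALSE]
  stat_fun <- function(M1, M2) {
    d <- ctd_from_columns(M1, ev_idx, risk, ties) -
         ctd_from_columns(M2, ev_idx, risk, ties)
    if (statistic == "t") {
      # per-event-column concordance differences as the paired sample
      v1 <- M1[cbind(ev_idx, seq_along(ev_idx))]
      v2 <- M2[cbind(ev_idx, seq_along(ev_idx))]
      c1 <- colSums(sweep(M1, 2L, v1, "<") & risk) / pmax(colSums(risk), 1L)
      c2 <- colSums(sweep(M2, 2L, v2, "<") & risk) / pmax(colSums(risk), 1L)
      dd <- c1 - c2
      s <- stats::sd(dd)
      if (!is.finite(s) || s == 0) return(0)
      return(mean(dd) / (s / sqrt(length(dd))))
    }
    d
  }
  observed <- stat_fun(Ma, Mb)
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    M1 <- Ma; M2 <- Mb
    M1[swap, ] <- Mb[swap, , drop = FALSE]
    M2[swap, ] <- Ma[swap, , drop = FALSE]
    if (abs(stat_fun(M1, M2)) >= abs(observed)) exceed <- exceed + 1L
  }
  list(observed_diff = observed,
       p_value = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm,
       ctd_a = ctd_from_columns(Ma, ev_idx, risk, ties),
       ctd_b = ctd_from_columns(Mb, ev_idx, risk, ties))
}

# Exact null distribution of the positive-rank sum V = W+ under random
# signs, as probabilities over the support of 2*V (integer even with
# average ranks doubled). Returns list(support2, prob).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1L)   # index = value of 2*V, offset by 1
  p[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(length(p) - r)])
    p <- 0.5 * (p + shifted)
  }
  list(support2 = 0:total, prob = p)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided exact test: zero differences are dropped, absolute
#' differences are ranked with average ranks for ties, the statistic is the
#' smaller of the two signed-rank sums, and the p-value comes from the
#' exact null distribution over all `2^n` sign assignments (computed by
#' convolution, equivalent to full enumeration; n is limited to 25). No
#' continuity correction.
#'
#' @param a First sequence of paired values, or the differences themselves
#'   if `b` is `NULL`.
#' @param b Optional second sequence; differences are `a - b`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (`"greater"`: differences tend positive).
#' @return List with `statistic` (min rank sum), `p_value`, `n` (nonzero
#'   differences), `w_plus`, `w_minus`.
#' @export
wilcoxon_exact <- function(a, b = NULL,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  if (any(!is.finite(d))) stopf("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stopf("all differences are zero: the test is undefined")
  if (n > 25L) stopf("exact enumeration supported for n <= 25 (got %d)", n)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  statistic <- min(w_plus, w_minus)
  null <- signed_rank_null(as.integer(round(2 * r)))
  cdf_le <- function(v2) sum(null$prob[null$support2 <= v2 + 1e-9])
  cdf_ge <- function(v2) sum(null$prob[null$support2 >= v2 - 1e-9])
  p <- switch(alternative,
    two.sided = min(1, 2 * min(cdf_le(2 * w_plus), cdf_ge(2 * w_plus))),
    greater = cdf_ge(2 * w_plus),
    less = cdf_le(2 * w_plus))
  list(statistic = statistic, p_value = p, n = n,
       w_plus = w_plus, w_minus = w_minus)
}

#' Effect size r for the Wilcoxon signed-rank test
#'
#' `Z = (statistic - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` without continuity
#' correction, and the effect size is `abs(Z) / sqrt(n)`.
#'
#' @param statistic Rank-sum statistic (the smaller signed-rank sum).
#' @param n Number of nonzero paired differences.
#' @return Effect size in `[0, 1]` (clipped).
#' @export
effect_size_r <- function(statistic, n) {
  if (n < 1L) stopf("n must be at least 1")
  mu <- n * (n + 1) / 4
  sd <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (statistic - mu) / sd
  min(abs(z) / sqrt(n), 1)
}
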