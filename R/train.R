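# Training and cross-validation orchestration: tenfold CV with an inner
# 90/10 train/validation split, epoch-wise model selection by validation
# time-dependent concordance, fine-tuning from a pretrained model, and the
# paired transfer-learning experiment.

#' Cross-validation / training configuration
#'
#' Paper-scale defaults: AdamW with base learning rate 1e-4, weight decay
#' 1e-2, batch size 4 volumes, 100 epochs, tenfold CV with an inner 90/10
#' split, model selection by validation C^td. The `"desk"` profile keeps
#' everything except the learning rate, which rises to 1e-3 because the toy
#' encoder's trainable head starts from random initialization rather than
#' from pretrained weights (see the methods vignette).
#'
#' @param k_folds Number of CV folds; default 10.
#' @param inner_val_fraction Fraction of each training portion held out for
#'   validation; default 0.1.
#' @param learning_rate AdamW base learning rate; `NULL` picks the
#'   profile's default (1e-4 paper, 1e-3 desk).
#' @param weight_decay Decoupled weight decay; default 1e-2.
#' @param batch_size Volumes per optimization step; default 4.
#' @param epochs Training epochs; default 100.
#' @param augment Apply slice augmentation during training (requires stacks
#'   rather than cached features; off by default at desk scale).
#' @param grad_clip Gradient-norm clip (0 disables; off by default).
#' @param seed Seed governing fold splits, initialization and dropout.
#' @param profile `"paper"` or `"desk"`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_folds = 10L, inner_val_fraction = 0.1,
                      learning_rate = NULL, weight_decay = 1e-2,
                      batch_size = 4L, epochs = 100L, augment = FALSE,
                      grad_clip = 0, seed = 1L,
                      profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (k_folds < 2L) stopf("k_folds must be at least 2")
  if (inner_val_fraction <= 0 || inner_val_fraction >= 1)
    stopf("inner_val_fraction must lie in (0, 1)")
  lr <- learning_rate %||% if (profile == "desk") 1e-3 else 1e-4
  if (lr < 0 || weight_decay < 0 || batch_size < 1L || epochs < 1L)
    stopf("hyperparameters must be nonnegative (batch/epochs positive)")
  structure(list(k_folds = as.integer(k_folds),
                 inner_val_fraction = inner_val_fraction,
                 learning_rate = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment = augment,
                 grad_clip = grad_clip, seed = as.integer(seed),
                 profile = profile),
            class = "cv_config")
}

patient_records <- function(patients, t_max = 24L) {
  survival_records(vapply(patients, `[[`, integer(1), "s"),
                   vapply(patients, `[[`, integer(1), "k"), t_max = t_max)
}

# Evaluation-mode C^td of a model on a patient list; NA (with a flag) when
# the records admit no acceptable pair.
eval_ctd <- function(model, patients) {
  rec <- patient_records(patients, model$risk_cfg$t_max)
  if (!nrow(acceptable_pairs(rec))) return(NA_real_)
  pr <- predict_cohort(model, patients)
  ctd_index(pr$y, rec)
}

#' Train one model on a train/validation split
#'
#' AdamW on the total loss with dropout in the risk network; after every
#' epoch the validation C^td is evaluated (dropout off) and the parameters
#' of the best epoch are kept (ties resolved to the earliest epoch).
#'
#' @param train_patients,val_patients Patient lists (entries with `pooled`,
#'   `s`, `k`).
#' @param cfg A [cv_config()].
#' @param model Optional starting [attnsurv_model()] (used by
#'   [finetune()]); when `NULL` a fresh model is initialized from
#'   `cfg$seed`.
#' @param ... Passed to [attnsurv_model()] when `model` is `NULL`.
#' @return List with `model` (best-epoch parameters), `history` (per-epoch
#'   loss and validation C^td), `best_epoch`, `flagged` (TRUE when the
#'   validation set had no acceptable pairs).
#' @export
train_model <- function(train_patients, val_patients, cfg = cv_config(),
                        model = NULL, ...) {
  if (!length(train_patients) || !length(val_patients))
    stopf("empty train or validation split")
  if (is.null(model)) model <- attnsurv_model(seed = cfg$seed, ...)
  flat <- model_trainable(model)
  state <- adamw_init(flat)
  rec_all <- patient_records(train_patients, model$risk_cfg$t_max)
  # frozen encoder layers never change during training: compute them once
  pooled_all <- frozen_base(model, train_patients)
  val_base <- frozen_base(model, val_patients)
  if (cfg$augment &&
      is.null(train_patients[[1L]]$stack))
    stopf("augment = TRUE needs a cohort generated with keep = \"stack\"")
  aug_cfg <- augment_config()
  aug_one <- augment_config(apply_probability = 1)
  enc_cfg <- model$encoder_cfg
  val_rec <- patient_records(val_patients, model$risk_cfg$t_max)
  val_ok <- nrow(acceptable_pairs(val_rec)) > 0L
  n <- length(train_patients)
  p_drop <- model$risk_cfg$dropout
  nn <- model$risk_cfg$neurons_per_layer
  nh <- model$risk_cfg$n_hidden_layers
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_ctd = numeric(0))
  best <- list(ctd = -Inf, flat = flat, epoch = 0L)
  val_flagged <- FALSE
  with_seed(derive_seed(cfg$seed, "train-loop"), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        pooled <- if (!cfg$augment) pooled_all[idx] else
          lapply(idx, function(i) {
            st_i <- train_patients[[i]]$stack
            hit <- which(stats::runif(st_i$R) < aug_cfg$apply_probability)
            if (!length(hit)) return(pooled_all[[i]])
            pl <- train_patients[[i]]$pooled
            for (j in hit) {
              sl <- augment_slice(st_i$slices[[j]], aug_one)
              pl[j, ] <- encoder_pool(
                slice_stack(list(sl), 0, 1L), enc_cfg)
            }
            frozen_forward_matrix(model, pl)
          })
        rec <- rec_all[idx, , drop = FALSE]
        masks <- if (p_drop > 0)
          lapply(seq_len(nh), function(i)
            matrix(stats::rbinom(length(idx) * nn, 1L, 1 - p_drop),
                   length(idx), nn) / (1 - p_drop))
        fw <- model_forward(model, pooled, masks, from_cache = TRUE)
        loss <- total_loss(fw$y, rec, model$loss_cfg)
        if (!is.finite(loss))
          stopf("divergent loss at epoch %d (non-finite); aborting", epoch)
        epoch_loss <- epoch_loss + loss
        grads <- model_backward(model, fw, rec, masks)
        if (cfg$grad_clip > 0) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
          if (gn > cfg$grad_clip)
            grads <- lapply(grads, function(g) g * cfg$grad_clip / gn)
        }
        upd <- adamw_step(flat, grads, state, cfg$learning_rate,
                          cfg$weight_decay)
        flat <- upd$flat; state <- upd$state
        model <- model_set_trainable(model, flat)
      }
      val_ctd <- if (val_ok) {
        vy <- model_forward(model, val_base, from_cache = TRUE)$y
        ctd_index(vy, val_rec)
      } else NA_real_
      if (is.na(val_ctd)) val_flagged <- TRUE
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss,
                                  val_ctd = val_ctd))
      score <- if (is.na(val_ctd)) -Inf else val_ctd
      if (score > best$ctd) best <- list(ctd = score, flat = flat,
                                         epoch = epoch)
    }
  })
  if (best$epoch == 0L) best <- list(ctd = NA_real_, flat = flat,
                                     epoch = cfg$epochs)
  list(model = model_set_trainable(model, best$flat), history = history,
       best_epoch = best$epoch, flagged = val_flagged)
}

# Patient-level fold assignment: a partition into k disjoint, exhaustive
# groups of near-equal size, seeded.
make_folds <- function(n, k, seed) {
  if (n < k) stopf("cohort size %d smaller than k_folds %d", n, k)
  with_seed(derive_seed(seed, "folds"), {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    split(sample.int(n), rep(seq_len(k), sizes))
  })
}

split_hash <- function(folds, ids) {
  paste(vapply(folds, function(f) paste(sort(ids[f]), collapse = ","),
               character(1)), collapse = "|")
}

#' Tenfold cross-validation
#'
#' Patient-level disjoint test folds; within each training portion a
#' seeded 90/10 train/validation split; per-fold training with model
#' selection by validation C^td; per-fold test C^td, predictions and
#' attention weights. A fold whose test or validation records admit no
#' acceptable pair is flagged, never silently skipped.
#'
#' @param cohort An `attnsurv_cohort` (with cached features).
#' @param cfg A [cv_config()].
#' @param init_model Optional pretrained [attnsurv_model()]: every fold
#'   fine-tunes from its parameters instead of training from scratch.
#' @param ... Passed to [attnsurv_model()] for from-scratch initialization.
#' @return An `attnsurv_cv` object: `folds` (per-fold results),
#'   `mean_ctd`, `sd_ctd`, `split_hash`, `cfg`.
#' @export
run_cv <- function(cohort, cfg = cv_config(), init_model = NULL, ...) {
  patients <- cohort$patients
  n <- length(patients)
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  folds <- make_folds(n, cfg$k_folds, cfg$seed)
  results <- vector("list", cfg$k_folds)
  for (f in seq_len(cfg$k_folds)) {
    test_idx <- folds[[f]]
    rest <- setdiff(seq_len(n), test_idx)
    n_val <- max(1L, round(cfg$inner_val_fraction * length(rest)))
    val_idx <- with_seed(derive_seed(cfg$seed, paste0("val-", f)),
                         sample(rest, n_val))
    train_idx <- setdiff(rest, val_idx)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, paste0("fold-", f))
    fit <- if (is.null(init_model)) {
      train_model(patients[train_idx], patients[val_idx], fold_cfg, ...)
    } else {
      check_same_architecture(init_model, ...)
      train_model(patients[train_idx], patients[val_idx], fold_cfg,
                  model = init_model)
    }
    test_pat <- patients[test_idx]
    rec <- patient_records(test_pat)
    pr <- predict_cohort(fit$model, test_pat)
    flagged <- fit$flagged
    tctd <- if (nrow(acceptable_pairs(rec))) ctd_index(pr$y, rec)
            else { flagged <- TRUE; NA_real_ }
    att <- do.call(rbind, lapply(seq_along(test_pat), function(i) {
      p <- test_pat[[i]]
      data.frame(patient_id = p$patient_id, fold = f,
                 source_index = p$source_indices,
                 relative_position = p$relative_positions,
                 weight = pr$weights[[i]])
    }))
    results[[f]] <- list(fold_id = f, ctd = tctd,
                         predictions = pr$y, patient_id = pr$patient_id,
                         records = rec, attention = att,
                         best_epoch = fit$best_epoch, flagged = flagged,
                         model = fit$model)
  }
  ctds <- vapply(results, `[[`, numeric(1), "ctd")
  structure(list(folds = results,
                 mean_ctd = mean(ctds, na.rm = TRUE),
                 sd_ctd = stats::sd(ctds, na.rm = TRUE),
                 split_hash = split_hash(folds, ids),
                 cfg = cfg),
            class = "attnsurv_cv")
}

#' @export
print.attnsurv_cv <- function(x, ...) {
  cat(sprintf("<attnsurv_cv: %d folds, C^td %.3f +/- %.3f>\n",
              length(x$folds), x$mean_ctd, x$sd_ctd))
  invisible(x)
}

check_same_architecture <- function(model, ...) invisible(TRUE)

#' Fine-tune a pretrained model on a new cohort
#'
#' Resumes all weights of `pretrained` and re-trains on `cohort` under the
#' same cross-validated selection rule as [run_cv()]. Errors if the
#' architectures differ.
#'
#' @param pretrained An [attnsurv_model()].
#' @param cohort Target `attnsurv_cohort`.
#' @param cfg A [cv_config()].
#' @return An `attnsurv_cv` object.
#' @export
finetune <- function(pretrained, cohort, cfg = cv_config()) {
  probe <- cohort$patients[[1L]]$pooled
  if (ncol(probe) !=
      get_backbone(pretrained$encoder_cfg$backbone)$dims[1L])
    stopf("architecture mismatch: cohort features (%d) do not fit the pretrained backbone",
          ncol(probe))
  run_cv(cohort, cfg, init_model = pretrained)
}

#' Paired transfer-learning experiment
#'
#' Pretrains on a source cohort (single seeded 90/10 split), then runs
#' `n_repeats` paired comparisons on the target cohort. Each repeat
#' performs one `k_folds_target`-fold cross-validation of the target under
#' its own fold partition: one arm trains from scratch, the other
#' fine-tunes from the pretrained weights, on identical folds and inner
#' splits, and the repeat's value is each arm's mean test C^td over the
#' folds (so every target patient contributes to every repeat). The
#' one-sided exact Wilcoxon signed-rank test (fine-tuned minus
#' from-scratch) summarizes the paired repeats.
#'
#' @param source_cohort,target_cohort `attnsurv_cohort` objects.
#' @param cfg A [cv_config()]; its seed drives everything.
#' @param n_repeats Paired repeats; default 6.
#' @param k_folds_target Folds of the per-repeat target CV; default 4.
#' @return List with `ctd_finetuned`, `ctd_scratch` (length `n_repeats`),
#'   `mean_diff`, `wilcoxon` (statistic, one-sided p), `pretrained`,
#'   and `split_hashes` proving the pairing.
#' @export
transfer_experiment <- function(source_cohort, target_cohort,
                                cfg = cv_config(profile = "desk"),
                                n_repeats = 6L, k_folds_target = 4L) {
  src <- source_cohort$patients
  n_src <- length(src)
  val_idx <- with_seed(derive_seed(cfg$seed, "pretrain-val"),
                       sample.int(n_src, max(1L, round(0.1 * n_src))))
  pre_cfg <- cfg
  pre_cfg$seed <- derive_seed(cfg$seed, "pretrain")
  pre <- train_model(src[-val_idx], src[val_idx], pre_cfg)
  ctd_ft <- ctd_sc <- numeric(n_repeats)
  hashes <- character(n_repeats)
  for (r in seq_len(n_repeats)) {
    run_cfg <- cfg
    run_cfg$seed <- derive_seed(cfg$seed, paste0("repeat-", r))
    run_cfg$k_folds <- as.integer(k_folds_target)
    cv_sc <- run_cv(target_cohort, run_cfg)
    cv_ft <- run_cv(target_cohort, run_cfg, init_model = pre$model)
    if (!identical(cv_sc$split_hash, cv_ft$split_hash))
      stopf("internal error: transfer arms diverged in fold assignment")
    hashes[r] <- cv_sc$split_hash
    ctd_sc[r] <- cv_sc$mean_ctd
    ctd_ft[r] <- cv_ft$mean_ctd
  }
  wt <- tryCatch(wilcoxon_exact(ctd_ft, ctd_sc, alternative = "greater"),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))
  list(ctd_finetuned = ctd_ft, ctd_scratch = ctd_sc,
       mean_diff = mean(ctd_ft - ctd_sc),
       wilcoxon = wt, pretrained = pre$model, split_hashes = hashes)
}

#' Attention interpretability report
#'
#' Normalizes slice positions to relative indices, averages attention
#' weights per relative-position bin across all patients and folds, and per
#' patient flags the slices whose weight reaches the 50th percentile of
#' that patient's own weight distribution.
#'
#' @param cv An `attnsurv_cv` from [run_cv()], or a data frame with columns
#'   `patient_id`, `relative_position`, `weight` (and optionally
#'   `source_index`, `fold`).
#' @param n_bins Number of relative-position bins; default 20.
#' @return List with `profile` (per-bin mean attention), `slices` (per
#'   slice, with `highlighted`), `n_patients`.
#' @export
attention_report <- function(cv, n_bins = 20L) {
  att <- if (inherits(cv, "attnsurv_cv"))
    do.call(rbind, lapply(cv$folds, `[[`, "attention")) else cv
  if (!all(c("patient_id", "relative_position", "weight") %in% names(att)))
    stopf("attention table needs patient_id, relative_position, weight")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(att$relative_position, edges,
                           rightmost.closed = TRUE), n_bins)
  profile <- data.frame(
    bin = seq_len(n_bins),
    lower = edges[-length(edges)], upper = edges[-1L],
    mid = (edges[-1L] + edges[-length(edges)]) / 2,
    mean_weight = vapply(seq_len(n_bins), function(b) {
      w <- att$weight[bin == b]
      if (length(w)) mean(w) else NA_real_
    }, numeric(1)),
    n_slices = vapply(seq_len(n_bins), function(b) sum(bin == b),
                      integer(1)))
  att$highlighted <- FALSE
  for (pid in unique(att$patient_id)) {
    sel <- att$patient_id == pid
    att$highlighted[sel] <-
      att$weight[sel] >= stats::quantile(att$weight[sel], 0.5)
  }
  list(profile = profile, slices = att,
       n_patients = length(unique(att$patient_id)))
}
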