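# attnsurv

Attention-based CT slice fusion for discrete-time survival risk
prediction.

## The problem

Predicting two-year overall survival of lung-cancer patients from a
baseline thoracic CT alone is a censored-outcome learning problem: for
many patients only "alive up to month *s*" is observed. `attnsurv`
implements a complete, tested pipeline for this task:

1. **Preprocessing** — Hounsfield-unit conversion from DICOM series or
   NIfTI, trilinear resampling to (1, 1, 3) mm, rule-based lung
   segmentation (pluggable), exclusion of slices with less than 2% lung
   area, cropping to the union lung bounding box, 224×224 resize with a
   (−1000, 400) HU window onto [0, 1].
2. **Slice encoding** — a pluggable 2D backbone produces one embedding
   `s_j` of size `d_e` per axial slice. A deterministic desk-scale "toy"
   backbone ships with the package (no weight downloads): a fixed
   per-slice feature stage (intensity histogram, band-occupancy spatial
   moments, intensity summaries) plus one trainable ReLU head with
   layer-normalized output.
3. **Soft-attention fusion** — a learned scalar score per slice, softmaxed
   over the volume:
   `w_j = exp(W s_j + b) / Σ_k exp(W s_k + b)`, and
   `x = Σ_j w_j s_j`, a convex combination of the slice embeddings.
   Ablation aggregators: plain averaging and a self-attention block with a
   class token.
4. **Risk network** — a DeepHit-style head: a shared 5×100 ReLU
   sub-network with dropout 0.2, a cause-specific part consuming
   `(f_s(x), x)` (residual input connection), and a single softmax over
   `T_max = 24` monthly bins, giving a distribution `y` with CIF
   `F̂(t|x) = Σ_{m≤t} y_m`.
5. **Loss** — `L = α L1 + β L2` (α = β = 0.5): the censoring-aware
   likelihood
   `L1 = −Σ_i [1(k_i=1) log y_{i,s_i} + 1(k_i=0) log(1 − F̂(s_i))]`
   plus the ranking term accumulating
   `exp(−(F̂_i(s_i) − F̂_j(s_i))/σ)`, σ = 0.1, over pairs with
   `k_i = 1, s_i < s_j`. Gradients are analytic and verified numerically.
6. **Evaluation** — the time-dependent concordance index
   `C^td = Σ_{pairs} 1(F̂_i(s_i) > F̂_j(s_i)) / #pairs`, a patient-level
   permutation test for paired model comparison, and the exact Wilcoxon
   signed-rank test with effect size `r = |Z|/√n`.
7. **Synthetic cohorts** — thoracic phantoms (body + two basally-widening
   lungs + optional lesion) whose lesion volume and axial depth drive a
   known discrete-time hazard, so the whole pipeline can be exercised and
   validated end to end with no external data.

## Worked example

```r
library(attnsurv)

# a phantom patient with a 6 mm mid-lung lesion
ph  <- generate_phantom(phantom_config(seed = 3))
pre <- preprocess_volume(ph$volume)
pre$stack
#> <slice_stack phantom: R=27 slices of 224x224>

# encode, attend, predict
emb <- encode_slices(pre$stack, encoder_config())
w   <- attention_weights(emb, attention_params(32, seed = 1))
x   <- aggregate_soft_attention(emb, w)
y   <- forward_risk(x, risk_params(32, seed = 1))
estimated_cif(y[1, ], c(6, 12, 24))
#> [1] 0.2532031 0.5049243 1.0000000   # nondecreasing CIF, F(24) = 1

# the printed reference statistics: six paired runs, one-signed differences
wt <- wilcoxon_exact(c(0.01, 0.05, 0.02, 0.08, 0.03, 0.04))
wt$statistic; wt$p_value
#> [1] 0
#> [1] 0.03125
effect_size_r(wt$statistic, wt$n)
#> [1] 0.8987121   # prints as r = 0.899

# a small synthetic cohort, cross-validated end to end
co <- generate_cohort(60, seed = 11, keep = "stack", out_size = 64L)
cv <- run_cv(co, cv_config(k_folds = 5, epochs = 40, profile = "desk",
                           seed = 1))
cv
#> <attnsurv_cv: 5 folds, C^td ...>   # mean test concordance over folds
attention_report(cv)$profile        # mean attention per relative position
```

The numbers above that are shown are exact analytic values; the
cross-validated concordance depends on the seed — the acceptance suite
(`tests/testthat/test-acceptance.R`) runs the full-scale version of this
experiment (n = 200, tenfold) and checks it against the synthetic
generator's constructed discrimination ceiling of ≈ 0.75.

## Command line

```sh
Rscript inst/cli/attnsurv.R simulate --n 200 --seed 11 --out data/
Rscript inst/cli/attnsurv.R preprocess --input data/ --output prep/ \
    --min-lung-fraction 0.02 --spacing 1,1,3 --size 224
Rscript inst/cli/attnsurv.R train --n 60 --seed 1 --out runs/base
Rscript inst/cli/attnsurv.R compare --preds-a a.csv --preds-b b.csv \
    --records records.csv --n-perm 5000 --seed 7 --out report.json
```

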