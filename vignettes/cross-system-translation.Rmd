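---
title: "Cross-system omics translation: model, assumptions and numerical choices"
author: "latentbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-system omics translation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Two biological systems — cell lines, or species — observe overlapping
biology through different measurement channels. A drug perturbation tested
in both induces a shared underlying state, but the readouts live in
different feature spaces and carry system-specific offsets. `latentbridge`
models each system with its own autoencoder and shapes one *global* latent
space shared by both encoders: embeddings of the same condition measured in
different systems are pulled together, while each decoder remains free to
reconstruct its own system's profiles. Translation is then
encode-with-source, decode-with-target.

Each encoder/decoder hidden layer is a fully connected map followed by
batch normalization, an ELU activation and dropout; the final layer of both
is a single fully connected map without a trainable bias, so an all-zero
weight matrix yields an exactly-zero embedding. In count mode the encoder
consumes `log10(count + 1)`-transformed values after an elementwise product
with a trainable per-gene scaling vector, and the decoder emits two heads —
mean and inverse dispersion, both through softplus links floored at 1e-8 —
while the likelihood is evaluated against the raw counts with variance
`mu + mu^2/theta` (theta → ∞ recovers the Poisson limit).

The training objective combines, with configurable non-negative weights:
mean per-sample summed squared error (or the negative-binomial negative
log-likelihood); the mean Euclidean distance between same-condition
cross-system embedding pairs (minimized) and their mean cosine similarity
(maximized — this is the term that keeps embedding norms in check, since
nothing else normalizes the latent space); a Jensen–Shannon
mutual-information bound computed by a pairwise discriminator over the
batch, using the positive-pair mask; an adversarial prior term against a
uniform [0, 1] prior computed by a second discriminator; cross-entropy for
any task classifiers; and L2 penalties on the weights and biases of
encoders, decoders and classifiers. Variant v2 adds trainable covariate
vectors that compose the latent code before decoding plus an adversarial
system classifier whose cross-entropy the encoders *maximize*; its
parameters are updated only on its own alternating step, and it is
pre-trained together with the encoders and the two discriminators (no
decoders, no task classifiers) before joint training. Variant v3 trains a
competitive system classifier on the global space through the ordinary
classifier-entropy term.

One deliberate sign choice deserves a note. The prior term is written as
`mean(log D2(v) + log(1 - D2(z)))` and enters the minimized objective with
a positive weight, which — combined with the discriminator's own ascent
step — drives the embeddings *towards* the uniform prior, as in
adversarial-autoencoder practice. The framework's stated intent of letting
embeddings drift away from the prior is available by flipping
`prior_sign = -1` in `model_config()`; we default to the literal form
because it is the stable adversarial game, and because the prior term is
reported to make little practical difference either way.

## Tunable parameters

* `latent_dim` — global space width. Presets cover the four study
  modes (292 for a 978-gene panel, 1024 for ~10k genes, 512 for the
  single-cell mode, 32 for serology); the desk-scale default used
  throughout the package's own experiments is 16.
* `enc_hidden` / `dec_hidden` — hidden widths, interpolating between input
  and latent dimension (desk default one layer of 64).
* `batch_size` (desk 128), `epochs` (desk 150), `lr` 0.001 under an
  adaptive-moment optimizer (plain SGD by flag; the optimizer is a package
  choice), dropout 0.1.
* Loss weights: the `loss_weights()` constructor defaults every multiplier
  to 1, which is the right surface for algebraic work with
  `total_loss()`. For *training*, `model_config()` installs
  `default_train_weights()`: reconstruction, distance and cosine at 1, MI
  at 0.1, prior at 0.01, classifier entropy at 1, adversary at 0.1, and
  all L2 terms at 1e-4. These were fixed once, by checking that the
  training loss converges on the generator's default data — the L2 and
  prior terms otherwise dwarf a ~50-feature reconstruction error — and are
  fully exposed in the configuration.
* `pretrain_epochs` — v2 adversary pretraining, default 10% of `epochs`;
  the adversary then alternates 1:1 with framework steps.
* Batches are sampled condition-wise (all samples of a sampled condition
  enter together), so both members of a paired condition always co-occur
  and the in-batch positive mask is well defined; when a batch happens to
  contain no positives the alignment and MI terms are skipped for that
  batch. Batch normalization requires at least 2 samples per system per
  batch; smaller fragments are dropped from the batch.

Cross-validation folds are assigned at the *condition* level
(`make_folds()`), so a paired condition is hidden from training in both
systems at once; fold sizes differ by at most one condition.

## The synthetic benchmark

`generate_paired_bulk()` emulates the design the framework assumes: each
condition c has a true latent state `u_c ~ N(0, I)` (default dimension 10)
observed by system s as `x = W_s g(u_c) + b_s + eps`. Defaults — 300
conditions, half paired, 50/80 features, unit-scale additive system effect,
Gaussian noise with sd 0.5 on unit-scale signals, linear `g` — are the
package's benchmark conditions; `W_s` entries are N(0, 1/sqrt(latent_dim))
so profiles have O(1) scale. The count generator exponentiates the linear
predictor into negative-binomial means with a common inverse dispersion
(default 4, a typical single-cell value); the serology generator plants a
known subset (20%) of each species' panel that shifts by `protection_effect`
with the binary protection label, with exactly balanced classes.

What the generator does *not* emulate: gene-regulatory covariance between
features, dose–response structure within a perturbagen, batch effects
beyond one additive system offset, library-size variation in counts, and
the heavy-tailed noise of real panels. Passing tests therefore show that
the machinery recovers structure it was built to recover under its own
assumptions; they do not certify performance on any real dataset.

Because the two systems' feature panels are disjoint, the "direct
translation" reference in the benchmark is the correlation between
index-matched features of paired profiles — what naive feature matching
would score; with independently drawn loadings it sits near zero, which is
exactly why the latent route is needed.

## Numerical choices

* softplus is evaluated in a branched form (`x + log1p(exp(-x))` for
  x > 30) so discriminator scores of any magnitude never overflow; the MI
  loss treats the mask diagonal as neither positive nor negative (a sample
  is not its own negative pair) and refuses batches that lack positives or
  negatives rather than returning a degenerate value.
* Integrated gradients use a trapezoid rule over the zero-baseline path
  (default 50 steps). The trapezoid's O(1/m²) error is what makes the
  completeness identity `sum_i IG_i = F(x) - F(0)` hold to 1e-3 at 200
  steps; a left-Riemann rule (O(1/m), the common attribution-library
  convention) is available via `method = "riemann_left"`. Analytic
  gradients flow through the model's tape; generic callables fall back to
  central finite differences.
* On standardized panels the per-feature sample average of signed
  attributions is ~0 by construction (each score is `x_i · g_i` with
  `E[x_i] = 0`), so `rank_cross_system_features()` defaults to a
  class-contrast aggregation — protected-class mean attribution minus
  unprotected-class mean — whenever protection labels are supplied; the
  plain sample mean remains available.
* The GSEA rank distance scores the top-t and bottom-t genes of one
  profile in the other's ranking with an unweighted running-sum enrichment
  statistic (hit step 1/|S|, miss step 1/(N−|S|), signed by the maximum
  deviation), combines them as (ES_up − ES_down)/2, symmetrizes over the
  two directions and averages over thresholds {100, 250, 500} (scaled to
  10/25/50% of the universe below 1000 genes). Identical rankings give 0,
  reversed rankings 2, independent rankings ≈ 1. Thresholds above half the
  universe would overlap the top and bottom sets and are refused.
* The k-means importance split clusters absolute scores into three groups
  (10 restarts, fixed seed): the middle cluster and the small high-score
  outlier cluster are important; the threshold is the midpoint between the
  highest unimportant and the lowest important score. All-equal scores are
  refused ("no separation").
* The per-latent likelihood-ratio test compares nested Gaussian linear
  models by exact log-likelihood (equivalent to `lmtest::lrtest`, which
  serves as an independent cross-check in the tests). A constant
  protection column simply drops out (LRT 0, p 1); genuinely collinear
  covariate pairs raise an error naming the pair. The null-calibration
  simulation in the acceptance tests uses n = 200, where the chi-square
  reference is accurate; at n = 100 the test is mildly anticonservative
  (rejection ~0.06), which its power companion (standardized effect 1,
  n = 100) is insensitive to.
* Spearman correlations use average ranks for ties; "more than three
  replicates" is read strictly as ≥ 4, and "half passed QC" rounds up for
  odd replicate counts — both thresholds are parameters of
  `filter_l1000()`. Serology standardization statistics are computed on
  the full matrix by default, with a `stats_rows` argument for
  train-only-statistics workflows.

## Problem sizes used in the shipped experiments

The test suite and acceptance experiments run the benchmark at its default
conditions (300 conditions, 50/80 features) with 150-epoch trainings, five
seeds for the translation-margin experiment, one v2 run for the
globality/separation properties, 1000 null replicates for the LRT
calibration, and two 250-epoch serology runs for the planted-feature
recovery pipeline. These sizes are the package's chosen desk-scale
benchmark; all of them are configuration, not constants.

## Known limitations

Exactly two systems per model; covariates beyond system/cell type must be
folded into the condition key; the "network" covariate-composition mode
mirrors the classifier architecture since only the additive form is fully
specified; no hyperparameter search is attempted (matching the source
framework's practice); and the adversarial prior game, like all GAN-style
objectives, is not guaranteed to converge for aggressive weightings — the
defaults keep it a weak regularizer.
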