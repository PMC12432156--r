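---
title: "Methods and modeling choices in omicfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in omicfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `omicfuse`, the meaning
and rationale of the main tuning parameters, the scope of the synthetic data
generator, and the numerical choices that affect results. The README covers
the workflow itself; here we explain *why* the defaults are what they are.

## The model

`omicfuse` assumes that the samples of a study live near a shared
low-dimensional latent space and that each omics modality is a noisy,
modality-specific view of it. All architectures therefore share the same
skeleton: per-modality (or concatenated) feed-forward ReLU encoders map
inputs to an embedding, and small supervisor heads map the embedding to each
target.

- **Fusion.** `early` concatenates the modality matrices before a single
  encoder; `intermediate` gives each modality its own encoder and
  concatenates the per-modality embeddings. Intermediate fusion is the
  default recommendation because it lets each modality keep its own scale of
  representation; early fusion is cheaper and is the only mode supported by
  the graph architecture.
- **Architectures.** `DirectPred` is the plain encoder + heads model.
  `supervised_vae` adds a stochastic embedding regularized toward a standard
  normal prior with a squared maximum mean discrepancy (MMD) penalty rather
  than an analytic KL term; the MMD version is a V-statistic with a Gaussian
  kernel, so the penalty is exact for the minibatch at hand and remains valid
  with no distributional assumption on the encoder output. With no targets it
  degenerates to an unsupervised embedding model. `CrossModalPred` encodes a
  chosen subset of modalities and adds decoders that reconstruct another
  subset, forcing the embedding to carry cross-modality information.
  `MultiTripletNetwork` adds a triplet margin loss on the primary categorical
  target so classes separate geometrically in the embedding. `GNN` encodes a
  sample-similarity graph (or a user-supplied edge list) with graph
  convolutions.
- **Tasks and masking.** Each target is `regression` (masked mean squared
  error), `classification` (masked softmax cross-entropy), or `survival`
  (negative Cox partial log-likelihood). Samples with missing labels
  contribute nothing to that target's loss but still contribute to every
  other target and to reconstruction terms, which is how partially labeled
  multi-omics cohorts are used in full.
- **Multi-task weighting.** Per-task losses are combined with learned
  homoscedastic-uncertainty weights: each task has a log-variance parameter
  `s`, and contributes `exp(-s) * loss + s`. Tasks that remain noisy are
  automatically down-weighted without a user-set weight vector.

The entire network, including gradients, is implemented in R. That choice
keeps the package dependency-free and makes every gradient auditable; the
cost is speed, which is why the default problem sizes below are in the
hundreds of samples and features. These sizes are package defaults, not
limits of the method.

## Cox survival head

The survival head outputs a scalar risk score per sample and is trained with
the negative Cox partial log-likelihood using the **Breslow** convention for
tied event times. The loss is normalized by the **number of events**, not the
number of samples: censored-heavy batches then produce gradients on the same
scale as event-rich batches, which keeps the uncertainty weighting across
tasks meaningful and makes early-stopping losses comparable across
validation splits with different censoring fractions.

## Leakage-safe harmonization

`harmonize()` turns a raw train/test dataset plus a `task_spec()` into
model-ready matrices. Every data-dependent statistic — feature variances,
Laplacian scores, redundancy correlations, centers, and scales — is computed
on the training split only and then *applied* to the test split. The test
transform is exactly `(x - train_center) / train_scale`; corrupting the test
split cannot change anything fitted. Defaults:

- `variance_quantile = 0.01`: drop the bottom 1% of features by training
  variance. This removes near-constant features that destabilize scaling
  while touching almost nothing else.
- `feature_top_fraction = 1` with `min_features = 20`: optional unsupervised
  selection by Laplacian score on a row-normalized sample-similarity graph;
  by default nothing is dropped. The Laplacian score favors features smooth
  over the sample manifold, i.e. features that respect whatever cluster or
  gradient structure the cohort has, without using labels.
- `redundancy_threshold = 0.8`: among selected features, prune the
  lower-scoring member of any pair with absolute training correlation above
  0.8, so the encoder does not spend capacity on near-duplicates.

## Training, early stopping, and hyperparameter search

`train_once()` uses minibatch Adam (`batch_size = 32` by default) with early
stopping on a validation split (`val_fraction = 0.2`, stratified for
classification; `early_stop_patience = 10`). The returned model is the
parameter snapshot at the best validation loss, not the last epoch.

`hpo_search()` runs `n_init = 5` random configurations and then proposes the
remaining trials with a Gaussian-process surrogate (RBF kernel on the
normalized search space) maximizing expected improvement over 256 random
candidates. The default search space spans `latent_dim` in [16, 128],
`hidden_dim_factor` in [0.2, 0.5], learning rate in [1e-4, 1e-2] (log
scale), `supervisor_hidden_dim` in [8, 32], and `batch_size` in
{32, 64, 128}. These bounds bracket the regime where feed-forward encoders
on hundreds-of-features omics matrices are well behaved; values pinned in
the template spec are excluded from the search.

`finetune()` adapts a trained model to a shifted cohort: half of the new
cohort (`holdin_fraction = 0.5`) is used for adaptation, the other half is
kept untouched for honest evaluation. The adaptation itself is a small
cross-validated grid (`cv_folds = 5`, `patience = 3`) over learning rates
`{1e-4, 1e-3, 1e-2}` crossed with three freezing strategies (nothing frozen,
encoders frozen, heads frozen), and the winning combination is refit on the
full hold-in set.

All randomness flows through explicit seeds: a policy seed fixes the split,
initialization, and minibatch order, so any run is bit-for-bit reproducible.
Derived seeds are produced by modular arithmetic inside the 32-bit integer
range.

## Attribution: exact integrated gradients

Integrated gradients attribute a prediction to input features by integrating
the gradient along the straight path from a baseline to the input. For a
ReLU network in evaluation mode, the prediction restricted to that path is
**piecewise linear**: it only changes slope where some pre-activation crosses
zero. `integrated_gradients(..., exact = TRUE)` exploits this. It collects
all pre-activation values at both path endpoints, locates every crossing by
linear interpolation, evaluates the (constant) gradient at the midpoint of
each resulting segment, and sums gradient × segment length. The result is the
exact path integral up to floating-point error, so the completeness identity
— attributions summing to `f(x) - f(baseline)` — holds to near machine
precision. A fixed-step Riemann rule (the default, `steps = 64`) converges
only at rate 1/steps near kinks and cannot reach that accuracy at any
practical step count; it remains available because it is cheaper and
method-agnostic. GradientSHAP is provided as the sampling-based counterpart:
attributions are averaged over noisy interpolates against a baseline
distribution, and for a linear model its expectation coincides with
integrated gradients.

`compute_markers()` aggregates absolute attributions over test samples,
grouped per target (and per class for classification), and ranks features
with importances normalized to the top feature.

## Post-hoc embedding alignment and clustering

- `rpca_mnn_align()` removes batch offsets between two embedding sets: each
  batch is centered, projected into the other's principal-component space,
  mutual nearest neighbors are matched one-to-one as anchors, and each moving
  sample is shifted by a Gaussian-weighted average of anchor displacements.
- `ot_align()` solves the optimal-transport problem between the two
  embeddings' empirical distributions. With `regularization = 0` and
  equal-size uniform batches it uses an exact assignment solver
  (Jonker–Volgenant), so self-transport is recovered exactly. Otherwise it
  uses log-domain Sinkhorn iterations, which are robust to small
  regularization values; iterations run until the marginal error is below
  1e-7 (up to 1e5 iterations), so the returned plan's marginals are correct
  to well below any downstream tolerance.
- `cluster_embeddings()` fits k-means over `k_range = 2:8` (or Louvain over a
  resolution grid) and selects the solution with the best mean silhouette
  width. `adjusted_mutual_information()` implements AMI with the exact
  hypergeometric expected mutual information, so chance agreement scores 0
  regardless of cluster-size imbalance.

## The synthetic generator

`simulate_multiomics()` exists so that every claim in the package can be
tested against known ground truth. Its generative model intentionally
mirrors the assumptions above:

- A latent matrix `Z` (default `latent_dim_true = 4`) is standard normal,
  optionally a Gaussian mixture: with `n_clusters > 1`, component means are
  rescaled so the **minimum pairwise** center distance equals `cluster_sep`,
  making the separation parameter mean the same thing for any draw.
- Each modality is `X = Z W' + noise` with a fixed Gaussian loading matrix
  and i.i.d. Gaussian noise (`noise_sd = 0.5` by default, roughly
  feature-level signal-to-noise of 2 per latent unit).
- Numeric targets are linear in `Z` plus noise. Categorical targets are
  argmax of `Z B` plus Gaussian score noise (`label_noise_sd = 0.25`), which
  produces a small, size-controlled Bayes error so that perfect accuracy is
  not attainable and overfitting is visible. Survival targets are exponential
  with rate `exp(Z γ)`; the censoring rate is calibrated by bisection so the
  realized censoring fraction matches the request.
- `batch_shift` applies per-feature affine shifts to emulate platform
  effects; `label_missing_frac` masks labels to emulate partially annotated
  cohorts.

Scope and limits: the generator is linear-Gaussian by design. It can say
whether the pipeline recovers planted structure, respects leakage
boundaries, and ranks planted markers; it cannot certify behavior on heavy
tails, count data, or nonlinear latent geometry. Conclusions from it are
about the implementation, not about biology.

## Reproducibility

`run_pipeline()` derives one sub-seed per stage (splitting, hyperparameter
search, final training, attribution, fine-tuning) from the single run seed,
records them in `manifest.json` together with input checksums, per-stage
timings, and MD5 sums of all outputs, and writes artifacts atomically. Two
runs with the same config and seed produce identical metric files. The
script `scripts/acceptance.R` recomputes the package's headline quantities
end-to-end from a single seed and writes them as JSON; see the README.
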