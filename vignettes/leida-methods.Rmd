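---
title: "Phase-locking state analysis: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking state analysis: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leidar)
```

This vignette describes the model behind `leidar`, the assumptions each stage
makes, and the reasoning behind the numerical and statistical choices. The
worked example at the end runs the full pipeline on a small synthetic dataset.

## The model

`leidar` implements a leading-eigenvector dynamics analysis (LEiDA) of
multichannel oscillatory recordings. The pipeline views an N-channel recording
as N coupled oscillators and asks, at every time point, *which channels are
phase-aligned with which*:

1. **Band-pass filtering.** Each channel is demeaned and filtered with a
   zero-phase (forward-backward) Butterworth band-pass, by default 1–40 Hz.
   Zero-phase filtering matters because the next stage extracts *phase*: a
   causal filter would add a frequency-dependent phase lag to every channel.

2. **Instantaneous phase.** The analytic signal of each channel is computed
   with an FFT-based Hilbert transform; its angle is the instantaneous phase
   `theta(n, t)` and its magnitude the envelope. This is only meaningful for
   band-limited signals — broadband input makes "the" instantaneous phase
   ill-defined, which is why filtering precedes it.

3. **Dynamic phase-locking (dPL) tensor.** At each retained time point the
   N × N matrix

   `dPL(n, p, t) = cos(theta(n, t) - theta(p, t))`

   is formed: 1 for perfectly aligned channel pairs, 0 for pairs 90° apart,
   −1 for opposing phases. Each slice equals `c c' + s s'` with
   `c = cos(theta)`, `s = sin(theta)`, so it is symmetric, positive
   semidefinite, and of rank at most two — which is what makes a single
   eigenvector a faithful summary.

4. **Leading eigenvectors.** For every slice the unit eigenvector `V1(t)` of
   the largest-magnitude eigenvalue is kept. Eigenvectors are defined only up
   to sign, so a deterministic convention is applied: flip so that the
   majority of elements are negative; when positive and negative counts tie,
   force the first element non-positive. The convention is idempotent and
   makes runs bit-reproducible. The sign split of `V1(t)` partitions channels
   into two phase-aligned communities.

5. **Phase-locking states.** `V1(t)` rows pooled over all subjects,
   conditions and time points are clustered with best-of-`n_init` k-means
   (Lloyd iterations, k-means++ seeding). Euclidean distance on unit-norm
   vectors is monotone in cosine distance, so plain k-means is appropriate.
   States are renumbered by descending occupancy, making "state 1 = most
   visited" stable across runs. The headline configuration uses `k = 8`;
   `scan_k()` reports inertia and silhouette across a range of k but makes no
   automatic selection, since k is a resolution parameter rather than an
   estimand.

6. **State statistics and inference.** Per subject and condition the package
   computes fractional occupancy, mean dwell time (runs truncate at epoch
   boundaries) and empirical transition probabilities. Conditions are
   compared per state with a Welch t statistic and a permutation null
   (default 10,000 permutations). The default scheme is *paired*: each
   subject's A/B pair is swapped with probability ½, matching a
   within-subject design in which every participant experienced both
   conditions; an unpaired full-reshuffle scheme is available for
   between-group designs. P-values use the add-one correction
   `p = (1 + #{|t_null| >= |t_obs|}) / (n_perm + 1)`, which keeps them valid
   (never zero) at finite permutation counts, and are Benjamini–Hochberg
   adjusted across states. The observed statistic is computed through the
   same vectorised code path as the null draws, so the identity permutation
   compares exactly equal — without this, last-bit rounding differences can
   make the test anti-conservative.

7. **Graph metrics.** Time-averaged `|dPL|` gives a static connectivity
   matrix (a phase-locking-value-style quantity in [0, 1]). It is thresholded
   either absolutely (keep pairs above 0.2, the default) or proportionally
   (keep the strongest 20% of pairs), and the resulting graphs are compared
   between conditions on mean connectivity, average clustering coefficient,
   characteristic path length, mean degree and greedy modularity, with
   Bonferroni adjustment over the metrics tested. Path length is reported as
   `NaN` for disconnected graphs — a real outcome at conservative thresholds
   — and such records are excluded from that metric's test with the exclusion
   counted, rather than imputed.

8. **Classification.** A compact 1D convolutional network
   (Conv1D(64, kernel 3, ReLU) → MaxPool(2) → Dropout(0.5) → Flatten →
   Dense(100, ReLU) → Dense(1, sigmoid); Adam on binary cross-entropy, at
   most 10 epochs, batch 10, 20% validation split, patience-5 early stopping
   with best-weight restoration) classifies condition per time point from one
   of three feature sets: raw channel values, flattened dPL slices, or
   leading eigenvectors. The network is written directly in R (im2col
   convolution and hand-derived backpropagation, verified against finite
   differences in the test suite) because no deep-learning backend is
   available in the target environment. Features are standardised with
   training-split statistics only, and the default train/test split is
   *group-aware*: whole subjects go to one side, so accuracy measures
   generalisation to unseen subjects rather than within-subject
   interpolation.

## The synthetic generator

Real multichannel EEG is not available to a self-contained package, so
validation rests on a generator with known ground truth. Each subject ×
condition epoch draws a hidden state sequence from a Markov chain; each state
assigns channels to phase-aligned communities whose phase offsets are equally
spaced on [0, π); every channel's phase advances at the carrier rate plus its
community offset plus von Mises jitter, and the signal is `cos(phase)` plus
Gaussian amplitude noise. Condition B multiplies one designated state's
self-transition probability by `occupancy_boost`, so the two conditions share
a state repertoire and differ only in how much time they spend in that state —
an occupancy effect confined to a single state, which is exactly the effect
class the inference stage is built to detect.

Two generator details are deliberate:

* **Unequal (60/40) communities.** With two equal-size communities at
  orthogonal offsets, the planted phase-locking matrix has a *degenerate*
  leading eigenvalue and `V1(t)` is undefined — clustering then sees
  arbitrary vectors. The default partitions split the montage 60/40 with a
  state-specific rotation, keeping the spectrum simple and each state's
  eigenvector signature well defined.

* **Block-persistent states.** States switch only every `state_step` samples
  (50 ms at the default rates), so a state persists over several carrier
  cycles — without this, "occupancy" at the sample level would be dominated
  by switching transients.

What the generator does **not** emulate: volume conduction and sensor mixing,
1/f background spectra, artifacts (blinks, muscle), non-stationary amplitude
dynamics, or spatially realistic electrode covariance. It is a validation
harness for the *pipeline's* correctness and sensitivity, not a forward model
of EEG.

## Numerical choices

* **Edge trimming.** The FFT Hilbert transform assumes periodicity, so phase
  estimates are distorted near epoch edges. The pipeline trims one carrier
  period per edge by default (`sampling_rate / carrier_freq` samples, or one
  period of the band centre when the carrier is unknown).
* **Eigendecomposition.** `eigen(symmetric = TRUE)` per slice; the leading
  eigenvector is selected by largest *magnitude* eigenvalue. The test suite
  cross-checks this against the general dense solver.
* **Determinism.** A single run seed is hashed into per-stage seeds
  (`derive_seed`), so changing the draw count of one stage never perturbs
  another stage's random stream; identical configurations give byte-identical
  summaries.
* **Serialisation.** All artifacts are text (TSV/JSON); epoch matrices are
  written with 17 significant digits so TSV round trips are bit-identical.
  A minimal 16-bit EDF writer/reader is included for interoperability, with
  physical scaling bounds widened before header rounding so that quantisation
  stays within one 16-bit step. Configuration files use JSON rather than a
  TOML dialect because a JSON parser is available as a package dependency
  while a TOML parser is not.

## Worked example

A small end-to-end run (sizes chosen to keep the vignette fast; the defaults
emulate a 47-subject, 64-channel study):

```{r pipeline, eval = FALSE}
cfg <- run_config(
  synth = synth_config(n_subjects = 8, n_channels = 8, n_samples = 1500,
                       n_states = 3, boost_state = 3, occupancy_boost = 4,
                       seed = 1),
  decimate = 5, k = 3, n_init = 10, n_perm = 2000,
  clf = cnn_config(conv_filters = 16, dense_units = 32, epochs = 5),
  clf_seeds = 1, seed = 1)
summary <- run_pipeline(cfg, out_dir = "leida_demo", verbose = TRUE)
summary$occupancy_tests
```

The run directory then contains `epochs/`, `eigenvectors/`,
`state_model.json`, the occupancy/dwell/transition tables,
`occupancy_tests.tsv`, the graph comparison, the classifier comparison and a
machine-readable `summary.json` carrying a hash of the configuration.

Individual stages compose just as well without the orchestrator:

```{r stages, eval = FALSE}
d <- generate_dataset(synth_config(n_subjects = 4, n_channels = 8,
                                   n_samples = 1000, n_states = 3, seed = 2))
eigs <- lapply(d$epochs, function(e) {
  ph <- instantaneous_phase(bandpass_filter(e, 1, 40))
  leading_eigenvector(compute_dpl(ph, decimate = 5, edge_samples = 50))
})
pool <- pool_eigenvectors(eigs)
model <- cluster_eigenvectors(pool, k = 3, n_init = 10, seed = 3)
metrics <- compute_state_metrics(model, pool, sampling_rate = 500,
                                 decimate = 5)
permutation_test(occupancy_contrast(metrics), n_perm = 2000, seed = 4)
```

## Statistical design decisions, summarised

* Welch (unequal-variance) t statistics throughout: occupancies and graph
  metrics have no reason to share variances across conditions, and Welch
  costs essentially nothing relative to Student's t.
* Paired permutation as the default scheme, because the designs this pipeline
  targets are within-subject.
* Benjamini–Hochberg across states (a discovery problem over a state
  repertoire), Bonferroni across graph metrics (few, confirmatory tests).
* No automatic k selection; k is configuration, with `scan_k()` for
  diagnostics.
* Group-aware classifier splits by default, so reported accuracy is
  subject-generalising.
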