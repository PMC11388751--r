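---
title: "ecgarr: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgarr: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgarr)
```

## The problem and the pipeline

Ventricular tachycardia (VT), premature ventricular contractions (PVC) and
ST-segment changes are arrhythmias whose signatures — rate, QRS width,
ectopy, ST-level shifts — alter the shape of the ECG. `ecgarr` implements a
detection pipeline that treats each fixed-length epoch of signal as one
sample: epochs are decimated 1-in-20, embedded into a low-dimensional
space by a nonlinear manifold method, optionally pruned to an informative
subset by a metaheuristic selector, and classified against normal sinus
rhythm (NSR) by one of seven two-class rules, with optional hyperparameter
tuning. Every stage is seeded, so a pipeline run is a pure function of its
configuration.

Epoch conventions follow the source recordings: arrhythmia classes use
360-sample epochs at 360 Hz, NSR uses 128-sample epochs at 128 Hz; both
are one second of signal. Epochs are contiguous, non-overlapping slices —
nothing in the epoch-count bookkeeping suggests R-peak-centred alignment,
so contiguous slicing is used and recorded in the `provenance` field of
every epoch matrix.

## The synthetic generator

Real archived recordings are deliberately not required: the generator
(`generate_synthetic_ecg()`) emulates the class structure the pipeline
needs rather than clinical realism. Each epoch is a beat train built from
Gaussian bumps (P wave, Q/R/S complex, T wave) with:

* class-specific rate — 75 bpm (NSR, ST), 80 bpm (PVC), 190 bpm (VT);
* class-specific morphology — VT is wide-complex, large-amplitude and
  P-free (its QRS bumps are widened several-fold, matching the
  near-sinusoidal appearance of real VT); PVC epochs contain one wide,
  inverted ectopic beat; ST epochs carry a raised plateau between the S
  and T waves;
* per-epoch variability — ±5% rate jitter, ±10% log-normal amplitude
  jitter, a uniform phase, and additive Gaussian noise with baseline
  standard deviation 0.25 (in R-wave units) multiplied by a per-epoch
  log-normal factor (sdlog 0.5), so a minority of epochs are heavily
  artifact-corrupted as in ambulatory data.

The noise heterogeneity is what gives the selection stage something real
to do: Fisher-ratio selection preferentially discards the artifact
epochs. The parameters were fixed so that the generator satisfies its
design contract — a plain linear discriminant on per-epoch mean and
variance separates VT from NSR at ≥ 90% held-out accuracy — while leaving
the harder pairs (PVC, ST vs NSR) genuinely difficult. What passing tests
on this generator do **not** show is performance on real recordings:
morphology here is stylized, there is no baseline wander, electrode noise
is white, and inter-patient variability is absent.

## Dimensionality reduction

Three embeddings are implemented from their definitions:

* **LLE** — `k = 12` neighbours by default, local Gram systems solved with
  a regularizer of `1e-3` times the Gram trace (collinear neighbourhoods
  are otherwise singular; with `reg = 0` such inputs are rejected with
  advice). Embedding coordinates are scaled so their sample covariance is
  the identity; eigenvector signs are fixed by making the first nonzero
  entry positive.
* **Diffusion maps** — Gaussian kernel width `σ` defaults to the median
  pairwise distance; the Markov matrix is diagonalized through its
  symmetric conjugate for numerical stability; coordinates are the `h`
  nontrivial eigenvectors scaled by `λᵗ` (default `t = 1`, `h = 10`). The
  trivial `λ = 1` constant eigenvector is dropped.
* **Laplacian eigenmaps** — symmetrized `m = 12`-nearest-neighbour graph
  with Gaussian weights, unnormalized Laplacian `E = P − A`, generalized
  eigenproblem solved via the `P^{-1/2}` conjugation. A disconnected
  neighbourhood graph is rejected (with component sizes) because the
  embedding is ill-defined across components.

None of the embedding parameters are prescribed by the published tables,
so the defaults above are declared package conventions, all overridable
and logged in the result's `params`.

The published epoch-count bookkeeping reduces epoch *counts* roughly
20-fold "after dimensionality reduction" while the classical algorithms
reduce feature *dimension*. The package reconciles the two by decimating
epochs first (`decimate_epoch_count()`, keep the first of every block of
20, `ceiling(n/20)` retained) and then embedding the retained epochs to
`target_dim` (default 10).

Because VT/PVC/ST epochs have 360 samples and NSR epochs 128, a joint
embedding needs a common representation: the pipeline time-normalizes
every epoch onto a 128-point grid by linear interpolation and embeds the
pooled set once. Embedding each class separately was rejected — each
class would land in its own arbitrary eigenbasis, and coordinates across
classes would not be comparable, making downstream classification
meaningless. The per-class epoch counts of the bookkeeping stage are
unaffected by this choice.

## Epoch selection

Selection is encoded as a continuous optimization over `[0, 1]^n`: within
each class the epochs holding the largest coordinates are kept, up to the
class's target count (ties to the lower index, so results are
deterministic). The objective is the negated Fisher class-separability
ratio (between-class over within-class scatter of the retained embedding
rows); a custom fitness can be supplied. The published per-class retained
counts imply class-specific retention ratios with no stated rule, so
target counts are explicit inputs, defaulting to the published ratios
(≈ 15.4% for VT, 19.8% for NSR).

The cuckoo search core keeps the published Lévy exponent `β = 0.2` and
step scale `γ = 1` as defaults. `β = 0.2` lies outside the usual
(0.3, 2) range of Mantegna-style samplers and yields extremely
heavy-tailed steps; `levy_step(warn = TRUE)` points this out. Harmony
search defaults (HS = 20, HCR = 0.9, PAR = 0.3, bw = 0.05, Vmax = 2000)
are package conventions, as none are published.

## Classifiers

The seven families share one contract: real-valued score, hard label =
`score ≥ threshold`, ties to the arrhythmia class. Completions chosen
where only densities or optimizers are published:

* **GMM / EM** classify by class-conditional log-likelihood plus log
  prior. GMM covariances are diagonal (a deliberate restriction: a larger
  set of diagonal components substitutes for full covariances). The EM
  density family supports missing feature entries through conditional-mean
  imputation alternated with re-estimation, and collapses to the
  closed-form Gaussian fit on complete data — the published derivation of
  this classifier is typographically corrupted, so this completion is a
  declared interpretation.
* **NLR** fits the saturation model `γ₁a/(γ₂+a)` (the garbled published
  expression read as a Michaelis–Menten form) to 0/1 labels along a
  1-D discriminant projection, thresholded at 0.5.
* **LR** is ridge-penalized logistic regression by IRLS; step-halving
  guarantees the penalized deviance decreases every accepted step.
* **BDLC** is a pooled-covariance linear discriminant with configurable
  priors and margin `M` (default 0, equal treatment of both classes).
* **Detrended FA** thresholds each epoch's DFA scaling exponent at the
  midpoint of the class-mean training exponents. DFA needs series much
  longer than a 10-dimensional embedding row, so the pipeline feeds this
  family the raw epoch samples instead of embedding coordinates.
* **Firefly** searches for a pair of class centroids plus a margin
  minimizing training error. Swarm moves toward brighter fireflies are
  composed pairwise in order of increasing brightness (the strongest pull
  applied last), and the randomization amplitude decays geometrically
  (damping 0.97 per sweep) so the swarm converges; the optimizer-core
  default budget is 1000 sweeps, while the classifier defaults to 200 —
  at the problem sizes the package targets the error surface is resolved
  well before that, and the budget is configurable.

## Tuning and evaluation

Tunable hyperparameters are scalars in `[0, 1]` per family (GMM: weight
tempering, mean shrinkage, variance scale; EM: variance scale; BDLC: mean
shrinkage and ridge scale; Firefly: `γ`, `α_min`, randomization amplitude,
`α₀`). Mixture means and covariances cannot literally be frozen at a tuned
scalar, so the scalars act as multipliers on the internally fitted
quantities, which keeps the scalar-in-`[0, 1]` search box meaningful.

Grid search evaluates every point of a regular grid (11 points per axis
by default, reduced so total evaluations stay within 500) by stratified
k-fold cross-validated error; ties resolve to the lexicographically
smallest tuple so the result is independent of evaluation order. Adam
uses the published constants (`l = 0.0009`, `R₁ = 0.74`, `R₂ = 0.82`,
`ε = 10⁻⁷`, 300 steps) with a secant error-rate gradient: `e/g_init` at
the first step, elementwise finite differences afterwards, and a zero
gradient for stalled coordinates instead of a division error. Tuning CV
uses a fold seed distinct from the final evaluation folds, so the
reported metrics never score the folds the tuner saw.

Evaluation is stratified 10-fold cross-validation (per-class fold counts
differ by at most 1; `k = n` degenerates to leave-one-out). Metrics are
computed from the pooled confusion matrix in exact integer arithmetic
before half-up rounding (2 decimals for the percent metrics, 4 for MCC).
The error rate is reported as the exact complement of overall accuracy,
matching how the published tables print the pair. MCC is implemented on
its true range `[-1, 1]`; the published claim that it ranges 0–1 is an
erratum. A zero MCC denominator yields 0 with a `degenerate_mcc` flag.
The published per-class target coding for MSE (recording indices as
regression targets) makes MSE incomparable across classes and is treated
as a reporting artifact; the package compares scores against 0/1-coded
labels instead.

The shipped fixture `inst/extdata/printed_tables.csv` carries the
published per-configuration confusion matrices and metric values. Many
printed metric fields differ from exact recomputation in the last digit —
consistent with metrics computed before the averaged matrices were
rounded to integers — and a handful of cells are internally inconsistent
(e.g. one PVC row whose entries sum to 445 epochs instead of 444, and one
block whose perfect confusion matrix contradicts its printed 76% accuracy).
The test suite therefore asserts exactly the fields that recompute
consistently and tracks the remainder against an independent
exact-arithmetic oracle.

## Problem sizes

The default pipeline scale — 1200 generated epochs per class, 60 per
class after decimation, embedding dimension 10, 10-fold evaluation — was
chosen so a full dimensionality-reduction-by-classifier grid runs in
minutes on a laptop while every stage still has enough data to behave
like its full-scale counterpart. Heavier optimizer budgets (cuckoo 500
iterations, harmony 2000 improvisations, firefly 1000 sweeps) are kept at
their published or conventional values where the published work states
them.

## Known limitations

* The synthetic generator is stylized; headline accuracies on the real
  archived recordings are not reproducible from this package alone, and
  the embedding/selection/classifier settings behind them are not
  published.
* The pipeline embeds all epochs before cross-validation (as the source
  methodology does), so the embedding itself is transductive; fold
  isolation applies to classifier fitting and tuning only.
* Out-of-sample embedding extensions (Nyström), multiclass decision
  rules, and probability calibration are out of scope.
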