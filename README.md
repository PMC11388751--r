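# ecgarr

Detection of cardiac arrhythmias — ventricular tachycardia (VT), premature
ventricular contraction (PVC) and ST-segment change (ST) — against normal
sinus rhythm (NSR) from fixed-length ECG epochs, for researchers studying
how nonlinear dimensionality reduction, metaheuristic feature selection and
hyperparameter tuning interact in arrhythmia classification pipelines.

The package implements the full pipeline as a tested R library with a thin
command-line interface:

1. **Epoching** — continuous recordings are sliced into non-overlapping
   epochs (360 samples at 360 Hz for the arrhythmia classes, 128 samples at
   128 Hz for NSR); a seeded synthetic generator provides ECG-like epochs
   with class-specific morphology when real recordings are not available.
2. **Epoch decimation** — each class is thinned 1-in-20
   (`ceiling(n / 20)`), mapping the segmented per-class counts
   43333 / 57778 / 84000 / 141750 to 2167 / 2889 / 4200 / 7088.
3. **Nonlinear dimensionality reduction** — locally linear embedding
   (reconstruction weights `w` with `sum(w) = 1` per neighbourhood, bottom
   eigenvectors of `(I-W)'(I-W)`), diffusion maps (row-stochastic Markov
   kernel `b = a / rowSums(a)` with Gaussian `a_kl = exp(-d²/2σ²)`,
   coordinates `λᵢᵗ ψᵢ`), and Laplacian eigenmaps (generalized problem
   `E x = λ P x` on the graph Laplacian `E = P − A`).
4. **Metaheuristic epoch selection** — cuckoo search with Lévy flights
   (`f(t+1) = f(t) + γ ⊕ Lévy(β)`, discovery probability `fa`) and harmony
   search (memory considering rate HCR, pitch adjusting rate PAR,
   bandwidth bw), both maximizing a Fisher class-separability ratio of the
   retained subset.
5. **Seven classifiers** — diagonal-covariance Gaussian mixtures (EM),
   an EM-fitted Gaussian density supporting missing entries, nonlinear
   saturation regression `g(a) = γ₁a/(γ₂+a)`, ridge-penalized logistic
   regression, a Bayesian linear discriminant (`s_m(g) − s_n(g) ≥ M`),
   detrended fluctuation analysis (scaling-exponent thresholding), and a
   firefly-swarm discriminant (attractiveness `α₀ e^{−βp²}`).
6. **Tuning** — exhaustive grid search over `[0, 1]` hyperparameter boxes
   scored by 10-fold cross-validated error, and Adam
   (`l = 0.0009, R₁ = 0.74, R₂ = 0.82, ε = 10⁻⁷`) driven by a secant
   approximation of the error-rate gradient.
7. **Evaluation** — stratified 10-fold cross-validation, confusion
   matrices, and OA / ER / GDR / F1 / MCC / MSE, where
   `GDR = ((TP+TN)−FP)/((TP+TN)+FN)·100` and
   `MCC = (TP·TN−FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.

## Worked example

```r
library(ecgarr)

# metric suite from a published confusion matrix
metrics_from_confusion(list(tp = 1275, tn = 4080, fp = 3008, fn = 892))
#> <metrics_record> OA=57.86% ER=42.14% GDR=37.57% F1=39.53% MCC=0.1393

# one full pipeline cell on synthetic data:
# LLE embedding + harmony-search selection + GMM + Adam tuning
res <- run_pipeline(pipeline_config(
  pair = "VT", dr = "LLE", selector = "HSO", classifier = "gmm",
  tuner = "adam", seed = 1,
  selector_config = list(max_iter = 400),
  tuner_config = list(max_iter = 20)))
res[, c("OA", "F1", "GDR", "MCC", "ER")]
#>     OA    F1   GDR    MCC  ER
#>   97.5 97.56 97.44 0.9512 2.5
```

The OA of 97.5% means that after harmony-search selection kept the most
separable 40 epochs and Adam nudged the mixture hyperparameters, 39 of the
40 retained epochs were classified correctly under 10-fold
cross-validation; the same cell without selection and tuning scores
87.5% on the same seed, illustrating the gain the selection and tuning
stages contribute.

The command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ecgarr.R", package = "ecgarr"))')
Rscript $CLI simulate --class VT --n-epochs 100 --seed 1 --out vt.csv
Rscript $CLI reduce --method lle --in vt.csv --dim 10 --out emb.csv
Rscript $CLI metrics --cm 1275,4080,3008,892
Rscript $CLI run --pair VT --dr LLE --classifier gmm --seed 1 --out results.csv
```

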