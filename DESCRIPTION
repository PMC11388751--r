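Package: ecgarr
Title: Manifold Learning and Metaheuristic Classification of ECG Arrhythmia Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for detecting cardiac arrhythmias
    (ventricular tachycardia, premature ventricular contraction, ST change)
    against normal sinus rhythm from fixed-length ECG epochs. Provides a
    synthetic ECG epoch generator, nonlinear dimensionality reduction
    (locally linear embedding, diffusion maps, Laplacian eigenmaps),
    metaheuristic epoch selection (cuckoo search with Levy flights,
    harmony search), seven two-class decision rules (Gaussian mixture
    models, expectation-maximization density fits, nonlinear and logistic
    regression, a Bayesian linear discriminant, detrended fluctuation
    analysis, and a firefly-optimized discriminant), hyperparameter tuning
    by exhaustive grid search and by Adam driven by a secant error-rate
    gradient, stratified 10-fold cross-validation, and a full confusion
    matrix metric suite (overall accuracy, error rate, good detection
    ratio, F1 score, Matthews correlation, mean squared error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
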