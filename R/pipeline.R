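# End-to-end orchestration: simulate -> epoch -> decimate -> embed ->
# select -> (tune) -> train -> evaluate, and tabular reporting.

DR_METHODS <- c("LLE", "DM", "LE")

#' Pipeline run configuration
#'
#' Describes one cell of the evaluation grid: a disease pair, a
#' dimensionality-reduction method, an optional epoch selector, a
#' classifier family and an optional tuner, plus the synthetic-data scale
#' and a global seed that fixes every stochastic component.
#'
#' @param pair one of `"VT"`, `"PVC"`, `"ST"` (always vs NSR)
#' @param dr `"LLE"`, `"DM"` or `"LE"`
#' @param selector `"none"`, `"CS"` or `"HSO"`
#' @param classifier one of the seven families of [fit_classifier()]
#' @param tuner `"none"`, `"gso"` or `"adam"` (only families with a
#'   tunable set: gmm, em, bdlc, firefly)
#' @param n_epochs epochs generated per class before decimation
#'   (default 1200, i.e. 60 per class after the 1-in-20 decimation)
#' @param target_frac fraction of decimated epochs kept by the selector;
#'   defaults to the published per-class retention ratios
#'   (about 0.154 for the arrhythmia classes, 0.198 for NSR)
#' @param target_dim embedding dimension (default 10)
#' @param noise_sd generator noise level (default 0.25)
#' @param seed global seed
#' @param dr_config,selector_config,classifier_config,tuner_config
#'   optional per-module overrides
#' @param out_dir optional directory; when given, every stage artifact is
#'   written there (epochs, embedding, selection, model, metrics)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(pair = c("VT", "PVC", "ST"),
                            dr = DR_METHODS,
                            selector = c("none", "CS", "HSO"),
                            classifier = CLASSIFIER_FAMILIES,
                            tuner = c("none", "gso", "adam"),
                            n_epochs = 1200, target_frac = NULL,
                            target_dim = 10, noise_sd = 0.25, seed = 1L,
                            dr_config = list(), selector_config = list(),
                            classifier_config = list(),
                            tuner_config = list(), out_dir = NULL) {
  pair <- match.arg(pair)
  dr <- match.arg(dr)
  selector <- match.arg(selector)
  classifier <- match.arg(classifier)
  tuner <- match.arg(tuner)
  if (tuner != "none" && is.null(TUNABLE_HYPERPARAMETERS[[classifier]])) {
    stop_ecgarr("tuner '", tuner, "' requires a tunable family ",
                "(gmm, em, bdlc, firefly); got '", classifier, "'")
  }
  structure(
    list(pair = pair, dr = dr, selector = selector, classifier = classifier,
         tuner = tuner, n_epochs = n_epochs, target_frac = target_frac,
         target_dim = target_dim, noise_sd = noise_sd, seed = as.integer(seed),
         dr_config = dr_config, selector_config = selector_config,
         classifier_config = classifier_config, tuner_config = tuner_config,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# published post-selection / post-decimation retention ratios
PUBLISHED_RETENTION <- c(VT = 333 / 2167, PVC = 444 / 2889, ST = 778 / 4200,
                         NSR = 1406 / 7088)

# Linear-interpolation resampling of each row onto a common length
# (time-normalization across sampling rates).
resample_rows <- function(m, len) {
  if (ncol(m) == len) return(m)
  t(apply(m, 1, function(r) {
    stats::approx(seq(0, 1, length.out = length(r)), r,
                  xout = seq(0, 1, length.out = len))$y
  }))
}

embed_with <- function(method, epochs, target_dim, cfg) {
  switch(method,
    LLE = lle_embed(epochs, k = cfg[["k"]] %||% 12, target_dim = target_dim,
                    reg = cfg[["reg"]] %||% 1e-3),
    DM = diffusion_map_embed(epochs, sigma = cfg[["sigma"]], t = cfg[["t"]] %||% 1,
                             h = target_dim),
    LE = laplacian_eigenmap_embed(epochs, m = cfg[["m"]] %||% 12,
                                  sigma = cfg[["sigma"]], target_dim = target_dim))
}

stage_fail <- function(stage, e) {
  stop_ecgarr("pipeline stage '", stage, "' failed: ", conditionMessage(e))
}

#' Run one pipeline cell end-to-end
#'
#' Generates synthetic epochs for the configured arrhythmia class and NSR,
#' decimates each class 1-in-20, embeds each class with the chosen
#' dimensionality-reduction method, optionally selects an epoch subset
#' with cuckoo or harmony search, optionally tunes the classifier's
#' hyperparameters (grid search or Adam, scored on a tuning fold plan
#' seeded separately from the final evaluation), trains the classifier and
#' evaluates it by stratified 10-fold cross-validation. Identical
#' configurations (including the seed) reproduce the result bit for bit.
#'
#' @param config a [pipeline_config()]
#' @return a one-row data.frame (class `pipeline_result`) with the cell
#'   key, the pooled confusion counts and `OA`, `F1`, `GDR`, `MCC`, `ER`,
#'   `MSE`; the full stage objects are attached as the `"stages"`
#'   attribute
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_ecgarr("config must come from pipeline_config()")
  }
  seed <- config[["seed"]]
  # --- simulate + epoch ---------------------------------------------------
  em_pos <- tryCatch(
    generate_synthetic_ecg(synthetic_config(config[["pair"]], config[["n_epochs"]],
                                            seed = seed,
                                            noise_sd = config[["noise_sd"]])),
    error = function(e) stage_fail("simulate", e))
  em_neg <- tryCatch(
    generate_synthetic_ecg(synthetic_config("NSR", config[["n_epochs"]],
                                            seed = seed + 1000L,
                                            noise_sd = config[["noise_sd"]])),
    error = function(e) stage_fail("simulate", e))
  # --- decimate -----------------------------------------------------------
  dec_pos <- decimate_epochs(em_pos)
  dec_neg <- decimate_epochs(em_neg)
  # --- embed --------------------------------------------------------------
  # epoch lengths differ across classes (360 vs 128 samples); each epoch is
  # time-normalized to a common 128-point grid so the pooled set shares one
  # embedding space
  common_len <- 128L
  pooled <- rbind(resample_rows(dec_pos$data, common_len),
                  resample_rows(dec_neg$data, common_len))
  labels <- c(dec_pos$labels, dec_neg$labels)
  emb <- tryCatch(
    embed_with(config[["dr"]], pooled, config[["target_dim"]],
               config[["dr_config"]]),
    error = function(e) stage_fail("embed", e))
  coords <- emb$coords
  n_pos_rows <- nrow(dec_pos$data)
  raw <- list(pos = dec_pos$data, neg = dec_neg$data)
  # --- select -------------------------------------------------------------
  sel <- NULL
  if (config[["selector"]] != "none") {
    frac <- config[["target_frac"]]
    targets <- c(
      round((frac %||% PUBLISHED_RETENTION[[config[["pair"]]]]) * n_pos_rows),
      round((frac %||% PUBLISHED_RETENTION[["NSR"]]) * (nrow(coords) - n_pos_rows)))
    targets <- pmax(targets, 20L) # keep enough epochs for 10-fold CV
    names(targets) <- c(config[["pair"]], "NSR")
    sel <- tryCatch(
      select_epochs(coords, labels, selector = config[["selector"]],
                    target_counts = targets,
                    config = config[["selector_config"]], seed = seed + 2L),
      error = function(e) stage_fail("select", e))
    keep <- sel$kept_ids
  } else {
    keep <- seq_along(labels)
  }
  x <- coords[keep, , drop = FALSE]
  y <- labels[keep]
  if (config[["classifier"]] == "dfa") {
    # DFA needs long series; classify the raw (variable-rate) epochs
    n_pos <- nrow(raw$pos)
    x <- NULL
    x_list <- c(lapply(seq_len(n_pos), function(i) raw$pos[i, ]),
                lapply(seq_len(nrow(raw$neg)), function(i) raw$neg[i, ]))
    min_len <- min(ncol(raw$pos), ncol(raw$neg))
    x <- t(vapply(x_list, function(r) r[seq_len(min_len)], numeric(min_len)))
    x <- x[keep, , drop = FALSE]
  }
  # --- tune ---------------------------------------------------------------
  cls_cfg <- config[["classifier_config"]]
  cls_cfg$positive <- config[["pair"]]
  cls_cfg$seed <- seed + 3L
  tuned_info <- NULL
  if (config[["tuner"]] == "gso") {
    tc <- config[["tuner_config"]]
    gs <- tryCatch(
      grid_search(config[["classifier"]],
                  grid_spec(points = tc[["points"]] %||% 5,
                            folds = tc[["folds"]] %||% 10,
                            gso_max_iter = tc[["gso_max_iter"]] %||% 500),
                  x, y, config = cls_cfg, seed = seed + 4L),
      error = function(e) stage_fail("tune", e))
    cls_cfg$tuned <- as.list(gs$best)
    tuned_info <- gs
  } else if (config[["tuner"]] == "adam") {
    tc <- config[["tuner_config"]]
    ad <- tryCatch(
      adam_tune(config[["classifier"]], x, y, config = cls_cfg,
                max_iter = tc[["max_iter"]] %||% 30, folds = tc[["folds"]] %||% 10,
                seed = seed + 4L),
      error = function(e) stage_fail("tune", e))
    cls_cfg$tuned <- as.list(ad$best)
    tuned_info <- ad
  }
  # --- evaluate (fresh fold seed, distinct from the tuning folds) ---------
  ev <- tryCatch(
    cv_evaluate(x, y, config[["classifier"]], cls_cfg, k = 10, seed = seed + 5L),
    error = function(e) stage_fail("evaluate", e))
  row <- data.frame(
    pair = paste0(config[["pair"]], "-vs-NSR"), dr = config[["dr"]],
    selector = config[["selector"]], classifier = config[["classifier"]],
    tuner = config[["tuner"]], n_train = length(y),
    tp = ev$confusion$tp, tn = ev$confusion$tn, fp = ev$confusion$fp,
    fn = ev$confusion$fn,
    OA = ev$metrics$OA, F1 = ev$metrics$F1, GDR = ev$metrics$GDR,
    MCC = ev$metrics$MCC, ER = ev$metrics$ER, MSE = ev$mse,
    seed = seed, stringsAsFactors = FALSE
  )
  class(row) <- c("pipeline_result", class(row))
  attr(row, "stages") <- list(selection = sel, tuning = tuned_info,
                              evaluation = ev)
  if (!is.null(config[["out_dir"]])) write_pipeline_artifacts(config, row, list(
    epochs_pos = em_pos, epochs_neg = em_neg, coords = coords,
    labels = labels, keep = keep))
  row
}

write_pipeline_artifacts <- function(config, row, stages) {
  dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  write_epoch_matrix(stages$epochs_pos,
                     file.path(config[["out_dir"]], "epochs_arrhythmia.csv"))
  write_epoch_matrix(stages$epochs_neg,
                     file.path(config[["out_dir"]], "epochs_nsr.csv"))
  emb <- data.frame(label = stages$labels, stages$coords)
  utils::write.csv(emb, file.path(config[["out_dir"]], "embedding.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(kept_id = stages$keep),
                   file.path(config[["out_dir"]], "selected.csv"),
                   row.names = FALSE)
  report_results(row, file.path(config[["out_dir"]], "metrics.csv"))
  invisible(NULL)
}

#' Run a grid of pipeline cells
#'
#' Convenience wrapper running [run_pipeline()] over the cartesian product
#' of the supplied settings and row-binding the results.
#'
#' @param pairs,drs,selectors,classifiers,tuners vectors of settings
#' @param ... forwarded to [pipeline_config()]
#' @return a results data.frame, one row per cell
#' @export
run_pipeline_grid <- function(pairs = "VT", drs = DR_METHODS,
                              selectors = "none", classifiers = "gmm",
                              tuners = "none", ...) {
  grid <- expand.grid(pair = pairs, dr = drs, selector = selectors,
                      classifier = classifiers, tuner = tuners,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- pipeline_config(pair = grid$pair[i], dr = grid$dr[i],
                           selector = grid$selector[i],
                           classifier = grid$classifier[i],
                           tuner = grid$tuner[i], ...)
    res <- run_pipeline(cfg)
    attr(res, "stages") <- NULL
    res
  })
  do.call(rbind, out)
}

#' Write a results table to CSV
#'
#' @param results a results data.frame from [run_pipeline()] /
#'   [run_pipeline_grid()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
report_results <- function(results, path) {
  if (nrow(results) < 1) stop_ecgarr("results table is empty")
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [report_results()]
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
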