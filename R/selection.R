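# Epoch subset selection driven by a metaheuristic optimizer.

# Fisher class-separability ratio of a feature matrix under binary labels:
# trace of between-class scatter over trace of within-class scatter.
fisher_ratio <- function(x, labels) {
  x <- as.matrix(x)
  classes <- unique(labels)
  if (length(classes) < 2) return(0)
  grand <- colMeans(x)
  between <- 0
  within <- 0
  for (cl in classes) {
    rows <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    between <- between + nrow(rows) * sum((mu - grand)^2)
    within <- within + sum(sweep(rows, 2, mu)^2)
  }
  if (within <= .Machine$double.eps) return(Inf)
  between / within
}

# Decode a continuous position in [0,1]^n into per-class kept indices:
# within each class, the target_count largest coordinates win, ties broken
# toward the lower index.
decode_selection <- function(position, labels, target_counts) {
  kept <- integer(0)
  for (cl in names(target_counts)) {
    ids <- which(labels == cl)
    k <- target_counts[[cl]]
    ord <- ids[order(-position[ids], ids)]
    kept <- c(kept, ord[seq_len(k)])
  }
  sort(kept)
}

#' Select an informative epoch subset
#'
#' Encodes a per-epoch inclusion preference as a continuous vector in
#' `[0, 1]^n`, decoded by keeping, within each class, the epochs with the
#' largest coordinates up to that class's target count (ties toward the
#' lower index). Cuckoo search (`"CS"`) or harmony search (`"HSO"`)
#' minimizes the negated Fisher class-separability ratio of the retained
#' subset, so the kept epochs are the ones that make the two classes most
#' separable in the embedding space.
#'
#' @param embedding an `embedding_result` or coordinate matrix
#' @param labels per-row class labels
#' @param selector `"CS"` or `"HSO"`
#' @param target_counts named integer vector of kept counts per class;
#'   each must not exceed that class's available epochs
#' @param fitness objective to minimize over kept subsets; defaults to the
#'   negative Fisher ratio. Receives `(coords_kept, labels_kept)`.
#' @param config optional list of optimizer settings overriding the
#'   defaults of [cuckoo_search_minimize()] / [harmony_search_minimize()]
#'   (e.g. `max_iter`, `n_nests`, `hs`, `seed`)
#' @param seed RNG seed (overridden by `config[["seed"]]` if present)
#' @return a `selected_features` object: `kept_ids` (unique, sorted),
#'   `fitness_trace` (best-so-far, non-increasing), `selector`, `config`
#' @export
select_epochs <- function(embedding, labels, selector = c("CS", "HSO"),
                          target_counts, fitness = NULL, config = list(),
                          seed = 1L) {
  selector <- match.arg(selector)
  coords <- if (inherits(embedding, "embedding_result")) {
    embedding$coords
  } else {
    as.matrix(embedding)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) {
    stop_ecgarr("labels must have one entry per embedding row")
  }
  if (is.null(names(target_counts)) ||
      !all(names(target_counts) %in% labels)) {
    stop_ecgarr("target_counts must be named by class labels present in `labels`")
  }
  avail <- table(labels)
  for (cl in names(target_counts)) {
    if (target_counts[[cl]] < 1 || target_counts[[cl]] > avail[[cl]]) {
      stop_ecgarr("infeasible target count for class ", cl, ": ",
                  target_counts[[cl]], " requested, ", avail[[cl]], " available")
    }
  }
  n <- nrow(coords)
  seed <- config[["seed"]] %||% seed
  fitness <- fitness %||% function(x, lab) -fisher_ratio(x, lab)
  objective <- function(position) {
    kept <- decode_selection(position, labels, target_counts)
    fitness(coords[kept, , drop = FALSE], labels[kept])
  }
  res <- if (selector == "CS") {
    cuckoo_search_minimize(
      objective, dim = n,
      n_nests = config[["n_nests"]] %||% 25, fa = config[["fa"]] %||% 0.25,
      gamma = config[["gamma"]] %||% 1, beta = config[["beta"]] %||% 0.2,
      max_iter = config[["max_iter"]] %||% 150, seed = seed)
  } else {
    harmony_search_minimize(
      objective, dim = n,
      hs = config[["hs"]] %||% 20, hcr = config[["hcr"]] %||% 0.9,
      par = config[["par"]] %||% 0.3, bw = config[["bw"]] %||% 0.05,
      v_max = config[["max_iter"]] %||% 2000, seed = seed)
  }
  kept <- decode_selection(res$par, labels, target_counts)
  structure(
    list(kept_ids = kept, fitness_trace = res$trace, selector = selector,
         config = c(config, list(seed = seed, target_counts = target_counts))),
    class = "selected_features"
  )
}

#' @export
print.selected_features <- function(x, ...) {
  cat("<selected_features> ", x$selector, ": kept ", length(x$kept_ids),
      " epochs; final fitness ",
      signif(x$fitness_trace[length(x$fitness_trace)], 6), "\n", sep = "")
  invisible(x)
}
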