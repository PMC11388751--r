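# Per-class statistical descriptor panel: moments, correlation, entropies.

#' Rényi entropy of a discrete distribution
#'
#' \eqn{H_\alpha(p) = \frac{1}{1-\alpha}\ln \sum_i p_i^\alpha} in nats.
#'
#' @param probabilities non-negative weights summing to 1 (within 1e-6)
#' @param alpha entropy order; `alpha > 0`, `alpha != 1`
#' @return Rényi entropy in nats
#' @examples
#' renyi_entropy(rep(1 / 8, 8), 2) # log(8)
#' @export
renyi_entropy <- function(probabilities, alpha = 2) {
  if (any(probabilities < 0)) stop_ecgarr("probabilities must be non-negative")
  if (abs(sum(probabilities) - 1) > 1e-6) {
    stop_ecgarr("probabilities must sum to 1 (got ", sum(probabilities), ")")
  }
  if (alpha <= 0 || alpha == 1) stop_ecgarr("alpha must be > 0 and != 1")
  p <- probabilities[probabilities > 0]
  log(sum(p^alpha)) / (1 - alpha)
}

#' Approximate entropy
#'
#' ApEn(m, r) of a sequence: the negative average log conditional
#' probability that runs of length `m` that match within tolerance `r`
#' (Chebyshev distance, self-matches included) still match at length
#' `m + 1`. Regular sequences score near 0; i.i.d. noise scores high.
#'
#' @param x numeric sequence (length >= m + 2)
#' @param m embedding window (default 2)
#' @param r match tolerance; defaults to `0.2 * sd(x)`
#' @return approximate entropy in nats (0 when the sequence is constant)
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 1) stop_ecgarr("ApEn needs length >= m + 1 (got ", n, ")")
  if (is.na(r) || r == 0) {
    if (stats::sd(x) == 0 || is.na(stats::sd(x))) return(0) # constant sequence
    stop_ecgarr("tolerance r must be > 0")
  }
  # pairwise template matches under the Chebyshev metric, vectorized:
  # windows match iff every offset's samples are within r
  close_pairs <- abs(outer(x, x, `-`)) <= r
  phi <- function(mm) {
    nv <- n - mm + 1
    match_mat <- matrix(TRUE, nv, nv)
    for (j in 0:(mm - 1)) {
      idx <- seq_len(nv) + j
      match_mat <- match_mat & close_pairs[idx, idx]
    }
    mean(log(rowSums(match_mat) / nv))
  }
  phi(m) - phi(m + 1)
}

#' Permutation entropy
#'
#' Shannon entropy (nats) of the distribution of ordinal patterns of
#' length `order` (ties broken by position, unit delay by default).
#' A monotone sequence has a single pattern, hence entropy 0; the maximum
#' is `log(factorial(order))`.
#'
#' @param x numeric sequence
#' @param order pattern length (default 3)
#' @param delay lag between pattern elements (default 1)
#' @return permutation entropy in nats
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x) - (order - 1) * delay
  if (n < 1) stop_ecgarr("PeEn needs length >= (order - 1) * delay + 1")
  pats <- vapply(seq_len(n), function(i) {
    idx <- i + delay * (seq_len(order) - 1)
    paste(order(x[idx]), collapse = "")
  }, character(1))
  p <- table(pats) / n
  -sum(p * log(p))
}

#' Full statistical descriptor panel for one sequence
#'
#' Computes the nine descriptors reported per class: mean, standard
#' deviation, variance, skewness, excess kurtosis, Pearson correlation
#' coefficient (lag-1 autocorrelation unless a companion sequence is
#' supplied), approximate entropy, Rényi entropy (over a 16-bin equal-width
#' histogram) and permutation entropy. The entropy parameters used are
#' recorded alongside the results.
#'
#' @param values numeric sequence
#' @param companion optional second sequence for the Pearson correlation;
#'   when `NULL` the lag-1 autocorrelation of `values` is used
#' @param apen_m,apen_r ApEn embedding window and tolerance
#'   (defaults m = 2, r = 0.2 sd)
#' @param renyi_alpha Rényi order (default 2)
#' @param renyi_bins histogram bins for the Rényi estimate (default 16)
#' @param pe_order,pe_delay permutation-entropy order and delay
#' @param max_entropy_samples cap on the subsequence length used for the
#'   (quadratic-cost) approximate entropy (default 2000); moments and the
#'   other descriptors always use the full sequence
#' @return a `stat_summary` list with fields `mu`, `sigma`, `sigma2`,
#'   `skew`, `C` (excess kurtosis), `PCC`, `ApEn`, `ReEn`, `PeEn` and
#'   `params`
#' @export
describe <- function(values, companion = NULL, apen_m = 2,
                     apen_r = 0.2 * stats::sd(values), renyi_alpha = 2,
                     renyi_bins = 16, pe_order = 3, pe_delay = 1,
                     max_entropy_samples = 2000) {
  x <- as.numeric(values)
  need <- max(apen_m + 1, (pe_order - 1) * pe_delay + 1)
  if (length(x) < need) {
    stop_ecgarr("sequence of length ", length(x), " is too short: ",
                "ApEn needs >= ", apen_m + 1, " and PeEn needs >= ",
                (pe_order - 1) * pe_delay + 1)
  }
  mu <- mean(x)
  sigma <- stats::sd(x)
  xc <- x - mu
  skew <- if (sigma > 0) mean(xc^3) / (sqrt(mean(xc^2)))^3 else 0
  kurt <- if (sigma > 0) mean(xc^4) / (mean(xc^2))^2 - 3 else 0
  pcc <- if (!is.null(companion)) {
    stats::cor(x, as.numeric(companion))
  } else if (sigma > 0) {
    stats::cor(x[-length(x)], x[-1])
  } else 0
  if (sigma > 0) {
    br <- seq(min(x), max(x), length.out = renyi_bins + 1)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = renyi_bins)
    reen <- renyi_entropy(cnt / sum(cnt), renyi_alpha)
  } else {
    reen <- 0
  }
  structure(
    list(mu = mu, sigma = sigma, sigma2 = stats::var(x), skew = skew,
         C = kurt, PCC = pcc,
         ApEn = if (sigma > 0) {
           approximate_entropy(x[seq_len(min(length(x), max_entropy_samples))],
                               apen_m, apen_r)
         } else 0,
         ReEn = reen,
         PeEn = permutation_entropy(x, pe_order, pe_delay),
         params = list(apen_m = apen_m, apen_r = apen_r,
                       renyi_alpha = renyi_alpha, renyi_bins = renyi_bins,
                       pe_order = pe_order, pe_delay = pe_delay)),
    class = "stat_summary"
  )
}

#' Per-class descriptor table for an epoch matrix
#'
#' Applies [describe()] to the pooled samples of each class and reports the
#' class-level Pearson correlation coefficient as the mean correlation
#' between consecutive epochs' sample vectors within the class.
#'
#' @param epochs an [epoch_matrix()] (or an embedding coordinate matrix
#'   with a `labels` vector)
#' @param labels per-row labels; taken from `epochs` when it is an
#'   `epoch_matrix`
#' @param ... passed to [describe()]
#' @return a data.frame with one row per class and one column per
#'   descriptor (`mu`, `sigma`, `sigma2`, `skew`, `C`, `PCC`, `ApEn`,
#'   `ReEn`, `PeEn`)
#' @export
describe_epochs <- function(epochs, labels = NULL, ...) {
  if (inherits(epochs, "epoch_matrix")) {
    labels <- epochs$labels
    m <- epochs$data
  } else {
    m <- as.matrix(epochs)
    if (is.null(labels) || length(labels) != nrow(m)) {
      stop_ecgarr("labels must be given with one entry per row")
    }
  }
  out <- lapply(unique(labels), function(cl) {
    rows <- which(labels == cl)
    s <- describe(as.numeric(t(m[rows, , drop = FALSE])), ...)
    pcc <- if (length(rows) >= 2) {
      mean(vapply(seq_len(length(rows) - 1), function(i) {
        stats::cor(m[rows[i], ], m[rows[i + 1], ])
      }, numeric(1)))
    } else NA_real_
    data.frame(class = cl, mu = s$mu, sigma = s$sigma, sigma2 = s$sigma2,
               skew = s$skew, C = s$C, PCC = pcc, ApEn = s$ApEn,
               ReEn = s$ReEn, PeEn = s$PeEn)
  })
  do.call(rbind, out)
}
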