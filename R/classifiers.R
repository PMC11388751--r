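# Seven two-class decision rules with a uniform fit/predict contract.
# Scores are real-valued (log-likelihood ratio, fitted probability, or
# discriminant value); hard label = score >= family threshold, with ties
# broken toward the positive (arrhythmia) class.

CLASSIFIER_FAMILIES <- c("gmm", "em", "nlr", "lr", "bdlc", "dfa", "firefly")

check_binary_input <- function(x, y, allow_na = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ok <- if (allow_na) all(is.finite(x) | is.na(x)) else all(is.finite(x))
  if (!ok) stop_ecgarr("features must be finite")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop_ecgarr("labels must match feature rows")
  lev <- unique(y)
  if (length(lev) != 2) {
    stop_ecgarr("exactly two classes required (got ",
                paste(lev, collapse = ", "), ")")
  }
  list(x = x, y = y, levels = lev)
}

positive_level <- function(levels, positive = NULL) {
  if (!is.null(positive)) {
    if (!positive %in% levels) stop_ecgarr("positive class not present in labels")
    return(positive)
  }
  non_nsr <- setdiff(levels, "NSR")
  if (length(non_nsr) == 1) non_nsr else levels[1]
}

#' Fit a two-class arrhythmia classifier
#'
#' Uniform entry point over the seven decision-rule families:
#' \describe{
#'   \item{`gmm`}{per-class diagonal-covariance Gaussian mixtures fitted by
#'     expectation-maximization; classifies by class-conditional
#'     log-likelihood plus log prior.}
#'   \item{`em`}{per-class single Gaussian density (diagonal) estimated by
#'     an EM loop that supports missing feature entries (`NA`); reduces to
#'     the closed-form Gaussian fit with complete data.}
#'   \item{`nlr`}{nonlinear (saturation) regression
#'     \eqn{g(a) = \gamma_1 a / (\gamma_2 + a)} of the 0/1 label on a
#'     1-D discriminant projection; threshold 0.5.}
#'   \item{`lr`}{ridge-penalized logistic regression fitted by
#'     iteratively reweighted least squares with step halving;
#'     threshold 0.5 on the fitted probability.}
#'   \item{`bdlc`}{Bayesian linear discriminant with pooled covariance and
#'     configurable priors and decision margin `M`.}
#'   \item{`dfa`}{thresholds the detrended-fluctuation scaling exponent of
#'     each feature row at the midpoint of the class-mean exponents.}
#'   \item{`firefly`}{firefly-swarm search for a pair of class centroids
#'     and a margin minimizing training error.}
#' }
#'
#' @param x numeric feature matrix (rows = epochs); for `dfa` the rows
#'   should be raw sample series long enough for the configured scales
#' @param y two-level label vector
#' @param family one of `r paste0('"', CLASSIFIER_FAMILIES, '"', collapse = ", ")`
#' @param config family-specific settings (see Details); common entries:
#'   `positive` (positive class; default the non-NSR level), `seed`,
#'   `tuned` (named tunable scalars in `[0, 1]`, see [grid_search()])
#' @return an `ecg_classifier` object with a [predict.ecg_classifier()]
#'   method
#' @export
fit_classifier <- function(x, y, family = CLASSIFIER_FAMILIES,
                           config = list()) {
  family <- match.arg(family)
  # the EM density family tolerates missing feature entries at fit time
  inp <- check_binary_input(x, y, allow_na = (family == "em"))
  pos <- positive_level(inp$levels, config[["positive"]])
  neg <- setdiff(inp$levels, pos)
  fitter <- switch(family, gmm = fit_gmm, em = fit_emgauss, nlr = fit_nlr,
                   lr = fit_lr, bdlc = fit_bdlc, dfa = fit_dfa,
                   firefly = fit_firefly)
  model <- fitter(inp$x, inp$y, pos, neg, config)
  structure(
    c(model,
      list(family = family, positive = pos, negative = neg,
           n_features = ncol(inp$x), config = config)),
    class = c(paste0("ecgarr_", family), "ecg_classifier")
  )
}

#' Predict from a fitted classifier
#'
#' @param object an `ecg_classifier`
#' @param newdata feature matrix with the training feature dimension
#' @param ... unused
#' @return data.frame with `score` (real-valued decision score) and
#'   `label`; `label` is the positive class whenever
#'   `score >= threshold` (ties go to the arrhythmia class)
#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (object$family != "dfa" && ncol(x) != object$n_features) {
    stop_ecgarr("feature dimension mismatch: model trained on ",
                object$n_features, " features, got ", ncol(x))
  }
  score <- classifier_score(object, x)
  data.frame(
    score = score,
    label = ifelse(score >= object$threshold, object$positive, object$negative),
    stringsAsFactors = FALSE
  )
}

classifier_score <- function(object, x) UseMethod("classifier_score")

# ---------------------------------------------------------------------------
# Gaussian mixture model (diagonal covariances, EM)

# EM for a diagonal-covariance Gaussian mixture; k-means initialization.
# Log-likelihood is non-decreasing across iterations (EM guarantee).
fit_diag_mixture <- function(x, n_components, max_iter, tol, seed) {
  n <- nrow(x)
  d <- ncol(x)
  k <- min(n_components, n)
  with_seed(seed, {
    if (k > 1) {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 3))
      mu <- km$centers
      assign <- km$cluster
    } else {
      mu <- matrix(colMeans(x), 1, d)
      assign <- rep(1L, n)
    }
    w <- as.numeric(table(factor(assign, levels = seq_len(k)))) / n
    var0 <- apply(x, 2, stats::var)
    var0[var0 < 1e-8] <- 1e-8
    sig <- matrix(rep(var0, each = k), k, d)
    loglik <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      logd <- sapply(seq_len(k), function(j) {
        -0.5 * colSums((t(x) - mu[j, ])^2 / sig[j, ]) -
          0.5 * sum(log(2 * pi * sig[j, ])) + log(w[j])
      })
      logd <- matrix(logd, n, k)
      mx <- apply(logd, 1, max)
      ll <- sum(mx + log(rowSums(exp(logd - mx))))
      resp <- exp(logd - mx - log(rowSums(exp(logd - mx))))
      nk <- colSums(resp)
      w <- nk / n
      w <- w / sum(w)
      for (j in seq_len(k)) {
        if (nk[j] < 1e-10) next
        mu[j, ] <- colSums(resp[, j] * x) / nk[j]
        sig[j, ] <- colSums(resp[, j] * sweep(x, 2, mu[j, ])^2) / nk[j]
        sig[j, sig[j, ] < 1e-8] <- 1e-8
      }
      trace <- c(trace, ll)
      if (is.finite(loglik) && ll - loglik < tol) break
      loglik <- ll
    }
    list(weights = w, means = mu, vars = sig, loglik_trace = trace)
  })
}

mixture_loglik <- function(mix, x) {
  k <- length(mix$weights)
  logd <- sapply(seq_len(k), function(j) {
    -0.5 * colSums((t(x) - mix$means[j, ])^2 / mix$vars[j, ]) -
      0.5 * sum(log(2 * pi * mix$vars[j, ])) + log(max(mix$weights[j], 1e-300))
  })
  logd <- matrix(logd, nrow(x), k)
  mx <- apply(logd, 1, max)
  mx + log(rowSums(exp(logd - mx)))
}

# tuned scalars: beta_k tempering toward uniform weights (neutral 1),
# mu_k shrink of component means toward the class mean (neutral 1),
# sigma_k variance scale (neutral 0.5, multiplier 2 * sigma_k).
apply_gmm_tuning <- function(mix, tuned) {
  if (!is.null(tuned[["beta_k"]])) {
    k <- length(mix$weights)
    w <- tuned[["beta_k"]] * mix$weights + (1 - tuned[["beta_k"]]) / k
    mix$weights <- w / sum(w)
  }
  if (!is.null(tuned[["mu_k"]])) {
    centre <- colSums(mix$weights * mix$means)
    mix$means <- matrix(rep(centre, each = nrow(mix$means)),
                        nrow(mix$means)) +
      tuned[["mu_k"]] * sweep(mix$means, 2, centre)
  }
  if (!is.null(tuned[["sigma_k"]])) {
    mix$vars <- mix$vars * max(2 * tuned[["sigma_k"]], 0.05)
  }
  mix
}

fit_gmm <- function(x, y, pos, neg, config) {
  ncomp <- config[["n_components"]] %||% 2
  max_iter <- config[["max_iter"]] %||% 100
  tol <- config[["tol"]] %||% 1e-8
  seed <- config[["seed"]] %||% 1L
  tuned <- config[["tuned"]] %||% list()
  mix_pos <- apply_gmm_tuning(
    fit_diag_mixture(x[y == pos, , drop = FALSE], ncomp, max_iter, tol, seed),
    tuned)
  mix_neg <- apply_gmm_tuning(
    fit_diag_mixture(x[y == neg, , drop = FALSE], ncomp, max_iter, tol, seed + 1L),
    tuned)
  list(mix_pos = mix_pos, mix_neg = mix_neg,
       log_prior = log(mean(y == pos) / mean(y == neg)),
       threshold = config[["threshold"]] %||% 0)
}

classifier_score.ecgarr_gmm <- function(object, x) {
  mixture_loglik(object$mix_pos, x) - mixture_loglik(object$mix_neg, x) +
    object$log_prior
}

# ---------------------------------------------------------------------------
# EM Gaussian density classifier (supports missing entries)

# Single diagonal Gaussian per class; missing entries are handled by an
# EM loop that alternates conditional-mean imputation (E) with parameter
# re-estimation (M). With complete data one pass gives the closed form.
fit_gauss_missing <- function(x, max_iter = 50, tol = 1e-8) {
  xx <- x
  miss <- is.na(xx)
  for (j in seq_len(ncol(xx))) {
    col_mean <- mean(xx[, j], na.rm = TRUE)
    xx[miss[, j], j] <- col_mean
  }
  mu <- colMeans(xx)
  v <- apply(xx, 2, function(c) mean((c - mean(c))^2))
  if (any(miss)) {
    for (it in seq_len(max_iter)) {
      for (j in seq_len(ncol(xx))) xx[miss[, j], j] <- mu[j]
      mu_new <- colMeans(xx)
      # E[ (x - mu)^2 ] adds the conditional variance v for missing entries
      v_new <- colMeans(sweep(xx, 2, mu_new)^2) + colMeans(miss) * v
      if (max(abs(mu_new - mu)) + max(abs(v_new - v)) < tol) {
        mu <- mu_new; v <- v_new
        break
      }
      mu <- mu_new
      v <- v_new
    }
  }
  v[v < 1e-8] <- 1e-8
  list(mean = mu, var = v)
}

fit_emgauss <- function(x, y, pos, neg, config) {
  tuned <- config[["tuned"]] %||% list()
  g_pos <- fit_gauss_missing(x[y == pos, , drop = FALSE])
  g_neg <- fit_gauss_missing(x[y == neg, , drop = FALSE])
  if (!is.null(tuned[["K"]])) {
    s <- max(2 * tuned[["K"]], 0.05) # neutral at K = 0.5
    g_pos$var <- g_pos$var * s
    g_neg$var <- g_neg$var * s
  }
  list(g_pos = g_pos, g_neg = g_neg,
       log_prior = log(mean(y == pos) / mean(y == neg)),
       threshold = config[["threshold"]] %||% 0)
}

gauss_loglik <- function(g, x) {
  -0.5 * colSums((t(x) - g$mean)^2 / g$var) - 0.5 * sum(log(2 * pi * g$var))
}

classifier_score.ecgarr_em <- function(object, x) {
  gauss_loglik(object$g_pos, x) - gauss_loglik(object$g_neg, x) +
    object$log_prior
}

# ---------------------------------------------------------------------------
# Nonlinear (saturation) regression

fit_nlr <- function(x, y, pos, neg, config) {
  y01 <- as.numeric(y == pos)
  mu_pos <- colMeans(x[y == pos, , drop = FALSE])
  mu_neg <- colMeans(x[y == neg, , drop = FALSE])
  w <- mu_pos - mu_neg
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) w <- rep(1 / sqrt(length(w)), length(w)) else w <- w / nw
  a_raw <- drop(x %*% w)
  shift <- min(a_raw)
  scale <- max(a_raw) - shift
  if (scale < 1e-12) scale <- 1
  a <- 0.05 + (a_raw - shift) / scale # strictly positive regressor
  df <- data.frame(a = a, y = y01)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ g1 * a / (g2 + a), data = df,
                      start = list(g1 = 1.5, g2 = stats::median(a)),
                      lower = c(1e-6, 1e-6), upper = c(100, 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # coarse grid fallback for degenerate responses
    grid <- expand.grid(g1 = c(0.5, 1, 1.5, 2, 4),
                        g2 = stats::quantile(a, c(.1, .25, .5, .75, .9)))
    sse <- apply(grid, 1, function(g) sum((y01 - g[1] * a / (g[2] + a))^2))
    gamma <- as.numeric(grid[which.min(sse), ])
  } else {
    gamma <- stats::coef(fit)
  }
  resid <- y01 - gamma[1] * a / (gamma[2] + a)
  list(gamma1 = gamma[1], gamma2 = gamma[2], projection = w,
       shift = shift, scale = scale, sigma2 = mean(resid^2),
       threshold = config[["threshold"]] %||% 0.5)
}

classifier_score.ecgarr_nlr <- function(object, x) {
  a <- 0.05 + (drop(x %*% object$projection) - object$shift) / object$scale
  object$gamma1 * a / (object$gamma2 + a)
}

# ---------------------------------------------------------------------------
# Logistic regression (ridge-penalized IRLS with step halving)

fit_lr <- function(x, y, pos, neg, config) {
  y01 <- as.numeric(y == pos)
  alpha <- config[["alpha"]] %||% 0.01
  max_iter <- config[["max_iter"]] %||% 50
  xm <- cbind(1, x) # f_m0 = 1 intercept convention
  p <- ncol(xm)
  pen <- c(0, rep(alpha, p - 1)) # intercept unpenalized
  gamma <- rep(0, p)
  dev_fn <- function(g) {
    eta <- drop(xm %*% g)
    # -2 * penalized log-likelihood
    2 * sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y01 * eta) +
      sum(pen * g^2)
  }
  dev <- dev_fn(gamma)
  dev_trace <- dev
  for (it in seq_len(max_iter)) {
    eta <- drop(xm %*% gamma)
    mu <- 1 / (1 + exp(-eta))
    wts <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(t(xm) %*% (mu - y01)) + pen * gamma
    hess <- t(xm) %*% (wts * xm) + diag(pen, p)
    delta <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- gamma - step * delta
      dc <- dev_fn(cand)
      if (dc < dev || step < 1e-8) break
      step <- step / 2 # step halving keeps the penalized deviance decreasing
    }
    if (dc >= dev) break
    gamma <- cand
    dev <- dc
    dev_trace <- c(dev_trace, dev)
    if (length(dev_trace) > 1 &&
        abs(diff(utils::tail(dev_trace, 2))) < 1e-10) break
  }
  list(gamma = gamma, alpha = alpha, deviance = dev, dev_trace = dev_trace,
       threshold = config[["threshold"]] %||% 0.5)
}

classifier_score.ecgarr_lr <- function(object, x) {
  1 / (1 + exp(-drop(cbind(1, x) %*% object$gamma)))
}

# ---------------------------------------------------------------------------
# Bayesian linear discriminant (pooled covariance)

fit_bdlc <- function(x, y, pos, neg, config) {
  tuned <- config[["tuned"]] %||% list()
  mu_pos <- colMeans(x[y == pos, , drop = FALSE])
  mu_neg <- colMeans(x[y == neg, , drop = FALSE])
  n_pos <- sum(y == pos)
  n_neg <- sum(y == neg)
  d <- ncol(x)
  s_pos <- stats::cov(x[y == pos, , drop = FALSE])
  s_neg <- stats::cov(x[y == neg, , drop = FALSE])
  pooled <- ((n_pos - 1) * s_pos + (n_neg - 1) * s_neg) / (n_pos + n_neg - 2)
  eps <- config[["eps"]] %||% 1e-6
  if (!is.null(tuned[["eps_scale"]])) eps <- eps * max(2 * tuned[["eps_scale"]], 0.05)
  if (!is.null(tuned[["mu_scale"]])) {
    grand <- (n_pos * mu_pos + n_neg * mu_neg) / (n_pos + n_neg)
    mu_pos <- grand + tuned[["mu_scale"]] * (mu_pos - grand)
    mu_neg <- grand + tuned[["mu_scale"]] * (mu_neg - grand)
  }
  pooled <- pooled + diag(eps * mean(diag(pooled)) + 1e-12, d)
  priors <- config[["priors"]] %||% c(n_pos, n_neg) / (n_pos + n_neg)
  inv <- solve(pooled)
  list(mu_pos = mu_pos, mu_neg = mu_neg, pooled = pooled, inv = inv,
       priors = priors, threshold = config[["M"]] %||% 0)
}

classifier_score.ecgarr_bdlc <- function(object, x) {
  disc <- function(mu, prior) {
    -0.5 * colSums((t(x) - mu) * (object$inv %*% (t(x) - mu))) + log(prior)
  }
  disc(object$mu_pos, object$priors[1]) - disc(object$mu_neg, object$priors[2])
}

# ---------------------------------------------------------------------------
# Detrended fluctuation analysis

#' Detrended-fluctuation scaling exponent
#'
#' Classic DFA: build the cumulative (integrated) profile of the
#' mean-centred series, split it into non-overlapping segments of each
#' scale `u` (taken from both ends to use the whole series), remove a
#' polynomial trend of the given order per segment, and regress the log
#' root-mean-square fluctuation `k(u)` on `log(u)`. White noise scores
#' about 0.5, a random walk about 1.5.
#'
#' @param series numeric series (length >= 4 * max(scales))
#' @param scales strictly increasing segment lengths, each >= order + 2;
#'   at least 4 scales. Default: a logarithmic ladder from 4 to
#'   `length(series) / 4`.
#' @param order polynomial detrending order (default 1)
#' @return list with `exponent`, `scales`, `fluctuation` (the `k(u)`
#'   values, all non-negative)
#' @export
dfa_exponent <- function(series, scales = NULL, order = 1) {
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(4), log(max(n %/% 4, 5)),
                                   length.out = 10))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4) stop_ecgarr("need at least 4 scales")
  if (any(scales < order + 2)) {
    stop_ecgarr("every scale must be >= order + 2")
  }
  if (max(scales) > n) stop_ecgarr("scale ", max(scales),
                                   " exceeds series length ", n)
  prof <- cumsum(x - mean(x))
  fluct <- vapply(scales, function(u) {
    nseg <- n %/% u
    tt <- seq_len(u)
    design <- outer(tt, 0:order, `^`)
    sq <- numeric(0)
    for (p in list(prof, rev(prof))) { # both ends, so no samples are wasted
      for (j in seq_len(nseg)) {
        seg <- p[((j - 1) * u + 1):(j * u)]
        sq <- c(sq, mean(stats::lm.fit(design, seg)$residuals^2))
      }
    }
    sqrt(mean(sq))
  }, numeric(1))
  fit <- stats::lm(log(fluct) ~ log(scales))
  list(exponent = unname(stats::coef(fit)[2]), scales = scales,
       fluctuation = fluct)
}

fit_dfa <- function(x, y, pos, neg, config) {
  order <- config[["order"]] %||% 1
  scales <- config[["scales"]]
  expo <- apply(x, 1, function(r) dfa_exponent(r, scales, order)$exponent)
  m_pos <- mean(expo[y == pos])
  m_neg <- mean(expo[y == neg])
  list(order = order, scales = scales,
       midpoint = (m_pos + m_neg) / 2,
       direction = if (m_pos >= m_neg) 1 else -1,
       threshold = 0)
}

classifier_score.ecgarr_dfa <- function(object, x) {
  expo <- apply(x, 1, function(r) {
    dfa_exponent(r, object$scales, object$order)$exponent
  })
  object$direction * (expo - object$midpoint)
}

# ---------------------------------------------------------------------------
# Firefly-optimized centroid discriminant

firefly_decision_score <- function(x, c_pos, c_neg, margin) {
  d_neg <- sqrt(colSums((t(x) - c_neg)^2))
  d_pos <- sqrt(colSums((t(x) - c_pos)^2))
  d_neg - d_pos - margin
}

fit_firefly <- function(x, y, pos, neg, config) {
  d <- ncol(x)
  tuned <- config[["tuned"]] %||% list()
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- pmax(hi - lo, 1e-12)
  y01 <- y == pos
  decode <- function(par) {
    list(c_pos = lo + par[seq_len(d)] * span,
         c_neg = lo + par[d + seq_len(d)] * span,
         margin = (par[2 * d + 1] - 0.5) * 2 * max(span))
  }
  objective <- function(par) {
    p <- decode(par)
    sc <- firefly_decision_score(x, p$c_pos, p$c_neg, p$margin)
    mean((sc >= 0) != y01)
  }
  res <- firefly_optimize(
    objective, dim = 2 * d + 1,
    n = config[["n"]] %||% 40,
    alpha0 = tuned[["alpha0"]] %||% config[["alpha0"]] %||% 1,
    alpha_min = tuned[["alpha_min"]] %||% config[["alpha_min"]] %||% 0,
    beta = config[["beta"]] %||% 1,
    gamma = tuned[["gamma"]] %||% config[["gamma"]] %||% 0.5,
    rand_scale = tuned[["rand"]] %||% config[["rand_scale"]] %||% 1,
    damping = config[["damping"]] %||% 0.97,
    max_iter = config[["max_iter"]] %||% 200,
    seed = config[["seed"]] %||% 1L)
  p <- decode(res$par)
  c(p, list(trace = res$trace, train_error = res$value, threshold = 0))
}

classifier_score.ecgarr_firefly <- function(object, x) {
  firefly_decision_score(x, object$c_pos, object$c_neg, object$margin)
}
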