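# Hyperparameter tuning: exhaustive grid search scored by cross-validated
# error, and Adam driven by a secant approximation of the error-rate
# gradient. All tuned hyperparameters are scalars restricted to [0, 1].

# Tunable hyperparameter sets per family (scalar multipliers in [0, 1]
# applied to internally fitted quantities; see fit_classifier).
TUNABLE_HYPERPARAMETERS <- list(
  gmm = c("beta_k", "mu_k", "sigma_k"),
  em = "K",
  bdlc = c("mu_scale", "eps_scale"),
  firefly = c("gamma", "alpha_min", "rand", "alpha0")
)

default_tunable <- function(family) {
  hp <- TUNABLE_HYPERPARAMETERS[[family]]
  if (is.null(hp)) {
    stop_ecgarr("no tunable hyperparameters defined for family '", family, "'")
  }
  stats::setNames(rep(0.5, length(hp)), hp)
}

tuning_cv_error <- function(family, data, labels, tuned, config, k, seed) {
  cfg <- config
  cfg[["tuned"]] <- as.list(tuned)
  res <- tryCatch(
    cv_evaluate(data, labels, family, cfg, k = k, seed = seed),
    error = function(e) NULL)
  if (is.null(res)) return(NA_real_) # fit failure: caller records worst score
  res$error_rate
}

#' Grid specification
#'
#' @param lower,upper per-hyperparameter limits (scalars or named vectors;
#'   default the unit interval, the selection limits used throughout)
#' @param points grid points per axis (default 11); automatically reduced
#'   so the total number of grid evaluations does not exceed
#'   `gso_max_iter`
#' @param folds cross-validation folds used for scoring (default 10)
#' @param gso_max_iter cap on total grid evaluations (default 500)
#' @return a `grid_spec` list
#' @export
grid_spec <- function(lower = 0, upper = 1, points = 11, folds = 10,
                      gso_max_iter = 500) {
  if (any(lower > upper)) stop_ecgarr("lower must be <= upper")
  if (points < 1) stop_ecgarr("need >= 1 grid point per axis")
  structure(list(lower = lower, upper = upper, points = points,
                 folds = folds, gso_max_iter = gso_max_iter),
            class = "grid_spec")
}

#' Exhaustive grid search over classifier hyperparameters
#'
#' Evaluates every point of a regular grid over the family's tunable
#' hyperparameters by stratified k-fold cross-validated error rate and
#' returns the argmin. Ties are broken by the lexicographically smallest
#' hyperparameter tuple; grid points whose fit fails are recorded with the
#' worst possible score (error 1) rather than aborting.
#'
#' @param family classifier family with tunable hyperparameters
#'   (`"gmm"`, `"em"`, `"bdlc"`, `"firefly"`)
#' @param grid a [grid_spec()]
#' @param data feature matrix
#' @param labels two-level labels
#' @param config base classifier config
#' @param seed RNG seed for folds and fits
#' @return list with `best` (named hyperparameter vector), `best_error`,
#'   and `table` (data.frame of every grid point and its CV error)
#' @export
grid_search <- function(family, grid, data, labels, config = list(),
                        seed = 1L) {
  if (!inherits(grid, "grid_spec")) stop_ecgarr("grid must be a grid_spec")
  hp <- TUNABLE_HYPERPARAMETERS[[family]]
  if (is.null(hp)) stop_ecgarr("family '", family, "' has no tunable set")
  d <- length(hp)
  lower <- rep_len(grid$lower, d)
  upper <- rep_len(grid$upper, d)
  points <- grid$points
  while (points > 1 && points^d > grid$gso_max_iter) points <- points - 1
  axes <- lapply(seq_len(d), function(j) {
    if (points == 1) (lower[j] + upper[j]) / 2
    else seq(lower[j], upper[j], length.out = points)
  })
  names(axes) <- hp
  pts <- do.call(expand.grid, axes)
  errs <- vapply(seq_len(nrow(pts)), function(i) {
    e <- tuning_cv_error(family, data, labels, as.numeric(pts[i, ]) |>
                           stats::setNames(hp), config, grid$folds, seed)
    if (is.na(e)) 1 else e
  }, numeric(1))
  # argmin with lexicographic tie-break on the hyperparameter tuple
  best_ids <- which(errs == min(errs))
  ord <- do.call(order, as.list(pts[best_ids, , drop = FALSE]))
  best_i <- best_ids[ord[1]]
  list(best = stats::setNames(as.numeric(pts[best_i, ]), hp),
       best_error = errs[best_i],
       table = cbind(pts, cv_error = errs))
}

#' Adam optimizer state
#'
#' Bias-corrected exponential-moving-average optimizer state with the
#' study's constants: learning rate `l = 0.0009`, decay rates
#' `R1 = 0.74`, `R2 = 0.82`, `eps = 1e-7`.
#'
#' @param par initial parameter vector
#' @param l learning rate
#' @param r1,r2 first/second-moment decay constants in (0, 1)
#' @param eps denominator stabilizer
#' @param max_iter step budget (default 300)
#' @return an `adam_state` list with zeroed moments and step count 0
#' @export
adam_state <- function(par, l = 0.0009, r1 = 0.74, r2 = 0.82, eps = 1e-7,
                       max_iter = 300) {
  if (l < 0 || r1 <= 0 || r1 >= 1 || r2 <= 0 || r2 >= 1 || eps <= 0) {
    stop_ecgarr("invalid Adam constants")
  }
  structure(list(par = as.numeric(par), m = numeric(length(par)),
                 v = numeric(length(par)), t = 0L, l = l, r1 = r1, r2 = r2,
                 eps = eps, max_iter = max_iter),
            class = "adam_state")
}

#' One Adam update
#'
#' Updates the moments `D_t = R1 D_{t-1} + (1-R1) grad` and
#' `K_t = R2 K_{t-1} + (1-R2) grad^2`, applies bias correction
#' `D_t / (1-R1^t)`, `K_t / (1-R2^t)`, and takes the step
#' `par - l / (sqrt(K_hat) + eps) * D_hat`.
#'
#' @param state an [adam_state()]
#' @param gradient finite gradient vector
#' @return the updated `adam_state`
#' @export
adam_step <- function(state, gradient) {
  if (!all(is.finite(gradient))) stop_ecgarr("gradient must be finite")
  state$t <- state$t + 1L
  state$m <- state$r1 * state$m + (1 - state$r1) * gradient
  state$v <- state$r2 * state$v + (1 - state$r2) * gradient^2
  m_hat <- state$m / (1 - state$r1^state$t)
  v_hat <- state$v / (1 - state$r2^state$t)
  state$par <- state$par - state$l / (sqrt(v_hat) + state$eps) * m_hat
  state
}

#' Secant approximation of the error-rate gradient
#'
#' At the first iteration the gradient is `e_now / g_init` per coordinate;
#' afterwards it is the finite difference
#' `(e_now - e_prev) / (g_now - g_prev)` elementwise. A coordinate whose
#' parameter has stalled (`|g_now - g_prev| < 1e-12`) gets gradient 0
#' rather than a division error.
#'
#' @param e_now,e_prev current and previous error rates (scalars)
#' @param g_now,g_prev current and previous parameter vectors
#' @param g_init initial parameter vector (used at the first iteration)
#' @param first `TRUE` at the first iteration
#' @return gradient vector
#' @export
secant_error_gradient <- function(e_now, e_prev, g_now, g_prev, g_init,
                                  first = FALSE) {
  if (first) return(e_now / g_init)
  dg <- g_now - g_prev
  out <- numeric(length(dg))
  ok <- abs(dg) >= 1e-12
  out[ok] <- (e_now - e_prev) / dg[ok]
  out
}

#' Adam hyperparameter tuning
#'
#' Iterates: evaluate the cross-validated error rate at the current
#' hyperparameters, form the secant error gradient, take one Adam step,
#' and clip back to `[0, 1]`. Returns the hyperparameters achieving the
#' minimum error seen (the trace includes the starting point, so the
#' result never exceeds the initial error).
#'
#' @param family classifier family with tunable hyperparameters
#' @param data feature matrix
#' @param labels two-level labels
#' @param init named initial hyperparameters in `[0, 1]` (default 0.5
#'   each); must be nonzero (the first secant gradient divides by them)
#' @param config base classifier config
#' @param constants list overriding `l`, `r1`, `r2`, `eps`
#' @param max_iter Adam step budget (default 300)
#' @param folds CV folds (default 10)
#' @param seed RNG seed
#' @return list with `best`, `best_error`, `trace` (data.frame of
#'   hyperparameters and error per iteration)
#' @export
adam_tune <- function(family, data, labels, init = NULL, config = list(),
                      constants = list(), max_iter = 300, folds = 10,
                      seed = 1L) {
  hp <- TUNABLE_HYPERPARAMETERS[[family]]
  if (is.null(hp)) stop_ecgarr("family '", family, "' has no tunable set")
  g <- if (is.null(init)) default_tunable(family) else {
    if (!all(hp %in% names(init))) {
      stop_ecgarr("init must name all of: ", paste(hp, collapse = ", "))
    }
    init[hp]
  }
  if (any(g < 0 | g > 1)) stop_ecgarr("initial hyperparameters must lie in [0, 1]")
  st <- adam_state(g, l = constants$l %||% 0.0009,
                   r1 = constants$r1 %||% 0.74,
                   r2 = constants$r2 %||% 0.82,
                   eps = constants$eps %||% 1e-7, max_iter = max_iter)
  g_init <- g
  e_prev <- NA_real_
  g_prev <- g
  best <- g
  best_err <- Inf
  rows <- vector("list", max_iter + 1)
  for (it in seq_len(max_iter + 1)) {
    e_now <- tuning_cv_error(family, data, labels, g, config, folds, seed)
    if (is.na(e_now)) e_now <- 1
    rows[[it]] <- c(g, error = e_now)
    if (e_now < best_err) {
      best_err <- e_now
      best <- g
    }
    if (it > max_iter) break
    grad <- secant_error_gradient(e_now, e_prev, g, g_prev, g_init,
                                  first = (it == 1))
    g_prev <- g
    e_prev <- e_now
    st <- adam_step(st, grad)
    st$par <- clip(st$par, 0, 1)
    g <- stats::setNames(st$par, hp)
  }
  list(best = best, best_error = best_err,
       trace = do.call(rbind, lapply(rows, function(r) as.data.frame(t(r)))))
}
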