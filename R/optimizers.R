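# Continuous metaheuristic optimizer cores: cuckoo search with Levy
# flights, harmony search, and the firefly swarm. All minimize a scalar
# objective over a box, are seed-deterministic, and return a best-so-far
# trace that is non-increasing by construction.

check_objective_value <- function(val, pos) {
  if (!is.finite(val)) {
    stop_ecgarr("objective returned a non-finite value at position (",
                paste(signif(pos, 6), collapse = ", "), ")")
  }
  val
}

#' Lévy-flight step sample
#'
#' Heavy-tailed random steps via the Mantegna scheme for a Lévy exponent
#' `beta`: \eqn{u / |v|^{1/\beta}} with suitably scaled Gaussian `u`, `v`.
#' The default `beta = 0.2` gives an extremely heavy tail (it lies outside
#' the usual (0.3, 2) range; a warning notes this once per call unless
#' suppressed).
#'
#' @param beta Lévy exponent (> 0)
#' @param size number of samples
#' @param warn warn when `beta` is outside (0.3, 2)
#' @return numeric vector of `size` steps
#' @export
levy_step <- function(beta = 0.2, size = 1, warn = FALSE) {
  if (beta <= 0) stop_ecgarr("beta must be > 0")
  if (warn && (beta <= 0.3 || beta >= 2)) {
    warning("Levy exponent beta = ", beta,
            " is outside the usual (0.3, 2) range; steps are very heavy-tailed")
  }
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(size, 0, sigma_u)
  v <- stats::rnorm(size)
  u / abs(v)^(1 / beta)
}

#' Cuckoo search minimization
#'
#' Population of `n_nests` candidate solutions ("nests") in
#' `[lower, upper]^dim`. Per iteration each nest proposes a Lévy-flight
#' move scaled toward the current best (`gamma` times a Lévy step times the
#' displacement from the best); the proposal greedily replaces a randomly
#' chosen nest when better; then the worst fraction `fa` of nests is
#' abandoned and redrawn uniformly.
#'
#' @param objective function of a numeric vector returning a finite scalar
#' @param dim problem dimension
#' @param n_nests population size (>= 2, default 25)
#' @param fa discovery/abandonment probability in `[0, 1]` (default 0.25)
#' @param gamma step-size scale (> 0, default 1)
#' @param beta Lévy exponent (default 0.2)
#' @param max_iter iterations (default 500)
#' @param lower,upper box bounds (scalars, default unit box)
#' @param seed RNG seed
#' @return list with `par` (best position), `value`, `trace`
#'   (best-so-far per iteration, non-increasing), and `population`
#' @export
cuckoo_search_minimize <- function(objective, dim, n_nests = 25, fa = 0.25,
                                   gamma = 1, beta = 0.2, max_iter = 500,
                                   lower = 0, upper = 1, seed = 1L) {
  if (n_nests < 2) stop_ecgarr("n_nests must be >= 2")
  if (fa < 0 || fa > 1) stop_ecgarr("fa must be in [0, 1]")
  if (gamma < 0) stop_ecgarr("gamma must be >= 0")
  with_seed(seed, {
    nests <- matrix(stats::runif(n_nests * dim, lower, upper), n_nests, dim)
    fit <- apply(nests, 1, function(p) check_objective_value(objective(p), p))
    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      best_i <- which.min(fit)
      for (i in seq_len(n_nests)) {
        step <- gamma * 0.01 * levy_step(beta, dim) *
          (nests[i, ] - nests[best_i, ])
        cand <- clip(nests[i, ] + step, lower, upper)
        j <- sample.int(n_nests, 1)
        fc <- check_objective_value(objective(cand), cand)
        if (fc < fit[j]) {
          nests[j, ] <- cand
          fit[j] <- fc
        }
      }
      n_abandon <- floor(fa * n_nests)
      if (n_abandon > 0) {
        worst <- order(fit, decreasing = TRUE)[seq_len(n_abandon)]
        keep_best <- which.min(fit)
        worst <- setdiff(worst, keep_best)
        for (w in worst) {
          nests[w, ] <- stats::runif(dim, lower, upper)
          fit[w] <- check_objective_value(objective(nests[w, ]), nests[w, ])
        }
      }
      trace[it] <- min(fit, if (it > 1) trace[it - 1] else Inf)
    }
    best_i <- which.min(fit)
    list(par = nests[best_i, ], value = fit[best_i], trace = trace,
         population = nests)
  })
}

#' Harmony search minimization
#'
#' Harmony memory of `hs` solution vectors. Each improvisation draws every
#' decision variable from memory with probability `hcr` (then perturbs it
#' by `± bw * r` with probability `par`), otherwise uniformly at random
#' within bounds. The improvisation replaces the worst memory member only
#' when better.
#'
#' @param objective function of a numeric vector returning a finite scalar
#' @param dim problem dimension
#' @param hs harmony memory size (>= 2, default 20)
#' @param hcr harmony memory considering rate in `[0, 1]` (default 0.9)
#' @param par pitch adjusting rate in `[0, 1]` (default 0.3)
#' @param bw pitch bandwidth in decision-variable units (default 0.05)
#' @param v_max maximum improvisations (default 2000); with `v_max = 0`
#'   the best initial memory member is returned unchanged
#' @param lower,upper per-variable bounds (scalars or length-`dim`)
#' @param seed RNG seed
#' @return list with `par`, `value`, `trace` (best-so-far per
#'   improvisation), `memory`, and `worst_trace`
#' @export
harmony_search_minimize <- function(objective, dim, hs = 20, hcr = 0.9,
                                    par = 0.3, bw = 0.05, v_max = 2000,
                                    lower = 0, upper = 1, seed = 1L) {
  if (hs < 2) stop_ecgarr("harmony memory size must be >= 2")
  if (hcr < 0 || hcr > 1 || par < 0 || par > 1) {
    stop_ecgarr("HCR and PAR must be in [0, 1]")
  }
  if (bw <= 0) stop_ecgarr("bandwidth bw must be > 0")
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop_ecgarr("lower bounds must not exceed upper bounds")
  with_seed(seed, {
    mem <- sapply(seq_len(dim), function(j) stats::runif(hs, lower[j], upper[j]))
    mem <- matrix(mem, nrow = hs)
    fit <- apply(mem, 1, function(p) check_objective_value(objective(p), p))
    trace <- numeric(v_max)
    worst_trace <- numeric(v_max)
    for (it in seq_len(v_max)) {
      cand <- numeric(dim)
      for (j in seq_len(dim)) {
        if (stats::runif(1) < hcr) {
          cand[j] <- mem[sample.int(hs, 1), j]
          if (stats::runif(1) < par) {
            cand[j] <- cand[j] + sample(c(-1, 1), 1) * bw * stats::runif(1)
          }
        } else {
          cand[j] <- stats::runif(1, lower[j], upper[j])
        }
      }
      cand <- clip(cand, lower, upper)
      fc <- check_objective_value(objective(cand), cand)
      worst <- which.max(fit)
      if (fc < fit[worst]) {
        mem[worst, ] <- cand
        fit[worst] <- fc
      }
      trace[it] <- min(fit)
      worst_trace[it] <- max(fit)
    }
    best <- which.min(fit)
    list(par = mem[best, ], value = fit[best], trace = trace,
         memory = mem, worst_trace = worst_trace)
  })
}

#' Firefly attractiveness
#'
#' Closed-form attractiveness \eqn{\alpha(p) = \alpha_0 e^{-\beta p^2}}
#' between two fireflies at distance `p`, with absorption coefficient
#' `beta`.
#'
#' @param p distance (>= 0)
#' @param alpha0 attractiveness at distance 0
#' @param beta absorption coefficient (>= 0)
#' @return attractiveness in `(0, alpha0]`
#' @export
firefly_attractiveness <- function(p, alpha0 = 1, beta = 1) {
  alpha0 * exp(-beta * p^2)
}

#' Firefly swarm minimization
#'
#' Each firefly's brightness is the (negated) objective. Per sweep, every
#' firefly moves toward the brighter ones with attractiveness
#' `alpha_min + (alpha0 - alpha_min) exp(-beta p^2)` (moves toward all
#' brighter fireflies are aggregated, with the total attraction capped at
#' 1 for stability) plus a randomization term
#' `gamma * (U(0,1) - 1/2) * scale` whose amplitude decays geometrically
#' (`damping` per sweep) so the swarm converges; the brightest firefly
#' performs only the damped random walk.
#'
#' @param objective function of a numeric vector returning a finite scalar
#' @param dim problem dimension
#' @param n population size (>= 2, default 40)
#' @param alpha0 attractiveness at distance 0 (default 1)
#' @param alpha_min attractiveness floor at large distance (default 0)
#' @param beta absorption coefficient (default 1)
#' @param gamma randomization weight (default 0.5)
#' @param rand_scale extra multiplier on the randomization amplitude
#'   (default 1); exposed as a tunable hyperparameter
#' @param damping per-sweep decay of the randomization amplitude
#'   (default 0.97)
#' @param max_iter sweeps (default 1000)
#' @param lower,upper box bounds (scalars)
#' @param seed RNG seed
#' @return list with `par`, `value`, `trace` (best-so-far, non-increasing)
#' @export
firefly_optimize <- function(objective, dim, n = 40, alpha0 = 1,
                             alpha_min = 0, beta = 1, gamma = 0.5,
                             rand_scale = 1, damping = 0.97, max_iter = 1000,
                             lower = 0, upper = 1, seed = 1L) {
  if (n < 2) stop_ecgarr("population must be >= 2")
  scale <- upper - lower
  with_seed(seed, {
    z <- matrix(stats::runif(n * dim, lower, upper), n, dim)
    fit <- apply(z, 1, function(p) check_objective_value(objective(p), p))
    best_par <- z[which.min(fit), ]
    best_val <- min(fit)
    trace <- numeric(max_iter)
    amp <- gamma * rand_scale
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(z))
      znew <- z
      for (m in seq_len(n)) {
        # pairwise moves toward each brighter firefly, composed in order of
        # increasing brightness so the strongest pull (toward the best) is
        # applied last; coefficients use start-of-sweep distances
        brighter <- order(fit)[seq_len(sum(fit < fit[m]))]
        pos <- z[m, ]
        if (length(brighter)) {
          brighter <- rev(brighter) # worst brighter first, brightest last
          a <- alpha_min + (alpha0 - alpha_min) * exp(-beta * d[m, brighter]^2)
          a <- clip(a, 0, 1)
          k <- length(a)
          tail_prod <- rev(cumprod(rev(c(1 - a, 1))))[-1] # prod over later moves
          w <- a * tail_prod
          pos <- prod(1 - a) * pos +
            colSums(w * z[brighter, , drop = FALSE])
        }
        rnd <- amp * (stats::runif(dim) - 0.5) * scale
        znew[m, ] <- clip(pos + rnd, lower, upper)
      }
      z <- znew
      fit <- apply(z, 1, function(p) check_objective_value(objective(p), p))
      if (min(fit) < best_val) {
        best_val <- min(fit)
        best_par <- z[which.min(fit), ]
      }
      trace[it] <- best_val
      amp <- amp * damping
    }
    list(par = best_par, value = best_val, trace = trace, population = z)
  })
}
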