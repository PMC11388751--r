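# The seven decision-rule families and their shared fit/predict contract.

test_that("GMM recovers well-separated class means and the EM guarantee holds", {
  set.seed(1)
  x <- rbind(matrix(rnorm(500, 0), ncol = 1), matrix(rnorm(500, 5), ncol = 1))
  y <- rep(c("VT", "NSR"), each = 500)
  fit <- fit_classifier(x, y, "gmm", config = list(n_components = 1, seed = 1))
  expect_lt(abs(fit$mix_pos$means[1, 1] - 0), 0.1)
  expect_lt(abs(fit$mix_neg$means[1, 1] - 5), 0.1)
  expect_equal(sum(fit$mix_pos$weights), 1, tolerance = 1e-9)

  # mixture log-likelihood is non-decreasing across EM iterations
  set.seed(2)
  xm <- rbind(matrix(rnorm(200, 0), ncol = 2), matrix(rnorm(200, 3), ncol = 2))
  ym <- rep(c("ST", "NSR"), each = 100)
  fm <- fit_classifier(xm, ym, "gmm", config = list(n_components = 3, seed = 5))
  for (mix in list(fm$mix_pos, fm$mix_neg)) {
    expect_true(all(diff(mix$loglik_trace) > -1e-6))
    expect_equal(sum(mix$weights), 1, tolerance = 1e-9)
    expect_true(all(mix$vars > 0))
  }
})

test_that("GMM separates 8-sigma classes at >= 99% held-out accuracy", {
  set.seed(3)
  tr <- make_two_clusters(200, d = 2, sep = 8, seed = 3)
  te <- make_two_clusters(200, d = 2, sep = 8, seed = 4)
  fit <- fit_classifier(tr$x, tr$y, "gmm", config = list(seed = 1))
  expect_gte(mean(predict(fit, te$x)$label == te$y), 0.99)
})

test_that("EM Gaussian classifier handles missing entries and matches the closed form", {
  set.seed(4)
  d <- make_two_clusters(150, d = 3, sep = 4, seed = 5)
  complete <- fit_classifier(d$x, d$y, "em")
  # closed form: per-class sample means
  expect_equal(complete$g_pos$mean, colMeans(d$x[d$y == "VT", ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  x_miss <- d$x
  x_miss[sample(length(x_miss), 60)] <- NA
  with_miss <- fit_classifier(x_miss, d$y, "em",
                              config = list(allow_missing = TRUE))
  expect_lt(max(abs(with_miss$g_pos$mean - complete$g_pos$mean)), 0.3)
  acc <- mean(predict(with_miss, d$x)$label == d$y)
  expect_gte(acc, 0.95)
})

test_that("logistic regression recovers generating coefficients within 3 SE", {
  set.seed(6)
  n <- 2000
  x <- cbind(rnorm(n), rnorm(n))
  beta <- c(1.5, -2.0)
  p <- 1 / (1 + exp(-(x %*% beta)))
  y <- ifelse(runif(n) < p, "VT", "NSR")
  fit <- fit_classifier(x, y, "lr", config = list(alpha = 0.01))
  # SEs from an independent fit of the same model family
  ref <- glm(I(y == "VT") ~ x, family = binomial())
  se <- summary(ref)$coefficients[2:3, "Std. Error"]
  expect_lt(abs(fit$gamma[2] - 1.5), 3 * se[1])
  expect_lt(abs(fit$gamma[3] - (-2.0)), 3 * se[2])
  # penalized deviance decreases monotonically (step-halving contract)
  expect_true(all(diff(fit$dev_trace) < 0))
})

test_that("BDLC behaves like a discriminant: chance on no-signal data, monotone in M", {
  set.seed(7)
  x <- matrix(rnorm(2000 * 2), 2000, 2) # identical class distributions
  y <- rep(c("PVC", "NSR"), each = 1000)
  fit <- fit_classifier(x, y, "bdlc")
  acc <- mean(predict(fit, x)$label == y)
  expect_lt(abs(acc - 0.5), 0.05)

  d <- make_two_clusters(100, d = 3, sep = 2, seed = 8)
  n_pos <- vapply(c(-2, -1, 0, 1, 2), function(m) {
    f <- fit_classifier(d$x, d$y, "bdlc", config = list(M = m))
    sum(predict(f, d$x)$label == "VT")
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0)) # raising M never adds positives

  # independent cross-check against a reference discriminant implementation
  f0 <- fit_classifier(d$x, d$y, "bdlc")
  ld <- MASS::lda(d$x, grouping = d$y)
  agree <- mean(predict(f0, d$x)$label ==
                  as.character(predict(ld)$class))
  expect_gte(agree, 0.98)
})

test_that("a decision-boundary tie goes to the arrhythmia class", {
  x <- rbind(c(-1, 0), c(-1, 2), c(1, 0), c(1, 2))
  y <- c("VT", "VT", "NSR", "NSR")
  fit <- fit_classifier(x, y, "bdlc")
  p <- predict(fit, rbind(c(0, 1))) # exactly equidistant midpoint
  expect_equal(p$score, 0)
  expect_equal(p$label, "VT")
})

test_that("the nonlinear saturation regression separates saturating responses", {
  set.seed(9)
  d <- make_two_clusters(200, d = 2, sep = 5, seed = 9)
  fit <- fit_classifier(d$x, d$y, "nlr")
  expect_true(is.finite(fit$gamma1) && is.finite(fit$gamma2))
  expect_gte(fit$sigma2, 0)
  expect_gte(mean(predict(fit, d$x)$label == d$y), 0.95)
})

test_that("DFA exponents match their theoretical values for noise and walks", {
  expo_noise <- vapply(1:20, function(s) {
    set.seed(s)
    dfa_exponent(rnorm(4096), order = 1)$exponent
  }, numeric(1))
  expect_lt(abs(mean(expo_noise) - 0.5), 0.1)

  expo_walk <- vapply(1:20, function(s) {
    set.seed(100 + s)
    dfa_exponent(cumsum(rnorm(4096)), order = 1)$exponent
  }, numeric(1))
  expect_lt(abs(mean(expo_walk) - 1.5), 0.15)

  res <- dfa_exponent(rnorm(512))
  expect_true(all(res$fluctuation >= 0))
  expect_error(dfa_exponent(rnorm(50), scales = c(10, 20, 30, 100)),
               "exceeds")
  expect_error(dfa_exponent(rnorm(50), scales = c(8, 12)), "4 scales")
})

test_that("the DFA classifier is exactly thresholded recomputation of exponents", {
  set.seed(10)
  x <- rbind(t(replicate(20, rnorm(256))),
             t(replicate(20, cumsum(rnorm(256)))))
  y <- rep(c("NSR", "VT"), each = 20)
  fit <- fit_classifier(x, y, "dfa", config = list(positive = "VT"))
  p <- predict(fit, x)
  # brute-force recomputation per epoch
  expo <- apply(x, 1, function(r) dfa_exponent(r, order = 1)$exponent)
  manual <- ifelse(fit$direction * (expo - fit$midpoint) >= 0, "VT", "NSR")
  expect_identical(p$label, manual)
  expect_gte(mean(p$label == y), 0.95)
})

test_that("firefly attractiveness follows its closed form and contracts the swarm", {
  expect_equal(firefly_attractiveness(0, alpha0 = 0.7), 0.7)
  p <- seq(0, 3, by = 0.1)
  a <- firefly_attractiveness(p, alpha0 = 1, beta = 2)
  expect_true(all(diff(a) < 0))
  expect_true(all(a > 0 & a <= 1))

  # gamma = 0, small beta: every firefly strictly approaches the brightest
  set.seed(11)
  res <- firefly_optimize(sphere_fn, dim = 2, n = 8, beta = 1e-6, gamma = 0,
                          max_iter = 1, lower = -1, upper = 1, seed = 11)
  init <- local({
    set.seed(11L)
    matrix(runif(8 * 2, -1, 1), 8, 2)
  })
  f0 <- apply(init, 1, sphere_fn)
  best <- which.min(f0)
  d_before <- sqrt(rowSums((init - rep(init[best, ], each = 8))^2))
  d_after <- sqrt(rowSums((res$population -
                             rep(init[best, ], each = 8))^2))
  expect_true(all(d_after[-best] < d_before[-best]))
})

test_that("the firefly classifier attains zero training error on separated clusters", {
  d <- make_two_clusters(100, d = 2, sep = 6, seed = 12)
  fit <- fit_classifier(d$x, d$y, "firefly",
                        config = list(max_iter = 100, seed = 1))
  p <- predict(fit, d$x)
  # the reported training error equals the trace value at the optimum
  expect_equal(mean(p$label != d$y), fit$train_error)
  expect_equal(fit$train_error, fit$trace[length(fit$trace)])
  expect_lte(fit$train_error, 0.02)
})

test_that("fits are seed-deterministic and reject degenerate input", {
  d <- make_two_clusters(40, d = 2, sep = 3, seed = 13)
  for (fam in c("gmm", "firefly")) {
    f1 <- fit_classifier(d$x, d$y, fam, config = list(seed = 7, max_iter = 30))
    f2 <- fit_classifier(d$x, d$y, fam, config = list(seed = 7, max_iter = 30))
    expect_identical(predict(f1, d$x)$score, predict(f2, d$x)$score)
  }
  expect_error(fit_classifier(d$x, rep("VT", 80), "gmm"), "two classes")
  xbad <- d$x
  xbad[1, 1] <- Inf
  expect_error(fit_classifier(xbad, d$y, "gmm"), "finite")
  fit <- fit_classifier(d$x, d$y, "lr")
  expect_error(predict(fit, matrix(0, 2, 5)), "dimension mismatch")
})
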