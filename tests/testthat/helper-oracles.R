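# Shared fixtures and independent oracles used across test files.

sphere_fn <- function(p) sum(p^2)

# Two well-separated Gaussian clusters in `d` dimensions.
make_two_clusters <- function(n_per_class = 50, d = 4, sep = 5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, 0), ncol = d),
             matrix(rnorm(n_per_class * d, sep), ncol = d))
  list(x = x, y = rep(c("VT", "NSR"), each = n_per_class))
}

# 2-D S-curve manifold embedded in 3-D.
make_s_curve <- function(n = 400, seed = 1) {
  set.seed(seed)
  t <- runif(n, -1.5 * pi, 1.5 * pi)
  h <- runif(n, 0, 2)
  cbind(sin(t), h, sign(t) * (cos(t) - 1))
}

# Trustworthiness of an embedding (brute-force pairwise-distance oracle):
# penalizes points that enter the embedded k-neighbourhood without being
# close in the original space.
trustworthiness_oracle <- function(x, emb, k = 10) {
  n <- nrow(x)
  dx <- as.matrix(dist(x))
  de <- as.matrix(dist(emb))
  penalty <- 0
  for (i in seq_len(n)) {
    rank_orig <- rank(dx[i, -i], ties.method = "first")
    names(rank_orig) <- setdiff(seq_len(n), i)
    nn_emb <- setdiff(order(de[i, ]), i)[seq_len(k)]
    nn_orig <- setdiff(order(dx[i, ]), i)[seq_len(k)]
    intruders <- setdiff(nn_emb, nn_orig)
    penalty <- penalty + sum(rank_orig[as.character(intruders)] - k)
  }
  1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}

# Independent metric evaluator: evaluates the textbook formulas as parsed
# strings on unrounded rationals (a separate code path from
# metrics_from_confusion).
metrics_formula_oracle <- function(tp, tn, fp, fn) {
  env <- list2env(list(TP = as.numeric(tp), TN = as.numeric(tn),
                       FP = as.numeric(fp), FN = as.numeric(fn)))
  ev <- function(s) eval(parse(text = s), env)
  list(
    OA = ev("(TN + TP) / (TN + TP + FN + FP) * 100"),
    ER = ev("(FN + FP) / (TN + TP + FN + FP) * 100"),
    GDR = ev("((TP + TN) - FP) / ((TP + TN) + FN) * 100"),
    F1 = ev("2 * TP / (2 * TP + FP + FN) * 100"),
    MCC = ev(paste0("(TP * TN - FP * FN) / ",
                    "sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))"))
  )
}

# round half-up, oracle-side duplicate kept deliberately trivial
round_hu <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
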