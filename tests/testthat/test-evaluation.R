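# Fold plans, confusion matrices, and the metric suite.

test_that("stratified folds spread each class evenly and partition all indices", {
  y <- rep(c("VT", "NSR"), each = 50)
  fp <- make_folds(y, k = 10, seed = 1)
  sizes <- lengths(fp$test_indices)
  expect_true(all(sizes == 10))
  expect_identical(sort(unlist(fp$test_indices)), seq_along(y))

  y2 <- c(rep("ST", 40), rep("NSR", 60))
  fp2 <- make_folds(y2, k = 10, seed = 2)
  for (f in fp2$test_indices) {
    expect_equal(sum(y2[f] == "ST"), 4)
    expect_equal(sum(y2[f] == "NSR"), 6)
  }

  # k = n gives leave-one-out
  y3 <- rep(c("VT", "NSR"), each = 6)
  fp3 <- make_folds(y3, k = 12, seed = 3)
  expect_true(all(lengths(fp3$test_indices) == 1))

  expect_error(make_folds(y3, k = 13), "exceeds")
  expect_error(make_folds(c(rep("VT", 3), rep("NSR", 97)), k = 10),
               "fewer than k")
  expect_identical(make_folds(y, k = 5, seed = 9)$test_indices,
                   make_folds(y, k = 5, seed = 9)$test_indices)
})

test_that("mse matches its definition and rejects mismatched lengths", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2), c(0, 0)), 2.5)
  set.seed(4)
  for (rep in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    expect_gte(mse(a, b), 0)
  }
  expect_error(mse(1:3, 1:4), "lengths differ")
})

test_that("confusion counts follow the standard 2x2 contract", {
  y <- rep(c("VT", "NSR"), each = 50)
  perfect <- confusion(y, y, positive = "VT")
  expect_equal(unclass(perfect)[c("tp", "tn", "fp", "fn")],
               list(tp = 50L, tn = 50L, fp = 0L, fn = 0L))

  inverted <- confusion(y, rev(y), positive = "VT")
  expect_equal(unclass(inverted)[c("tp", "tn", "fp", "fn")],
               list(tp = 0L, tn = 0L, fp = 50L, fn = 50L))

  y2 <- c(rep("ST", 30), rep("NSR", 70))
  allpos <- confusion(y2, rep("ST", 100), positive = "ST")
  expect_equal(unclass(allpos)[c("tp", "tn", "fp", "fn")],
               list(tp = 30L, tn = 0L, fp = 70L, fn = 0L))

  expect_error(confusion(y, c(y[-1], "XX"), positive = "VT"), "binary")
})

test_that("a perfect classifier scores 100/0/100/100/1 and degenerate MCC is flagged", {
  m <- metrics_from_confusion(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(m$OA, 100)
  expect_equal(m$ER, 0)
  expect_equal(m$GDR, 100)
  expect_equal(m$F1, 100)
  expect_equal(m$MCC, 1)
  expect_false(m$degenerate_mcc)

  # an always-wrong classifier is anti-correlated, not degenerate
  inv <- metrics_from_confusion(list(tp = 0, tn = 0, fp = 50, fn = 50))
  expect_equal(inv$MCC, -1)

  # all-negative predictions zero the TP+FP factor: flagged degenerate
  deg <- metrics_from_confusion(list(tp = 0, tn = 50, fp = 0, fn = 50))
  expect_equal(deg$MCC, 0)
  expect_true(deg$degenerate_mcc)
})

test_that("OA + ER = 100 exactly and the suite matches a formula oracle on random matrices", {
  set.seed(5)
  for (rep in 1:1000) {
    cm <- as.list(sample(0:500, 4, replace = TRUE))
    names(cm) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cm)) == 0) next
    m <- metrics_from_confusion(cm)
    expect_identical(m$OA + m$ER, 100)
    o <- metrics_formula_oracle(cm$tp, cm$tn, cm$fp, cm$fn)
    # the package rounds in exact integer arithmetic; the floating-point
    # oracle can sit a hair on the other side of a .005 boundary, so
    # compare at half-unit-in-last-place precision
    expect_lt(abs(m$OA - o$OA), 0.005 + 1e-9)
    expect_lt(abs(m$ER - o$ER), 0.005 + 1e-9)
    if (is.finite(o$GDR)) expect_lt(abs(m$GDR - o$GDR), 0.005 + 1e-9)
    if (is.finite(o$F1)) expect_lt(abs(m$F1 - o$F1), 0.005 + 1e-9)
    if (!m$degenerate_mcc) expect_lt(abs(m$MCC - o$MCC), 5e-5 + 1e-12)
    # algebraic relation: GDR <= OA * total / (TP + TN + FN)
    if (is.finite(o$GDR)) {
      total <- with(cm, tp + tn + fp + fn)
      expect_lte(o$GDR, o$OA * total / with(cm, tp + tn + fn) + 1e-9)
    }
  }
})

test_that("pooled cross-validation confusion equals the sum of fold confusions", {
  d <- make_two_clusters(40, d = 2, sep = 3, seed = 6)
  ev <- cv_evaluate(d$x, d$y, "bdlc", k = 5, seed = 1)
  fold_sum <- Reduce(function(a, b) Map(`+`, a, b),
                     lapply(ev$fold_confusions, unclass))
  expect_equal(unclass(ev$confusion)[c("tp", "tn", "fp", "fn")],
               fold_sum[c("tp", "tn", "fp", "fn")])
  expect_equal(ev$error_rate, (ev$confusion$fp + ev$confusion$fn) / 80)
  expect_gte(ev$mse, 0)
})

test_that("the shipped printed tables load with coherent epoch totals", {
  tab <- printed_reference_tables()
  expect_equal(nrow(tab), 333)
  full <- tab$selector == "none"
  expect_true(all(tab$tp[full] + tab$fn[full] %in% c(2167, 2889, 4200)))
  expect_true(all(tab$tn[full] + tab$fp[full] == 7088))
  expect_true(all(tab$oa >= 0 & tab$oa <= 100))
  expect_true(all(tab$mcc >= -1 & tab$mcc <= 1))
})
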