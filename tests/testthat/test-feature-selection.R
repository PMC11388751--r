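# Levy flights, cuckoo search, harmony search, and epoch-subset selection.

test_that("Levy steps are seeded-deterministic and heavy-tailed", {
  for (s in 1:3) {
    a <- with(list(), {set.seed(s); levy_step(0.2, 50)})
    b <- with(list(), {set.seed(s); levy_step(0.2, 50)})
    expect_identical(a, b)
  }
  kurts <- vapply(1:5, function(s) {
    set.seed(s)
    x <- levy_step(0.2, 10000)
    m <- mean(x)
    mean((x - m)^4) / mean((x - m)^2)^2 - 3
  }, numeric(1))
  expect_true(all(kurts > 3)) # far heavier-tailed than a Gaussian
  expect_error(levy_step(-1), "beta")
})

test_that("cuckoo search minimizes the sphere and keeps a monotone trace", {
  for (s in 1:5) {
    res <- cuckoo_search_minimize(sphere_fn, dim = 2, n_nests = 25,
                                  max_iter = 500, lower = -1, upper = 1,
                                  seed = s)
    expect_lt(res$value, 1e-2)
    expect_true(all(diff(res$trace) <= 0))
    expect_true(all(res$population >= -1 & res$population <= 1))
  }
})

test_that("with gamma = 0 and fa = 0 the nest population is conserved", {
  set.seed(1)
  obj <- function(p) 1 # constant objective: no greedy replacement possible
  res <- cuckoo_search_minimize(obj, dim = 3, n_nests = 10, fa = 0,
                                gamma = 0, max_iter = 20, seed = 4)
  init <- with_seed_population <- local({
    set.seed(4L)
    matrix(runif(10 * 3), 10, 3)
  })
  expect_equal(res$population, init)
  expect_true(all(res$trace == 1))
})

test_that("non-finite objectives are rejected with the offending position", {
  expect_error(
    cuckoo_search_minimize(function(p) NaN, dim = 2, max_iter = 5, seed = 1),
    "non-finite")
  expect_error(
    harmony_search_minimize(function(p) Inf * -1 + NA, dim = 2, v_max = 5,
                            seed = 1),
    "non-finite")
})

test_that("harmony search obeys its replace-worst contract and minimizes the sphere", {
  # Vmax = 0: the best member of the initial random memory is returned
  obj_calls <- new.env()
  obj_calls$n <- 0
  res0 <- harmony_search_minimize(function(p) {
    obj_calls$n <- obj_calls$n + 1
    sphere_fn(p)
  }, dim = 2, hs = 12, v_max = 0, lower = -1, upper = 1, seed = 2)
  expect_equal(obj_calls$n, 12) # only the initial memory was evaluated
  expect_equal(res0$value, min(apply(res0$memory, 1, sphere_fn)))

  for (s in 1:5) {
    res <- harmony_search_minimize(sphere_fn, dim = 2, hs = 20, hcr = 0.9,
                                   par = 0.3, v_max = 2000, lower = -1,
                                   upper = 1, seed = s)
    expect_lt(res$value, 1e-2)
    expect_true(all(diff(res$trace) <= 0))
    expect_true(all(diff(res$worst_trace) <= 0)) # replace-worst-if-better
    expect_true(all(res$memory >= -1 & res$memory <= 1))
  }
})

test_that("selection keeps exactly the requested per-class counts", {
  set.seed(9)
  n_vt <- 2167
  n_nsr <- 400
  coords <- matrix(rnorm((n_vt + n_nsr) * 3), ncol = 3)
  labels <- c(rep("VT", n_vt), rep("NSR", n_nsr))
  sel <- select_epochs(coords, labels, "CS",
                       target_counts = c(VT = 333, NSR = 100),
                       config = list(max_iter = 3, n_nests = 6), seed = 1)
  expect_equal(sum(labels[sel$kept_ids] == "VT"), 333)
  expect_equal(sum(labels[sel$kept_ids] == "NSR"), 100)
  expect_false(is.unsorted(sel$kept_ids))
  expect_equal(anyDuplicated(sel$kept_ids), 0)
  expect_true(all(diff(sel$fitness_trace) <= 0))

  # target = available: forced identity selection, either selector
  for (selr in c("CS", "HSO")) {
    sel_all <- select_epochs(coords[1:30, ], rep(c("VT", "NSR"), 15), selr,
                             target_counts = c(VT = 15, NSR = 15),
                             config = list(max_iter = 2), seed = 1)
    expect_identical(sel_all$kept_ids, 1:30)
  }

  expect_error(
    select_epochs(coords[1:30, ], rep(c("VT", "NSR"), 15), "CS",
                  target_counts = c(VT = 16, NSR = 2)),
    "infeasible")
})

test_that("selection is a pure function of its seed", {
  set.seed(10)
  coords <- matrix(rnorm(120 * 2), 120, 2)
  labels <- rep(c("ST", "NSR"), each = 60)
  s1 <- select_epochs(coords, labels, "HSO",
                      target_counts = c(ST = 20, NSR = 20),
                      config = list(max_iter = 50), seed = 33)
  s2 <- select_epochs(coords, labels, "HSO",
                      target_counts = c(ST = 20, NSR = 20),
                      config = list(max_iter = 50), seed = 33)
  expect_identical(s1$kept_ids, s2$kept_ids)
  expect_identical(s1$fitness_trace, s2$fitness_trace)
})

test_that("cuckoo selection enriches signal-carrying epochs over random choice", {
  # 10% of epochs carry the class signal; the rest are pure noise.
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 100 # per class
    n_sig <- 10
    make_class <- function(mu) {
      rbind(matrix(rnorm(n_sig * 2, mean = mu), ncol = 2),
            matrix(rnorm((n - n_sig) * 2), ncol = 2))
    }
    coords <- rbind(make_class(3), make_class(-3))
    labels <- rep(c("VT", "NSR"), each = n)
    signal_ids <- c(1:n_sig, n + 1:n_sig)
    sel <- select_epochs(coords, labels, "CS",
                         target_counts = c(VT = 10, NSR = 10),
                         config = list(max_iter = 80, n_nests = 15),
                         seed = s)
    got <- length(intersect(sel$kept_ids, signal_ids))
    expected_random <- 20 * n_sig / n # 2 signal epochs by chance
    got / expected_random
  }, numeric(1))
  expect_gte(median(ratios), 2)
})
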