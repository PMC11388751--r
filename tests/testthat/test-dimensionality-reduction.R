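# LLE, diffusion maps, Laplacian eigenmaps, and epoch-count decimation.

test_that("LLE reconstructs collinear data exactly and normalizes its weights", {
  set.seed(1)
  t <- sort(runif(50))
  dir <- rnorm(10)
  x <- outer(t, dir) # 50 points on a 1-D line in 10-D
  emb <- lle_embed(x, k = 5, target_dim = 1, reg = 1e-9)
  expect_lt(max(emb$params$reconstruction_cost), 1e-10)
  expect_lt(max(abs(rowSums(emb$params$weights) - 1)), 1e-12)
  # with no regularizer at all, the rank-deficient local system is rejected
  # with advice
  expect_error(lle_embed(x, k = 5, target_dim = 1, reg = 0), "reg")
})

test_that("LLE weight rows always sum to one and coords have identity covariance", {
  set.seed(2)
  x <- matrix(rnorm(80 * 6), 80, 6)
  emb <- lle_embed(x, k = 10, target_dim = 3)
  expect_lt(max(abs(rowSums(emb$params$weights) - 1)), 1e-12)
  expect_lt(max(abs(cov(emb$coords) - diag(3))), 1e-6)
  expect_error(lle_embed(x, k = 80, target_dim = 3), "k_neighbors")
  expect_error(lle_embed(x, k = 3, target_dim = 3), "target_dim")
})

test_that("LLE preserves S-curve neighbourhoods (trustworthiness oracle)", {
  x <- make_s_curve(400, seed = 3)
  emb <- lle_embed(x, k = 10, target_dim = 2)
  expect_gte(trustworthiness_oracle(x, emb$coords, k = 10), 0.85)
})

test_that("diffusion transition matrix is row-stochastic; coincident points coincide", {
  set.seed(4)
  x <- matrix(rnorm(40 * 5), 40, 5)
  x[7, ] <- x[23, ] # coincident pair
  emb <- diffusion_map_embed(x, h = 4)
  expect_lt(max(abs(rowSums(emb$params$transition) - 1)), 1e-12)
  expect_lt(max(abs(emb$coords[7, ] - emb$coords[23, ])), 1e-10)
})

test_that("3-point diffusion map matches a dense eigendecomposition oracle", {
  x <- matrix(c(0, 1, 2), ncol = 1) # mutual distances {1, 1, 2}
  emb <- diffusion_map_embed(x, sigma = 1, t = 1, h = 2)
  # oracle: direct dense eigendecomposition of the 3x3 Markov matrix
  a <- exp(-as.matrix(dist(x))^2 / 2)
  b <- a / rowSums(a)
  e <- eigen(b)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  vec <- Re(e$vectors)[, ord]
  vec <- apply(vec, 2, function(v) v / sqrt(sum(v^2)))
  oracle <- sweep(vec[, 2:3], 2, lam[2:3], `*`)
  for (j in 1:2) {
    diff_same <- max(abs(emb$coords[, j] - oracle[, j]))
    diff_flip <- max(abs(emb$coords[, j] + oracle[, j]))
    expect_lt(min(diff_same, diff_flip), 1e-8)
  }
})

test_that("diffusion coordinates shrink monotonically with diffusion time", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30, 4)
  norms <- vapply(1:4, function(tt) {
    max(abs(diffusion_map_embed(x, t = tt, h = 3)$coords))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("graph Laplacian has zero row sums; path graph eigenvalues are {0,1,3}", {
  a <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)) # unweighted 3-node path
  lap <- graph_laplacian(a)
  expect_true(isSymmetric(lap))
  expect_lt(max(abs(rowSums(lap))), 1e-12)
  expect_equal(sort(eigen(lap, symmetric = TRUE)$values), c(0, 1, 3),
               tolerance = 1e-10)
})

test_that("Laplacian eigenmap solves the generalized problem and drops the null vector", {
  set.seed(6)
  x <- matrix(rnorm(60 * 5), 60, 5)
  emb <- laplacian_eigenmap_embed(x, m = 8, target_dim = 3)
  # returned eigenvalues are the smallest nonzero ones
  expect_true(all(emb$params$eigenvalues > 1e-8))
  # generalized eigen residual: E x = lambda P x
  lap <- emb$params$laplacian
  p <- rowSums(emb$params$adjacency)
  for (j in 1:3) {
    v <- emb$coords[, j]
    lambda <- emb$params$eigenvalues[j]
    expect_lt(max(abs(lap %*% v - lambda * (p * v))), 1e-8)
    # orthogonal to the constant null vector in the P inner product
    expect_lt(abs(sum(p * v)), 1e-8)
  }
})

test_that("a disconnected neighbourhood graph is rejected with component sizes", {
  x <- rbind(matrix(rnorm(20 * 3), 20, 3),
             matrix(rnorm(20 * 3, mean = 1000), 20, 3))
  expect_error(laplacian_eigenmap_embed(x, m = 3, target_dim = 2),
               "disconnected.*20")
})

test_that("the embedding cost beats random orthonormal competitors", {
  set.seed(7)
  x <- matrix(rnorm(50 * 4), 50, 4)
  emb <- laplacian_eigenmap_embed(x, m = 8, target_dim = 2)
  a <- emb$params$adjacency
  ours <- laplacian_cost(emb$coords, a)
  for (rep in 1:20) {
    q <- qr.Q(qr(matrix(rnorm(50 * 2), 50, 2)))
    expect_lte(ours, laplacian_cost(q, a))
  }
})

test_that("embeddings are permutation-invariant up to rotation of coordinates", {
  set.seed(8)
  x <- matrix(rnorm(50 * 4), 50, 4)
  perm <- sample(nrow(x))
  for (method in c("lle", "dm", "le")) {
    emb1 <- switch(method,
                   lle = lle_embed(x, k = 8, target_dim = 2),
                   dm = diffusion_map_embed(x, h = 2),
                   le = laplacian_eigenmap_embed(x, m = 8, target_dim = 2))
    emb2 <- switch(method,
                   lle = lle_embed(x[perm, ], k = 8, target_dim = 2),
                   dm = diffusion_map_embed(x[perm, ], h = 2),
                   le = laplacian_eigenmap_embed(x[perm, ], m = 8, target_dim = 2))
    # compare pairwise distance matrices (rotation/sign-blind) after
    # realigning rows via the permutation
    d1 <- as.matrix(dist(emb1$coords))[perm, perm]
    d2 <- as.matrix(dist(emb2$coords))
    expect_lt(max(abs(d1 - d2)), 1e-6)
  }
})

test_that("epoch-count decimation reproduces the published bookkeeping", {
  expect_identical(decimate_epoch_count(c(43333, 57778, 84000, 141750)),
                   c(2167L, 2889L, 4200L, 7088L))
  expect_identical(decimate_epoch_count(20), 1L)
  expect_identical(decimate_epoch_count(21), 2L)
  expect_error(decimate_epoch_count(0), ">= 1")

  em <- generate_synthetic_ecg(synthetic_config("NSR", 47, seed = 1))
  dec <- decimate_epochs(em)
  expect_equal(nrow(dec$data), decimate_epoch_count(47))
  expect_equal(dec$data[2, ], em$data[21, ]) # first of each block of 20
})
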