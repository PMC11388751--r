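# Nonlinear dimensionality reduction: LLE, diffusion maps, Laplacian
# eigenmaps, plus the epoch-count decimation bookkeeping that precedes
# embedding in the pipeline.

as_feature_matrix <- function(epochs) {
  if (inherits(epochs, "epoch_matrix")) epochs$data else as.matrix(epochs)
}

# Deterministic eigenvector sign convention: first nonzero entry positive.
fix_eigen_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    nz <- which(abs(v[, j]) > 1e-12)
    if (length(nz) && v[nz[1], j] < 0) v[, j] <- -v[, j]
  }
  v
}

embedding_result <- function(coords, method, params, source_epoch_ids) {
  structure(
    list(coords = coords, method = method, params = params,
         source_epoch_ids = source_epoch_ids),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", x$method, ": ", nrow(x$coords), " points x ",
      ncol(x$coords), " dims\n", sep = "")
  invisible(x)
}

pairwise_dist <- function(x) {
  as.matrix(stats::dist(x))
}

knn_index <- function(d, k) {
  # k nearest neighbours per row of a distance matrix (self excluded)
  t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
}

#' Locally linear embedding
#'
#' Reconstructs each point from its `k` nearest neighbours with weights
#' summing to 1 (regularized local Gram system), then embeds by the bottom
#' nonconstant eigenvectors of \eqn{(I-W)^\top (I-W)}. Coordinates are
#' scaled so their sample covariance is the identity.
#'
#' @param epochs an [epoch_matrix()] or numeric matrix (rows = points)
#' @param k number of nearest neighbours (default 12; must exceed
#'   `target_dim`)
#' @param target_dim embedding dimension (default 10)
#' @param reg regularizer added to the local Gram matrix, as a fraction of
#'   its trace (default 1e-3). Set to 0 to require exactly solvable local
#'   systems.
#' @return an `embedding_result` with the reconstruction weight matrix in
#'   `params$weights` and per-point reconstruction cost in
#'   `params$reconstruction_cost`
#' @export
lle_embed <- function(epochs, k = 12, target_dim = 10, reg = 1e-3) {
  x <- as_feature_matrix(epochs)
  n <- nrow(x)
  if (k >= n) stop_ecgarr("k_neighbors (", k, ") must be < number of points (", n, ")")
  if (k < target_dim + 1) {
    stop_ecgarr("k_neighbors must be >= target_dim + 1 (got k = ", k,
                ", target_dim = ", target_dim, ")")
  }
  d <- pairwise_dist(x)
  nb <- knn_index(d, k)
  w <- matrix(0, n, n)
  cost <- numeric(n)
  for (i in seq_len(n)) {
    z <- sweep(x[nb[i, ], , drop = FALSE], 2, x[i, ]) # neighbours centred on i
    g <- z %*% t(z)
    tr <- sum(diag(g))
    if (reg > 0) {
      g <- g + diag(reg * max(tr, .Machine$double.eps), k)
    } else if (rcond(g) < .Machine$double.eps) {
      stop_ecgarr("singular local Gram matrix at point ", i,
                  "; increase `reg` to regularize the local system")
    }
    wi <- solve(g, rep(1, k))
    wi <- wi / sum(wi)
    w[i, nb[i, ]] <- wi
    cost[i] <- sum((x[i, ] - colSums(wi * x[nb[i, ], , drop = FALSE]))^2)
  }
  m <- diag(n) - w
  m <- t(m) %*% m
  e <- eigen(m, symmetric = TRUE)
  # bottom eigenvectors, dropping the constant one (smallest eigenvalue)
  idx <- seq(n - 1, by = -1, length.out = target_dim)
  v <- fix_eigen_signs(e$vectors[, idx, drop = FALSE])
  coords <- v * sqrt(n - 1) # sample covariance = identity
  embedding_result(coords, "LLE",
                   list(k_neighbors = k, target_dim = target_dim, reg = reg,
                        weights = w, reconstruction_cost = cost),
                   seq_len(n))
}

#' Diffusion map embedding
#'
#' Builds the Gaussian kernel \eqn{a_{kl} = \exp(-\|y_k-y_l\|^2 /
#' (2\sigma^2))}, row-normalizes it to a Markov transition matrix, and
#' embeds with the top `h` nontrivial eigenvectors scaled by
#' \eqn{\lambda_i^t} (the trivial constant eigenvector with
#' \eqn{\lambda = 1} is dropped).
#'
#' @param epochs an [epoch_matrix()] or numeric matrix
#' @param sigma Gaussian kernel width; defaults to the median pairwise
#'   distance
#' @param t diffusion time (positive integer, default 1)
#' @param h number of nontrivial eigenvectors retained (default 10)
#' @return an `embedding_result`; `params$transition` holds the
#'   row-stochastic matrix, `params$eigenvalues` the retained eigenvalues
#' @export
diffusion_map_embed <- function(epochs, sigma = NULL, t = 1, h = 10) {
  x <- as_feature_matrix(epochs)
  n <- nrow(x)
  if (h >= n) stop_ecgarr("h (", h, ") must be < number of points (", n, ")")
  if (t < 1) stop_ecgarr("diffusion time t must be >= 1")
  d <- pairwise_dist(x)
  if (is.null(sigma)) sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) stop_ecgarr("sigma must be > 0")
  a <- exp(-d^2 / (2 * sigma^2))
  if (all(a[upper.tri(a)] < .Machine$double.eps)) {
    warning("kernel width sigma is so small the kernel is numerically the identity")
  }
  deg <- rowSums(a)
  b <- a / deg
  # symmetric conjugate for a stable eigendecomposition:
  # S = D^{-1/2} A D^{-1/2} shares eigenvalues with B = D^{-1} A
  s <- a / sqrt(outer(deg, deg))
  e <- eigen(s, symmetric = TRUE)
  psi <- e$vectors / sqrt(deg) # right eigenvectors of B
  # normalize each so the trivial one is constant; keep unit norm otherwise
  psi <- apply(psi, 2, function(v) v / sqrt(sum(v^2)))
  psi <- fix_eigen_signs(matrix(psi, nrow = n))
  lam <- e$values
  keep <- seq(2, h + 1)
  coords <- sweep(psi[, keep, drop = FALSE], 2, lam[keep]^t, `*`)
  embedding_result(coords, "DM",
                   list(sigma = sigma, t = t, h = h, transition = b,
                        eigenvalues = lam[keep]),
                   seq_len(n))
}

#' Graph Laplacian
#'
#' Unnormalized Laplacian `E = P - A` of a symmetric (weighted) adjacency
#' matrix, where `P` is the diagonal degree matrix. Row sums of the result
#' are zero.
#'
#' @param a symmetric adjacency/weight matrix with zero diagonal
#' @return the Laplacian matrix
#' @export
graph_laplacian <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(a, tol = 1e-10)) stop_ecgarr("adjacency matrix must be symmetric")
  diag(rowSums(a)) - a
}

graph_components <- function(a) {
  # connected components of the graph with adjacency a (> 0 entries)
  n <- nrow(a)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nbrs <- which(a[v, ] > 0 & is.na(comp))
      comp[nbrs] <- cur
      queue <- c(queue, nbrs)
    }
  }
  comp
}

#' Laplacian eigenmap embedding
#'
#' Builds an `m`-nearest-neighbour graph (symmetrized) with Gaussian edge
#' weights, forms the unnormalized Laplacian `E = P - A`, and solves the
#' generalized eigenproblem \eqn{E x = \lambda P x}. The embedding uses
#' the eigenvectors of the `target_dim` smallest nonzero eigenvalues; the
#' constant null eigenvector is excluded.
#'
#' @param epochs an [epoch_matrix()] or numeric matrix
#' @param m number of nearest neighbours for the graph (default 12)
#' @param sigma Gaussian kernel width; defaults to the median pairwise
#'   distance
#' @param target_dim embedding dimension (default 10)
#' @return an `embedding_result`; `params$laplacian`, `params$adjacency`
#'   and `params$eigenvalues` expose the graph quantities
#' @export
laplacian_eigenmap_embed <- function(epochs, m = 12, sigma = NULL,
                                     target_dim = 10) {
  x <- as_feature_matrix(epochs)
  n <- nrow(x)
  if (m < 1) stop_ecgarr("m_neighbors must be >= 1")
  if (m >= n) stop_ecgarr("m_neighbors must be < number of points")
  d <- pairwise_dist(x)
  if (is.null(sigma)) sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) stop_ecgarr("sigma must be > 0")
  nb <- knn_index(d, m)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, nb[i, ]] <- 1
  adj <- pmax(adj, t(adj)) # symmetrize (union of neighbourhoods)
  comp <- graph_components(adj)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop_ecgarr("neighbourhood graph is disconnected (component sizes: ",
                paste(sizes, collapse = ", "),
                "); the embedding is ill-defined across components")
  }
  a <- adj * exp(-d^2 / (2 * sigma^2))
  diag(a) <- 0
  lap <- graph_laplacian(a)
  p <- rowSums(a)
  # generalized problem E x = lambda P x via the symmetric conjugate
  # P^{-1/2} E P^{-1/2}
  ps <- 1 / sqrt(p)
  s <- lap * outer(ps, ps)
  e <- eigen(s, symmetric = TRUE)
  ord <- order(e$values) # ascending; first is ~0 (constant vector)
  keep <- ord[seq(2, target_dim + 1)]
  v <- e$vectors[, keep, drop = FALSE] * ps
  v <- fix_eigen_signs(v)
  v <- apply(v, 2, function(col) col / sqrt(sum(col^2)))
  embedding_result(matrix(v, nrow = n), "LE",
                   list(m_neighbors = m, sigma = sigma,
                        target_dim = target_dim, adjacency = a,
                        laplacian = lap,
                        eigenvalues = e$values[keep]),
                   seq_len(n))
}

#' Laplacian eigenmap cost
#'
#' Evaluates \eqn{\phi(F) = \sum_{n,t} (f_n - f_t)^2 a_{nt}} for an
#' embedding `f` on the weighted graph `a` (equivalently
#' \eqn{2\,\mathrm{tr}(F^\top E F)}).
#'
#' @param f embedding matrix (rows = points)
#' @param a symmetric weight matrix
#' @return the scalar cost
#' @export
laplacian_cost <- function(f, a) {
  f <- as.matrix(f)
  2 * sum(diag(t(f) %*% graph_laplacian(a) %*% f))
}

#' Epoch-count decimation
#'
#' The pipeline thins each class to one epoch in twenty before embedding;
#' this maps the segmented per-class epoch counts (43333 / 57778 / 84000 /
#' 141750) to the post-reduction counts (2167 / 2889 / 4200 / 7088).
#'
#' @param n_epochs epoch count before decimation (>= 1)
#' @return `ceiling(n_epochs / 20)`
#' @examples
#' decimate_epoch_count(43333) # 2167
#' @export
decimate_epoch_count <- function(n_epochs) {
  if (any(n_epochs < 1)) stop_ecgarr("n_epochs must be >= 1")
  as.integer(ceiling(n_epochs / 20))
}

#' Decimate an epoch matrix
#'
#' Keeps the first epoch of each block of `every` consecutive epochs, so
#' the retained count equals [decimate_epoch_count()] when `every = 20`.
#'
#' @param epochs an [epoch_matrix()]
#' @param every block length (default 20)
#' @return an [epoch_matrix()] of the retained epochs
#' @export
decimate_epochs <- function(epochs, every = 20) {
  if (!inherits(epochs, "epoch_matrix")) stop_ecgarr("not an epoch_matrix")
  keep <- seq(1, nrow(epochs$data), by = every)
  epoch_matrix(epochs$data[keep, , drop = FALSE], fs = epochs$fs,
               labels = epochs$labels[keep],
               provenance = paste0(epochs$provenance, " | decimated 1/", every))
}
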