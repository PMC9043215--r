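# Similarity network fusion: per-omic patient affinities merged into one
# consensus network by iterative cross-diffusion.

#' Euclidean distance matrix between samples
#'
#' @param X Numeric matrix, rows = samples; no missing values.
#' @return Symmetric n x n matrix of Euclidean distances with zero diagonal.
#' @export
pairwise_distance <- function(X) {
  X <- as.matrix(X)
  stop_if(nrow(X) < 2, "need at least two samples")
  stop_if(anyNA(X), "missing values in feature matrix")
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

# Mean distance from each sample to its K nearest neighbours (self excluded;
# ties broken towards the smaller sample index).
knn_mean_distance <- function(D, K) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    mean(sort(d, method = "radix")[seq_len(K)])
  }, numeric(1))
}

#' Scaled exponential affinity matrix
#'
#' Converts distances into similarities via
#' `W_ij = exp(-d_ij^2 / (alpha * gamma_ij))` where
#' `gamma_ij = (mean dist of i to its K nearest neighbours +
#'              mean dist of j to its K nearest neighbours + d_ij) / 3`
#' absorbs local scale, so the kernel bandwidth adapts to each pair's
#' neighbourhood density. The diagonal follows the same rule: zero
#' self-distance gives `W_ii = 1`.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param K Neighbourhood size, `1 <= K <= n - 1`.
#' @param alpha Positive bandwidth hyperparameter (typical range 0.3-0.8).
#' @return Symmetric affinity matrix with entries in (0, 1].
#' @export
affinity_matrix <- function(D, K, alpha = 0.5) {
  D <- as.matrix(D)
  n <- nrow(D)
  stop_if(n != ncol(D) || max(abs(D - t(D))) > 1e-8, "D must be symmetric")
  stop_if(any(diag(D) != 0), "D must have a zero diagonal")
  stop_if(K < 1 || K > n - 1, "K must be in [1, n-1]")
  stop_if(alpha <= 0, "alpha must be positive")
  mu <- knn_mean_distance(D, K)
  gam <- (outer(mu, mu, "+") + D) / 3
  if (any(gam[upper.tri(gam)] == 0)) {
    warning("degenerate zero scale for duplicate points; clamping", call. = FALSE)
    gam[gam == 0] <- 1e-12
  }
  W <- exp(-D^2 / (alpha * gam))
  diag(W) <- 1
  dimnames(W) <- dimnames(D)
  W
}

#' Full normalization of an affinity matrix
#'
#' Produces the row-stochastic matrix `P` with `P_ii = 1/2` and, off the
#' diagonal, `P_ij = W_ij / (2 * sum_{k != i} W_ik)`, so every row sums to 1
#' and half of each patient's mass stays on itself.
#'
#' @param W Nonnegative affinity matrix; every row needs positive
#'   off-diagonal mass.
#' @return Row-stochastic matrix of the same dimension.
#' @export
normalize_full <- function(W) {
  W <- as.matrix(W)
  stop_if(any(W < 0), "affinities must be nonnegative")
  off <- rowSums(W) - diag(W)
  stop_if(any(off <= 0), "row(s) with zero off-diagonal affinity")
  P <- W / (2 * off)
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  P
}

# K nearest neighbours of each row by descending affinity, self excluded,
# ties resolved towards the smaller column index.
knn_index <- function(W, K) {
  n <- nrow(W)
  t(vapply(seq_len(n), function(i) {
    ord <- order(-W[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(K)]
  }, integer(K)))
}

#' Local affinity matrix over K-nearest neighbourhoods
#'
#' Keeps only each patient's K strongest affinities and renormalizes them to
#' sum to one: `S_ij = W_ij / sum_{k in N_i} W_ik` when j is among i's K
#' nearest neighbours, 0 otherwise. S carries only local structure and is
#' what diffuses information during fusion.
#'
#' @param W Nonnegative affinity matrix.
#' @param K Neighbourhood size.
#' @return Matrix whose rows each sum to 1 over the neighbourhood.
#' @export
local_affinity <- function(W, K) {
  W <- as.matrix(W)
  n <- nrow(W)
  stop_if(any(W < 0), "affinities must be nonnegative")
  stop_if(K < 1 || K > n - 1, "K must be in [1, n-1]")
  nn <- knn_index(W, K)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    denom <- sum(W[i, nn[i, ]])
    stop_if(denom == 0, "zero total affinity over the neighbourhood of row ", i)
    S[i, nn[i, ]] <- W[i, nn[i, ]] / denom
  }
  S
}

#' Fuse per-omic affinity matrices into one patient similarity network
#'
#' Iterative cross-diffusion: each data type's full kernel `P^(h)` is updated
#' as `S^(h) %*% (mean of the other types' P) %*% t(S^(h))`, where `S^(h)` is
#' the type's local (K-NN) kernel, then renormalized to keep rows stochastic.
#' After `iterations` rounds the fused network is the average of the per-type
#' matrices, symmetrized as `(P + t(P)) / 2`.
#'
#' @param Ws List of two or more affinity matrices (same samples, same
#'   order), e.g. from [affinity_matrix()].
#' @param K Neighbourhood size for the local kernels.
#' @param iterations Number of diffusion rounds (default 20). `0` returns the
#'   symmetrized average of the initial full kernels.
#' @return Symmetric nonnegative fused similarity matrix.
#' @export
snf_fuse <- function(Ws, K, iterations = 20) {
  m <- length(Ws)
  stop_if(m < 2, "fusion needs at least two data types")
  ns <- vapply(Ws, nrow, integer(1))
  stop_if(length(unique(ns)) != 1, "matrices differ in size")
  ids <- lapply(Ws, rownames)
  if (!is.null(ids[[1]])) {
    stop_if(!all(vapply(ids, identical, logical(1), y = ids[[1]])),
            "sample orders differ across matrices")
  }
  P <- lapply(Ws, normalize_full)
  S <- lapply(Ws, local_affinity, K = K)
  if (iterations > 0) {
    for (t in seq_len(iterations)) {
      P_new <- vector("list", m)
      for (h in seq_len(m)) {
        others <- Reduce(`+`, P[-h]) / (m - 1)
        P_new[[h]] <- S[[h]] %*% others %*% t(S[[h]])
      }
      P <- lapply(P_new, normalize_full)
    }
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  check_finite(fused, "fused network")
  dimnames(fused) <- dimnames(Ws[[1]])
  fused
}

#' Default SNF neighbourhood size
#'
#' @param n Number of samples.
#' @return `max(3, round(n / 10))`, capped at `n - 1`.
#' @export
default_snf_k <- function(n) min(max(3L, as.integer(round(n / 10))), n - 1L)
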