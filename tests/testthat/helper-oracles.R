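# Independent straight-line oracles. These deliberately avoid the package's
# vectorised code paths: explicit loops, scalar arithmetic, no shared
# helpers, so agreement is evidence and not tautology.

oracle_distance <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(ncol(X))) s <- s + (X[i, k] - X[j, k])^2
      D[i, j] <- sqrt(s)
    }
  }
  D
}

# Scalar evaluation of the scaled exponential kernel with the three-way
# averaged local scale.
oracle_affinity <- function(D, K, alpha) {
  n <- nrow(D)
  mu <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(D[i, setdiff(seq_len(n), i)])
    mu[i] <- mean(d[1:K])
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gam <- (mu[i] + mu[j] + D[i, j]) / 3
      W[i, j] <- exp(-D[i, j]^2 / (alpha * gam))
    }
  }
  diag(W) <- 1
  W
}

oracle_normalize_full <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) if (k != i) s <- s + W[i, k]
    for (j in seq_len(n)) {
      P[i, j] <- if (j == i) 0.5 else W[i, j] / (2 * s)
    }
  }
  P
}

# Neighbourhoods ranked by descending affinity, self excluded, ties to the
# smaller index (same convention the package documents).
oracle_local_affinity <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(-W[i, others], others)][1:K]
    denom <- sum(W[i, nb])
    for (j in nb) S[i, j] <- W[i, j] / denom
  }
  S
}

# Full cross-diffusion with explicit loops for the matrix products.
oracle_snf <- function(Ws, K, iterations) {
  m <- length(Ws)
  n <- nrow(Ws[[1]])
  matmul <- function(A, B) {
    C <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(n)) s <- s + A[i, k] * B[k, j]
      C[i, j] <- s
    }
    C
  }
  P <- lapply(Ws, oracle_normalize_full)
  S <- lapply(Ws, oracle_local_affinity, K = K)
  for (t in seq_len(iterations)) {
    P_new <- vector("list", m)
    for (h in seq_len(m)) {
      avg <- matrix(0, n, n)
      for (k in seq_len(m)) if (k != h) avg <- avg + P[[k]]
      avg <- avg / (m - 1)
      P_new[[h]] <- matmul(matmul(S[[h]], avg), t(S[[h]]))
    }
    P <- lapply(P_new, oracle_normalize_full)
  }
  fused <- matrix(0, n, n)
  for (h in seq_len(m)) fused <- fused + P[[h]]
  fused <- fused / m
  (fused + t(fused)) / 2
}

oracle_normalize_adjacency <- function(A) {
  n <- nrow(A)
  Ah <- A + diag(n)
  deg <- rowSums(Ah)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- Ah[i, j] / (sqrt(deg[i]) * sqrt(deg[j]))
  }
  out
}

# Straight-line dense forward pass: block b sees [X, O_1, ..., O_{b-1}],
# classifier reads the final concatenation. No dropout, rectifier blocks.
oracle_dense_forward <- function(X, A_norm, params) {
  C <- X
  for (b in seq_along(params$blocks)) {
    Z <- A_norm %*% C %*% params$blocks[[b]]$W
    Z <- Z + matrix(params$blocks[[b]]$b, nrow(Z), ncol(Z), byrow = TRUE)
    O <- pmax(Z, 0)
    C <- cbind(C, O)
  }
  logits <- C %*% params$W_out +
    matrix(params$b_out, nrow(C), 2, byrow = TRUE)
  e <- exp(logits - apply(logits, 1, max))
  list(probs = e / rowSums(e), embedding = C)
}

# Central-difference numerical gradient of a scalar function of one
# parameter array.
numerical_grad <- function(fn, value, eps = 1e-5) {
  g <- array(0, dim = dim(value) %||% length(value))
  for (i in seq_along(value)) {
    up <- value; up[i] <- up[i] + eps
    dn <- value; dn[i] <- dn[i] - eps
    g[i] <- (fn(up) - fn(dn)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate an expression under a seed without touching the suite's stream.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
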