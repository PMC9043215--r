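# Densely connected graph convolutional classifier over a patient
# similarity network. Each block sees the concatenation of the input
# features and every previous block's output, which keeps gradients flowing
# through deep stacks.

#' DenseGCN configuration
#'
#' Defaults follow the reference recipe: 10 graph-convolution blocks,
#' learning rate 0.01, 500 full-batch epochs; per-block width (growth rate)
#' 32 and dropout 0.5 on block inputs are this package's choices.
#'
#' @param n_layers Number of graph-convolution blocks.
#' @param growth Output width of each block (representation grows by this
#'   much per layer through concatenation).
#' @param learning_rate Adam step size.
#' @param epochs Training epochs (full-graph batches).
#' @param dropout Dropout probability on block inputs during training,
#'   in \[0, 1).
#' @param seed Integer seed for initialisation and dropout.
#' @return A list of class `gcn_config`.
#' @export
gcn_config <- function(n_layers = 10, growth = 32, learning_rate = 0.01,
                       epochs = 500, dropout = 0.5, seed = 1L) {
  stop_if(n_layers < 1 || growth < 1 || epochs < 1,
          "layers, growth and epochs must be positive")
  stop_if(dropout < 0 || dropout >= 1, "dropout must be in [0, 1)")
  stop_if(learning_rate <= 0, "learning rate must be positive")
  structure(list(n_layers = as.integer(n_layers), growth = as.integer(growth),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 dropout = dropout, seed = seed),
            class = "gcn_config")
}

#' Bundle a graph classification problem
#'
#' @param adjacency Symmetric nonnegative n x n matrix (fused patient
#'   similarity network, or the identity for the no-graph ablation).
#' @param features Numeric n x f node-feature matrix in the same sample order.
#' @param labels Integer 0/1 vector of length n (1 = tumor).
#' @param masks List with disjoint integer index vectors `train`, `val`,
#'   `test` (see [split_samples()]).
#' @return Object of class `graph_dataset`.
#' @export
graph_dataset <- function(adjacency, features, labels, masks) {
  adjacency <- as.matrix(adjacency)
  features <- as.matrix(features)
  n <- nrow(adjacency)
  stop_if(ncol(adjacency) != n, "adjacency must be square")
  stop_if(max(abs(adjacency - t(adjacency))) > 1e-8, "adjacency must be symmetric")
  stop_if(any(adjacency < 0), "adjacency must be nonnegative")
  stop_if(nrow(features) != n, "features/adjacency row mismatch")
  stop_if(length(labels) != n, "labels/adjacency length mismatch")
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be 0/1")
  idx <- sort(c(masks$train, masks$val, masks$test))
  stop_if(!identical(idx, seq_len(n)), "masks must partition 1..n")
  structure(list(adjacency = adjacency, features = features,
                 labels = as.integer(labels), masks = masks),
            class = "graph_dataset")
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Adds the identity to `A` and rescales by the resulting degrees:
#' `D^(-1/2) (A + I) D^(-1/2)`. Self-loops let each node keep its own
#' features; the symmetric scaling stops repeated propagation from inflating
#' feature magnitudes.
#'
#' @param A Symmetric nonnegative matrix.
#' @return Symmetric normalized operator of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  stop_if(any(A < 0), "adjacency must be nonnegative")
  stop_if(max(abs(A - t(A))) > 1e-8, "adjacency must be symmetric")
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  stopifnot(all(is.finite(dinv)))  # self-loops guarantee positive degree
  out <- Ahat * outer(dinv, dinv)
  dimnames(out) <- dimnames(A)
  out
}

#' Single graph-convolution layer
#'
#' Computes `sigma(A_norm %*% H %*% W + b)`.
#'
#' @param H Node representation matrix (n x f).
#' @param A_norm Normalized adjacency from [normalize_adjacency()].
#' @param W Weight matrix (f x f').
#' @param b Optional bias vector of length f'.
#' @param activation Elementwise nonlinearity (default rectifier).
#' @return Matrix n x f'.
#' @export
gcn_layer <- function(H, A_norm, W, b = NULL, activation = relu) {
  stop_if(ncol(H) != nrow(W), "H/W shape mismatch")
  stop_if(nrow(H) != ncol(A_norm), "H/A shape mismatch")
  Z <- A_norm %*% H %*% W
  if (!is.null(b)) Z <- sweep(Z, 2L, b, "+")
  activation(Z)
}

densegcn_init <- function(f_in, n_layers, growth, n_classes = 2L) {
  blocks <- vector("list", n_layers)
  width <- f_in
  for (b in seq_len(n_layers)) {
    blocks[[b]] <- list(W = glorot(width, growth), b = numeric(growth))
    width <- width + growth
  }
  list(blocks = blocks, W_out = glorot(width, n_classes),
       b_out = numeric(n_classes))
}

# Flatten/unflatten block parameters for the Adam helper.
flatten_params <- function(p) {
  out <- list()
  for (b in seq_along(p$blocks)) {
    out[[paste0("W", b)]] <- p$blocks[[b]]$W
    out[[paste0("b", b)]] <- p$blocks[[b]]$b
  }
  out$W_out <- p$W_out
  out$b_out <- p$b_out
  out
}

unflatten_params <- function(flat, n_layers) {
  blocks <- lapply(seq_len(n_layers), function(b) {
    list(W = flat[[paste0("W", b)]], b = as.numeric(flat[[paste0("b", b)]]))
  })
  list(blocks = blocks, W_out = flat$W_out, b_out = as.numeric(flat$b_out))
}

#' DenseGCN forward pass
#'
#' Runs `n_layers` graph-convolution blocks in which each block's input is
#' the column-wise concatenation of the raw node features and all previous
#' blocks' outputs. The classifier is an affine map plus softmax over two
#' classes applied to the final concatenated representation.
#'
#' During training, dropout is applied once per segment of the concatenated
#' representation (the input features and each block's output), so every
#' consumer of a segment sees the same dropped copy. Because the graph
#' propagation is linear in the columns, `A %*% segment` is computed once
#' per segment and reused by all later blocks.
#'
#' @param X Node features (n x f).
#' @param A_norm Normalized adjacency ([normalize_adjacency()]).
#' @param params Parameter list from `densegcn_init()` (or a trained model's
#'   `$params`).
#' @param dropout Dropout rate on segments when `training = TRUE` (inverted
#'   dropout, so inference needs no rescaling).
#' @param training Logical; enables dropout and caches intermediates.
#' @return List with `probs` (n x 2 row-stochastic class probabilities),
#'   `logits`, and `embedding` (the final concatenated representation). When
#'   `training = TRUE` also the caches used by the backward pass.
#' @export
densegcn_forward <- function(X, A_norm, params, dropout = 0,
                             training = FALSE) {
  X <- as.matrix(X)
  n_layers <- length(params$blocks)
  drop_seg <- function(S) {
    if (!training || dropout == 0) return(list(seg = S, mask = NULL))
    mask <- matrix(stats::runif(length(S)) >= dropout, nrow(S), ncol(S)) /
      (1 - dropout)
    list(seg = S * mask, mask = mask)
  }
  d0 <- drop_seg(X)
  C <- d0$seg                 # concatenated (dropped) representation
  M <- A_norm %*% d0$seg      # propagated copy, grown segment by segment
  Zs <- if (training) vector("list", n_layers) else NULL
  masks <- if (training) c(list(d0$mask), vector("list", n_layers)) else NULL
  for (b in seq_len(n_layers)) {
    blk <- params$blocks[[b]]
    stop_if(ncol(C) != nrow(blk$W), "parameter/shape mismatch at block ", b)
    Z <- sweep(M %*% blk$W, 2L, blk$b, "+")
    O <- relu(Z)
    db <- drop_seg(O)
    if (training) {
      Zs[[b]] <- Z
      masks[b + 1L] <- list(db$mask)  # keep NULL placeholders when no dropout
    }
    C <- cbind(C, db$seg)
    if (b < n_layers) M <- cbind(M, A_norm %*% db$seg)
  }
  logits <- sweep(C %*% params$W_out, 2L, params$b_out, "+")
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, embedding = C)
  if (training) {
    out$caches <- list(M = M, Zs = Zs, masks = masks)
  }
  out
}

# Backward pass for masked cross-entropy. Rows outside the training mask
# contribute zero gradient, which is what makes training transductive but
# leakage-free. dAM accumulates gradients w.r.t. the propagated segments;
# block b's own segment has received all its contributions (they come only
# from blocks after b) by the time the descending sweep reaches it.
densegcn_grads <- function(X, A_norm, params, fw, y, train_idx) {
  n <- nrow(fw$probs)
  f_in <- ncol(X)
  growth <- ncol(params$blocks[[1]]$W)
  n_layers <- length(params$blocks)
  Y <- matrix(0, n, 2L)
  Y[cbind(train_idx, y[train_idx] + 1L)] <- 1
  dlogits <- (fw$probs - Y) / length(train_idx)
  dlogits[-train_idx, ] <- 0
  C <- fw$embedding
  grads <- list(W_out = t(C) %*% dlogits, b_out = colSums(dlogits))
  dC <- dlogits %*% t(params$W_out)
  At <- t(A_norm)
  M <- fw$caches$M
  dAM <- matrix(0, n, ncol(M))
  for (b in rev(seq_len(n_layers))) {
    in_width <- f_in + (b - 1L) * growth
    cols <- in_width + seq_len(growth)
    dOd <- dC[, cols, drop = FALSE]
    if (b < n_layers) {
      dOd <- dOd + At %*% dAM[, cols, drop = FALSE]
    }
    mask <- fw$caches$masks[[b + 1L]]
    if (!is.null(mask)) dOd <- dOd * mask
    dZ <- dOd * (fw$caches$Zs[[b]] > 0)
    grads[[paste0("W", b)]] <- t(M[, seq_len(in_width), drop = FALSE]) %*% dZ
    grads[[paste0("b", b)]] <- colSums(dZ)
    dAM[, seq_len(in_width)] <- dAM[, seq_len(in_width), drop = FALSE] +
      dZ %*% t(params$blocks[[b]]$W)
  }
  grads
}

masked_cross_entropy <- function(probs, y, idx) {
  p <- probs[cbind(idx, y[idx] + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a DenseGCN transductively
#'
#' Full-graph training: every forward pass runs over all nodes, but the
#' cross-entropy loss (and its gradient) is restricted to training-mask
#' nodes, so validation and test labels never influence the parameters.
#' Validation accuracy is tracked per epoch and the parameters with the best
#' validation accuracy are retained.
#'
#' @param data A [graph_dataset()].
#' @param cfg A [gcn_config()].
#' @return Object of class `densegcn` with `params` (best-validation),
#'   `final_params`, `config`, `A_norm`, and `history` (data frame with
#'   per-epoch train loss/accuracy and validation accuracy).
#' @export
train_densegcn <- function(data, cfg = gcn_config()) {
  stopifnot(inherits(data, "graph_dataset"), inherits(cfg, "gcn_config"))
  y <- data$labels
  tr <- data$masks$train
  va <- data$masks$val
  stop_if(length(unique(y[tr])) < 2, "training mask must contain both classes")
  A_norm <- normalize_adjacency(data$adjacency)
  X <- data$features
  with_seed(cfg$seed, {
    params <- densegcn_init(ncol(X), cfg$n_layers, cfg$growth)
    flat <- flatten_params(params)
    st <- adam_init(flat)
    hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                       train_acc = NA_real_, val_acc = NA_real_)
    best <- list(acc = -Inf, flat = flat)
    for (ep in seq_len(cfg$epochs)) {
      fw <- densegcn_forward(X, A_norm, params, dropout = cfg$dropout,
                             training = TRUE)
      loss <- masked_cross_entropy(fw$probs, y, tr)
      stop_if(!is.finite(loss), "non-finite training loss at epoch ", ep)
      g <- densegcn_grads(X, A_norm, params, fw, y, tr)
      upd <- adam_step(flat, g, st, cfg$learning_rate)
      flat <- upd$params; st <- upd$state
      params <- unflatten_params(flat, cfg$n_layers)
      ev <- densegcn_forward(X, A_norm, params)
      pred <- max.col(ev$probs, ties.method = "first") - 1L
      hist$train_loss[ep] <- loss
      hist$train_acc[ep] <- mean(pred[tr] == y[tr])
      hist$val_acc[ep] <- if (length(va)) mean(pred[va] == y[va]) else NA_real_
      if (length(va) && hist$val_acc[ep] > best$acc) {
        best <- list(acc = hist$val_acc[ep], flat = flat)
      }
    }
    if (!length(va)) best$flat <- flat
    structure(list(params = unflatten_params(best$flat, cfg$n_layers),
                   final_params = unflatten_params(flat, cfg$n_layers),
                   config = cfg, A_norm = A_norm, history = hist),
              class = "densegcn")
  })
}

#' Predict class probabilities and hard labels for all nodes
#'
#' @param object Trained [train_densegcn()] model.
#' @param data A [graph_dataset()] with the same graph/features the model
#'   was trained on (transductive setting).
#' @param ... Unused.
#' @return List with `probs` (n x 2), `labels` (0/1 hard calls; a tied row
#'   is called class 0 with a warning).
#' @export
predict.densegcn <- function(object, data, ...) {
  stopifnot(inherits(data, "graph_dataset"))
  fw <- densegcn_forward(data$features, object$A_norm, object$params)
  ties <- fw$probs[, 1L] == fw$probs[, 2L]
  if (any(ties)) {
    warning(sum(ties), " tied probability row(s) assigned to class 0",
            call. = FALSE)
  }
  labels <- as.integer(fw$probs[, 2L] > fw$probs[, 1L])
  list(probs = fw$probs, labels = labels)
}

#' @export
print.densegcn <- function(x, ...) {
  h <- x$history
  cat(sprintf("<densegcn> %d blocks (growth %d), %d epochs; best val acc %.3f\n",
              x$config$n_layers, x$config$growth, nrow(h),
              max(h$val_acc, na.rm = TRUE)))
  invisible(x)
}
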