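# Denoising autoencoder: per-omic nonlinear compression trained to
# reconstruct clean profiles from corrupted copies.

#' Denoising autoencoder configuration
#'
#' Defaults follow the reference training recipe: learning rate 0.01,
#' 50 epochs, mini-batches of 8, 300 latent features per omic, masking
#' corruption at rate 0.2.
#'
#' @param latent_dim Size of the latent embedding (must be < input width).
#' @param hidden_dim Width of the single hidden layer on each side.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param noise_kind `"masking"` (entries zeroed independently) or
#'   `"gaussian"` (i.i.d. additive noise).
#' @param noise_level Masking probability in \[0,1\], or gaussian sd > 0.
#' @param seed Integer seed controlling initialisation, corruption and
#'   batch shuffling.
#' @return A list of class `dae_config`.
#' @export
dae_config <- function(latent_dim = 300, hidden_dim = 1024,
                       learning_rate = 0.01, epochs = 50, batch_size = 8,
                       noise_kind = c("masking", "gaussian"),
                       noise_level = 0.2, seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  stop_if(latent_dim < 1 || hidden_dim < 1 || epochs < 1 || batch_size < 1,
          "dimensions, epochs and batch size must be positive")
  stop_if(learning_rate <= 0, "learning rate must be positive")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 noise_kind = noise_kind, noise_level = noise_level,
                 seed = seed),
            class = "dae_config")
}

#' Corrupt a matrix for denoising training
#'
#' @param X Finite numeric matrix.
#' @param noise_kind `"masking"` zeroes each entry independently with
#'   probability `noise_level`; `"gaussian"` adds i.i.d. `N(0, noise_level^2)`.
#' @param noise_level Masking rate in \[0,1\] or gaussian sd (>= 0).
#' @param seed Optional seed; corruption is deterministic given it.
#' @return Corrupted matrix of the same shape.
#' @export
corrupt <- function(X, noise_kind = c("masking", "gaussian"),
                    noise_level = 0.2, seed = NULL) {
  noise_kind <- match.arg(noise_kind)
  check_finite(X, "input")
  if (noise_kind == "masking") {
    stop_if(noise_level < 0 || noise_level > 1,
            "masking rate must be in [0, 1]")
  } else {
    stop_if(noise_level < 0, "gaussian noise sd must be nonnegative")
  }
  if (noise_level == 0) return(X)
  with_seed(seed, {
    if (noise_kind == "masking") {
      mask <- matrix(stats::runif(length(X)) < noise_level, nrow(X), ncol(X))
      X[mask] <- 0
      X
    } else {
      X + matrix(stats::rnorm(length(X), 0, noise_level), nrow(X), ncol(X))
    }
  })
}

# The output bias starts at the logit of each feature's mean so the decoder
# matches the per-feature base rates from step one; without this the first
# training phase is spent learning column means, a local optimum in which
# the latent pathway is prone to collapse.
dae_init <- function(d, h, q, col_means = rep(0.5, d)) {
  cm <- pmin(pmax(col_means, 1e-3), 1 - 1e-3)
  list(W1 = glorot(d, h), b1 = numeric(h),
       W2 = glorot(h, q), b2 = numeric(q),
       W3 = glorot(q, h), b3 = numeric(h),
       W4 = glorot(h, d), b4 = stats::qlogis(cm))
}

# Forward pass; returns activations needed for backprop. Hidden layers are
# tanh, the latent code is linear (an unsquashed code resists the collapse a
# doubly saturated bottleneck is prone to), the output is sigmoid to match
# the [0, 1] input range.
dae_forward <- function(Xb, p) {
  a1 <- tanh(sweep(Xb %*% p$W1, 2L, p$b1, "+"))
  z  <- sweep(a1 %*% p$W2, 2L, p$b2, "+")
  a3 <- tanh(sweep(z %*% p$W3, 2L, p$b3, "+"))
  xh <- sigmoid(sweep(a3 %*% p$W4, 2L, p$b4, "+"))
  list(a1 = a1, z = z, a3 = a3, xh = xh)
}

# Analytic gradients of mean squared reconstruction error against the clean
# target (tanh: d/dpre = 1 - a^2; sigmoid: a(1 - a); linear latent).
dae_grads <- function(Xnoise, Xclean, p, fw) {
  B <- nrow(Xnoise)
  d <- ncol(Xnoise)
  d4 <- (2 * (fw$xh - Xclean) / (B * d)) * fw$xh * (1 - fw$xh)
  d3 <- (d4 %*% t(p$W4)) * (1 - fw$a3^2)
  d2 <- d3 %*% t(p$W3)
  d1 <- (d2 %*% t(p$W2)) * (1 - fw$a1^2)
  list(W1 = t(Xnoise) %*% d1, b1 = colSums(d1),
       W2 = t(fw$a1) %*% d2, b2 = colSums(d2),
       W3 = t(fw$z) %*% d3,  b3 = colSums(d3),
       W4 = t(fw$a3) %*% d4, b4 = colSums(d4))
}

#' Train a denoising autoencoder on one omic
#'
#' The encoder maps profiles through a tanh hidden layer to a linear latent
#' code; the mirrored decoder (tanh hidden, sigmoid output) reconstructs the
#' input, with its output bias initialised to the logit of each feature's
#' mean so base rates are matched from the first step. Each epoch the
#' rows are shuffled, every mini-batch is freshly corrupted, and Adam
#' minimises the mean squared error between the reconstruction of the
#' corrupted batch and the clean batch.
#'
#' @param X Numeric matrix (samples x features) normalized to \[0, 1\].
#' @param cfg A [dae_config()].
#' @return Object of class `dae` with elements `params`, `config`, and
#'   `loss` (per-epoch mean training loss, length `cfg$epochs`).
#' @export
train_dae <- function(X, cfg = dae_config()) {
  stopifnot(inherits(cfg, "dae_config"))
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  check_finite(X, "training matrix")
  stop_if(cfg$latent_dim >= d, "latent_dim must be smaller than input width")
  stop_if(n < cfg$batch_size, "fewer samples than batch size")
  with_seed(cfg$seed, {
    p <- dae_init(d, cfg$hidden_dim, cfg$latent_dim, colMeans(X))
    st <- adam_init(p)
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        Xc <- X[rows, , drop = FALSE]
        Xn <- corrupt(Xc, cfg$noise_kind, cfg$noise_level)
        fw <- dae_forward(Xn, p)
        losses[bi] <- mean((fw$xh - Xc)^2)
        g <- dae_grads(Xn, Xc, p, fw)
        upd <- adam_step(p, g, st, cfg$learning_rate)
        p <- upd$params; st <- upd$state
      }
      trace[ep] <- mean(losses)
      stop_if(!is.finite(trace[ep]),
              "non-finite training loss at epoch ", ep,
              " (learning rate too high?)")
    }
    structure(list(params = p, config = cfg, loss = trace), class = "dae")
  })
}

#' Encode samples with a trained autoencoder
#'
#' Applies the encoder half to clean (uncorrupted) input.
#'
#' @param model A trained [train_dae()] object.
#' @param X Matrix with the same feature width the model was trained on.
#' @return Latent matrix (`nrow(X)` x `latent_dim`), row names preserved.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "dae"))
  X <- as.matrix(X)
  stop_if(ncol(X) != nrow(model$params$W1),
          "feature width ", ncol(X), " does not match trained width ",
          nrow(model$params$W1))
  p <- model$params
  a1 <- tanh(sweep(X %*% p$W1, 2L, p$b1, "+"))
  z <- sweep(a1 %*% p$W2, 2L, p$b2, "+")
  rownames(z) <- rownames(X)
  z
}

#' Reconstruct input through a trained autoencoder
#'
#' Runs the full encoder-decoder on clean input; useful for inspecting
#' reconstruction quality.
#'
#' @param model A trained [train_dae()] object.
#' @param X Matrix with the trained feature width.
#' @return Reconstruction matrix of the same shape as `X`, values in (0, 1).
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "dae"))
  X <- as.matrix(X)
  stop_if(ncol(X) != nrow(model$params$W1), "feature width mismatch")
  out <- dae_forward(X, model$params)$xh
  dimnames(out) <- dimnames(X)
  out
}

#' Concatenate per-omic latent matrices column-wise
#'
#' @param Zs List of latent matrices with identical row (sample) order, in a
#'   fixed omic order (e.g. RNA, methylation, CNV).
#' @return Single matrix with columns stacked in list order.
#' @export
concat_latents <- function(Zs) {
  stop_if(length(Zs) < 1, "no latent matrices supplied")
  rn <- rownames(Zs[[1]])
  for (z in Zs[-1]) {
    stop_if(nrow(z) != nrow(Zs[[1]]), "row counts differ")
    stop_if(!is.null(rn) && !identical(rownames(z), rn),
            "sample order differs across latent matrices")
  }
  do.call(cbind, Zs)
}

#' @export
print.dae <- function(x, ...) {
  cat(sprintf("<dae> %d -> %d -> %d, final training MSE %.4g\n",
              nrow(x$params$W1), x$config$hidden_dim, x$config$latent_dim,
              x$loss[length(x$loss)]))
  invisible(x)
}
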