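# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so seeded package internals never perturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seeds for pipeline stages, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max subtraction for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot/Xavier uniform initialisation for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# --- Adam optimiser over a flat named list of numeric arrays ---------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_finite <- function(x, what) {
  stop_if(any(!is.finite(x)), what, " contains non-finite values")
  invisible(x)
}
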