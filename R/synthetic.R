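# Synthetic multi-view omics generator: high-dimensional, few-sample
# matrices sharing one latent class structure, with injected missingness.
# Every stage of the package is testable against it without any download.

#' Specification for a synthetic multi-omics cohort
#'
#' Samples carry a latent factor vector whose class means are `separation`
#' apart (in latent SD units); each omic observes the latent factors through
#' its own sparse random loading matrix plus gaussian noise, emulating
#' complementary molecular views of one disease state. Defaults mimic a
#' ~400-patient cohort with reduced feature counts.
#'
#' @param n_samples Number of patients (labels are balanced).
#' @param dims Integer vector of per-omic feature counts.
#' @param latent_rank Number of shared latent factors r.
#' @param separation Euclidean distance between class means in latent space.
#' @param noise_sd Per-omic observation noise sd (recycled to `length(dims)`).
#' @param missing_rate Fraction of entries masked missing, in \[0, 0.5\].
#' @param informative_fraction Per-omic fraction of features with nonzero
#'   loadings (recycled).
#' @param omic_names Labels for the views.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400,
                           dims = c(2000, 2000, 2400),
                           latent_rank = 5,
                           separation = 4,
                           noise_sd = 0.5,
                           missing_rate = 0.05,
                           informative_fraction = 0.1,
                           omic_names = c("rna", "methylation", "cnv")[seq_along(dims)],
                           seed = 1L) {
  stop_if(n_samples < 4, "need at least 4 samples")
  stop_if(any(dims < 2), "each omic needs at least 2 features")
  stop_if(latent_rank < 1 || latent_rank >= min(dims),
          "latent_rank must be in [1, min(dims))")
  stop_if(separation < 0, "separation must be nonnegative")
  stop_if(missing_rate < 0 || missing_rate > 0.5,
          "missing_rate must be in [0, 0.5]")
  noise_sd <- rep_len(noise_sd, length(dims))
  informative_fraction <- rep_len(informative_fraction, length(dims))
  stop_if(any(noise_sd <= 0), "noise_sd must be positive")
  stop_if(any(informative_fraction <= 0 | informative_fraction > 1),
          "informative_fraction must be in (0, 1]")
  stop_if(length(omic_names) != length(dims), "one name per omic required")
  structure(list(n_samples = as.integer(n_samples), dims = as.integer(dims),
                 latent_rank = as.integer(latent_rank),
                 separation = separation, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 informative_fraction = informative_fraction,
                 omic_names = omic_names, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-omics cohort with known class structure
#'
#' Balanced 0/1 labels are drawn; each sample gets a latent vector
#' `z ~ N(mu_class, I_r)` with `||mu_1 - mu_0|| = separation`. Each omic is
#' `X_h = z %*% W_h + eps_h` where only a random `informative_fraction` of
#' the columns of `W_h` are nonzero and `eps_h ~ N(0, noise_sd_h^2)`. Columns
#' are shifted to a nonnegative range, then entries are masked missing at
#' `missing_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrices` (list of [omics_matrix()]), `labels` (named
#'   0/1 vector), `latent` (the ground-truth n x r factor matrix) and
#'   `informative` (per-omic informative column indices).
#' @export
generate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    r <- spec$latent_rank
    ids <- sprintf("S%04d", seq_len(n))
    lab <- sample(rep_len(c(0L, 1L), n))
    mu <- spec$separation / sqrt(r)
    z <- matrix(stats::rnorm(n * r), n, r) + mu * lab
    rownames(z) <- ids
    mats <- vector("list", length(spec$dims))
    info <- vector("list", length(spec$dims))
    for (h in seq_along(spec$dims)) {
      d <- spec$dims[h]
      k <- max(1L, round(spec$informative_fraction[h] * d))
      cols <- sort(sample.int(d, k))
      W <- matrix(0, r, d)
      W[, cols] <- stats::rnorm(r * k)
      X <- z %*% W + matrix(stats::rnorm(n * d, 0, spec$noise_sd[h]), n, d)
      X <- sweep(X, 2L, apply(X, 2L, min), "-")  # nonnegative range
      if (spec$missing_rate > 0) {
        X[stats::runif(n * d) < spec$missing_rate] <- NA_real_
      }
      dimnames(X) <- list(ids, sprintf("%s_f%05d", spec$omic_names[h],
                                       seq_len(d)))
      mats[[h]] <- omics_matrix(X, omic_name = spec$omic_names[h])
      info[[h]] <- cols
    }
    names(mats) <- spec$omic_names
    names(info) <- spec$omic_names
    list(matrices = mats, labels = make_labels(lab, ids), latent = z,
         informative = info)
  })
}

#' Generate a graph fixture where the network carries the signal
#'
#' Builds a [graph_dataset()] in which node features are only weakly
#' class-informative while the patient similarity network, fused from
#' strongly separated views, has clear within-class block structure. On such
#' data a graph-aware classifier should beat the same model run with an
#' identity adjacency, which is exactly what the PSN ablation checks.
#'
#' @param spec A [synthetic_spec()]; `spec$separation` governs the views the
#'   network is fused from.
#' @param feature_separation Class separation of the weak node features
#'   (default `spec$separation / 8`).
#' @param feature_dim Number of node features.
#' @param snf_k,snf_alpha,snf_iterations Fusion parameters.
#' @param split Train/validation/test fractions.
#' @return A [graph_dataset()] plus attribute `"fused"` carrying the PSN.
#' @export
generate_identity_unfavorable <- function(spec,
                                          feature_separation = spec$separation / 8,
                                          feature_dim = 30,
                                          snf_k = default_snf_k(spec$n_samples),
                                          snf_alpha = 0.5,
                                          snf_iterations = 20,
                                          split = c(0.6, 0.2, 0.2)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gen <- generate_multiomics(spec)
  pre <- lapply(gen$matrices, function(m) minmax_normalize(impute_mean(m)))
  Ws <- lapply(pre, function(m) {
    affinity_matrix(pairwise_distance(m$values), K = snf_k, alpha = snf_alpha)
  })
  fused <- snf_fuse(Ws, K = snf_k, iterations = snf_iterations)
  n <- spec$n_samples
  with_seed(derive_seed(spec$seed, 7919L), {
    lab <- gen$labels
    zf <- matrix(stats::rnorm(n * feature_dim), n, feature_dim) +
      (feature_separation / sqrt(feature_dim)) * as.integer(lab)
    zf <- (zf - min(zf)) / (max(zf) - min(zf))
    rownames(zf) <- names(lab)
    masks <- split_samples(lab, fractions = split,
                           seed = derive_seed(spec$seed, 104729L))
    gd <- graph_dataset(fused, zf, lab, masks)
    attr(gd, "fused") <- fused
    gd
  })
}
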