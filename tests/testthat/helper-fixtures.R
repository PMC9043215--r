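# Shared fixture builders. Everything is generated in code; sizes are kept
# at desk scale (the vignette documents the choices).

# Write a small omics table to a temp file and return the path.
write_omics_file <- function(values, ids = rownames(values),
                             features = colnames(values), sep = "\t",
                             ext = ".tsv") {
  path <- tempfile(fileext = ext)
  df <- data.frame(sample_id = ids, values, check.names = FALSE)
  colnames(df) <- c("sample_id", features)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A small omics_matrix with planted missingness.
toy_omics <- function(n = 10, d = 5, missing = NULL, seed = 1,
                      omic_name = "toy") {
  set.seed(seed)
  v <- matrix(stats::runif(n * d, 1, 10), n, d,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("f%d", seq_len(d))))
  if (!is.null(missing)) v[missing] <- NA_real_
  omics_matrix(v, omic_name = omic_name)
}

# Two-block community graph with well-separated node features: the
# separable fixture used for trainability checks.
separable_graph <- function(n = 60, f = 20, separation = 6, seed = 1,
                            split = c(0.6, 0.2, 0.2)) {
  set.seed(seed)
  lab <- sample(rep_len(c(0L, 1L), n))
  X <- matrix(stats::rnorm(n * f), n, f) + (separation / sqrt(f)) * lab
  X <- (X - min(X)) / (max(X) - min(X))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  W <- affinity_matrix(pairwise_distance(X), K = 5, alpha = 0.5)
  A <- normalize_full(W)
  A <- (A + t(A)) / 2
  labels <- stats::setNames(lab, rownames(X))
  masks <- split_samples(labels, fractions = split, seed = seed + 1)
  graph_dataset(A, X, labels, masks)
}

# Desk-scale generator settings used by the end-to-end checks: the cohort
# size and class separations follow the study conditions; feature counts and
# network widths are reduced for runtime (documented in the vignette).
accept_spec <- function(separation, seed,
                        n_samples = 400, dims = c(500, 500, 600)) {
  synthetic_spec(n_samples = n_samples, dims = dims, latent_rank = 5,
                 separation = separation, noise_sd = 0.5,
                 missing_rate = 0.05, informative_fraction = 0.1,
                 seed = seed)
}

accept_config <- function(spec, seed = 1L, gcn_epochs = 150L,
                          omics = NULL, adjacency = "psn") {
  pipeline_config(
    synthetic = spec,
    omics = omics,
    adjacency = adjacency,
    snf = list(alpha = 0.5, K = NULL, iterations = 20),
    dae = dae_config(latent_dim = 64, hidden_dim = 128, epochs = 50,
                     batch_size = 8, learning_rate = 0.01),
    gcn = gcn_config(n_layers = 10, growth = 32, epochs = gcn_epochs,
                     dropout = 0.5, learning_rate = 0.01),
    repeats = 5L,
    seed = seed
  )
}

# Complementary-views fixture: each omic alone is weakly informative (a
# linear probe reaches ~0.6-0.7) while the three views carry independent
# noise, so their combination is stronger.
complementary_spec <- function(seed) {
  synthetic_spec(n_samples = 200, dims = c(300, 300, 300), latent_rank = 4,
                 separation = 2, noise_sd = 1.5, missing_rate = 0.02,
                 informative_fraction = c(0.02, 0.03, 0.05), seed = seed)
}

complementary_config <- function(seed, omics = NULL) {
  pipeline_config(
    synthetic = complementary_spec(seed),
    omics = omics,
    snf = list(alpha = 0.5, K = NULL, iterations = 20),
    dae = dae_config(latent_dim = 32, hidden_dim = 128, epochs = 50,
                     batch_size = 8),
    gcn = gcn_config(n_layers = 5, growth = 16, epochs = 120, dropout = 0.5),
    repeats = 5L,
    seed = seed
  )
}

# Fixture where the network, not the features, carries the class signal.
unfavorable_fixture <- function(seed) {
  spec <- synthetic_spec(n_samples = 200, dims = c(120, 120, 120),
                         latent_rank = 3, separation = 6, noise_sd = 0.5,
                         missing_rate = 0, informative_fraction = 0.2,
                         seed = seed)
  generate_identity_unfavorable(spec)
}
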