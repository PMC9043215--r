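# Orchestration: preprocessing -> SNF -> DAE -> DenseGCN, with splits,
# repeats, metrics and ablations.

#' Random stratum-checked train/validation/test split
#'
#' Sizes are `floor(f1 * n)` train, `floor(f2 * n)` validation, remainder
#' test. A split leaving any part single-class is resampled up to
#' `max_retries` times before erroring.
#'
#' @param labels 0/1 vector (named or not) of length n.
#' @param fractions Numeric triple summing to 1 (default 0.6/0.2/0.2).
#' @param seed Integer seed; the split is deterministic given it.
#' @param max_retries Resampling attempts for degenerate splits.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_samples <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          max_retries = 100L) {
  n <- length(labels)
  stop_if(n < 10, "need at least 10 samples to split")
  stop_if(length(unique(labels)) < 2, "both classes must be present")
  stop_if(abs(sum(fractions) - 1) > 1e-8, "fractions must sum to 1")
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      ord <- sample.int(n)
      masks <- list(train = sort(ord[seq_len(n_tr)]),
                    val = sort(ord[n_tr + seq_len(n_va)]),
                    test = sort(ord[(n_tr + n_va + 1L):n]))
      ok <- all(vapply(masks, function(i) length(unique(labels[i])) == 2,
                       logical(1)))
      if (ok) return(masks)
    }
    stop("could not draw a split with both classes in every part",
         call. = FALSE)
  })
}

#' Classification metrics for a binary diagnosis run
#'
#' Computes, with class 1 (tumor) as positive: precision TP/(TP+FP), recall
#' TP/(TP+FN), F1 (harmonic mean of the two), accuracy, and AUC as the
#' midrank (Mann-Whitney) statistic of the positive-class probability. A
#' degenerate denominator yields 0 with a warning.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @param y_prob Probability of class 1 (needed for AUC; may be `NULL`, in
#'   which case AUC is `NA`).
#' @return List of class `metrics_report` with fields `precision`, `recall`,
#'   `f1`, `accuracy`, `auc` and the confusion counts.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL) {
  stop_if(length(y_true) == 0, "empty input")
  stop_if(length(y_true) != length(y_pred), "length mismatch")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("degenerate denominator for ", what, "; reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("degenerate denominator for F1; reporting 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(y_true)
  auc <- NA_real_
  if (!is.null(y_prob)) {
    stop_if(length(y_prob) != length(y_true), "y_prob length mismatch")
    n1 <- sum(y_true == 1)
    n0 <- sum(y_true == 0)
    if (n1 == 0 || n0 == 0) {
      warning("single-class truth; AUC reported as 0", call. = FALSE)
      auc <- 0
    } else {
      r <- rank(y_prob)  # midranks handle probability ties
      auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, auc = auc,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f  AUC %s\n",
              x$precision, x$recall, x$f1, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Assemble a full pipeline configuration
#'
#' One object drives [run_pipeline()]: data source (real matrices or a
#' synthetic spec), SNF, DAE and DenseGCN settings, split fractions,
#' adjacency mode and seed.
#'
#' @param synthetic A [synthetic_spec()] used to generate data when `data`
#'   is `NULL`.
#' @param data Optional list with `matrices` (list of [omics_matrix()]) and
#'   `labels`; bypasses generation.
#' @param omics Optional character vector restricting the run to a subset of
#'   omic names (single-omic runs use that omic's full kernel as the PSN).
#' @param adjacency `"psn"` (fused similarity network) or `"identity"` (the
#'   graph-free ablation).
#' @param snf List with `alpha`, `K` (`NULL` = `default_snf_k(n)`),
#'   `iterations`.
#' @param dae A [dae_config()].
#' @param gcn A [gcn_config()].
#' @param split Train/validation/test fractions.
#' @param repeats Number of repeated experiments for [repeat_experiments()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for stage artifacts and the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            data = NULL,
                            omics = NULL,
                            adjacency = c("psn", "identity"),
                            snf = list(alpha = 0.5, K = NULL, iterations = 20),
                            dae = dae_config(),
                            gcn = gcn_config(),
                            split = c(0.6, 0.2, 0.2),
                            repeats = 5L,
                            seed = 1L,
                            out_dir = NULL) {
  adjacency <- match.arg(adjacency)
  structure(list(synthetic = synthetic, data = data, omics = omics,
                 adjacency = adjacency, snf = snf, dae = dae, gcn = gcn,
                 split = split, repeats = as.integer(repeats),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Resolve the data source for one run.
pipeline_data <- function(config) {
  if (!is.null(config$data)) {
    list(matrices = config$data$matrices, labels = config$data$labels)
  } else {
    gen <- generate_multiomics(config$synthetic)
    list(matrices = gen$matrices, labels = gen$labels)
  }
}

#' Run the full diagnosis pipeline once
#'
#' Stages: preprocessing (filter, intersect, impute, normalize); patient
#' similarity network by SNF on the normalized full-dimensional matrices
#' (single-omic runs use that omic's full kernel, symmetrized); one denoising
#' autoencoder per omic trained on training-mask samples only, encoding all
#' samples; column-wise concatenation of the latent matrices; transductive
#' DenseGCN training; metrics on the test mask.
#'
#' @param config A [pipeline_config()].
#' @param seed Optional override of `config$seed` for this run.
#' @return List of class `pipeline_result` with `metrics`
#'   ([compute_metrics()] on the test mask), `predictions`, `masks`,
#'   `history`, and `manifest` (stage sizes and derived seeds).
#' @export
run_pipeline <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- pipeline_data(config)
  pre <- preprocess_omics(dat$matrices, dat$labels)
  mats <- pre$matrices
  labels <- pre$labels
  if (!is.null(config$omics)) {
    keep <- vapply(mats, function(m) m$omic_name %in% config$omics, logical(1))
    stop_if(!any(keep), "no omics left after subsetting")
    mats <- mats[keep]
  }
  n <- length(labels)
  masks <- split_samples(labels, fractions = config$split,
                         seed = derive_seed(seed, 1000L))

  # --- patient similarity network (or identity ablation) -------------------
  K <- config$snf$K %||% default_snf_k(n)
  if (config$adjacency == "identity") {
    A <- diag(n)
  } else {
    Ws <- lapply(mats, function(m) {
      affinity_matrix(pairwise_distance(m$values), K = K,
                      alpha = config$snf$alpha)
    })
    A <- if (length(Ws) >= 2) {
      snf_fuse(Ws, K = K, iterations = config$snf$iterations)
    } else {
      P <- normalize_full(Ws[[1]])
      (P + t(P)) / 2
    }
  }

  # --- per-omic denoising autoencoders (trained on training rows only) -----
  latents <- vector("list", length(mats))
  dae_losses <- vector("list", length(mats))
  for (h in seq_along(mats)) {
    dcfg <- config$dae
    dcfg$seed <- derive_seed(seed, 2000L + h)
    model <- train_dae(mats[[h]]$values[masks$train, , drop = FALSE], dcfg)
    latents[[h]] <- encode(model, mats[[h]]$values)
    dae_losses[[h]] <- model$loss
  }
  features <- concat_latents(latents)

  # --- dense GCN classification --------------------------------------------
  gcfg <- config$gcn
  gcfg$seed <- derive_seed(seed, 3000L)
  gd <- graph_dataset(A, features, labels, masks)
  model <- train_densegcn(gd, gcfg)
  pred <- stats::predict(model, gd)
  te <- masks$test
  metrics <- compute_metrics(labels[te], pred$labels[te], pred$probs[te, 2L])

  manifest <- list(
    seed = seed,
    n_samples = n,
    omics = vapply(mats, function(m) m$omic_name, character(1)),
    omic_dims = vapply(mats, function(m) ncol(m$values), integer(1)),
    adjacency = config$adjacency,
    snf = list(alpha = config$snf$alpha, K = K,
               iterations = config$snf$iterations),
    dae = unclass(config$dae), gcn = unclass(config$gcn),
    split_sizes = vapply(masks, length, integer(1)),
    dae_train_rows = masks$train,
    stage_seeds = list(split = derive_seed(seed, 1000L),
                       dae = derive_seed(seed, 2001L),
                       gcn = derive_seed(seed, 3000L))
  )
  res <- structure(list(metrics = metrics, predictions = pred, masks = masks,
                        labels = labels, history = model$history,
                        adjacency = A, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir,
                                                      features)
  res
}

write_pipeline_result <- function(res, out_dir, features) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$adjacency, file.path(out_dir, "fused_network.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(features, file.path(out_dir, "latent_features.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(res$metrics[c("precision", "recall", "f1",
                                     "accuracy", "auc")],
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Repeat the pipeline and aggregate metrics
#'
#' Runs [run_pipeline()] with seeds `seed + 0 ... seed + repeats - 1`; each
#' repeat re-randomizes the split and every network initialisation. Reports
#' per-repeat metrics and their arithmetic mean.
#'
#' @param config A [pipeline_config()].
#' @param repeats Number of repeats (default `config$repeats`).
#' @return List of class `metrics_aggregate` with `per_repeat` (data frame)
#'   and `mean` (named numeric vector).
#' @export
repeat_experiments <- function(config, repeats = config$repeats) {
  stop_if(repeats < 1, "repeats must be >= 1")
  rows <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    res <- run_pipeline(config, seed = derive_seed(config$seed, i - 1L))
    m <- res$metrics
    rows[[i]] <- data.frame(repeat_id = i, seed = derive_seed(config$seed, i - 1L),
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, accuracy = m$accuracy, auc = m$auc)
  }
  per <- do.call(rbind, rows)
  structure(list(per_repeat = per,
                 mean = colMeans(per[, c("precision", "recall", "f1",
                                         "accuracy", "auc")])),
            class = "metrics_aggregate")
}

#' @export
print.metrics_aggregate <- function(x, ...) {
  cat(sprintf("%d repeats; mean: precision %.4f recall %.4f F1 %.4f accuracy %.4f AUC %.4f\n",
              nrow(x$per_repeat), x$mean["precision"], x$mean["recall"],
              x$mean["f1"], x$mean["accuracy"], x$mean["auc"]))
  invisible(x)
}

#' Matched ablation experiments
#'
#' `mode = "adjacency"` runs the pipeline with the fused patient similarity
#' network and with an identity matrix in its place, all else (data, splits,
#' seeds, architectures) equal. `mode = "omics"` enumerates the seven
#' non-empty subsets of the three omics. Each setting is aggregated over
#' `repeats` matched seeds.
#'
#' @param config A [pipeline_config()].
#' @param mode `"adjacency"` or `"omics"`.
#' @param repeats Repeats per setting (default `config$repeats`).
#' @return Data frame, one row per setting, with mean metrics.
#' @export
run_ablation <- function(config, mode = c("adjacency", "omics"),
                         repeats = config$repeats) {
  mode <- match.arg(mode)
  settings <- if (mode == "adjacency") {
    list(psn = list(adjacency = "psn", omics = config$omics),
         identity = list(adjacency = "identity", omics = config$omics))
  } else {
    dat <- pipeline_data(config)
    nm <- vapply(dat$matrices, function(m) m$omic_name, character(1))
    combos <- unlist(lapply(seq_along(nm), function(k) {
      utils::combn(nm, k, simplify = FALSE)
    }), recursive = FALSE)
    stats::setNames(
      lapply(combos, function(cc) list(adjacency = config$adjacency, omics = cc)),
      vapply(combos, paste, character(1), collapse = "+")
    )
  }
  rows <- lapply(names(settings), function(nm) {
    cfg <- config
    cfg$adjacency <- settings[[nm]]$adjacency
    cfg$omics <- settings[[nm]]$omics
    agg <- repeat_experiments(cfg, repeats)
    data.frame(setting = nm, t(agg$mean))
  })
  do.call(rbind, rows)
}

#' Adjacency ablation on a prebuilt graph dataset
#'
#' Trains the same DenseGCN on `data` with its own adjacency and with the
#' identity matrix, over `repeats` matched seeds (the split is re-drawn each
#' repeat), and reports mean test metrics side by side. This is the direct
#' form of the PSN-vs-no-PSN comparison for fixtures built at the graph
#' level, e.g. [generate_identity_unfavorable()].
#'
#' @param data A [graph_dataset()].
#' @param cfg A [gcn_config()].
#' @param repeats Matched repeats.
#' @param seed Master seed.
#' @param split Fractions for the per-repeat resplits.
#' @return Data frame with one row per adjacency mode.
#' @export
ablate_adjacency <- function(data, cfg = gcn_config(), repeats = 5L,
                             seed = 1L, split = c(0.6, 0.2, 0.2)) {
  stopifnot(inherits(data, "graph_dataset"))
  n <- length(data$labels)
  adj <- list(psn = data$adjacency, identity = diag(n))
  rows <- lapply(names(adj), function(nm) {
    accs <- matrix(NA_real_, repeats, 5,
                   dimnames = list(NULL, c("precision", "recall", "f1",
                                           "accuracy", "auc")))
    for (i in seq_len(repeats)) {
      masks <- split_samples(data$labels, fractions = split,
                             seed = derive_seed(seed, 100L + i))
      gd <- graph_dataset(adj[[nm]], data$features, data$labels, masks)
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(seed, 200L + i)
      model <- train_densegcn(gd, cfg_i)
      pred <- stats::predict(model, gd)
      te <- masks$test
      m <- compute_metrics(data$labels[te], pred$labels[te],
                           pred$probs[te, 2L])
      accs[i, ] <- c(m$precision, m$recall, m$f1, m$accuracy, m$auc)
    }
    data.frame(setting = nm, t(colMeans(accs)))
  })
  do.call(rbind, rows)
}
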