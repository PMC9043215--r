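#' Filter features and samples by missingness
#'
#' Removes features whose fraction of missing entries strictly exceeds
#' `feature_frac`, then removes samples missing strictly more than
#' `sample_frac` of the surviving features. Features are filtered first so a
#' sample is judged only on measurements that remain in play.
#'
#' @param m An [omics_matrix()].
#' @param feature_frac Maximum tolerated missing fraction per feature
#'   (default 0.2).
#' @param sample_frac Maximum tolerated missing fraction per sample over the
#'   surviving features (default 0.2).
#' @return Filtered [omics_matrix()].
#' @export
filter_missing <- function(m, feature_frac = 0.2, sample_frac = 0.2) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  keep_f <- colMeans(is.na(v)) <= feature_frac
  stop_if(!any(keep_f), "all features removed by missingness filter")
  v <- v[, keep_f, drop = FALSE]
  keep_s <- rowMeans(is.na(v)) <= sample_frac
  stop_if(!any(keep_s), "all samples removed by missingness filter")
  message(sprintf("%s: removed %d/%d features and %d/%d samples (> %g%% / %g%% missing)",
                  m$omic_name, sum(!keep_f), length(keep_f),
                  sum(!keep_s), length(keep_s),
                  100 * feature_frac, 100 * sample_frac))
  omics_matrix(v[keep_s, , drop = FALSE],
               sample_ids = m$sample_ids[keep_s],
               feature_ids = m$feature_ids[keep_f],
               omic_name = m$omic_name)
}

#' Restrict omics matrices and labels to their common samples
#'
#' Keeps only samples present in every matrix and in the label vector, and
#' reorders all of them to one canonical order (sorted sample IDs) so results
#' do not depend on input file order.
#'
#' @param matrices List of two or more [omics_matrix()] objects.
#' @param labels Named 0/1 integer vector (see [read_labels()]).
#' @return List with elements `matrices` (reordered list) and `labels`.
#' @export
intersect_samples <- function(matrices, labels) {
  stop_if(length(matrices) < 1, "at least one omics matrix required")
  common <- Reduce(intersect, lapply(matrices, function(m) m$sample_ids))
  common <- intersect(common, names(labels))
  stop_if(length(common) == 0, "no common samples across inputs")
  common <- sort(common)
  message(sprintf("%d common samples retained", length(common)))
  mats <- lapply(matrices, function(m) {
    omics_matrix(m$values[common, , drop = FALSE], sample_ids = common,
                 feature_ids = m$feature_ids, omic_name = m$omic_name)
  })
  list(matrices = mats, labels = labels[common])
}

#' Impute missing entries with feature means
#'
#' Replaces each missing entry by the mean of the observed values in its
#' feature column, computed on the post-filter data.
#'
#' @param m An [omics_matrix()].
#' @return [omics_matrix()] with no missing entries.
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  n_miss <- sum(is.na(v))
  if (n_miss > 0) {
    mu <- colMeans(v, na.rm = TRUE)
    stop_if(any(!is.finite(mu)),
            "feature(s) with no observed values; filter before imputing")
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2L]]
    message(sprintf("%s: imputed %d entries with feature means",
                    m$omic_name, n_miss))
  }
  omics_matrix(v, sample_ids = m$sample_ids, feature_ids = m$feature_ids,
               omic_name = m$omic_name)
}

#' Min-max normalize each feature to [0, 1]
#'
#' Maps every column X to (X - min X) / (max X - min X). A constant column
#' has zero range; it is mapped to all zeros with a warning rather than
#' dividing by zero.
#'
#' @param m An [omics_matrix()] with no missing entries.
#' @return Normalized [omics_matrix()] with all values in \[0, 1\].
#' @export
minmax_normalize <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  stop_if(anyNA(v), "missing entries present; impute before normalizing")
  check_finite(v, "omics matrix")
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sum(const), " constant column(s) mapped to 0", call. = FALSE)
    rng[const] <- 1
  }
  v <- sweep(sweep(v, 2L, lo, "-"), 2L, rng, "/")
  v[, const] <- 0
  omics_matrix(v, sample_ids = m$sample_ids, feature_ids = m$feature_ids,
               omic_name = m$omic_name)
}

#' Run the full preprocessing chain on a set of omics matrices
#'
#' Applies, in order: missingness filtering per omic, restriction to common
#' samples, mean imputation, and min-max normalization.
#'
#' @param matrices List of [omics_matrix()] objects.
#' @param labels Named 0/1 label vector.
#' @inheritParams filter_missing
#' @return List with `matrices` (analysis-ready, values in \[0,1\]) and
#'   `labels` in the shared canonical sample order.
#' @export
preprocess_omics <- function(matrices, labels,
                             feature_frac = 0.2, sample_frac = 0.2) {
  filtered <- lapply(matrices, filter_missing,
                     feature_frac = feature_frac, sample_frac = sample_frac)
  common <- intersect_samples(filtered, labels)
  mats <- lapply(common$matrices, function(m) minmax_normalize(impute_mean(m)))
  list(matrices = mats, labels = common$labels)
}
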