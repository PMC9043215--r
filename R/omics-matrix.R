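#' Construct an omics matrix
#'
#' An `omics_matrix` holds one data type's samples-by-features numeric matrix
#' together with its identifiers. Missing entries are represented as `NA` in
#' `values`; downstream preprocessing ([filter_missing()], [impute_mean()])
#' consumes and clears this mask.
#'
#' @param values Numeric matrix, rows = samples, columns = features. `NA`
#'   marks a missing measurement.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `colnames(values)`).
#' @param omic_name Label for the data type (e.g. `"rna"`, `"methylation"`,
#'   `"cnv"`).
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values), omic_name = "omic") {
  stop_if(!is.matrix(values) || !is.numeric(values),
          "values must be a numeric matrix")
  stop_if(is.null(sample_ids) || is.null(feature_ids),
          "sample and feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  stop_if(length(sample_ids) != nrow(values),
          "sample_ids length does not match row count")
  stop_if(length(feature_ids) != ncol(values),
          "feature_ids length does not match column count")
  stop_if(anyDuplicated(sample_ids) > 0, "duplicate sample IDs")
  stop_if(anyDuplicated(feature_ids) > 0, "duplicate feature IDs")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_ids = feature_ids, omic_name = omic_name),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s'> %d samples x %d features (%d missing entries)\n",
              x$omic_name, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Load an omics matrix from delimited text
#'
#' Reads a samples-by-features table with a header row of feature IDs and a
#' first column of sample IDs. Cells equal to one of `missing_tokens`
#' (or empty) are flagged missing.
#'
#' @param path Path to a TSV/CSV file. The separator is taken from the file
#'   extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param omic_name Label for the data type.
#' @param missing_tokens Strings treated as missing values.
#' @param sep Field separator; overrides the extension-based default.
#' @return An [omics_matrix()].
#' @export
load_omics <- function(path, omic_name = "omic",
                       missing_tokens = c("", "NA", "NaN", "null"),
                       sep = NULL) {
  stop_if(!file.exists(path), "file not found: ", path)
  stop_if(file.size(path) == 0, "empty file: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          row.names = NULL, quote = "\"", comment.char = "")
  stop_if(nrow(df) == 0 || ncol(df) < 2, "no data rows/columns in ", path)
  ids <- df[[1L]]
  stop_if(anyDuplicated(ids) > 0, "duplicate sample IDs in ", path)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  miss <- raw %in% missing_tokens | is.na(raw)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- !miss & is.na(vals)
  stop_if(any(bad), "non-numeric cell(s) in ", path, ", e.g. '",
          raw[which(bad)[1L]], "'")
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = nrow(raw), ncol = ncol(raw))
  message(sprintf("loaded %s: %d samples x %d features, %d missing",
                  omic_name, nrow(m), ncol(m), sum(is.na(m))))
  omics_matrix(m, sample_ids = ids, feature_ids = colnames(df)[-1L],
               omic_name = omic_name)
}

#' Read a binary label file
#'
#' @param path Two-column delimited file (sample_id, label) with a header;
#'   labels must be 0/1 with 1 = tumor.
#' @param sep Field separator (default from extension as in [load_omics()]).
#' @return Named integer vector of 0/1 labels, names = sample IDs.
#' @export
read_labels <- function(path, sep = NULL) {
  stop_if(!file.exists(path), "file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "integer"))
  stop_if(ncol(df) < 2, "label file needs sample_id and label columns")
  make_labels(df[[2L]], df[[1L]])
}

# Validate a 0/1 label vector keyed by sample ID.
make_labels <- function(labels, sample_ids) {
  stop_if(anyDuplicated(sample_ids) > 0, "duplicate sample IDs in labels")
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be 0 (normal) or 1 (tumor)")
  stats::setNames(as.integer(labels), as.character(sample_ids))
}
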