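test_that("load_omics parses delimited text and flags missing cells", {
  v <- matrix(c(1, 2, 3, 4, NA, 6), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  path <- write_omics_file(v)
  suppressMessages(m <- load_omics(path, "rna"))
  expect_s3_class(m, "omics_matrix")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(sum(is.na(m$values)), 1L)
  expect_identical(m$values["a", "g1"], 1)
  # csv round trip
  pcsv <- write_omics_file(v, sep = ",", ext = ".csv")
  suppressMessages(mcsv <- load_omics(pcsv, "rna"))
  expect_equal(mcsv$values, m$values)
})

test_that("load_omics rejects duplicates, non-numeric cells and empty files", {
  v <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(suppressMessages(load_omics(write_omics_file(v), "x")),
               "duplicate")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1", "a\t1.5", "b\toops"), path)
  expect_error(suppressMessages(load_omics(path, "x")), "non-numeric")
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(load_omics(empty, "x"), "empty")
})

test_that("filter_missing removes features first, then samples, at strict 20%", {
  # feature f3 missing in 3/10 samples (30%) -> removed; 4 features remain
  m <- toy_omics(10, 5, missing = cbind(1:3, 3))
  suppressMessages(f <- filter_missing(m))
  expect_identical(ncol(f$values), 4L)
  expect_false("f3" %in% f$feature_ids)

  # exactly 20% missing is kept (strict >)
  m2 <- toy_omics(10, 5, missing = cbind(1:2, 3))
  suppressMessages(f2 <- filter_missing(m2))
  expect_identical(ncol(f2$values), 5L)

  # sample missing 2 of 8 surviving features (25%) -> removed
  v <- matrix(stats::runif(80), 10, 8,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("f%d", 1:8)))
  v[1, 1:2] <- NA
  suppressMessages(f3 <- filter_missing(omics_matrix(v)))
  expect_identical(nrow(f3$values), 9L)
  expect_false("S01" %in% f3$sample_ids)

  # no missing values -> identity
  clean <- toy_omics(6, 4)
  suppressMessages(expect_equal(filter_missing(clean)$values, clean$values))

  # surviving features never get more missing
  m4 <- toy_omics(20, 10, missing = rbind(cbind(1:8, 1), cbind(1:2, 2)),
                  seed = 4)
  before <- colMeans(is.na(m4$values))
  suppressMessages(f4 <- filter_missing(m4))
  after <- colMeans(is.na(f4$values))
  expect_true(all(after <= before[f4$feature_ids] + 1e-12))
})

test_that("intersect_samples restricts to sorted common IDs", {
  mk <- function(ids, name) {
    omics_matrix(matrix(seq_along(ids) * 1.0, length(ids), 1,
                        dimnames = list(ids, "f1")), omic_name = name)
  }
  labels <- make_labels(c(0L, 1L, 0L, 1L), c("a", "b", "c", "d"))
  out <- suppressMessages(intersect_samples(
    list(mk(c("c", "a", "b"), "x"), mk(c("b", "c", "d"), "y"),
         mk(c("b", "c"), "z")), labels))
  expect_identical(out$matrices[[1]]$sample_ids, c("b", "c"))
  expect_identical(names(out$labels), c("b", "c"))
  # values follow the reordering
  expect_identical(out$matrices[[1]]$values["b", "f1"], 3)

  same <- suppressMessages(intersect_samples(
    list(mk(c("b", "a"), "x"), mk(c("a", "b"), "y")), labels))
  expect_identical(same$matrices[[1]]$sample_ids, c("a", "b"))

  expect_error(suppressMessages(intersect_samples(
    list(mk(c("a", "b"), "x"), mk(c("c", "d"), "y")), labels)),
    "no common samples")
})

test_that("impute_mean fills with column means and errors on empty columns", {
  v <- matrix(c(1, NA, 3, 5, 5, 5), 3,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  suppressMessages(out <- impute_mean(omics_matrix(v)))
  expect_equal(out$values[, "f1"], c(a = 1, b = 2, c = 3))
  expect_false(anyNA(out$values))

  clean <- toy_omics(5, 3)
  expect_equal(impute_mean(clean)$values, clean$values)

  v[, 2] <- NA
  expect_error(impute_mean(omics_matrix(v)), "no observed values")
})

test_that("minmax_normalize maps columns onto [0,1] and handles constants", {
  v <- matrix(c(2, 4, 6, 0, 0.5, 1, 5, 5, 5), 3,
              dimnames = list(c("a", "b", "c"), c("f1", "f2", "f3")))
  expect_warning(out <- minmax_normalize(omics_matrix(v)), "constant")
  expect_equal(out$values[, "f1"], c(a = 0, b = 0.5, c = 1))
  expect_equal(out$values[, "f2"], c(a = 0, b = 0.5, c = 1))  # already [0,1]
  expect_equal(unname(out$values[, "f3"]), c(0, 0, 0))

  # per-column min 0 and max 1 for non-constant columns; idempotent
  m <- toy_omics(12, 6, seed = 2)
  norm1 <- minmax_normalize(m)
  expect_equal(unname(apply(norm1$values, 2, min)), rep(0, 6))
  expect_equal(unname(apply(norm1$values, 2, max)), rep(1, 6))
  expect_equal(minmax_normalize(norm1)$values, norm1$values)

  bad <- omics_matrix(matrix(c(1, Inf), 2, 1,
                             dimnames = list(c("a", "b"), "f1")))
  expect_error(minmax_normalize(bad), "non-finite")
})

test_that("preprocess chain yields aligned, finite, [0,1] matrices", {
  spec <- synthetic_spec(n_samples = 30, dims = c(25, 25), latent_rank = 2,
                         separation = 3, noise_sd = 0.5, missing_rate = 0.1,
                         omic_names = c("rna", "cnv"), seed = 11)
  gen <- generate_multiomics(spec)
  out <- suppressMessages(suppressWarnings(
    preprocess_omics(gen$matrices, gen$labels)))
  ids <- out$matrices[[1]]$sample_ids
  expect_identical(out$matrices[[2]]$sample_ids, ids)
  expect_identical(names(out$labels), ids)
  for (m in out$matrices) {
    expect_false(anyNA(m$values))
    expect_true(all(m$values >= 0 & m$values <= 1))
  }
})
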