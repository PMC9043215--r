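test_that("normalize_adjacency matches the elementwise oracle", {
  expect_equal(normalize_adjacency(matrix(0, 2, 2)), diag(2))
  expect_equal(normalize_adjacency(rbind(c(0, 1), c(1, 0))),
               matrix(0.5, 2, 2))

  set.seed(1)
  A <- matrix(runif(49), 7, 7)
  A <- (A + t(A)) / 2
  out <- normalize_adjacency(A)
  expect_equal(out, oracle_normalize_adjacency(A), tolerance = 1e-12)
  expect_lt(max(abs(out - t(out))), 1e-12)

  expect_error(normalize_adjacency(rbind(c(0, 1), c(2, 0))), "symmetric")
  expect_error(normalize_adjacency(matrix(-1, 2, 2)), "nonnegative")
})

test_that("gcn_layer computes sigma(A H W) and matches a loop oracle", {
  H <- matrix(runif(10, 0.1, 1), 5, 2)
  expect_equal(gcn_layer(H, diag(5), diag(2), activation = identity), H)
  expect_equal(gcn_layer(matrix(0, 5, 2), diag(5), matrix(rnorm(6), 2, 3)),
               matrix(0, 5, 3))

  set.seed(2)
  A <- normalize_adjacency({a <- matrix(runif(25), 5, 5); (a + t(a)) / 2})
  W <- matrix(rnorm(2 * 3), 2, 3)
  out <- gcn_layer(H, A, W)
  ref <- matrix(0, 5, 3)
  for (i in 1:5) for (j in 1:3) {
    s <- 0
    for (k in 1:5) for (l in 1:2) s <- s + A[i, k] * H[k, l] * W[l, j]
    ref[i, j] <- max(s, 0)
  }
  expect_equal(out, ref, tolerance = 1e-12)
  expect_error(gcn_layer(H, A, matrix(0, 3, 2)), "shape mismatch")
})

test_that("densegcn_forward matches the straight-line dense oracle", {
  set.seed(3)
  n <- 6
  A <- normalize_adjacency({a <- matrix(runif(n * n), n, n); (a + t(a)) / 2})
  X <- matrix(rnorm(n * 4), n, 4)
  params <- with_seed_test(4, snfgcn:::densegcn_init(4, 3, 5))
  fw <- densegcn_forward(X, A, params)
  ref <- oracle_dense_forward(X, A, params)
  expect_equal(fw$probs, ref$probs, tolerance = 1e-6)
  expect_equal(fw$embedding, ref$embedding, tolerance = 1e-6)
  expect_equal(rowSums(fw$probs), rep(1, n), ignore_attr = TRUE)

  # a single block reduces to one graph-convolution layer on X
  p1 <- with_seed_test(5, snfgcn:::densegcn_init(4, 1, 5))
  fw1 <- densegcn_forward(X, A, p1)
  blk <- gcn_layer(X, A, p1$blocks[[1]]$W, p1$blocks[[1]]$b)
  expect_equal(fw1$embedding, cbind(X, blk), tolerance = 1e-12)
})

test_that("densegcn gradients agree with numerical differentiation", {
  set.seed(6)
  n <- 6
  A <- normalize_adjacency({a <- matrix(runif(n * n), n, n); (a + t(a)) / 2})
  X <- matrix(rnorm(n * 3), n, 3)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  tr <- c(1L, 2L, 4L, 6L)
  params <- with_seed_test(7, snfgcn:::densegcn_init(3, 2, 4))
  fw <- densegcn_forward(X, A, params, training = TRUE)
  g <- snfgcn:::densegcn_grads(X, A, params, fw, y, tr)
  loss_with <- function(set_param) {
    function(val) {
      p2 <- set_param(params, val)
      out <- densegcn_forward(X, A, p2)
      snfgcn:::masked_cross_entropy(out$probs, y, tr)
    }
  }
  checks <- list(
    W_out = list(get = params$W_out,
                 set = function(p, v) { p$W_out <- v; p }),
    b_out = list(get = params$b_out,
                 set = function(p, v) { p$b_out <- as.numeric(v); p }),
    W1 = list(get = params$blocks[[1]]$W,
              set = function(p, v) { p$blocks[[1]]$W <- v; p }),
    W2 = list(get = params$blocks[[2]]$W,
              set = function(p, v) { p$blocks[[2]]$W <- v; p }),
    b1 = list(get = params$blocks[[1]]$b,
              set = function(p, v) { p$blocks[[1]]$b <- as.numeric(v); p })
  )
  for (nm in names(checks)) {
    num <- numerical_grad(loss_with(checks[[nm]]$set), checks[[nm]]$get)
    expect_equal(as.vector(g[[nm]]), as.vector(num), tolerance = 1e-5)
  }
})

test_that("training is deterministic, tracks history, and bounds accuracy", {
  gd <- separable_graph(n = 40, seed = 8)
  cfg <- gcn_config(n_layers = 2, growth = 8, epochs = 30, dropout = 0.3,
                    seed = 9)
  m1 <- train_densegcn(gd, cfg)
  m2 <- train_densegcn(gd, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_identical(nrow(m1$history), 30L)
  expect_true(all(m1$history$val_acc <= 1 & m1$history$val_acc >= 0))
  expect_true(all(is.finite(m1$history$train_loss)))

  bad <- gd
  bad$labels[bad$masks$train] <- 0L
  expect_error(train_densegcn(bad, cfg), "both classes")
})

test_that("forward pass is permutation-equivariant over nodes", {
  set.seed(10)
  n <- 9
  A <- {a <- matrix(runif(n * n), n, n); (a + t(a)) / 2}
  An <- normalize_adjacency(A)
  X <- matrix(rnorm(n * 4), n, 4)
  params <- with_seed_test(11, snfgcn:::densegcn_init(4, 3, 6))
  base <- densegcn_forward(X, An, params)$probs
  perm <- sample(n)
  permuted <- densegcn_forward(X[perm, ], normalize_adjacency(A[perm, perm]),
                               params)$probs
  expect_equal(permuted, base[perm, ], tolerance = 1e-10)
})

test_that("identity adjacency degenerates to a per-node network", {
  set.seed(12)
  X <- matrix(rnorm(5 * 3), 5, 3)
  X[2, ] <- X[4, ]  # two nodes share features
  An <- normalize_adjacency(diag(5) * 0)  # A = 0 -> operator = I
  params <- with_seed_test(13, snfgcn:::densegcn_init(3, 2, 4))
  fw <- densegcn_forward(X, An, params)
  expect_equal(fw$probs[2, ], fw$probs[4, ], tolerance = 1e-12)
})

test_that("predict returns calibrated rows and breaks ties to class 0", {
  gd <- separable_graph(n = 40, seed = 14)
  model <- train_densegcn(gd, gcn_config(n_layers = 2, growth = 8,
                                         epochs = 20, dropout = 0, seed = 15))
  pred <- predict(model, gd)
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))
  expect_equal(rowSums(pred$probs), rep(1, 40), ignore_attr = TRUE)
  expect_identical(pred$labels,
                   as.integer(pred$probs[, 2] > pred$probs[, 1]))

  # zeroed classifier weights force exact 0.5/0.5 ties -> class 0, warned
  tied <- model
  tied$params$W_out[] <- 0
  tied$params$b_out[] <- 0
  expect_warning(tp <- predict(tied, gd), "tied")
  expect_true(all(tp$labels == 0L))
  expect_equal(tp$probs, matrix(0.5, 40, 2), ignore_attr = TRUE)
})

test_that("dense connections keep deep stacks trainable", {
  gd <- separable_graph(n = 60, seed = 16)
  for (L in c(3, 5, 10)) {
    model <- train_densegcn(gd, gcn_config(n_layers = L, growth = 16,
                                           epochs = 60, dropout = 0,
                                           seed = 17))
    h <- model$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
    expect_equal(max(h$train_acc), 1)
  }
})
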