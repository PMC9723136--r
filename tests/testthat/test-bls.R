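# helper: the ridge objective the closed form is supposed to minimize
ridge_objective <- function(W, A, Y, lambda) {
  sum((A %*% W - Y)^2) + lambda * sum(W^2)
}

test_that("identity activations with identity weights pass inputs through", {
  X <- withr::with_seed(1, matrix(rnorm(5 * 3), 5, 3))
  model <- structure(
    list(mapping = list(list(W = diag(3), beta = numeric(3))),
         enhancement = list(list(W = diag(3), beta = numeric(3))),
         input_dim = 3L, map_activation = "identity",
         enh_activation = "identity", class_codes = c("a", "b"),
         W_bls = NULL),
    class = "bls_model")
  A <- bls_features(model, X)
  expect_equal(A[, 1:3], X, ignore_attr = TRUE)
  expect_equal(A[, 4:6], X, ignore_attr = TRUE)  # enhancement of Z = Z here
})

test_that("zero inputs and zero biases give all-zero tanh features", {
  X <- matrix(0, 4, 6)
  m <- fit_bls(rbind(X, X + 1), rep(c("a", "b"), each = 4), n_map_groups = 2,
               nodes_per_group = 3, enh_nodes_per_group = 2, seed = 3)
  m0 <- m
  m0$mapping <- lapply(m$mapping, function(g) { g$beta[] <- 0; g })
  m0$enhancement <- lapply(m$enhancement, function(g) { g$beta[] <- 0; g })
  expect_equal(bls_features(m0, X), matrix(0, 4, 8), ignore_attr = TRUE)
})

test_that("row permutation of inputs permutes feature rows identically", {
  X <- withr::with_seed(2, matrix(rnorm(8 * 4), 8, 4))
  m <- fit_bls(X, rep(c("a", "b"), 4), n_map_groups = 2, nodes_per_group = 5,
               enh_nodes_per_group = 3, seed = 1)
  perm <- withr::with_seed(3, sample(8))
  expect_equal(bls_features(m, X[perm, ]), bls_features(m, X)[perm, ],
               tolerance = 1e-14)
})

test_that("closed-form weights match an independent normal-equations solve", {
  for (seed in 1:10) {
    X <- withr::with_seed(seed, matrix(rnorm(30 * 10), 30, 10))
    y <- rep(c("pos", "neg"), 15)
    lambda <- 0.1
    m <- fit_bls(X, y, n_map_groups = 2, nodes_per_group = 4,
                 n_enh_groups = 1, enh_nodes_per_group = 3,
                 lambda = lambda, seed = seed)
    A <- bls_features(m, X)
    Y <- cbind(neg = as.numeric(y == "neg"), pos = as.numeric(y == "pos"))
    W_ref <- qr.solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, Y))
    expect_equal(unname(m$W_bls), unname(W_ref), tolerance = 1e-8)
  }
})

test_that("closed form agrees with a generic convex optimizer", {
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(rnorm(20 * 5), 20, 5))
    y <- rep(c("a", "b"), 10)
    lambda <- 0.5
    m <- fit_bls(X, y, n_map_groups = 1, nodes_per_group = 3,
                 enh_nodes_per_group = 2, lambda = lambda, seed = seed)
    A <- bls_features(m, X)
    Y <- cbind(a = as.numeric(y == "a"), b = as.numeric(y == "b"))
    opt <- stats::optim(numeric(length(m$W_bls)),
                        fn = function(w) ridge_objective(matrix(w, ncol = 2), A, Y, lambda),
                        gr = function(w) {
                          W <- matrix(w, ncol = 2)
                          as.numeric(2 * crossprod(A, A %*% W - Y) + 2 * lambda * W)
                        },
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    expect_equal(unname(m$W_bls), matrix(opt$par, ncol = 2), tolerance = 1e-5)
  }
})

test_that("primal and dual ridge routes agree", {
  A <- withr::with_seed(7, matrix(rnorm(12 * 30), 12, 30))  # N < P -> dual
  Y <- withr::with_seed(8, matrix(rnorm(12 * 2), 12, 2))
  lambda <- 1e-3
  W_dual <- hofcn:::ridge_solve(A, Y, lambda)
  W_primal <- solve(crossprod(A) + lambda * diag(30), crossprod(A, Y))
  expect_equal(W_dual, W_primal, tolerance = 1e-8)
})

test_that("near-zero ridge interpolates an invertible square system", {
  X <- withr::with_seed(4, matrix(rnorm(6 * 6), 6, 6))
  y <- rep(c("a", "b"), 3)
  m <- fit_bls(X, y, n_map_groups = 1, nodes_per_group = 6,
               n_enh_groups = 1, enh_nodes_per_group = 6,
               lambda = 1e-12, seed = 2,
               map_activation = "identity", enh_activation = "tanh")
  pred <- predict_bls(m, X)
  expect_equal(as.character(pred$labels), y)
  Y <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  expect_equal(unname(pred$scores), Y, tolerance = 1e-6)
})

test_that("ridge shrinkage: giant lambda crushes the weights", {
  X <- withr::with_seed(5, matrix(rnorm(20 * 4), 20, 4))
  y <- rep(c("a", "b"), 10)
  m <- fit_bls(X, y, n_map_groups = 1, nodes_per_group = 4,
               enh_nodes_per_group = 2, lambda = 1e10, seed = 1)
  A <- bls_features(m, X)
  Y <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  bound <- sqrt(sum(crossprod(A, Y)^2)) / 1e10
  expect_lte(sqrt(sum(m$W_bls^2)), bound + 1e-12)
})

test_that("training error is non-increasing as lambda decreases", {
  X <- withr::with_seed(6, matrix(rnorm(24 * 6), 24, 6))
  y <- rep(c("a", "b"), 12)
  Y <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  m <- fit_bls(X, y, n_map_groups = 2, nodes_per_group = 4,
               enh_nodes_per_group = 3, lambda = 1, seed = 9)
  A <- bls_features(m, X)
  errs <- vapply(c(100, 10, 1, 0.1, 0.01, 1e-4), function(lam) {
    W <- hofcn:::ridge_solve(A, Y, lam)
    sum((A %*% W - Y)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("appending duplicate feature columns never hurts the fit", {
  A <- withr::with_seed(10, matrix(rnorm(25 * 6), 25, 6))
  Y <- withr::with_seed(11, matrix(rnorm(25 * 2), 25, 2))
  lam <- 1e-10
  res1 <- sum((A %*% hofcn:::ridge_solve(A, Y, lam) - Y)^2)
  A2 <- cbind(A, A[, 1:3])
  res2 <- sum((A2 %*% hofcn:::ridge_solve(A2, Y, lam) - Y)^2)
  expect_lte(res2, res1 + 1e-8)
})

test_that("well-separated clouds are classified perfectly on training data", {
  withr::with_seed(12, {
    X <- rbind(matrix(rnorm(30 * 4, mean = 0), 30, 4),
               matrix(rnorm(30 * 4, mean = 20), 30, 4))
  })
  y <- rep(c("near", "far"), each = 30)
  m <- fit_bls(scale(X), y, n_map_groups = 4, nodes_per_group = 10,
               enh_nodes_per_group = 5, lambda = 1e-6, seed = 1)
  expect_equal(mean(predict_bls(m, scale(X))$labels == y), 1)
})

test_that("fits are bitwise reproducible and predictions deterministic", {
  X <- withr::with_seed(13, matrix(rnorm(16 * 5), 16, 5))
  y <- rep(c("a", "b"), 8)
  m1 <- fit_bls(X, y, seed = 99, n_map_groups = 2, nodes_per_group = 4)
  m2 <- fit_bls(X, y, seed = 99, n_map_groups = 2, nodes_per_group = 4)
  expect_identical(m1$W_bls, m2$W_bls)
  Xt <- rbind(X[3, ], X[3, ])
  sc <- predict_bls(m1, Xt)$scores
  expect_identical(sc[1, ], sc[2, ])
})

test_that("invalid training setups are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_bls(X, rep("a", 5)), "single class",
               class = "hofcn_validation_error")
  expect_error(fit_bls(X, c("a", "a", "b", "b", "b"), lambda = 0),
               class = "hofcn_validation_error")
  m <- fit_bls(X, c("a", "a", "b", "b", "b"), n_map_groups = 1,
               nodes_per_group = 2, enh_nodes_per_group = 2, seed = 1)
  expect_error(predict_bls(m, matrix(0, 2, 3)), class = "hofcn_validation_error")
})
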