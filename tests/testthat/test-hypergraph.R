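test_that("1-D kNN example produces the expected hyperedges", {
  feats <- matrix(c(0, 1, 10, 11), ncol = 1)
  hg <- build_knn_hypergraph(feats, k = 1)
  H <- hg$incidence
  expect_equal(colSums(H), rep(2, 4), ignore_attr = TRUE)
  edge_sets <- apply(H, 2, function(col) which(col == 1), simplify = FALSE)
  expect_equal(edge_sets, list(c(1, 2), c(1, 2), c(3, 4), c(3, 4)))
})

test_that("kNN hyperedges match a brute-force nearest-neighbour scan", {
  for (seed in 1:20) {
    inst <- random_knn_hypergraph(seed)
    feats <- withr::with_seed(seed, {
      M <- sample(6:30, 1); k <- sample(1:5, 1)
      matrix(rnorm(M * 4), M, 4)
    })
    expected <- oracle_knn_edges(feats, inst$k)
    got <- apply(inst$hg$incidence, 2, function(col) which(col == 1),
                 simplify = FALSE)
    expect_equal(got, expected)
  }
})

test_that("k = M - 1 saturates the incidence matrix", {
  feats <- withr::with_seed(1, matrix(rnorm(6 * 3), 6, 3))
  hg <- build_knn_hypergraph(feats, k = 5)
  expect_true(all(hg$incidence == 1))
})

test_that("distance ties break toward the lowest vertex index", {
  # vertices 1 and 2 coincide; vertex 3 is equidistant from both
  feats <- matrix(c(0, 0, 5), ncol = 1)
  hg <- build_knn_hypergraph(feats, k = 1)
  sets <- apply(hg$incidence, 2, function(col) which(col == 1),
                simplify = FALSE)
  expect_equal(sets[[1]], c(1, 2))   # centre 1 picks its twin
  expect_equal(sets[[2]], c(1, 2))   # centre 2 picks its twin
  expect_equal(sets[[3]], c(1, 3))   # tie between 1 and 2 -> lowest index
})

test_that("k out of range and non-finite features are rejected", {
  feats <- matrix(rnorm(8), 4, 2)
  expect_error(build_knn_hypergraph(feats, 0), class = "hofcn_validation_error")
  expect_error(build_knn_hypergraph(feats, 4), class = "hofcn_validation_error")
  feats[2, 1] <- NA
  expect_error(build_knn_hypergraph(feats, 1), class = "hofcn_validation_error")
})

test_that("degrees follow their definitions and respect weight linearity", {
  feats <- withr::with_seed(2, matrix(rnorm(6 * 3), 6, 3))
  hg_full <- build_knn_hypergraph(feats, k = 5)
  deg <- hypergraph_degrees(hg_full)
  expect_equal(deg$degrees_v, rep(6, 6))
  expect_equal(deg$degrees_e, rep(6, 6))

  hg_pairs <- build_knn_hypergraph(matrix(c(0, 1, 10, 11), ncol = 1), k = 1)
  deg2 <- hypergraph_degrees(hg_pairs)
  expect_equal(deg2$degrees_e, rep(2, 4))
  expect_equal(deg2$degrees_v, c(2, 2, 2, 2))

  doubled <- hypergraph(hg_pairs$incidence, hg_pairs$weights * 2, k = 1)
  deg3 <- hypergraph_degrees(doubled)
  expect_equal(deg3$degrees_v, 2 * deg2$degrees_v)
  expect_equal(deg3$degrees_e, deg2$degrees_e)
})

test_that("degree conservation: sum d(v) equals sum w_e * delta(e)", {
  for (seed in 1:10) {
    inst <- random_knn_hypergraph(seed)
    deg <- hypergraph_degrees(inst$hg)
    expect_equal(sum(deg$degrees_v),
                 sum(inst$hg$weights * deg$degrees_e))
    expect_equal(sum(deg$degrees_v), sum(inst$hg$incidence),
                 ignore_attr = TRUE)
  }
})

test_that("a single all-vertex hyperedge gives Delta = I - J/n", {
  for (n in c(3, 4, 7)) {
    hg <- hypergraph(matrix(1L, n, 1), weights = 1)
    ho <- hypergraph_laplacian(hg)
    expected <- diag(n) - matrix(1 / n, n, n)
    expect_equal(ho$laplacian, expected, tolerance = 1e-14)
    ev <- eigen(ho$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev), c(0, rep(1, n - 1)), tolerance = 1e-12)
    # here d(v) = 1 so S = A and the normalized form coincides
    expect_equal(ho$assoc, matrix(1 / n, n, n), tolerance = 1e-14)
  }
})

test_that("the two-pair example yields the block normalized Laplacian", {
  hg <- build_knn_hypergraph(matrix(c(0, 1, 10, 11), ncol = 1), k = 1)
  ho <- hypergraph_laplacian(hg)
  block <- matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2)
  expected <- rbind(cbind(block, matrix(0, 2, 2)),
                    cbind(matrix(0, 2, 2), block))
  expect_equal(ho$laplacian_norm, expected, tolerance = 1e-14)
})

test_that("Laplacian equals the brute-force triple-loop accumulation", {
  for (seed in 1:8) {
    hg <- withr::with_seed(seed, {
      M <- sample(4:10, 1)
      k <- sample(1:3, 1)
      build_knn_hypergraph(matrix(rnorm(M * 3), M, 3), k)
    })
    expect_equal(hypergraph_laplacian(hg)$laplacian,
                 oracle_laplacian(hg$incidence, hg$weights),
                 tolerance = 1e-12)
  }
})

test_that("spectral and stochasticity properties hold on random hypergraphs", {
  for (seed in 1:25) {
    inst <- random_knn_hypergraph(seed)
    ho <- hypergraph_laplacian(inst$hg)
    M <- inst$M
    expect_lt(max(abs(ho$laplacian %*% rep(1, M))), 1e-10)
    ev_lap <- eigen(ho$laplacian, symmetric = TRUE, only.values = TRUE)$values
    ev_norm <- eigen(ho$laplacian_norm, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev_lap), -1e-10)
    expect_gt(min(ev_norm), -1e-10)
    expect_lt(max(ev_norm), 2 + 1e-10)
    # D_v^{-1} H W D_e^{-1} H^T is row-stochastic
    P <- ho$assoc * outer(1 / sqrt(ho$degrees_v), sqrt(ho$degrees_v))
    expect_equal(rowSums(P), rep(1, M), tolerance = 1e-10)
  }
})

test_that("zero-degree structures are rejected", {
  H <- rbind(c(1, 1), c(0, 1), c(0, 0))
  expect_error(hypergraph(H, c(1, 1)), "isolated",
               class = "hofcn_validation_error")
})

test_that("high-order features vectorize the association operator", {
  hg <- hypergraph(matrix(1L, 4, 1), weights = 1)
  fv <- ho_features(hypergraph_laplacian(hg))
  expect_equal(fv$values, rep(0.25, 6))
})

test_that("permuting ROIs permutes features consistently", {
  feats <- withr::with_seed(9, matrix(rnorm(8 * 3), 8, 3))
  perm <- withr::with_seed(10, sample(8))
  ho <- hypergraph_laplacian(build_knn_hypergraph(feats, 2))
  ho_p <- hypergraph_laplacian(build_knn_hypergraph(feats[perm, ], 2))
  expect_equal(ho_p$assoc, ho$assoc[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("at saturation (k = M - 1) features are independent of the feature matrix", {
  f1 <- withr::with_seed(11, matrix(rnorm(5 * 2), 5, 2))
  f2 <- withr::with_seed(12, matrix(rnorm(5 * 6), 5, 6))
  s1 <- hypergraph_laplacian(build_knn_hypergraph(f1, 4))$assoc
  s2 <- hypergraph_laplacian(build_knn_hypergraph(f2, 4))$assoc
  expect_equal(s1, s2, tolerance = 1e-14)
})

test_that("subject_ho_features runs both feature spaces end to end", {
  ts <- roi_timeseries(withr::with_seed(13, matrix(rnorm(40 * 8), 40, 8)))
  fv1 <- subject_ho_features(ts, k = 3, feature_space = "fcn_rows")
  fv2 <- subject_ho_features(ts, k = 3, feature_space = "timeseries")
  expect_length(fv1$values, 28)
  expect_length(fv2$values, 28)
})

test_that("incidence export writes coordinate triples", {
  hg <- build_knn_hypergraph(matrix(c(0, 1, 10, 11), ncol = 1), k = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_incidence_coo(hg, f)
  coo <- utils::read.table(f, header = TRUE)
  expect_equal(nrow(coo), sum(hg$incidence))
  expect_true(all(coo$value == 1))
})
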