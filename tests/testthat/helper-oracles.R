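# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately avoid the code paths they verify.

# scalar Pearson correlation, direct evaluation of the defining formula
oracle_pearson <- function(u, v) {
  du <- u - mean(u)
  dv <- v - mean(v)
  sum(du * dv) / (sqrt(sum(du^2)) * sqrt(sum(dv^2)))
}

# full correlation matrix by double loop over the scalar formula
oracle_pearson_matrix <- function(X) {
  M <- ncol(X)
  C <- diag(1, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i != j) C[i, j] <- oracle_pearson(X[, i], X[, j])
  }
  C
}

# nearest-neighbour scan: hyperedge vertex sets by exhaustive distance
# comparison with lowest-index tie-breaking
oracle_knn_edges <- function(features, k) {
  M <- nrow(features)
  lapply(seq_len(M), function(centre) {
    d <- apply(features, 1, function(r) sqrt(sum((r - features[centre, ])^2)))
    d[centre] <- Inf
    ord <- order(d, seq_len(M))
    sort(c(centre, ord[seq_len(k)]))
  })
}

# hypergraph Laplacian by triple loop over (v, e, v') accumulation
oracle_laplacian <- function(H, w) {
  M <- nrow(H); E <- ncol(H)
  dv <- numeric(M); de <- numeric(E)
  for (i in seq_len(M)) for (j in seq_len(E)) dv[i] <- dv[i] + w[j] * H[i, j]
  for (j in seq_len(E)) for (i in seq_len(M)) de[j] <- de[j] + H[i, j]
  A <- matrix(0, M, M)
  for (u in seq_len(M)) for (v in seq_len(M)) for (e in seq_len(E)) {
    A[u, v] <- A[u, v] + w[e] * H[u, e] * H[v, e] / de[e]
  }
  diag(dv) - A
}

# random kNN hypergraph instance for property sweeps
random_knn_hypergraph <- function(seed) {
  withr::with_seed(seed, {
    M <- sample(6:30, 1)
    k <- sample(1:5, 1)
    feats <- matrix(stats::rnorm(M * 4), M, 4)
    list(hg = build_knn_hypergraph(feats, k), M = M, k = k)
  })
}

# small on-disk synthetic dataset for io/pipeline tests
make_tiny_dataset <- function(dir, n_per_class = 6, n_rois = 12, seed = 3,
                              delta = 0.4) {
  spec <- synthetic_spec(n_per_class = n_per_class, n_rois = n_rois,
                         n_timepoints = 60, n_modules = 3,
                         between_module_corr_case = 0.1 + delta, seed = seed)
  generate_dataset(spec, dir)
}

tiny_pipeline_config <- function(n_folds = 3, ...) {
  pipeline_config(ae_bottleneck = 8, ae_epochs = 15, ae_batch_size = 8,
                  bls_map_groups = 4, bls_window = 10, bls_enh_nodes = 4,
                  n_folds = n_folds, n_repeats = 1, ...)
}
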