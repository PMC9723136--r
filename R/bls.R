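# Broad Learning System. Inputs are projected through n groups of randomly
# weighted mapping nodes Z_i = phi(X W_ei + beta_ei); the concatenated
# mapping layer Z = [Z_1 ... Z_n] feeds m groups of enhancement nodes
# H_j = delta(Z W_hj + beta_hj); and the output weights of the flat network
# Y = [Z | H] W are solved in closed form by ridge regression against
# one-hot class targets. Random weights and biases are drawn uniform on
# [-1, 1], the convention of the original broad-learning literature; no
# iterative training is involved.

bls_activation <- function(name) {
  switch(name,
         tanh = tanh,
         identity = identity,
         stop_hofcn("unknown activation: ", name,
                    class = "hofcn_validation_error"))
}

bls_random_params <- function(input_dim, cfg, seed) {
  withr::with_seed(seed, {
    runifm <- function(r, c) matrix(stats::runif(r * c, -1, 1), r, c)
    mapping <- lapply(seq_len(cfg$n_map_groups), function(i)
      list(W = runifm(input_dim, cfg$nodes_per_group),
           beta = stats::runif(cfg$nodes_per_group, -1, 1)))
    z_dim <- cfg$n_map_groups * cfg$nodes_per_group
    enhancement <- lapply(seq_len(cfg$n_enh_groups), function(i)
      list(W = runifm(z_dim, cfg$enh_nodes_per_group),
           beta = stats::runif(cfg$enh_nodes_per_group, -1, 1)))
    list(mapping = mapping, enhancement = enhancement)
  })
}

#' Feature matrix of a BLS model
#'
#' Computes the concatenated mapping and enhancement node activations
#' `[Z_1 ... Z_n | H_1 ... H_m]` for a data matrix. Deterministic given the
#' model (the random projections are stored, not re-drawn).
#'
#' @param model A `bls_model`.
#' @param X Numeric N x D matrix, D matching the model input dimension.
#' @return Numeric N x (n*w + m*h) matrix.
#' @export
bls_features <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop_hofcn("input has ", ncol(X), " columns but the model expects ",
               model$input_dim, class = "hofcn_validation_error")
  }
  phi <- bls_activation(model$map_activation)
  dlt <- bls_activation(model$enh_activation)
  Z <- do.call(cbind, lapply(model$mapping, function(g)
    phi(sweep(X %*% g$W, 2, g$beta, "+"))))
  H <- do.call(cbind, lapply(model$enhancement, function(g)
    dlt(sweep(Z %*% g$W, 2, g$beta, "+"))))
  cbind(Z, H)
}

# exact ridge solve; uses the dual identity when the sample count is
# smaller than the node count, which keeps the Gram matrix small and
# well-conditioned at tiny lambda
ridge_solve <- function(A, Y, lambda) {
  N <- nrow(A); P <- ncol(A)
  if (P <= N) {
    solve(crossprod(A) + lambda * diag(P), crossprod(A, Y))
  } else {
    crossprod(A, solve(tcrossprod(A) + lambda * diag(N), Y))
  }
}

#' Fit a Broad Learning System classifier
#'
#' Draws the random mapping and enhancement parameters from `seed`, builds
#' the feature matrix `A = [Z | H]`, and solves the ridge problem
#' `min ||A W - Y||^2 + lambda ||W||^2` in closed form against one-hot
#' class targets.
#'
#' @param X Numeric N x D training matrix.
#' @param labels Factor (or coercible) of class labels, at least 2 classes.
#' @param n_map_groups Number of mapping-node groups n (default 20).
#' @param nodes_per_group Nodes per mapping group, the "window size" w
#'   (default 100).
#' @param n_enh_groups Number of enhancement groups m (default 1).
#' @param enh_nodes_per_group Enhancement nodes per group h (default 10).
#' @param lambda Ridge penalty, must be positive (default 1e-8).
#' @param seed Integer RNG seed for the random projections (default 1).
#' @param map_activation,enh_activation Nonlinearity names, `"tanh"`
#'   (default) or `"identity"` (for testing).
#' @return An object of class `bls_model` containing the stored random
#'   parameters, the trained output weights `W_bls`, and `class_codes` (the
#'   ordered class levels).
#' @export
fit_bls <- function(X, labels,
                    n_map_groups = 20, nodes_per_group = 100,
                    n_enh_groups = 1, enh_nodes_per_group = 10,
                    lambda = 1e-8, seed = 1,
                    map_activation = "tanh", enh_activation = "tanh") {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) {
    stop_hofcn("training labels contain a single class (",
               levels(labels), "); need at least 2",
               class = "hofcn_validation_error")
  }
  if (length(labels) != nrow(X)) {
    stop_hofcn("labels length must match nrow(X)", class = "hofcn_validation_error")
  }
  if (lambda <= 0) {
    stop_hofcn("lambda must be positive", class = "hofcn_validation_error")
  }
  cfg <- list(n_map_groups = n_map_groups, nodes_per_group = nodes_per_group,
              n_enh_groups = n_enh_groups, enh_nodes_per_group = enh_nodes_per_group)
  if (any(unlist(cfg) < 1)) {
    stop_hofcn("all node-count settings must be >= 1", class = "hofcn_validation_error")
  }
  par <- bls_random_params(ncol(X), cfg, seed)
  model <- structure(
    list(mapping = par$mapping, enhancement = par$enhancement,
         input_dim = ncol(X), map_activation = map_activation,
         enh_activation = enh_activation, lambda = lambda, seed = seed,
         class_codes = levels(labels), W_bls = NULL),
    class = "bls_model")
  A <- bls_features(model, X)
  Y <- stats::model.matrix(~ labels - 1)   # one-hot, column order = levels
  colnames(Y) <- levels(labels)
  model$W_bls <- ridge_solve(A, Y, lambda)
  model
}

#' @export
print.bls_model <- function(x, ...) {
  n_map <- length(x$mapping) * ncol(x$mapping[[1]]$W)
  n_enh <- length(x$enhancement) * ncol(x$enhancement[[1]]$W)
  cat(sprintf("<bls_model> %d mapping + %d enhancement nodes -> %d classes (lambda = %g)\n",
              n_map, n_enh, length(x$class_codes), x$lambda))
  invisible(x)
}

#' Predict with a trained BLS model
#'
#' Scores are `bls_features(X) %*% W_bls`; the predicted label is the class
#' with the highest score, ties broken toward the earlier class in
#' `class_codes`.
#'
#' @param model A fitted `bls_model`.
#' @param X Numeric N x D matrix.
#' @return List with `labels` (factor with the model's class levels) and
#'   `scores` (N x c numeric matrix, columns named by class).
#' @export
predict_bls <- function(model, X) {
  if (is.null(model$W_bls)) {
    stop_hofcn("model has no trained output weights", class = "hofcn_validation_error")
  }
  scores <- bls_features(model, X) %*% model$W_bls
  colnames(scores) <- model$class_codes
  idx <- max.col(scores, ties.method = "first")
  list(labels = factor(model$class_codes[idx], levels = model$class_codes),
       scores = scores)
}
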