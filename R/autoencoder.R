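# Stacked autoencoder for nonlinear dimensionality reduction of the
# high-order connectivity features. The encoder applies L tanh layers with
# strictly decreasing widths; the decoder mirrors the widths in reverse with
# strictly linear layers. Training minimizes the mean squared reconstruction
# error by mini-batch gradient descent with analytically derived gradients
# (plain backpropagation; no autodiff dependency needed at these scales).
# The default optimizer is Adam: plain SGD needs orders of magnitude more
# epochs to move a deep tanh stack off its initialization on data of this
# shape.

#' Geometric layer widths for the encoder
#'
#' Interpolates widths geometrically from the input dimension down to the
#' bottleneck over `n_layers` encoder layers, rounding to integers and
#' enforcing strict decrease.
#'
#' @param input_dim Input feature dimension D.
#' @param bottleneck Bottleneck width (default 512, sized for atlas-scale
#'   inputs of ~2e4 features; pass something smaller for desk-scale data).
#' @param n_layers Number of encoder layers L (default 3).
#' @return Integer vector of length `n_layers + 1`: `input_dim`, the hidden
#'   widths, then `bottleneck`.
#' @export
ae_layer_dims <- function(input_dim, bottleneck = 512, n_layers = 3) {
  if (bottleneck >= input_dim) {
    stop_hofcn("bottleneck (", bottleneck, ") must be smaller than the input ",
               "dimension (", input_dim, ")", class = "hofcn_validation_error")
  }
  dims <- round(exp(seq(log(input_dim), log(bottleneck), length.out = n_layers + 1)))
  # rounding can create plateaus on small inputs; force strict decrease
  for (i in 2:length(dims)) {
    if (dims[i] >= dims[i - 1]) dims[i] <- dims[i - 1] - 1L
  }
  if (any(dims < 1)) {
    stop_hofcn("cannot fit ", n_layers, " strictly decreasing layers between ",
               input_dim, " and ", bottleneck, class = "hofcn_validation_error")
  }
  as.integer(dims)
}

ae_init <- function(layer_dims) {
  L <- length(layer_dims) - 1L
  rev_dims <- rev(layer_dims)
  glorot <- function(fan_in, fan_out) {
    r <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
  }
  list(
    W_enc = lapply(seq_len(L), function(l) glorot(layer_dims[l], layer_dims[l + 1])),
    b_enc = lapply(seq_len(L), function(l) numeric(layer_dims[l + 1])),
    W_dec = lapply(seq_len(L), function(l) glorot(rev_dims[l], rev_dims[l + 1])),
    b_dec = lapply(seq_len(L), function(l) numeric(rev_dims[l + 1]))
  )
}

# forward pass keeping activations for backprop
ae_forward <- function(par, X) {
  L <- length(par$W_enc)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  h <- X
  for (l in seq_len(L)) {
    h <- tanh(sweep(h %*% par$W_enc[[l]], 2, par$b_enc[[l]], "+"))
    acts[[l + 1]] <- h
  }
  dec <- vector("list", L + 1L)
  dec[[1]] <- h
  for (l in seq_len(L)) {
    h <- sweep(h %*% par$W_dec[[l]], 2, par$b_dec[[l]], "+")
    dec[[l + 1]] <- h
  }
  list(acts = acts, dec = dec, xhat = h)
}

ae_loss <- function(par, X) {
  mean((ae_forward(par, X)$xhat - X)^2)
}

# gradients of mean((xhat - X)^2) w.r.t. every parameter
ae_gradients <- function(par, X) {
  L <- length(par$W_enc)
  fw <- ae_forward(par, X)
  n_entries <- length(X)
  G <- 2 * (fw$xhat - X) / n_entries
  gW_dec <- vector("list", L); gb_dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW_dec[[l]] <- crossprod(fw$dec[[l]], G)
    gb_dec[[l]] <- colSums(G)
    G <- tcrossprod(G, par$W_dec[[l]])
  }
  gW_enc <- vector("list", L); gb_enc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    G <- G * (1 - fw$acts[[l + 1]]^2)      # tanh'(z) = 1 - tanh(z)^2
    gW_enc[[l]] <- crossprod(fw$acts[[l]], G)
    gb_enc[[l]] <- colSums(G)
    G <- tcrossprod(G, par$W_enc[[l]])
  }
  list(W_enc = gW_enc, b_enc = gb_enc, W_dec = gW_dec, b_dec = gb_dec)
}

#' Fit a stacked autoencoder
#'
#' Trains the whole encoder/decoder stack jointly by mini-batch gradient
#' descent on the mean squared reconstruction error. Training is fully
#' deterministic given `seed` (weight initialization and batch shuffling
#' both draw from it).
#'
#' @param X Numeric N x D data matrix (rows are samples).
#' @param layer_dims Integer vector of widths, input dimension first and
#'   bottleneck last; see [ae_layer_dims()].
#' @param epochs Number of passes over the data (default 200).
#' @param batch_size Mini-batch size (default 32). If `N < batch_size`
#'   training silently falls back to full batch, with a warning.
#' @param learning_rate Step size (default 1e-3, the Adam convention).
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient steps).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `autoencoder_model` with the trained
#'   parameters, `layer_dims`, and `loss_history` — a numeric vector of
#'   length `epochs + 1` whose first element is the loss at initialization
#'   and element `e + 1` the full-data loss after epoch `e`.
#' @export
fit_autoencoder <- function(X, layer_dims, epochs = 200, batch_size = 32,
                            learning_rate = 1e-3,
                            optimizer = c("adam", "sgd"), seed = 1) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 2L) {
    stop_hofcn("need at least 2 samples to train", class = "hofcn_validation_error")
  }
  if (ncol(X) != layer_dims[1]) {
    stop_hofcn("layer_dims[1] (", layer_dims[1], ") must equal ncol(X) (",
               ncol(X), ")", class = "hofcn_validation_error")
  }
  if (any(diff(layer_dims) >= 0)) {
    stop_hofcn("encoder layer widths must be strictly decreasing",
               class = "hofcn_validation_error")
  }
  if (N < batch_size) {
    warning("N (", N, ") < batch_size (", batch_size, "); using full-batch training")
    batch_size <- N
  }
  withr::with_seed(seed, {
    par <- ae_init(layer_dims)
    slots <- c("W_enc", "b_enc", "W_dec", "b_dec")
    if (optimizer == "adam") {
      mom1 <- rapply(par, function(p) p * 0, how = "replace")
      mom2 <- mom1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      step <- 0L
    }
    loss_history <- numeric(epochs + 1L)
    loss_history[1] <- ae_loss(par, X)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, N)]
        g <- ae_gradients(par, X[idx, , drop = FALSE])
        if (optimizer == "adam") {
          step <- step + 1L
          corr1 <- 1 - b1^step
          corr2 <- 1 - b2^step
          for (sl in slots) for (l in seq_along(par[[sl]])) {
            mom1[[sl]][[l]] <- b1 * mom1[[sl]][[l]] + (1 - b1) * g[[sl]][[l]]
            mom2[[sl]][[l]] <- b2 * mom2[[sl]][[l]] + (1 - b2) * g[[sl]][[l]]^2
            par[[sl]][[l]] <- par[[sl]][[l]] - learning_rate *
              (mom1[[sl]][[l]] / corr1) / (sqrt(mom2[[sl]][[l]] / corr2) + eps)
          }
        } else {
          for (sl in slots) for (l in seq_along(par[[sl]])) {
            par[[sl]][[l]] <- par[[sl]][[l]] - learning_rate * g[[sl]][[l]]
          }
        }
      }
      loss_history[epoch + 1L] <- ae_loss(par, X)
      if (!is.finite(loss_history[epoch + 1L])) {
        stop_hofcn("training diverged (non-finite loss at epoch ", epoch,
                   "); try a smaller learning_rate",
                   class = "hofcn_divergence_error")
      }
    }
  })
  structure(c(par, list(layer_dims = as.integer(layer_dims),
                        n_layers = length(layer_dims) - 1L,
                        loss_history = loss_history,
                        seed = seed)),
            class = "autoencoder_model")
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("<autoencoder_model> %s; final reconstruction MSE %.4g\n",
              paste(x$layer_dims, collapse = " -> "),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Encode data with a trained autoencoder
#'
#' Applies the tanh encoder layers; output columns equal the bottleneck
#' width and all entries lie in (-1, 1).
#'
#' @param model An `autoencoder_model`.
#' @param X Numeric N x D matrix with D matching the model input dimension.
#' @return Numeric N x bottleneck matrix.
#' @export
ae_encode <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_dims[1]) {
    stop_hofcn("input has ", ncol(X), " columns but the model expects ",
               model$layer_dims[1], class = "hofcn_validation_error")
  }
  h <- X
  for (l in seq_len(model$n_layers)) {
    h <- tanh(sweep(h %*% model$W_enc[[l]], 2, model$b_enc[[l]], "+"))
  }
  h
}

#' Reconstruct data with a trained autoencoder
#'
#' Runs the full encoder/decoder stack (linear decoder).
#'
#' @param model An `autoencoder_model`.
#' @param X Numeric N x D matrix.
#' @return Numeric N x D reconstruction.
#' @export
ae_reconstruct <- function(model, X) {
  ae_forward(model[c("W_enc", "b_enc", "W_dec", "b_dec")], as.matrix(X))$xhat
}
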