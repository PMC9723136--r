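# Low-order functional connectivity: the M x M matrix of pairwise Pearson
# correlations between ROI time courses, and the vectorization of symmetric
# matrices into feature vectors for the learners.

#' Low-order functional connectivity network
#'
#' Computes the M x M Pearson correlation matrix of a subject's ROI time
#' series (the low-order FCN). The diagonal is forced to exactly 1 and the
#' matrix is symmetrized to remove floating-point drift, so downstream
#' hypergraph distances see a clean symmetric matrix. No Fisher z-transform
#' and no thresholding are applied; raw correlations flow downstream.
#'
#' @param ts A [roi_timeseries] (or plain numeric matrix, time points in
#'   rows).
#' @return An object of class `fcn_matrix`: a list with `values` (M x M
#'   symmetric matrix, unit diagonal, entries in `[-1, 1]`), `kind =
#'   "low_order"` and `roi_labels`.
#' @export
pearson_fcn <- function(ts) {
  X <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  if (nrow(X) < 3L) {
    stop_hofcn("need at least 3 time points for a correlation, got ", nrow(X),
               class = "hofcn_validation_error")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    bad <- which(sds < .Machine$double.eps)
    labs <- colnames(X)
    labs <- if (is.null(labs)) as.character(bad) else labs[bad]
    stop_hofcn("constant (zero-variance) ROI signal: ",
               paste(labs, collapse = ", "),
               "; a flat BOLD signal is a data defect, not a zero correlation",
               class = "hofcn_validation_error")
  }
  C <- stats::cor(X)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  fcn_matrix(C, kind = "low_order", roi_labels = colnames(X))
}

#' FCN matrix container
#'
#' @param values Symmetric numeric matrix.
#' @param kind `"low_order"` or `"high_order"`.
#' @param roi_labels Optional ROI labels.
#' @param tol Symmetry tolerance.
#' @return An object of class `fcn_matrix`.
#' @export
fcn_matrix <- function(values, kind = c("low_order", "high_order"),
                       roi_labels = NULL, tol = 1e-10) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_hofcn("FCN matrix must be square", class = "hofcn_validation_error")
  }
  if (max(abs(values - t(values))) > tol) {
    stop_hofcn("FCN matrix asymmetric beyond tolerance ", tol,
               class = "hofcn_validation_error")
  }
  structure(list(values = values, kind = kind, roi_labels = roi_labels),
            class = "fcn_matrix")
}

#' @export
print.fcn_matrix <- function(x, ...) {
  cat(sprintf("<fcn_matrix> %s, %d x %d\n", x$kind, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Emits the strict upper triangle (i < j) in row-major order together with
#' its index map, giving a feature vector of length M(M-1)/2.
#'
#' @param m An `fcn_matrix` or symmetric numeric matrix.
#' @param tol Symmetry tolerance.
#' @return An object of class `feature_vector`: `values` (numeric vector),
#'   `index_map` (two-column integer matrix of (i, j) pairs, i < j, row-major
#'   order), `n` (matrix dimension).
#' @export
vectorize_upper <- function(m, tol = 1e-10) {
  V <- if (inherits(m, "fcn_matrix")) m$values else as.matrix(m)
  if (nrow(V) != ncol(V) || max(abs(V - t(V))) > tol) {
    stop_hofcn("matrix must be symmetric to within ", tol,
               class = "hofcn_validation_error")
  }
  M <- nrow(V)
  lt <- lower.tri(V)
  # column-major traversal of the lower triangle visits (j+1..M, j) for
  # j = 1..M-1, i.e. the row-major order of the upper triangle of t(V) = V
  idx <- which(lt, arr.ind = TRUE)
  index_map <- cbind(i = idx[, "col"], j = idx[, "row"])
  structure(list(values = V[lt], index_map = index_map, n = M),
            class = "feature_vector")
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is filled with `diag_value`
#' (1 for a low-order FCN).
#'
#' @param fv A `feature_vector`.
#' @param diag_value Diagonal fill value.
#' @param kind Passed to [fcn_matrix()].
#' @return An `fcn_matrix`.
#' @export
devectorize_upper <- function(fv, diag_value = 1, kind = "low_order") {
  M <- fv$n
  V <- matrix(0, M, M)
  V[lower.tri(V)] <- fv$values
  V <- V + t(V)
  diag(V) <- diag_value
  fcn_matrix(V, kind = kind)
}

#' Export an FCN matrix as square CSV
#'
#' @param m An `fcn_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcn_csv <- function(m, path) {
  V <- m$values
  if (!is.null(m$roi_labels)) colnames(V) <- m$roi_labels
  utils::write.csv(V, path, row.names = FALSE)
  invisible(path)
}
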