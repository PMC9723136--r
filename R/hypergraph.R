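# Hypergraph-based high-order functional connectivity. Each ROI in turn is
# taken as a centre vertex; a hyperedge joins the centre with its k nearest
# vertices in Euclidean distance, giving exactly M hyperedges of size k+1.
# From the binary incidence matrix H and hyperedge weights W the vertex and
# hyperedge degrees, the hypergraph Laplacian
#   Delta = D_v - H W D_e^{-1} H^T,
# its normalized form
#   I - D_v^{-1/2} H W D_e^{-1} H^T D_v^{-1/2},
# and the normalized association operator S (the subtrahend of the
# normalized Laplacian) are assembled. S, vectorized over the strict upper
# triangle, is the high-order feature representation fed to the learners.

#' Build a k-nearest-neighbour hypergraph
#'
#' For each of the M vertices (ROIs), forms one hyperedge containing the
#' vertex itself (the centre) plus its `k` nearest other vertices by
#' Euclidean distance between feature rows. Ties in distance are broken
#' toward the lowest vertex index, so construction is deterministic across
#' platforms. Duplicate hyperedges (two centres selecting the same vertex
#' set) are retained as distinct columns so that the incidence matrix is
#' always M x M. All hyperedge weights are 1 by default.
#'
#' @param features Numeric M x D matrix; row i is the representation of
#'   vertex i (typically row i of the subject's low-order FCN, i.e. the
#'   ROI's connectivity profile).
#' @param k Number of nearest neighbours per centre, `1 <= k <= M - 1`.
#' @param weights Optional positive hyperedge weights (length M); default
#'   all 1.
#' @return An object of class `hypergraph`: `n_vertices`, `incidence`
#'   (binary M x M matrix H, column j is the hyperedge centred on vertex j),
#'   `weights`, `k`.
#' @export
build_knn_hypergraph <- function(features, k, weights = NULL) {
  X <- as.matrix(features)
  M <- nrow(X)
  if (!all(is.finite(X))) {
    stop_hofcn("non-finite entries in hypergraph feature matrix",
               class = "hofcn_validation_error")
  }
  if (length(k) != 1L || k < 1L || k > M - 1L) {
    stop_hofcn("k must satisfy 1 <= k <= M - 1 (M = ", M, ", k = ", k, ")",
               class = "hofcn_validation_error")
  }
  k <- as.integer(k)
  D <- as.matrix(stats::dist(X))
  H <- matrix(0L, M, M)
  for (centre in seq_len(M)) {
    d <- D[, centre]
    d[centre] <- Inf                       # self excluded from neighbour pool
    nbr <- order(d, seq_len(M))[seq_len(k)] # stable: ties -> lowest index
    H[c(centre, nbr), centre] <- 1L
  }
  if (is.null(weights)) weights <- rep(1, M)
  hypergraph(H, weights, k = k)
}

#' Hypergraph container
#'
#' @param incidence Binary M x M_e incidence matrix H.
#' @param weights Positive hyperedge weights, length M_e.
#' @param k Neighbour count used in construction (or `NA`).
#' @return An object of class `hypergraph`.
#' @export
hypergraph <- function(incidence, weights, k = NA_integer_) {
  H <- as.matrix(incidence)
  if (!all(H %in% c(0, 1))) {
    stop_hofcn("incidence matrix must be binary", class = "hofcn_validation_error")
  }
  if (length(weights) != ncol(H)) {
    stop_hofcn("need one weight per hyperedge", class = "hofcn_validation_error")
  }
  if (any(weights <= 0)) {
    stop_hofcn("hyperedge weights must be strictly positive",
               class = "hofcn_validation_error")
  }
  if (any(rowSums(H) == 0)) {
    stop_hofcn("isolated vertex (empty row in H)", class = "hofcn_validation_error")
  }
  structure(list(n_vertices = nrow(H), incidence = H,
                 weights = as.numeric(weights), k = k),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d vertices, %d hyperedges (k = %s)\n",
              x$n_vertices, ncol(x$incidence), x$k))
  invisible(x)
}

#' Vertex and hyperedge degrees
#'
#' The vertex degree is the weighted count of hyperedges containing the
#' vertex, `d(v_i) = sum_j w_j H_ij`; the hyperedge degree is its vertex
#' count, `delta(e_j) = sum_i H_ij`.
#'
#' @param hg A `hypergraph`.
#' @return List with numeric vectors `degrees_v` (length M) and `degrees_e`
#'   (length M_e).
#' @export
hypergraph_degrees <- function(hg) {
  H <- hg$incidence
  list(degrees_v = as.numeric(H %*% hg$weights),
       degrees_e = as.numeric(colSums(H)))
}

#' Hypergraph Laplacians and the high-order association operator
#'
#' Assembles the hypergraph Laplacian `Delta = D_v - H W D_e^{-1} H^T`, the
#' normalized association operator
#' `S = D_v^{-1/2} H W D_e^{-1} H^T D_v^{-1/2}`, and the normalized
#' Laplacian `I - S`. All three are symmetric; `Delta` annihilates the
#' constant vector and both Laplacians are positive semidefinite, with the
#' normalized spectrum contained in `[0, 2]`.
#'
#' @param hg A `hypergraph` with all vertex and hyperedge degrees positive.
#' @return An object of class `ho_fcn`: `assoc` (S), `laplacian` (Delta),
#'   `laplacian_norm` (I - S), `degrees_v`, `degrees_e`.
#' @export
hypergraph_laplacian <- function(hg) {
  H <- hg$incidence
  w <- hg$weights
  deg <- hypergraph_degrees(hg)
  dv <- deg$degrees_v
  de <- deg$degrees_e
  if (any(dv <= 0)) {
    stop_hofcn("zero vertex degree; hypergraph construction is broken",
               class = "hofcn_validation_error")
  }
  if (any(de <= 0)) {
    stop_hofcn("empty hyperedge", class = "hofcn_validation_error")
  }
  # H W D_e^{-1} H^T = H diag(w / de) H^T
  A <- tcrossprod(sweep(H, 2, w / de, "*"), H)
  A <- (A + t(A)) / 2
  lap <- diag(dv) - A
  inv_sqrt_dv <- 1 / sqrt(dv)
  S <- A * tcrossprod(inv_sqrt_dv)
  S <- (S + t(S)) / 2
  lap_norm <- diag(nrow(H)) - S
  structure(list(assoc = S, laplacian = lap, laplacian_norm = lap_norm,
                 degrees_v = dv, degrees_e = de),
            class = "ho_fcn")
}

#' @export
print.ho_fcn <- function(x, ...) {
  cat(sprintf("<ho_fcn> %d ROIs; assoc, laplacian, laplacian_norm\n",
              length(x$degrees_v)))
  invisible(x)
}

#' High-order feature vector of a subject
#'
#' Vectorizes the high-order connectivity operator over its strict upper
#' triangle. The default source is the normalized association `S`: it is
#' bounded, symmetric and comparable across subjects. The normalized
#' Laplacian and the raw incidence matrix are available as alternatives.
#'
#' @param ho An `ho_fcn` (or a `hypergraph` when `matrix = "incidence"`).
#' @param matrix Which operator to vectorize: `"assoc"` (default),
#'   `"laplacian_norm"`, or `"incidence"` (flattened whole matrix, since H
#'   is not symmetric).
#' @return A `feature_vector` (for symmetric sources) or plain numeric
#'   vector (incidence).
#' @export
ho_features <- function(ho, matrix = c("assoc", "laplacian_norm", "incidence")) {
  matrix <- match.arg(matrix)
  if (matrix == "incidence") {
    H <- if (inherits(ho, "hypergraph")) ho$incidence else
      stop_hofcn("incidence features need a hypergraph object",
                 class = "hofcn_validation_error")
    return(as.numeric(H))
  }
  vectorize_upper(ho[[matrix]])
}

#' Full high-order pipeline step for one subject
#'
#' Convenience wrapper: low-order FCN -> kNN hypergraph -> normalized
#' association -> upper-triangle feature vector.
#'
#' @param ts A [roi_timeseries].
#' @param k Neighbour count (default 5).
#' @param feature_space `"fcn_rows"` (default; Euclidean distance between
#'   rows of the low-order FCN, i.e. connectivity profiles) or
#'   `"timeseries"` (distance between raw ROI time courses).
#' @param matrix Operator to vectorize, see [ho_features()].
#' @return A `feature_vector`.
#' @export
subject_ho_features <- function(ts, k = 5,
                                feature_space = c("fcn_rows", "timeseries"),
                                matrix = c("assoc", "laplacian_norm", "incidence")) {
  feature_space <- match.arg(feature_space)
  matrix <- match.arg(matrix)
  fcn <- pearson_fcn(ts)
  feats <- switch(feature_space,
                  fcn_rows = fcn$values,
                  timeseries = t(ts$values))
  hg <- build_knn_hypergraph(feats, k = k)
  if (matrix == "incidence") return(ho_features(hg, matrix = "incidence"))
  ho_features(hypergraph_laplacian(hg), matrix = matrix)
}

#' Export an incidence matrix as sparse coordinate text
#'
#' Writes one `row col value` triple per line for the nonzero entries of H.
#'
#' @param hg A `hypergraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_coo <- function(hg, path) {
  idx <- which(hg$incidence != 0, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   value = hg$incidence[idx])
  utils::write.table(df[order(df$row, df$col), ], path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
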