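# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # deterministic sub-seed, kept inside 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629L)
}

#' @keywords internal
#' @noRd
stop_hofcn <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "hofcn_error")))
}

# Column-wise standardization fitted on one matrix and applied to another.
# Constant columns get scale 1 so they map to 0 rather than NaN.
#' @keywords internal
#' @noRd
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps] <- 1
  list(center = mu, scale = sdv)
}

#' @keywords internal
#' @noRd
apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @keywords internal
#' @noRd
check_finite_matrix <- function(X, what) {
  if (!all(is.finite(X))) {
    stop_hofcn(what, " contains non-finite entries", class = "hofcn_validation_error")
  }
  invisible(X)
}
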