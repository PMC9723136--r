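# Synthetic multi-subject two-class ROI time series. ROIs are partitioned
# into modules; each subject's series is drawn from a zero-mean multivariate
# normal whose correlation matrix has one value inside modules and another
# between modules, plus independent observation noise. The two classes
# differ only in the between-module coupling, so a classifier is rewarded
# exactly for detecting multi-region interaction structure rather than any
# single marker.

#' Specification for a synthetic two-class dataset
#'
#' Defaults describe a desk-scale study: 60 subjects per class, 40 ROIs in
#' 4 modules of 10, 150 time points, within-module correlation 0.6,
#' between-module correlation 0.1 for controls and 0.5 for cases, and
#' observation noise with standard deviation 0.2 on unit-variance signals.
#'
#' @param n_per_class Subjects per class.
#' @param n_rois Number of ROIs M.
#' @param n_timepoints Time points T per subject.
#' @param n_modules Number of equal-sized ROI modules (must divide M).
#' @param within_module_corr Correlation between ROIs of the same module,
#'   in `[0, 1)`.
#' @param between_module_corr_control,between_module_corr_case Correlation
#'   between ROIs of different modules for each class.
#' @param noise_sd Standard deviation of the independent observation noise.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_spec`. The implied per-class
#'   correlation matrices are checked for positive definiteness at
#'   construction.
#' @export
synthetic_spec <- function(n_per_class = 60, n_rois = 40, n_timepoints = 150,
                           n_modules = 4, within_module_corr = 0.6,
                           between_module_corr_control = 0.1,
                           between_module_corr_case = 0.5,
                           noise_sd = 0.2, seed = 1) {
  if (n_rois %% n_modules != 0) {
    stop_hofcn("n_modules (", n_modules, ") must divide n_rois (", n_rois, ")",
               class = "hofcn_validation_error")
  }
  if (within_module_corr < 0 || within_module_corr >= 1) {
    stop_hofcn("within_module_corr must lie in [0, 1)",
               class = "hofcn_validation_error")
  }
  if (noise_sd <= 0) {
    stop_hofcn("noise_sd must be positive", class = "hofcn_validation_error")
  }
  spec <- structure(
    list(n_per_class = as.integer(n_per_class), n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints), n_modules = as.integer(n_modules),
         within_module_corr = within_module_corr,
         between_module_corr_control = between_module_corr_control,
         between_module_corr_case = between_module_corr_case,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec")
  for (cls in c("control", "case")) class_correlation(spec, cls)  # PD check
  spec
}

#' Per-class target correlation matrix of a synthetic spec
#'
#' @param spec A `synthetic_spec`.
#' @param class `"control"` or `"case"`.
#' @return The M x M block correlation matrix.
#' @export
class_correlation <- function(spec, class = c("control", "case")) {
  class <- match.arg(class)
  between <- switch(class, control = spec$between_module_corr_control,
                    case = spec$between_module_corr_case)
  module <- rep(seq_len(spec$n_modules), each = spec$n_rois / spec$n_modules)
  same <- outer(module, module, "==")
  R <- ifelse(same, spec$within_module_corr, between)
  diag(R) <- 1
  lam_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min <= 1e-8) {
    stop_hofcn("target correlation matrix for class '", class,
               "' is not positive definite (smallest eigenvalue ",
               format(lam_min), ")", class = "hofcn_validation_error")
  }
  R
}

#' Generate a synthetic two-class dataset on disk
#'
#' Writes one CSV time-series file per subject (rows = time points,
#' columns = ROIs, with a header of ROI labels) and a `manifest.csv` to
#' `out_dir`. Subjects are drawn from the class's block-correlated
#' multivariate normal plus independent N(0, noise_sd^2) observation noise.
#' Byte-identical output is guaranteed for identical specs (all randomness
#' flows from `spec$seed`).
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory, created if needed.
#' @return The [subject_manifest] of the written dataset (invisibly also
#'   saved as `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roi_labels <- sprintf("roi%03d", seq_len(spec$n_rois))
  chol_by_class <- list(control = chol(class_correlation(spec, "control")),
                        case = chol(class_correlation(spec, "case")))
  ids <- character(0); paths <- character(0); labels <- character(0)
  withr::with_seed(spec$seed, {
    for (class in c("case", "control")) {
      lab <- if (class == "case") "ASD" else "NC"
      for (i in seq_len(spec$n_per_class)) {
        id <- sprintf("%s_%03d", tolower(lab), i)
        Z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
                    spec$n_timepoints, spec$n_rois)
        X <- Z %*% chol_by_class[[class]] +
          spec$noise_sd * matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
                                 spec$n_timepoints, spec$n_rois)
        ts <- roi_timeseries(X, subject_id = id, roi_labels = roi_labels)
        fn <- file.path(out_dir, paste0(id, ".csv"))
        write_timeseries(ts, fn, dialect = "csv")
        ids <- c(ids, id); paths <- c(paths, paste0(id, ".csv")); labels <- c(labels, lab)
      }
    }
  })
  man <- subject_manifest(ids, file.path(out_dir, paths), labels,
                          site = rep("synthetic", length(ids)))
  man_disk <- man
  man_disk$path <- paths                 # manifest stores relative paths
  write_manifest(man_disk, file.path(out_dir, "manifest.csv"))
  man
}
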