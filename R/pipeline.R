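# End-to-end orchestration: per-subject low-order FCN -> hypergraph-based
# high-order features, then per training fold: feature standardization,
# autoencoder fit, encoding, a second standardization of the encoded
# features, BLS fit, prediction on the held-out fold. Stratified k-fold
# cross-validation with optional repeats; metrics are accuracy, sensitivity,
# specificity and precision with the positive class being the patient group.

#' Pipeline configuration
#'
#' Bundles the tunable settings of every stage with the published operating
#' point as default: hypergraph neighbour count `k = 5`, autoencoder depth
#' `L = 3`, and a BLS with 20 mapping groups of window size 100 plus 10
#' enhancement nodes.
#'
#' @param k Hypergraph neighbour count.
#' @param feature_space Distance space for hyperedge construction:
#'   `"fcn_rows"` (connectivity profiles, default) or `"timeseries"`.
#' @param ho_matrix High-order operator to vectorize (see [ho_features()]).
#' @param ae_layers Autoencoder depth L.
#' @param ae_bottleneck Bottleneck width (default 64, sized for desk-scale
#'   inputs; raise for atlas-scale data).
#' @param ae_epochs,ae_batch_size,ae_lr Autoencoder training settings.
#' @param bls_map_groups,bls_window,bls_enh_groups,bls_enh_nodes,bls_lambda
#'   BLS architecture and ridge penalty.
#' @param n_folds,n_repeats,seed Cross-validation settings. Each repeat
#'   reshuffles the folds with a seed derived from `seed`; autoencoder and
#'   BLS seeds are likewise derived per fold, so a full run is reproducible
#'   from `seed` alone.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 5, feature_space = "fcn_rows",
                            ho_matrix = "assoc",
                            ae_layers = 3, ae_bottleneck = 64,
                            ae_epochs = 100, ae_batch_size = 32, ae_lr = 1e-3,
                            bls_map_groups = 20, bls_window = 100,
                            bls_enh_groups = 1, bls_enh_nodes = 10,
                            bls_lambda = 1e-8,
                            n_folds = 10, n_repeats = 10, seed = 42) {
  if (n_folds < 2) {
    stop_hofcn("n_folds must be at least 2", class = "hofcn_validation_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Stratified fold assignment
#'
#' Partitions subjects into `n_folds` test folds so that per-class counts
#' across folds differ by at most one. Deterministic given `seed`.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param n_folds Number of folds.
#' @param seed Integer RNG seed.
#' @return Integer vector of fold ids (1..n_folds), one per subject.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1) {
  labels <- as.factor(labels)
  N <- length(labels)
  if (n_folds > N) {
    stop_hofcn("n_folds (", n_folds, ") exceeds the number of subjects (", N, ")",
               class = "hofcn_validation_error")
  }
  if (n_folds > min(table(labels))) {
    warning("n_folds exceeds the smallest class count; some folds will lack a class")
  }
  fold <- integer(N)
  offset <- 0L
  withr::with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      # rotate the fold sequence between classes so small classes do not
      # pile into the earliest folds
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/total`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)`, with the positive class being the patient
#' group. A metric with a zero denominator is reported as `NA` (undefined),
#' never as 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Named list `acc`, `sen`, `spe`, `precision`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop_hofcn("confusion counts must be non-negative with positive total",
               class = "hofcn_validation_error")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(acc = (tp + tn) / sum(counts),
       sen = safe_div(tp, tp + fn),
       spe = safe_div(tn, tn + fp),
       precision = safe_div(tp, tp + fp))
}

load_subject_matrix <- function(manifest) {
  ts_list <- lapply(seq_len(nrow(manifest)), function(i)
    read_timeseries(manifest$path[i], subject_id = manifest$subject_id[i],
                    allow_wide = TRUE))
  Ms <- vapply(ts_list, function(ts) ncol(ts$values), integer(1))
  if (length(unique(Ms)) != 1L) {
    off <- manifest$subject_id[Ms != Ms[1]]
    stop_hofcn("inconsistent ROI count across subjects: ",
               paste(off, collapse = ", "), " differ from ",
               manifest$subject_id[1], class = "hofcn_validation_error")
  }
  ts_list
}

#' Run the full classification pipeline under cross-validation
#'
#' For every repeat and fold: standardization, autoencoder and BLS are
#' fitted on the training subjects only; each held-out subject then passes
#' through low-order FCN, hypergraph high-order features, the training
#' fold's scalers and encoder, and the BLS for prediction. Per-subject
#' high-order features involve no cross-subject fitting and are computed
#' once up front.
#'
#' @param manifest A [subject_manifest] with at least 2 subjects per class.
#' @param config A [pipeline_config()].
#' @param collect_models If `TRUE`, the per-fold trained models are
#'   attached to the result (for inspection; memory-heavy).
#' @param verbose Print per-stage progress.
#' @return An object of class `cv_result`: `folds` (data.frame with one row
#'   per repeat x fold: confusion counts and metrics), `summary` (mean and
#'   sd of each metric across cells), `config`, and optionally `models`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         collect_models = FALSE, verbose = FALSE) {
  labels <- manifest$label
  if (any(table(labels) < 2)) {
    stop_hofcn("need at least 2 subjects per class",
               class = "hofcn_validation_error")
  }
  say <- function(...) if (verbose) message(sprintf(...))

  ts_list <- load_subject_matrix(manifest)
  say("loaded %d subjects (%d x %d each)", length(ts_list),
      nrow(ts_list[[1]]$values), ncol(ts_list[[1]]$values))

  feats <- t(vapply(ts_list, function(ts)
    subject_ho_features(ts, k = config$k, feature_space = config$feature_space,
                        matrix = config$ho_matrix)$values,
    numeric(ncol(ts_list[[1]]$values) * (ncol(ts_list[[1]]$values) - 1) / 2)))
  say("high-order features: %d x %d", nrow(feats), ncol(feats))

  rows <- list(); models <- list()
  for (rep_i in seq_len(config$n_repeats)) {
    fold_seed <- derive_seed(config$seed, rep_i)
    fold <- stratified_folds(labels, config$n_folds, seed = fold_seed)
    for (f in sort(unique(fold))) {
      test <- fold == f
      train <- !test
      if (nlevels(droplevels(labels[train])) < 2L) {
        stop_hofcn("training split of fold ", f, " (repeat ", rep_i,
                   ") contains a single class; use fewer folds or another seed",
                   class = "hofcn_validation_error")
      }
      stage_seed <- derive_seed(fold_seed, f)

      scaler_in <- fit_scaler(feats[train, , drop = FALSE])
      Xtr <- apply_scaler(scaler_in, feats[train, , drop = FALSE])
      Xte <- apply_scaler(scaler_in, feats[test, , drop = FALSE])

      dims <- ae_layer_dims(ncol(Xtr), bottleneck = config$ae_bottleneck,
                            n_layers = config$ae_layers)
      ae <- fit_autoencoder(Xtr, dims, epochs = config$ae_epochs,
                            batch_size = config$ae_batch_size,
                            learning_rate = config$ae_lr, seed = stage_seed)
      Etr <- ae_encode(ae, Xtr)
      Ete <- ae_encode(ae, Xte)

      scaler_enc <- fit_scaler(Etr)
      Etr <- apply_scaler(scaler_enc, Etr)
      Ete <- apply_scaler(scaler_enc, Ete)

      bls <- fit_bls(Etr, labels[train],
                     n_map_groups = config$bls_map_groups,
                     nodes_per_group = config$bls_window,
                     n_enh_groups = config$bls_enh_groups,
                     enh_nodes_per_group = config$bls_enh_nodes,
                     lambda = config$bls_lambda,
                     seed = derive_seed(stage_seed, 1))
      pred <- predict_bls(bls, Ete)$labels

      truth <- labels[test]
      tp <- sum(pred == "positive" & truth == "positive")
      fp <- sum(pred == "positive" & truth == "control")
      tn <- sum(pred == "control" & truth == "control")
      fn <- sum(pred == "control" & truth == "positive")
      met <- compute_metrics(tp, fp, tn, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = rep_i, fold = f, n_test = sum(test),
        tp = tp, fp = fp, tn = tn, fn = fn,
        acc = met$acc, sen = met$sen, spe = met$spe, precision = met$precision)
      if (collect_models) {
        models[[sprintf("r%02d_f%02d", rep_i, f)]] <- list(
          scaler_input = scaler_in, autoencoder = ae,
          scaler_encoded = scaler_enc, bls = bls)
      }
      say("repeat %d fold %d: acc %.3f", rep_i, f, met$acc)
    }
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("acc", "sen", "spe", "precision")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  out <- structure(list(folds = folds, summary = summary, config = config),
                   class = "cv_result")
  if (collect_models) out$models <- models
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds x %d repeats\n",
              x$config$n_folds, x$config$n_repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Save a cv_result's per-fold table as CSV
#'
#' @param result A `cv_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(result, path) {
  utils::write.csv(result$folds, path, row.names = FALSE)
  invisible(path)
}
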