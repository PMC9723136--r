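# Reading and writing ROI time-series tables, subject manifests, and model
# archives. The time-series dialects are the delimited-text formats found in
# preprocessed resting-state releases: whitespace-separated ".1D" tables
# (optionally with "#" comment lines and a non-numeric header row) and plain
# CSV/TSV.

#' ROI time-series container
#'
#' A subject's BOLD signal table: `T` time points (rows) by `M` regions of
#' interest (columns).
#'
#' @param values Numeric matrix, time points in rows, ROIs in columns.
#' @param subject_id Character scalar identifying the subject.
#' @param roi_labels Optional character vector of length `ncol(values)`.
#'
#' @return An object of class `roi_timeseries` with elements `subject_id`,
#'   `values` and `roi_labels`.
#' @export
roi_timeseries <- function(values, subject_id = "subject", roi_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L) {
    stop_hofcn("time series needs at least 3 time points, got ", nrow(values),
               class = "hofcn_validation_error")
  }
  if (ncol(values) < 2L) {
    stop_hofcn("time series needs at least 2 ROIs, got ", ncol(values),
               class = "hofcn_validation_error")
  }
  check_finite_matrix(values, "time series")
  if (!is.null(roi_labels)) {
    stopifnot(length(roi_labels) == ncol(values))
    colnames(values) <- roi_labels
  }
  structure(
    list(subject_id = as.character(subject_id), values = values,
         roi_labels = if (is.null(roi_labels)) colnames(values) else as.character(roi_labels)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s: %d time points x %d ROIs\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

sep_for_dialect <- function(dialect) {
  switch(dialect, csv = ",", tsv = "\t", abide_1d = "[ \t]+",
         stop_hofcn("unknown dialect: ", dialect, class = "hofcn_validation_error"))
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", tsv = "tsv", "1d" = "abide_1d", txt = "abide_1d",
         "abide_1d")
}

tokenize_lines <- function(lines, sep) {
  lapply(lines, function(l) {
    toks <- strsplit(trimws(l), sep)[[1]]
    toks[nzchar(toks)]
  })
}

#' Read an ROI time-series table
#'
#' Reads a delimited time-series file with time points in rows and ROIs in
#' columns. Lines starting with `#` are treated as comments. If the first
#' non-comment row contains any non-numeric token it is taken to be a header
#' of ROI labels.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"` (default, by extension), `"abide_1d"`
#'   (whitespace-separated), `"csv"`, `"tsv"`.
#' @param subject_id Subject identifier stored in the result; defaults to the
#'   file name without extension.
#' @param transpose If `TRUE`, the file is read ROI-by-row and transposed.
#' @param allow_wide If `TRUE`, accept tables with more columns than rows
#'   without complaint. By default a table with `M > T` raises an error,
#'   because a silently transposed file corrupts every downstream
#'   correlation; pass `allow_wide = TRUE` for genuinely short scans.
#'
#' @return A [roi_timeseries].
#' @export
read_timeseries <- function(path, dialect = c("auto", "abide_1d", "csv", "tsv"),
                            subject_id = NULL, transpose = FALSE,
                            allow_wide = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_hofcn("file not found: ", path, class = "hofcn_io_error")
  }
  if (dialect == "auto") dialect <- guess_dialect(path)
  sep <- sep_for_dialect(dialect)

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  rows <- tokenize_lines(lines[keep], sep)
  if (length(rows) == 0L) {
    stop_hofcn("no data rows in ", path, class = "hofcn_parse_error")
  }

  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop_hofcn("ragged row in ", path, ": line ", line_no[bad], " has ",
               widths[bad], " fields, expected ", widths[1],
               class = "hofcn_parse_error")
  }

  roi_labels <- NULL
  first <- suppressWarnings(as.numeric(rows[[1]]))
  if (anyNA(first)) {
    roi_labels <- rows[[1]]
    rows <- rows[-1]
    line_no <- line_no[-1]
    if (length(rows) == 0L) {
      stop_hofcn("header-only file: ", path, class = "hofcn_parse_error")
    }
  }

  body <- suppressWarnings(vapply(rows, as.numeric, numeric(widths[1])))
  body <- t(matrix(body, nrow = widths[1]))
  if (anyNA(body)) {
    bad <- which(apply(is.na(body), 1, any))[1]
    stop_hofcn("non-numeric value in ", path, " at line ", line_no[bad],
               class = "hofcn_parse_error")
  }
  if (transpose) {
    body <- t(body)
    roi_labels <- NULL
  }
  if (!transpose && !allow_wide && ncol(body) > nrow(body)) {
    stop_hofcn("table in ", path, " has more columns (", ncol(body),
               ") than rows (", nrow(body), "); rows must be time points and ",
               "columns ROIs. Pass transpose = TRUE if the file stores ROIs ",
               "in rows, or allow_wide = TRUE for a genuinely short scan.",
               class = "hofcn_validation_error")
  }
  if (is.null(subject_id)) {
    subject_id <- tools::file_path_sans_ext(basename(path))
  }
  roi_timeseries(body, subject_id = subject_id, roi_labels = roi_labels)
}

#' Write an ROI time-series table
#'
#' Inverse of [read_timeseries()]: emits the matrix in the requested dialect,
#' with ROI labels as a header row when present. Values are written with 15
#' significant digits so a write/read round trip reproduces the matrix.
#'
#' @param ts A [roi_timeseries].
#' @param path Output path.
#' @param dialect `"abide_1d"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, dialect = c("csv", "tsv", "abide_1d")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, csv = ",", tsv = "\t", abide_1d = " ")
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "abide_1d") {
    writeLines(paste0("# subject ", ts$subject_id), con)
  }
  if (!is.null(ts$roi_labels)) {
    writeLines(paste(ts$roi_labels, collapse = sep), con)
  }
  body <- apply(ts$values, 1, function(r)
    paste(sprintf("%.15g", r), collapse = sep))
  writeLines(body, con)
  invisible(path)
}

#' Subject manifest
#'
#' A table of subjects for a classification run: one row per subject with a
#' unique id, the path of its time-series file, a binary label and an
#' optional acquisition-site id.
#'
#' @param subject_id Character vector of unique ids.
#' @param path Character vector of file paths.
#' @param label Character or factor; normalized to `"positive"`/`"control"`.
#' @param site Optional character vector of site ids.
#' @return An object of class `subject_manifest` (a data.frame).
#' @export
subject_manifest <- function(subject_id, path, label, site = NULL) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) {
    dup <- unique(subject_id[duplicated(subject_id)])
    stop_hofcn("duplicate subject_id: ", paste(dup, collapse = ", "),
               class = "hofcn_validation_error")
  }
  label <- normalize_labels(label)
  df <- data.frame(subject_id = subject_id, path = as.character(path),
                   label = label, stringsAsFactors = FALSE)
  df$site <- if (is.null(site)) NA_character_ else as.character(site)
  class(df) <- c("subject_manifest", "data.frame")
  df
}

positive_tokens <- c("positive", "asd", "case", "patient", "1")
control_tokens  <- c("control", "nc", "hc", "td", "healthy", "0")

normalize_labels <- function(label) {
  tok <- tolower(trimws(as.character(label)))
  out <- ifelse(tok %in% positive_tokens, "positive",
                ifelse(tok %in% control_tokens, "control", NA_character_))
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop_hofcn("unknown label token(s): ", paste(bad, collapse = ", "),
               "; accepted: ", paste(c(positive_tokens, control_tokens), collapse = ", "),
               class = "hofcn_validation_error")
  }
  factor(out, levels = c("positive", "control"))
}

#' Read a subject manifest
#'
#' Reads a CSV with columns `subject_id`, `path`, `label` and optional
#' `site`. Labels such as `ASD`/`NC` are normalized to
#' `positive`/`control`; relative paths are resolved against the manifest's
#' directory. Row order is preserved.
#'
#' @param path Path to the manifest CSV.
#' @return A [subject_manifest].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_hofcn("manifest not found: ", path, class = "hofcn_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_hofcn("manifest missing column(s): ", paste(miss, collapse = ", "),
               class = "hofcn_validation_error")
  }
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  subject_manifest(df$subject_id, df$path, df$label,
                   site = if ("site" %in% names(df)) df$site else NULL)
}

#' Write a subject manifest
#'
#' @param manifest A [subject_manifest].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Save / load a model archive
#'
#' Persists trained models and fold results as a single-file archive: an RDS
#' serialization of a named list. Keys used by the pipeline:
#' `autoencoder` (an `autoencoder_model`), `bls` (a `bls_model`),
#' `scaler_input`/`scaler_encoded` (standardization parameters),
#' `cv_result` (a `cv_result`), `config` (the pipeline configuration).
#'
#' @param object Named list (or single model) to persist.
#' @param path Archive path.
#' @return `path` invisibly for `save_model_archive`; the restored object for
#'   `load_model_archive`.
#' @export
save_model_archive <- function(object, path) {
  saveRDS(object, path, version = 3)
  invisible(path)
}

#' @rdname save_model_archive
#' @export
load_model_archive <- function(path) {
  if (!file.exists(path)) {
    stop_hofcn("archive not found: ", path, class = "hofcn_io_error")
  }
  readRDS(path)
}
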