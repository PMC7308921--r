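# Record and beat-table I/O.
#
# The record format is a WFDB-style *text* dialect: a record is stored as the
# triplet <name>.hea (header), <name>.csv (signal, one sample per line) and
# <name>.atr (annotations, "index symbol" per line, 0-based sample indices as
# in the WFDB convention). The reader reads exactly what the writer emits and
# validates the header. Binary WFDB variants are out of scope.

#' Write an ECG record as a WFDB-style text triplet
#'
#' @param record An `ecg_record`.
#' @param path Base path without extension; `.hea`, `.csv` and `.atr` files
#'   are written next to it.
#' @param lead Lead name recorded in the header (default `"MLII"`).
#' @return The base path, invisibly.
#' @export
write_record_wfdb <- function(record, path, lead = "MLII") {
  stopifnot(inherits(record, "ecg_record"))
  name <- basename(path)
  writeLines(
    c(
      sprintf("%s 1 %g %d", name, record$fs, length(record$signal)),
      sprintf("%s.csv text 1 0 0 %s", name, lead)
    ),
    paste0(path, ".hea")
  )
  writeLines(format(record$signal, digits = 17, trim = TRUE, scientific = FALSE),
             paste0(path, ".csv"))
  writeLines(
    sprintf("%d %s", record$annotations$index - 1L, record$annotations$label),
    paste0(path, ".atr")
  )
  invisible(path)
}

#' Read a WFDB-style text record
#'
#' Reads the triplet written by [write_record_wfdb()]: the selected lead's
#' signal, the sampling rate from the header, and the beat annotations
#' (converted from the file's 0-based indices to R's 1-based), keeping only
#' annotation symbols within `classes`.
#'
#' @param path Base path without extension.
#' @param lead Required lead name (default `"MLII"`).
#' @param classes Annotation symbols to keep; others are dropped with a
#'   message. Default: the eight target classes.
#' @return An `ecg_record`.
#' @export
read_record_wfdb <- function(path, lead = "MLII", classes = beat_classes()) {
  hea <- paste0(path, ".hea")
  sig <- paste0(path, ".csv")
  atr <- paste0(path, ".atr")
  for (f in c(hea, sig, atr)) {
    if (!file.exists(f)) abort(sprintf("Missing record file: %s", f))
  }
  header <- readLines(hea)
  if (length(header) < 2) abort(sprintf("Corrupt header file: %s", hea))
  top <- strsplit(trimws(header[1]), "\\s+")[[1]]
  if (length(top) < 3 || is.na(suppressWarnings(as.numeric(top[3])))) {
    abort(sprintf("Corrupt header file: %s", hea))
  }
  fs <- as.numeric(top[3])
  leads <- vapply(strsplit(header[-1], "\\s+"), function(x) x[length(x)], "")
  if (!lead %in% leads) {
    abort(sprintf(
      "Lead %s not present in %s; available: %s.",
      lead, hea, paste(leads, collapse = ", ")
    ))
  }
  signal <- as.numeric(readLines(sig))
  if (anyNA(signal)) abort(sprintf("Non-numeric samples in %s.", sig))
  ann_lines <- readLines(atr)
  ann_lines <- ann_lines[nzchar(trimws(ann_lines))]
  parts <- strsplit(trimws(ann_lines), "\\s+")
  ann <- tibble(
    index = vapply(parts, function(x) as.integer(x[1]), 1L) + 1L,
    label = vapply(parts, function(x) x[2], "")
  )
  dropped <- sum(!ann$label %in% classes)
  if (dropped > 0) {
    message(sprintf("Excluded %d annotation(s) outside the target classes.", dropped))
    ann <- ann[ann$label %in% classes, , drop = FALSE]
  }
  new_ecg_record(signal, fs, ann)
}

#' Write/read labelled beats as CSV
#'
#' Plain CSV dialect: one beat per row, a `label` column followed by the
#' sample columns `s001`, `s002`, ...
#'
#' @param beats Beat tibble with `label` and list column `beat`.
#' @param path CSV file path.
#' @return `write_beats_csv()`: the path, invisibly. `read_beats_csv()`: a
#'   beat tibble.
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(all(c("label", "beat") %in% names(beats)))
  m <- do.call(rbind, beats$beat)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  df <- cbind(data.frame(label = as.character(beats$label)), as.data.frame(m))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot("label" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  tibble(
    beat_id = seq_len(nrow(df)),
    label = factor(df$label, levels = beat_classes()),
    beat = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  )
}

#' Write/read feature tables as CSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV file path.
#' @return The path (write) or a feature tibble (read).
#' @export
write_features_csv <- function(features, path) {
  out <- features
  out$label <- as.character(out$label)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  df$label <- factor(df$label, levels = beat_classes())
  as_tibble(df)
}

# ---- bundled reference tables -----------------------------------------------

ecgopt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ecgopt", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (package loaded from source tree)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(sprintf("Bundled table %s not found.", file))
  path
}

#' Published eight-class MIT-BIH benchmark counts
#'
#' Per-class beat counts (lead MLII) of the standard eight-class unbalanced
#' arrhythmia benchmark drawn from the MIT-BIH Arrhythmia Database, as
#' distributed with the package for verification and reporting.
#'
#' @return Named integer vector of counts, in class order N, L, R, V, !, j,
#'   a, E.
#' @export
mitbih_class_counts <- function() {
  df <- read.csv(ecgopt_extdata("mitbih_class_counts.csv"), check.names = FALSE)
  stats::setNames(as.integer(df$count), df$class)
}

#' Reference confusion matrix of the best reported solution
#'
#' The 8x8 confusion matrix (true rows, predicted columns; class order a, E,
#' j, !, L, N, V, R) of the best solution of the benchmark's second
#' experiment (DE with high/low-pass filtering), bundled for worked-example
#' reconstruction of the per-class counts and metrics.
#'
#' @return Integer matrix with dimnames.
#' @export
reference_confusion_matrix <- function() {
  df <- read.csv(ecgopt_extdata("experiment2_confusion.csv"), check.names = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(truth = df[[1]], predicted = colnames(df)[-1])
  m
}

#' Reference repeated F1 scores of the four benchmark experiments
#'
#' The ten repeated cross-validated macro F1 scores (percent) of each of the
#' four reported experiment configurations (PSO/DE crossed with HL/wavelet
#' filtering), bundled for the repeated-runs t analysis.
#'
#' @return Tibble with columns `test`, `experiment1` ... `experiment4`.
#' @export
reference_f1_repetitions <- function() {
  as_tibble(read.csv(ecgopt_extdata("experiment_f1_repetitions.csv")))
}
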