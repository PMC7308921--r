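#' High-pass + low-pass Butterworth denoising
#'
#' The classical ECG denoising chain: a 1 Hz high-pass (Butterworth order 4)
#' removes baseline wander, then a 30 Hz low-pass (Butterworth order 6)
#' removes powerline interference and high-frequency muscle noise. Both are
#' applied zero-phase (forward-backward), so the QRS complex is not delayed —
#' important because segmentation uses fixed offsets around the annotation.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed 60 Hz (twice the low-pass
#'   cutoff).
#' @param low_cut,high_cut Cutoff frequencies in Hz.
#' @param low_order,high_order Filter orders.
#' @return Filtered signal, same length as the input.
#' @export
filter_hl <- function(x, fs, low_cut = 30, high_cut = 1,
                      low_order = 6, high_order = 4) {
  assert_scalar_number(fs, "fs")
  if (fs <= 2 * low_cut) {
    abort(sprintf("`fs` must exceed %g Hz (twice the low-pass cutoff).", 2 * low_cut))
  }
  min_len <- hl_min_length(low_order, high_order)
  if (length(x) < min_len) {
    abort(sprintf(
      "Signal too short for filtering: need at least %d samples, got %d.",
      min_len, length(x)
    ))
  }
  lp <- signal::butter(low_order, low_cut / (fs / 2), type = "low")
  hp <- signal::butter(high_order, high_cut / (fs / 2), type = "high")
  y <- signal::filtfilt(hp, x)
  as.numeric(signal::filtfilt(lp, y))
}

# Minimum signal length for stable forward-backward filtering: three times
# the longest filter's warm-up, as conventionally required by filtfilt.
hl_min_length <- function(low_order = 6, high_order = 4) {
  3L * (max(low_order, high_order) + 1L) * 2L
}

#' Wavelet denoising with baseline removal (db6, 9 levels)
#'
#' Decomposes the signal to nine levels with the Daubechies db6 basis
#' (shift-invariant maximal-overlap transform), discards the level-9
#' approximation sub-band (the slow baseline wander), soft-thresholds the
#' detail coefficients (universal threshold; the noise scale is estimated by
#' MAD on the finest detail level and propagated to coarser levels with the
#' transform's white-noise scaling), and reconstructs from the denoised
#' details alone.
#'
#' @param x Numeric signal, at least `2^levels` samples.
#' @param levels Decomposition depth (default 9).
#' @param threshold `"universal"` (default) or `"none"` to only remove the
#'   approximation sub-band without denoising.
#' @return Filtered signal, same length as the input.
#' @export
filter_wavelet <- function(x, levels = 9, threshold = c("universal", "none")) {
  threshold <- match.arg(threshold)
  w <- modwt_db6(x, levels = levels)
  if (threshold == "universal" && any(w$details[[1]] != 0)) {
    w <- soft_threshold(w, length(x))
  }
  w$smooth <- numeric(length(x))
  imodwt_db6(w)
}

#' Min-max amplitude normalization to [-1, 1]
#'
#' `y = 2 * (x - min(x)) / (max(x) - min(x)) - 1`: a monotone affine map
#' placing the minimum at -1 and the maximum at +1, applied per record to
#' reduce amplitude variation between patients.
#'
#' @param x Numeric signal; must not be constant.
#' @return Normalized signal.
#' @examples
#' normalize_amplitude(c(0, 5, 10))
#' @export
normalize_amplitude <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    abort("Cannot normalize a constant signal: max(x) - min(x) is zero.")
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Segment a record into fixed-length heartbeats
#'
#' For each annotation at (1-based) index `r`, extracts the window
#' `[r - left, r + (segment_length - left - 1)]` — by default 99 samples to
#' the left of the QRS reference point and 151 samples from it rightwards
#' (the reference sample counted within the right side), giving 250 samples.
#' Annotations too close to either record end are skipped with a warning.
#'
#' @param record An `ecg_record` (see [generate_record()]), normally already
#'   filtered and normalized.
#' @param left Samples kept left of the annotation (default 99).
#' @param segment_length Total samples per beat (default 250).
#' @return A tibble with columns `beat_id`, `label` (factor over
#'   [beat_classes()]), `source_index` and `beat` (list column).
#' @export
segment_beats <- function(record, left = 99, segment_length = 250) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$signal)
  right <- segment_length - left - 1L
  ann <- record$annotations
  ok <- ann$index - left >= 1 & ann$index + right <= n
  if (any(!ok)) {
    warn(sprintf(
      "Skipping %d annotation(s) without full %d-sample context.",
      sum(!ok), segment_length
    ))
  }
  ann <- ann[ok, , drop = FALSE]
  beats <- purrr::map(ann$index, function(r) {
    record$signal[(r - left):(r + right)]
  })
  tibble(
    beat_id = seq_len(nrow(ann)),
    label = factor(ann$label, levels = beat_classes()),
    source_index = ann$index,
    beat = beats
  )
}

#' Full preprocessing of one record
#'
#' Applies the configured denoising path, per-record amplitude normalization
#' to [-1, 1], and beat segmentation, in that order.
#'
#' @param record An `ecg_record`.
#' @param filter `"hl"` (Butterworth high/low-pass) or `"wavelet"` (db6).
#' @inheritParams segment_beats
#' @return A beat tibble as returned by [segment_beats()].
#' @export
preprocess_record <- function(record, filter = c("hl", "wavelet"),
                              left = 99, segment_length = 250) {
  filter <- match.arg(filter)
  y <- switch(filter,
    hl = filter_hl(record$signal, record$fs),
    wavelet = filter_wavelet(record$signal)
  )
  y <- normalize_amplitude(y)
  segment_beats(
    new_ecg_record(y, record$fs, record$annotations),
    left = left, segment_length = segment_length
  )
}
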