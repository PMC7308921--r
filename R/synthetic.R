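#' Heartbeat class alphabet
#'
#' The eight MIT-BIH annotation symbols handled by the pipeline: four majority
#' classes (N normal, L left bundle branch block, R right bundle branch block,
#' V premature ventricular contraction) and four minority classes
#' (! ventricular flutter wave, j nodal escape, a aberrated atrial premature,
#' E ventricular escape).
#'
#' @return Character vector of the eight class symbols.
#' @export
beat_classes <- function() c("N", "L", "R", "V", "!", "j", "a", "E")

#' Majority and minority class symbols
#'
#' @return Character vector of class symbols.
#' @export
majority_classes <- function() c("L", "N", "V", "R")

#' @rdname majority_classes
#' @export
minority_classes <- function() c("!", "j", "a", "E")

# Per-class P/QRS/T bump parameters: amplitude (template units), width and
# center as fractions of the template length. The QRS center is fixed at 0.4
# so that a 250-sample template has its reference point at sample 100, which
# is exactly what the 99-left / 151-right segmentation convention recovers.
template_morphologies <- function() {
  list(
    "N" = list(p = c(0.15, 0.030, 0.20), qrs = c(1.00, 0.010, 0.40), t = c(0.30, 0.055, 0.70)),
    "L" = list(p = c(0.10, 0.030, 0.18), qrs = c(0.85, 0.030, 0.40), t = c(0.35, 0.060, 0.72)),
    "R" = list(p = c(0.12, 0.030, 0.20), qrs = c(-0.95, 0.022, 0.40), t = c(0.25, 0.050, 0.70)),
    "V" = list(p = c(0.00, 0.030, 0.20), qrs = c(1.10, 0.035, 0.40), t = c(-0.45, 0.070, 0.68)),
    "!" = list(p = c(0.00, 0.030, 0.20), qrs = c(0.80, 0.060, 0.40), t = c(0.60, 0.090, 0.62)),
    "j" = list(p = c(-0.10, 0.025, 0.28), qrs = c(0.95, 0.012, 0.40), t = c(0.25, 0.050, 0.70)),
    "a" = list(p = c(0.25, 0.018, 0.15), qrs = c(0.90, 0.012, 0.40), t = c(0.28, 0.050, 0.70)),
    "E" = list(p = c(0.00, 0.030, 0.20), qrs = c(-1.05, 0.040, 0.40), t = c(0.40, 0.080, 0.75))
  )
}

#' Deterministic beat-morphology template
#'
#' Builds a noise-free waveform for one heartbeat class as the sum of three
#' Gaussian bumps standing in for the P wave, the QRS complex and the T wave.
#' The same inputs always produce bit-identical output; distinct classes have
#' distinct default morphologies.
#'
#' @param class_id One of [beat_classes()].
#' @param length Template length in samples (at 360 Hz; default 250,
#'   i.e. ~0.69 s). Must be at least 50.
#' @param morphology_params Optional list with elements `p`, `qrs`, `t`, each
#'   `c(amplitude, width_fraction, center_fraction)`; defaults are
#'   class-specific.
#' @return An object of class `beat_template`: list with `class_id`,
#'   `samples` (numeric of `length`), `morphology_params`, and `qrs_index`
#'   (the annotation reference point, 1-based).
#' @examples
#' tpl <- make_class_template("N")
#' which.max(tpl$samples) # the QRS reference point, sample 100
#' @export
make_class_template <- function(class_id, length = 250, morphology_params = NULL) {
  if (!is.character(class_id) || length(class_id) != 1L ||
      !class_id %in% beat_classes()) {
    abort(sprintf(
      "Unknown class_id %s; must be one of %s.",
      deparse(class_id), paste(beat_classes(), collapse = ", ")
    ))
  }
  assert_scalar_number(length, "length")
  if (length < 50) abort("`length` must be at least 50 samples.")
  length <- as.integer(length)
  params <- morphology_params %||% template_morphologies()[[class_id]]
  stopifnot(all(c("p", "qrs", "t") %in% names(params)))
  if (!all(vapply(params, function(x) all(is.finite(x)) && base::length(x) == 3L, TRUE))) {
    abort("Each morphology parameter must be 3 finite numbers (amp, width, center).")
  }
  i <- seq_len(length)
  bump <- function(par) {
    amp <- par[[1]]
    sigma <- par[[2]] * length
    center <- par[[3]] * length
    amp * exp(-((i - center)^2) / (2 * sigma^2))
  }
  samples <- bump(params$p) + bump(params$qrs) + bump(params$t)
  structure(
    list(
      class_id = class_id,
      samples = samples,
      morphology_params = params,
      qrs_index = as.integer(round(params$qrs[[3]] * length))
    ),
    class = "beat_template"
  )
}

#' Additive noise configuration for the synthetic generator
#'
#' Models the three contamination sources typical of ambulatory ECG: baseline
#' wander (slow 0.3 Hz sinusoid from respiration/electrode drift), powerline
#' interference (60 Hz sinusoid) and broadband white noise. Amplitudes are in
#' template units (the QRS bump has amplitude ~1).
#'
#' @param baseline,powerline,white Noise amplitudes; set all to 0 for clean
#'   beats.
#' @param baseline_freq,powerline_freq Frequencies in Hz.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(baseline = 0.15, powerline = 0.05, white = 0.03,
                         baseline_freq = 0.3, powerline_freq = 60) {
  for (nm in c("baseline", "powerline", "white", "baseline_freq", "powerline_freq")) {
    assert_scalar_number(get(nm), nm)
  }
  structure(
    list(
      baseline = baseline, powerline = powerline, white = white,
      baseline_freq = baseline_freq, powerline_freq = powerline_freq
    ),
    class = "noise_config"
  )
}

#' Default desk-scale class counts
#'
#' A scaled-down unbalanced profile preserving the majority/minority structure
#' of the eight-class MIT-BIH task (counts roughly 1/50 of the full database,
#' with minority classes floored so that stratified 10-fold cross-validation
#' places at least one instance of every class in every fold). The largest
#' pairwise imbalance ratio is 600/11 ~ 54.5.
#'
#' @return Named integer vector of per-class beat counts.
#' @export
default_class_counts <- function() {
  c("N" = 600L, "L" = 150L, "R" = 140L, "V" = 135L,
    "!" = 47L, "j" = 23L, "a" = 15L, "E" = 11L)
}

noise_vector <- function(n, fs, noise, phase_baseline, phase_powerline, white) {
  t <- (seq_len(n) - 1) / fs
  noise$baseline * sin(2 * pi * noise$baseline_freq * t + phase_baseline) +
    noise$powerline * sin(2 * pi * noise$powerline_freq * t + phase_powerline) +
    white
}

#' Generate a labelled, noise-corrupted, unbalanced beat dataset
#'
#' Produces exactly the requested number of 250-sample beats per class; each
#' beat is its class template plus baseline-wander and powerline sinusoids
#' (random phase per beat) and white noise at the configured amplitudes.
#' Fully reproducible under a fixed seed.
#'
#' @param class_counts Named vector of non-negative counts, names in
#'   [beat_classes()]. Defaults to [default_class_counts()].
#' @param noise A [noise_config()]; use `noise_config(0, 0, 0)` for clean,
#'   perfectly separable beats.
#' @param seed Integer seed.
#' @param length Beat length in samples (default 250).
#' @param fs Sampling rate in Hz (default 360).
#' @return A tibble with columns `beat_id`, `label` (factor with the full
#'   class alphabet as levels) and `beat` (list column of numeric vectors).
#' @examples
#' beats <- generate_beats(c(N = 20, E = 5), noise_config(0, 0, 0), seed = 1)
#' dplyr::count(beats, label, .drop = TRUE)
#' @export
generate_beats <- function(class_counts = default_class_counts(),
                           noise = noise_config(), seed,
                           length = 250, fs = 360) {
  stopifnot(inherits(noise, "noise_config"))
  if (missing(seed)) abort("`seed` must be supplied.")
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% beat_classes())) {
    abort("`class_counts` must be named with symbols from beat_classes().")
  }
  if (any(class_counts < 0)) abort("Class counts must be non-negative.")
  class_counts <- class_counts[class_counts > 0]
  templates <- lapply(names(class_counts), make_class_template, length = length)
  names(templates) <- names(class_counts)
  with_seed(as.integer(seed), {
    rows <- purrr::imap(as.list(class_counts), function(cnt, cls) {
      tpl <- templates[[cls]]$samples
      beats <- purrr::map(seq_len(cnt), function(i) {
        tpl + noise_vector(
          length, fs, noise,
          phase_baseline = runif(1, 0, 2 * pi),
          phase_powerline = runif(1, 0, 2 * pi),
          white = if (noise$white > 0) rnorm(length, 0, noise$white) else 0
        )
      })
      tibble(label = cls, beat = beats)
    })
    out <- bind_rows(rows)
    out$label <- factor(out$label, levels = beat_classes())
    out$beat_id <- seq_len(nrow(out))
    out[, c("beat_id", "label", "beat")]
  })
}

#' Generate a continuous annotated ECG record
#'
#' Concatenates class templates in the given order into one continuous signal,
#' adds record-wide noise, and returns the annotation index of each beat's QRS
#' reference point. Segmenting the zero-noise record with [segment_beats()]
#' recovers the planted beats exactly.
#'
#' @param beat_sequence Character vector of class symbols, in temporal order.
#' @param fs Sampling rate in Hz.
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param beat_length Samples per planted beat (default 250).
#' @return An object of class `ecg_record`: list with `signal` (numeric),
#'   `fs`, and `annotations` (tibble with 1-based `index` and `label`).
#' @examples
#' rec <- generate_record(c("N", "V", "N"), seed = 7, noise = noise_config(0, 0, 0))
#' rec$annotations
#' @export
generate_record <- function(beat_sequence, fs = 360, noise = noise_config(),
                            seed, beat_length = 250) {
  if (length(beat_sequence) == 0) abort("`beat_sequence` must be non-empty.")
  if (!all(beat_sequence %in% beat_classes())) abort("Unknown class in `beat_sequence`.")
  assert_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be positive.")
  if (missing(seed)) abort("`seed` must be supplied.")
  templates <- lapply(
    stats::setNames(nm = unique(beat_sequence)),
    make_class_template,
    length = beat_length
  )
  signal <- unlist(lapply(beat_sequence, function(cls) templates[[cls]]$samples),
                   use.names = FALSE)
  starts <- (seq_along(beat_sequence) - 1L) * as.integer(beat_length)
  idx <- starts + unname(vapply(beat_sequence, function(cls) templates[[cls]]$qrs_index, 1L))
  with_seed(as.integer(seed), {
    signal <- signal + noise_vector(
      length(signal), fs, noise,
      phase_baseline = runif(1, 0, 2 * pi),
      phase_powerline = runif(1, 0, 2 * pi),
      white = if (noise$white > 0) rnorm(length(signal), 0, noise$white) else 0
    )
  })
  new_ecg_record(signal, fs, tibble(index = idx, label = beat_sequence))
}

new_ecg_record <- function(signal, fs, annotations) {
  stopifnot(is.numeric(signal), nrow(annotations) == 0 ||
              all(annotations$index >= 1 & annotations$index <= length(signal)))
  structure(
    list(signal = as.numeric(signal), fs = fs, annotations = as_tibble(annotations)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples @ %g Hz (%.1f s), %d annotations\n",
    length(x$signal), x$fs, length(x$signal) / x$fs, nrow(x$annotations)
  ))
  invisible(x)
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf(
    "<beat_template> class %s, %d samples, QRS reference at sample %d\n",
    x$class_id, length(x$samples), x$qrs_index
  ))
  invisible(x)
}
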