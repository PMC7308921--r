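#' Five statistical descriptors of a subsegment
#'
#' Population-moment definitions: mean, standard deviation `sqrt(m2)`, energy
#' `sum(x^2)`, skewness `m3 / m2^1.5` and Pearson (non-excess) kurtosis
#' `m4 / m2^2`, where `mk` is the k-th central moment with denominator `n`.
#' A zero-variance subsegment returns skewness and kurtosis 0 by convention.
#'
#' @param x Numeric vector with at least 2 samples.
#' @return Named numeric vector `c(skew, kurt, energy, mean, std)`.
#' @examples
#' subsegment_stats(c(1, 2, 3, 4))
#' @export
subsegment_stats <- function(x) {
  if (length(x) < 2) abort("A subsegment needs at least 2 samples.")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 < .Machine$double.eps) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  c(skew = skew, kurt = kurt, energy = sum(x^2), mean = m, std = sqrt(m2))
}

feature_stat_names <- c("skew", "kurt", "energy", "mean", "std")

#' Names of the feature columns
#'
#' Layout is subsegment-major with the fixed statistic order skewness,
#' kurtosis, energy, mean, standard deviation: feature `5*(j-1) + s` belongs
#' to subsegment `j`, statistic `s`.
#'
#' @param n_subsegments Number of subsegments (default 10).
#' @return Character vector like `f01_skew, f01_kurt, ..., f10_std`.
#' @export
feature_names <- function(n_subsegments = 10) {
  as.vector(vapply(
    seq_len(n_subsegments),
    function(j) sprintf("f%02d_%s", j, feature_stat_names),
    character(5)
  ))
}

#' Extract per-beat statistical feature vectors
#'
#' Divides each beat into `n_subsegments` contiguous, equal-length blocks in
#' temporal order and computes the five statistics of [subsegment_stats()]
#' for each, giving `5 * n_subsegments` features per beat (50 by default for
#' 250-sample beats).
#'
#' @param beats A beat tibble with a `beat` list column and a `label` column
#'   (as produced by [generate_beats()] or [segment_beats()]), or a single
#'   numeric beat vector.
#' @param n_subsegments Number of equal subsegments; must divide the beat
#'   length (default 10).
#' @return For a beat tibble: a tibble with `beat_id`, `label` and one column
#'   per feature. For a single vector: a named feature vector.
#' @examples
#' beats <- generate_beats(c(N = 3, V = 2), noise_config(0, 0, 0), seed = 1)
#' extract_features(beats)[, 1:4]
#' @export
extract_features <- function(beats, n_subsegments = 10) {
  if (is.numeric(beats)) {
    return(beat_feature_vector(beats, n_subsegments))
  }
  stopifnot(is.data.frame(beats), "beat" %in% names(beats))
  lens <- lengths(beats$beat)
  if (length(unique(lens)) > 1) abort("All beats must have the same length.")
  feats <- t(vapply(
    beats$beat, beat_feature_vector,
    numeric(5 * n_subsegments),
    n_subsegments = n_subsegments
  ))
  out <- as_tibble(feats)
  out$beat_id <- if ("beat_id" %in% names(beats)) beats$beat_id else seq_len(nrow(beats))
  out$label <- beats$label
  out[, c("beat_id", "label", feature_names(n_subsegments))]
}

beat_feature_vector <- function(x, n_subsegments) {
  n <- length(x)
  if (n %% n_subsegments != 0) {
    abort(sprintf(
      "Beat length %d is not divisible by %d subsegments.", n, n_subsegments
    ))
  }
  size <- n %/% n_subsegments
  out <- vapply(
    seq_len(n_subsegments),
    function(j) subsegment_stats(x[((j - 1) * size + 1):(j * size)]),
    numeric(5)
  )
  stats::setNames(as.vector(out), feature_names(n_subsegments))
}
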