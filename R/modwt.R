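# Maximal-overlap discrete wavelet transform (MODWT) with the Daubechies
# db6 basis, used by the wavelet denoising path. The MODWT is shift-invariant,
# defined for any signal length (circular boundary), and its multiresolution
# analysis is additive: x = D1 + ... + DJ + SJ exactly, which makes "remove
# the level-J approximation" a well-defined linear operation.

# Daubechies extremal-phase 6-vanishing-moment scaling filter (L = 12).
db6_scaling_filter <- function() {
  c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
    -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
    -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
    0.7511339080210954, 0.49462389039845306, 0.11154074335010947)
}

# Quadrature-mirror wavelet filter h_l = (-1)^l g_{L-1-l}.
db6_wavelet_filter <- function() {
  g <- db6_scaling_filter()
  L <- length(g)
  rev(g) * (-1)^(seq_len(L) - 1)
}

# One circular MODWT filtering step at level j: y_t = sum_l f_l x_{t - 2^(j-1) l}.
modwt_filt <- function(x, f, j) {
  n <- length(x)
  s <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    idx <- (t0 - s * (l - 1L)) %% n
    y <- y + f[l] * x[idx + 1L]
  }
  y
}

# Adjoint (reconstruction) step: y_t = sum_l f_l x_{t + 2^(j-1) l}.
modwt_filt_adj <- function(x, f, j) {
  n <- length(x)
  s <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    idx <- (t0 + s * (l - 1L)) %% n
    y <- y + f[l] * x[idx + 1L]
  }
  y
}

#' Maximal-overlap DWT decomposition (db6)
#'
#' @param x Numeric signal, length at least `2^levels`.
#' @param levels Number of decomposition levels (default 9).
#' @return List with `details` (list of `levels` wavelet-coefficient vectors),
#'   `smooth` (level-`levels` scaling coefficients) and `levels`.
#' @keywords internal
#' @export
modwt_db6 <- function(x, levels = 9) {
  n <- length(x)
  if (n < 2^levels) {
    abort(sprintf(
      "Signal too short for %d decomposition levels: need at least %d samples, got %d.",
      levels, 2^levels, n
    ))
  }
  g <- db6_scaling_filter() / sqrt(2)
  h <- db6_wavelet_filter() / sqrt(2)
  details <- vector("list", levels)
  v <- x
  for (j in seq_len(levels)) {
    details[[j]] <- modwt_filt(v, h, j)
    v <- modwt_filt(v, g, j)
  }
  list(details = details, smooth = v, levels = levels)
}

#' Inverse maximal-overlap DWT (db6)
#'
#' Exact inverse of [modwt_db6()]: reconstructs the signal from all detail
#' levels plus the smooth, to machine precision.
#'
#' @param w A decomposition as returned by [modwt_db6()].
#' @return Numeric signal.
#' @keywords internal
#' @export
imodwt_db6 <- function(w) {
  g <- db6_scaling_filter() / sqrt(2)
  h <- db6_wavelet_filter() / sqrt(2)
  v <- w$smooth
  for (j in rev(seq_len(w$levels))) {
    v <- modwt_filt_adj(v, g, j) + modwt_filt_adj(w$details[[j]], h, j)
  }
  v
}

# Universal soft threshold. The noise scale is estimated once from the
# finest detail level (where the ECG contributes least), by the median
# absolute deviation, and propagated to coarser levels with the MODWT
# white-noise scaling 2^(-(j-1)/2); estimating sigma per level from
# signal-dominated mid levels would over-shrink the QRS content.
soft_threshold <- function(w, n) {
  sigma <- stats::median(abs(w$details[[1]])) / 0.6745
  for (j in seq_len(w$levels)) {
    thr <- sigma * 2^(-(j - 1) / 2) * sqrt(2 * log(n))
    d <- w$details[[j]]
    w$details[[j]] <- sign(d) * pmax(abs(d) - thr, 0)
  }
  w
}
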