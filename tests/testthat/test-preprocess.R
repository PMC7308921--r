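# Analytic frequency-response oracle for the zero-phase Butterworth chain:
# filtfilt applies the filter twice, so the magnitude response is |H(f)|^2.
hl_gain <- function(f, fs, low_cut = 30, high_cut = 1, low_order = 6, high_order = 4) {
  lp <- 1 / sqrt(1 + (f / low_cut)^(2 * low_order))
  hp <- 1 / sqrt(1 + (high_cut / f)^(2 * high_order))
  (lp * hp)^2
}

test_that("HL filter attenuates 60 Hz powerline and preserves the 5-25 Hz band", {
  fs <- 360
  t <- (0:(8 * fs - 1)) / fs
  for (freq in c(10, 60)) {
    x <- sin(2 * pi * freq * t)
    y <- filter_hl(x, fs)
    core <- seq(fs, length(x) - fs) # ignore ends where transients live
    ratio <- sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
    expect_equal(ratio, hl_gain(freq, fs), tolerance = 0.02)
  }
  expect_lt(
    sqrt(mean(filter_hl(sin(2 * pi * 60 * t), fs)^2)) / sqrt(0.5),
    0.05
  ) # 60 Hz RMS < 5 % of input RMS
  expect_gt(hl_gain(10, fs), 10^(-3 / 20)) # 10 Hz within 3 dB
})

test_that("filters are linear and preserve length; zero in, zero out", {
  fs <- 360
  set.seed(4)
  x <- rnorm(1024)
  y <- rnorm(1024)
  # the wavelet path is linear with thresholding disabled; soft thresholding
  # itself is deliberately nonlinear
  for (filt in list(function(s) filter_hl(s, fs),
                    function(s) filter_wavelet(s, threshold = "none"))) {
    expect_equal(filt(numeric(1024)), numeric(1024))
    expect_length(filt(x), 1024)
    expect_equal(filt(2 * x - 3 * y), 2 * filt(x) - 3 * filt(y), tolerance = 1e-8)
  }
  expect_error(filter_hl(rnorm(10), fs), "at least")
  expect_error(filter_wavelet(rnorm(100)), "at least")
})

test_that("wavelet transform reconstructs perfectly and removes constant offsets", {
  set.seed(11)
  x <- rnorm(700)
  w <- modwt_db6(x)
  expect_equal(imodwt_db6(w), x, tolerance = 1e-10)
  # a constant lives entirely in the discarded approximation sub-band
  y <- filter_wavelet(x + 42, threshold = "none")
  expect_lt(abs(mean(y)), 1e-8)
  expect_equal(y, filter_wavelet(x, threshold = "none"), tolerance = 1e-8)
})

test_that("wavelet denoising suppresses broadband noise on a clean record", {
  rec <- generate_record(rep("N", 4), seed = 2, noise = no_noise())
  set.seed(8)
  noisy <- rec$signal + rnorm(length(rec$signal), 0, 0.1)
  den <- filter_wavelet(noisy)
  clean <- rec$signal - mean(rec$signal)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("amplitude normalization maps to [-1, 1] and is idempotent", {
  expect_equal(normalize_amplitude(c(0, 5, 10)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(100, 3, 7)
  y <- normalize_amplitude(x)
  expect_equal(range(y), c(-1, 1))
  expect_equal(normalize_amplitude(y), y, tolerance = 1e-12)
  # monotone affine: order preserved
  expect_equal(order(x), order(y))
  expect_error(normalize_amplitude(rep(3, 5)), "constant")
})

test_that("segmentation uses the 99-left / 151-right window and skips edges", {
  x <- as.numeric(seq_len(1000))
  rec <- ecgopt:::new_ecg_record(x, 360, tibble::tibble(index = c(50L, 500L), label = c("N", "V")))
  expect_warning(seg <- segment_beats(rec), "Skipping 1")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$beat[[1]], as.numeric(401:650))
  expect_equal(seg$source_index, 500L)
  expect_equal(as.character(seg$label), "V")
})

test_that("segment count equals annotation count when context is complete", {
  rec <- generate_record(rep("N", 7), seed = 1, noise = no_noise())
  seg <- segment_beats(rec)
  expect_equal(nrow(seg), nrow(rec$annotations))
  expect_true(all(lengths(seg$beat) == 250))
})

test_that("preprocess_record chains filter, per-record normalization and segmentation", {
  rec <- generate_record(rep(c("N", "V"), 5), seed = 13)
  for (f in c("hl", "wavelet")) {
    seg <- preprocess_record(rec, filter = f)
    expect_equal(nrow(seg), 10)
    rng <- range(unlist(seg$beat))
    expect_true(rng[1] >= -1 && rng[2] <= 1)
    expect_true(all(vapply(seg$beat, function(b) all(is.finite(b)), TRUE)))
  }
})
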