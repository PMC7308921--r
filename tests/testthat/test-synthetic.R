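test_that("class templates are deterministic, distinct and well-formed", {
  for (cls in beat_classes()) {
    tpl <- make_class_template(cls, 250)
    expect_length(tpl$samples, 250)
    expect_true(all(is.finite(tpl$samples)))
    expect_identical(tpl$samples, make_class_template(cls, 250)$samples)
  }
  # pairwise distinct morphologies
  mats <- sapply(beat_classes(), function(cls) make_class_template(cls)$samples)
  d <- as.matrix(dist(t(mats)))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("the normal template has a single dominant positive peak", {
  tpl <- make_class_template("N", 250)
  peak <- which.max(tpl$samples)
  expect_equal(peak, 100)
  away <- abs(seq_along(tpl$samples) - peak) > 15
  expect_true(max(tpl$samples[away]) < 0.5 * tpl$samples[peak])
})

test_that("zero amplitudes give an all-zero template and unknown classes error", {
  zero <- list(p = c(0, .03, .2), qrs = c(0, .01, .4), t = c(0, .05, .7))
  expect_equal(make_class_template("N", 250, zero)$samples, rep(0, 250))
  expect_error(make_class_template("Z", 250), "Unknown class_id")
  expect_error(make_class_template("N", 10), "at least 50")
})

test_that("generate_beats realizes requested counts exactly and reproducibly", {
  counts <- c(N = 40, L = 12, E = 4)
  b1 <- generate_beats(counts, noise_config(), seed = 5)
  b2 <- generate_beats(counts, noise_config(), seed = 5)
  b3 <- generate_beats(counts, noise_config(), seed = 6)
  got <- table(droplevels(b1$label))
  expect_equal(as.integer(got[names(counts)]), unname(as.integer(counts)))
  expect_identical(b1$beat, b2$beat)
  expect_false(isTRUE(all.equal(b1$beat[[1]], b3$beat[[1]])))
  # requested imbalance ratio is realized exactly
  expect_equal(imbalance_ratio(sum(b1$label == "N"), sum(b1$label == "E")), 10)
  expect_error(generate_beats(c(N = -1), noise_config(), seed = 1), "non-negative")
})

test_that("zero noise reproduces templates; within-class identical, between-class apart", {
  b <- generate_beats(c(N = 3, V = 3), no_noise(), seed = 9)
  tplN <- make_class_template("N")$samples
  n_rows <- which(b$label == "N")
  v_rows <- which(b$label == "V")
  for (i in n_rows) expect_equal(b$beat[[i]], tplN)
  expect_identical(b$beat[[n_rows[1]]], b$beat[[n_rows[2]]])
  expect_gt(sqrt(sum((b$beat[[n_rows[1]]] - b$beat[[v_rows[1]]])^2)), 1)
})

test_that("generate_record plants strictly increasing annotations that round-trip", {
  seqs <- rep(c("N", "L", "V", "E"), 3)
  rec <- generate_record(seqs, seed = 3, noise = no_noise())
  expect_s3_class(rec, "ecg_record")
  expect_equal(nrow(rec$annotations), 12)
  expect_true(all(diff(rec$annotations$index) > 0))
  seg <- segment_beats(rec)
  expect_equal(as.character(seg$label), seqs)
  for (i in seq_along(seqs)) {
    expect_equal(seg$beat[[i]], make_class_template(seqs[i])$samples,
                 tolerance = 1e-12)
  }
})

test_that("record round-trip holds for several seeds with default noise", {
  for (s in c(1, 22, 333)) {
    labels <- c("N", "R", "j", "a", "N")
    rec <- generate_record(labels, seed = s)
    seg <- suppressWarnings(segment_beats(rec))
    expect_equal(as.character(seg$label), labels)
  }
  expect_error(generate_record(character(0), seed = 1), "non-empty")
})
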