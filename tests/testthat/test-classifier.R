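test_that("linearly separable blobs are fit to training accuracy 1", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30), matrix(rnorm(60, 5, 0.5), 30))
  y <- rep(c("lo", "hi"), each = 30)
  m <- train_ann(X, y, n_hidden = 10, seed = 2, maxit = 100)
  expect_equal(mean(predict(m, X) == y), 1.0)
})

test_that("XOR is solvable with 4 hidden units over a best-of-5 seed search", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("a", "b", "b", "a")
  accs <- vapply(1:5, function(s) {
    m <- train_ann(X, y, n_hidden = 4, seed = s, maxit = 300)
    mean(predict(m, X) == y)
  }, 1)
  expect_equal(max(accs), 1.0)
})

test_that("an 8-class problem yields an 8-dimensional softmax output", {
  b <- generate_beats(
    stats::setNames(rep(6L, 8), beat_classes()),
    no_noise(), seed = 12
  )
  f <- extract_features(b)
  X <- as.matrix(f[, feature_names()])
  m <- train_ann(X, f$label, n_hidden = 12, seed = 3, maxit = 60)
  P <- predict(m, X, type = "prob")
  expect_equal(ncol(P), 8)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
  expect_true(all(predict(m, X) %in% beat_classes()))
})

test_that("training is bit-reproducible and prediction deterministic", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rep(c("a", "b"), 20)
  m1 <- train_ann(X, y, n_hidden = 7, seed = 11, maxit = 50)
  m2 <- train_ann(X, y, n_hidden = 7, seed = 11, maxit = 50)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, X), predict(m2, X))
  # identical rows predict identically
  X2 <- X[c(1, 1), , drop = FALSE]
  expect_identical(predict(m1, X2)[1], predict(m1, X2)[2])
})

test_that("SCG loss history is non-increasing", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60)
  y <- rep(c("a", "b", "c"), 20)
  m <- train_ann(X, y, n_hidden = 8, seed = 4, maxit = 80)
  expect_true(all(diff(m$loss_history) <= 1e-10))
})

test_that("invalid inputs are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_ann(X, rep("a", 10), n_hidden = 5, seed = 1), "2 distinct")
  Xn <- X; Xn[1, 1] <- NaN
  expect_error(train_ann(Xn, rep(c("a", "b"), 5), n_hidden = 5, seed = 1), "finite")
  m <- train_ann(X, rep(c("a", "b"), 5), n_hidden = 5, seed = 1, maxit = 10)
  expect_error(predict(m, matrix(0, 2, 5)), "dimension")
})

test_that("SCG agrees with an independent BFGS network on a separable task", {
  skip_if_not_installed("nnet")
  set.seed(9)
  X <- rbind(matrix(rnorm(80, -2, 0.4), 40), matrix(rnorm(80, 2, 0.4), 40))
  y <- factor(rep(c("a", "b"), each = 40))
  ours <- train_ann(X, y, n_hidden = 5, seed = 2, maxit = 100)
  ref <- nnet::nnet(X, nnet::class.ind(y), size = 5, softmax = TRUE,
                    maxit = 200, trace = FALSE)
  ref_pred <- factor(colnames(nnet::class.ind(y))[max.col(predict(ref, X))], levels(y))
  expect_equal(mean(predict(ours, X) == y), 1.0)
  expect_equal(mean(ref_pred == y), 1.0)
  expect_equal(as.character(predict(ours, X)), as.character(ref_pred))
})
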