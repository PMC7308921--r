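test_that("identical instances collapse onto one winning neuron", {
  X <- matrix(1, 20, 10)
  som <- train_som(X, 2, seed = 1, epochs = 20)
  rk <- assign_and_rank(som, X)
  expect_equal(length(unique(rk$neuron)), 1)
  expect_true(all(rk$distance < 1e-6))
})

test_that("two well-separated blobs are clustered as 2-means does", {
  set.seed(42)
  X <- rbind(
    matrix(rnorm(30 * 5, -10, 0.1), 30),
    matrix(rnorm(30 * 5, 10, 0.1), 30)
  )
  truth <- rep(1:2, each = 30)
  som <- train_som(X, 2, seed = 7, epochs = 50)
  rk <- assign_and_rank(som, X)
  assign <- rk$neuron[order(rk$instance)]
  km <- kmeans(X, 2, nstart = 5)
  # purity against the known blobs, and agreement with the k-means oracle
  tab <- table(assign, truth)
  expect_equal(sum(apply(tab, 1, max)) / length(truth), 1.0)
  tab2 <- table(assign, km$cluster)
  expect_equal(sum(apply(tab2, 1, max)) / length(truth), 1.0)
})

test_that("a k x k grid has k^2 neurons and at most k^2 non-empty clusters", {
  b <- tiny_beats(c(N = 12, V = 12, E = 6))
  X <- beat_matrix(b)
  som <- train_som(X, 3, seed = 2, epochs = 15)
  expect_equal(nrow(som$weights), 9)
  rk <- assign_and_rank(som, X)
  expect_lte(length(unique(rk$neuron)), 9)
})

test_that("training is deterministic under a fixed seed and validates inputs", {
  X <- beat_matrix(tiny_beats(c(N = 10, V = 10)))
  s1 <- train_som(X, 2, seed = 5, epochs = 10)
  s2 <- train_som(X, 2, seed = 5, epochs = 10)
  expect_identical(s1$weights, s2$weights)
  expect_error(train_som(X, 1, seed = 1), "between 2 and 10")
  expect_error(train_som(X[0, , drop = FALSE], 2, seed = 1), "At least one")
})

test_that("quantization error does not increase on average over training", {
  X <- beat_matrix(tiny_beats(c(N = 25, V = 25, L = 20), seed = 3))
  deltas <- vapply(1:3, function(s) {
    qe <- train_som(X, 3, seed = s, epochs = 40)$qe
    mean(tail(qe, 10)) - mean(head(qe, 10))
  }, 1)
  expect_lt(mean(deltas), 1e-3)
})

test_that("ranking sorts ascending by distance to the cluster center", {
  som <- train_som(matrix(rnorm(50 * 4), 50), 2, seed = 1, epochs = 10)
  # instances placed at known distances from one neuron weight
  w <- som$weights[1, ]
  probes <- rbind(w, w + c(1, 0, 0, 0), w + c(0, 2, 0, 0), w + c(0, 0, 3, 0))
  rk <- assign_and_rank(som, probes)
  first <- rk[rk$instance == 1, ]
  expect_equal(first$distance, 0)
  expect_equal(first$rank, 1)
  cl <- rk[rk$neuron == first$neuron, ]
  expect_true(!is.unsorted(cl$distance))
  # partition: every instance exactly once
  expect_setequal(rk$instance, 1:4)
  expect_error(assign_and_rank(som, matrix(0, 2, 9)), "dimension")
})

test_that("instance selection takes the per-cluster head with the max(1, round) rule", {
  rk <- tibble::tibble(
    neuron = rep(1:2, c(10, 3)),
    instance = 1:13,
    distance = c(sort(runif(10)), sort(runif(3))),
    rank = c(1:10, 1:3)
  )
  class(rk) <- c("ranked_clusters", class(rk))
  expect_equal(select_instances(rk, 0.5), c(1:5, 11, 12)) # 5 of 10, round(1.5)=2 of 3
  expect_equal(select_instances(rk, 0.01), c(1, 11)) # max(1, .) floor
  big <- tibble::tibble(neuron = 1L, instance = 1:1000,
                        distance = seq_len(1000), rank = 1:1000)
  expect_length(select_instances(big, 0.999), 999)
  expect_error(select_instances(rk, 0), "fraction")
  expect_error(select_instances(rk, 1), "fraction")
})

test_that("selection is monotone in the fraction and matches the count formula", {
  X <- beat_matrix(tiny_beats(c(N = 40, V = 20), seed = 8))
  som <- train_som(X, 3, seed = 9, epochs = 15)
  rk <- assign_and_rank(som, X)
  sizes <- table(rk$neuron)
  prev <- integer(0)
  for (p in c(0.05, 0.2, 0.5, 0.8, 0.999)) {
    sel <- select_instances(rk, p)
    expect_true(all(prev %in% sel))
    expect_length(sel, sum(pmax(1, round_half_away(p * as.integer(sizes)))))
    prev <- sel
  }
})

test_that("the SOM cache trains each (class, grid size) once and reuses it", {
  b <- tiny_beats(c(N = 20, V = 15, E = 5))
  cache <- som_cache(b, classes = c("N", "V"), seed = 4, epochs = 5)
  r1 <- cache_ranking(cache, "N", 2)
  r2 <- cache_ranking(cache, "N", 2)
  expect_identical(r1, r2)
  # rankings index rows of the full beat tibble, restricted to the class
  expect_true(all(b$label[r1$ranking$instance] == "N"))
  expect_error(cache_ranking(cache, "E", 2), "not cached")
})
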