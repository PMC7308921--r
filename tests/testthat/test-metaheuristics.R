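test_that("decoding clips to bounds then rounds the integer slots", {
  raw <- c(4.4, rep(0.5, 4), 99.7, rep(0.6, 50))
  cfg <- decode_vector(raw)
  expect_equal(cfg$grid_k, 4L)
  expect_equal(cfg$n_hidden, 100L)
  expect_true(all(cfg$feature_mask))
  expect_equal(sum(decode_vector(c(3, rep(0.5, 4), 50, rep(0.4, 50)))$feature_mask), 0)
  expect_equal(decode_vector(c(11, rep(0.5, 4), 50, rep(1, 50)))$grid_k, 10L)
  expect_equal(decode_vector(c(2, rep(2, 4), 50, rep(1, 50)))$fractions[["N"]], 0.999)
  expect_error(decode_vector(c(1, 2, 3)), "length 56")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5, -1.5)), c(1, 2, 3, -1, -2))
  expect_equal(decode_vector(c(2.5, rep(0.5, 4), 10.5, rep(0.5, 50)))$grid_k, 3L)
})

test_that("DE solves the sphere surrogate to within 1e-2", {
  run <- optimize_de(neg_sphere, sphere_bounds(), n = 50, F = 0.5, Cr = 0.9,
                     budget = 2000, seed = 17)
  expect_gt(run$best_fitness, -1e-2)
  expect_true(all(diff(run$history$best_so_far) >= 0))
})

test_that("PSO solves the sphere surrogate to within 1e-1", {
  run <- optimize_pso(neg_sphere, sphere_bounds(), n = 50, budget = 2000, seed = 19)
  expect_gt(run$best_fitness, -1e-1)
  expect_true(all(diff(run$history$best_so_far) >= 0))
})

test_that("budget accounting: population times generations, same for DE and PSO", {
  fde <- counting(neg_sphere)
  de <- optimize_de(fde, sphere_bounds(), n = 5, budget = 12, seed = 1)
  expect_equal(calls_of(fde), de$evaluations)
  expect_equal(de$evaluations %% 5, 0) # whole generations only
  expect_lte(de$evaluations, 12 + 4) # overshoot at most population - 1
  fpso <- counting(neg_sphere)
  pso <- optimize_pso(fpso, sphere_bounds(), n = 5, budget = 12, seed = 1)
  expect_equal(calls_of(fpso), pso$evaluations)
  expect_equal(pso$evaluations, de$evaluations)
  expect_error(optimize_de(neg_sphere, sphere_bounds(), n = 3, seed = 1), "at least 4")
})

test_that("degenerate DE parameters freeze the population but never regress", {
  run <- optimize_de(neg_sphere, sphere_bounds(), n = 6, F = 0, Cr = 0,
                     budget = 60, seed = 23)
  expect_true(all(diff(run$history$best_so_far) >= 0))
  # greedy selection: every population member ends at least as fit as it started
  expect_true(all(run$fitness >= run$history$fitness[1:6] - 1e-12))
})

test_that("PSO with zero coefficients keeps positions static", {
  f <- counting(function(x) -sum(x^2))
  run <- optimize_pso(f, sphere_bounds(), n = 4, wmax = 0, wmin = 0, c1 = 0,
                      c2 = 0, budget = 16, seed = 3)
  # zero inertia and accelerations: velocities stay 0, fitness repeats
  per_gen <- matrix(run$history$fitness, nrow = 4)
  expect_equal(per_gen[, 2], per_gen[, 1])
  expect_equal(run$best_fitness, max(run$history$fitness))
})

test_that("optimizer runs are reproducible under a fixed seed", {
  r1 <- optimize_de(neg_sphere, sphere_bounds(), n = 8, budget = 40, seed = 99)
  r2 <- optimize_de(neg_sphere, sphere_bounds(), n = 8, budget = 40, seed = 99)
  expect_identical(r1$best_vector, r2$best_vector)
  expect_identical(r1$history, r2$history)
})

# ---- the cross-validated objective ------------------------------------------

make_prepared <- function(counts = c(N = 40, V = 30, L = 25, E = 10),
                          noise = no_noise(), seed = 55) {
  beats <- generate_beats(counts, noise, seed = seed)
  prepare_pipeline(beats, seed = seed + 1, som_epochs = 10,
                   ann = list(maxit = 25, decay = 0))
}

permissive_raw <- function(h = 20) c(2, rep(0.9, 4), h, rep(1, 50))

test_that("a permissive config on separable classes reaches mean F1 ~ 100", {
  prepared <- make_prepared()
  res <- evaluate_objective(decode_vector(permissive_raw()), prepared)
  expect_gte(res$mean_f1, 99.5)
  expect_equal(nrow(res$fold_metrics), 10)
  expect_false(res$degenerate)
})

test_that("one objective call trains one model per fold and costs one evaluation", {
  prepared <- make_prepared(c(N = 25, V = 20, E = 10))
  obj <- pipeline_objective(prepared)
  f1 <- obj(permissive_raw())
  expect_equal(environment(obj)$evaluations, 1L)
  res <- evaluate_objective(decode_vector(permissive_raw()), prepared)
  expect_equal(nrow(res$fold_metrics), prepared$folds)
  expect_equal(res$mean_f1, f1)
})

test_that("permuted labels collapse fitness towards chance level", {
  prepared <- make_prepared(c(N = 30, V = 30, L = 30, E = 30))
  sep <- evaluate_objective(decode_vector(permissive_raw()), prepared)
  shuffled <- prepared
  set.seed(77)
  shuffled$labels <- sample(prepared$labels)
  perm <- suppressWarnings(
    evaluate_objective(decode_vector(permissive_raw()), shuffled)
  )
  expect_gte(sep$mean_f1, 99)
  expect_lt(perm$mean_f1, 60)
})

test_that("degenerate configurations score zero instead of raising", {
  prepared <- make_prepared(c(N = 25, V = 20, E = 8))
  no_features <- c(2, rep(0.9, 4), 20, rep(0, 50))
  expect_warning(res <- evaluate_objective(decode_vector(no_features), prepared),
                 "Degenerate")
  expect_equal(res$mean_f1, 0)
  expect_true(res$degenerate)
})

test_that("the objective is reproducible and responds to the undersampling fractions", {
  prepared <- make_prepared()
  raw <- c(2, rep(0.3, 4), 15, rep(1, 50))
  # strong undersampling can leave a class out of some test fold; the 0/0
  # convention warns, which is not what this test is about
  r1 <- suppressWarnings(evaluate_objective(decode_vector(raw), prepared))
  r2 <- suppressWarnings(evaluate_objective(decode_vector(raw), prepared))
  expect_equal(r1$mean_f1, r2$mean_f1)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  full <- evaluate_objective(decode_vector(permissive_raw()), prepared)
  expect_lt(r1$subset_size, full$subset_size)
  # minority classes are never undersampled
  expect_gte(r1$subset_size, sum(prepared$labels == "E"))
})
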