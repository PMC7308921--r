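#' Bounds of the 56-element representation vector
#'
#' One candidate solution is encoded as 56 reals: slot 1 the SOM grid side
#' (2-10), slots 2-5 the undersampling fractions for classes L, N, V, R
#' (lower bounds 0.01, 0.001, 0.01, 0.01; upper 0.999), slot 6 the
#' hidden-layer width (10-500), slots 7-56 the 50-bit feature mask (0-1).
#' Slots 1, 6 and 7-56 are rounded (half away from zero) at decode time;
#' the fractions pass through unrounded.
#'
#' @param n_features Number of feature-mask slots (default 50).
#' @param n_hidden_range Hidden-width bounds, default `c(10, 500)`.
#' @return Tibble with columns `slot`, `name`, `lower`, `upper`, `integer`.
#' @export
representation_bounds <- function(n_features = 50, n_hidden_range = c(10, 500)) {
  tibble(
    slot = seq_len(6 + n_features),
    name = c(
      "grid_k", "frac_L", "frac_N", "frac_V", "frac_R", "n_hidden",
      sprintf("feature_%02d", seq_len(n_features))
    ),
    lower = c(2, 0.01, 0.001, 0.01, 0.01, n_hidden_range[1], rep(0, n_features)),
    upper = c(10, 0.999, 0.999, 0.999, 0.999, n_hidden_range[2], rep(1, n_features)),
    integer = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, rep(TRUE, n_features))
  )
}

#' Decode a raw representation vector into a pipeline configuration
#'
#' Values are first clipped to the bounds, then the integer slots (grid side,
#' hidden width, feature mask) are rounded half away from zero; the four
#' undersampling fractions are used as-is.
#'
#' @param raw Numeric vector of length `nrow(bounds)`.
#' @param bounds A [representation_bounds()] table.
#' @return An object of class `pipeline_config`: list with `grid_k`,
#'   `fractions` (named L, N, V, R), `n_hidden` and logical `feature_mask`.
#' @examples
#' cfg <- decode_vector(c(4.4, 0.5, 0.5, 0.5, 0.5, 99.7, rep(0.6, 50)))
#' cfg$grid_k; cfg$n_hidden; sum(cfg$feature_mask)
#' @export
decode_vector <- function(raw, bounds = representation_bounds()) {
  if (length(raw) != nrow(bounds)) {
    abort(sprintf(
      "Representation vector must have length %d, got %d.",
      nrow(bounds), length(raw)
    ))
  }
  x <- clip(raw, bounds$lower, bounds$upper)
  x[bounds$integer] <- round_half_away(x[bounds$integer])
  structure(
    list(
      grid_k = as.integer(x[1]),
      fractions = c(L = x[2], N = x[3], V = x[4], R = x[5]),
      n_hidden = as.integer(x[6]),
      feature_mask = x[-(1:6)] == 1
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> SOM %dx%d, fractions L %.3f N %.3f V %.3f R %.3f, %d hidden, %d/%d features\n",
    x$grid_k, x$grid_k, x$fractions[["L"]], x$fractions[["N"]],
    x$fractions[["V"]], x$fractions[["R"]], x$n_hidden,
    sum(x$feature_mask), length(x$feature_mask)
  ))
  invisible(x)
}

#' Prepare the data structures the objective function reuses
#'
#' Computes the feature table once and sets up the lazy SOM ranking cache for
#' the majority classes, so each objective evaluation only undersamples,
#' masks features and cross-validates.
#'
#' @param beats Beat tibble (`label` factor, `beat` list column).
#' @param n_subsegments Subsegments per beat for feature extraction.
#' @param majority Classes to undersample.
#' @param seed Master seed (drives SOM training, fold shuffles and network
#'   initializations).
#' @param som_epochs SOM training epochs.
#' @param ann List of classifier settings passed to [train_ann()]:
#'   `maxit`, `decay`.
#' @param folds Number of cross-validation folds (default 10).
#' @return An object of class `prepared_pipeline`.
#' @export
prepare_pipeline <- function(beats, n_subsegments = 10,
                             majority = majority_classes(), seed,
                             som_epochs = 100,
                             ann = list(maxit = 200, decay = 0),
                             folds = 10) {
  stopifnot(is.data.frame(beats), all(c("label", "beat") %in% names(beats)))
  feats <- extract_features(beats, n_subsegments)
  fmat <- as.matrix(feats[, feature_names(n_subsegments)])
  labels <- factor(as.character(feats$label),
                   levels = intersect(beat_classes(), unique(as.character(feats$label))))
  structure(
    list(
      features = fmat,
      labels = labels,
      majority = intersect(majority, levels(labels)),
      minority_rows = which(!as.character(labels) %in% majority),
      cache = som_cache(beats, intersect(majority, levels(labels)),
                        seed = seed, epochs = som_epochs),
      seed = as.integer(seed),
      folds = folds,
      ann = utils::modifyList(list(maxit = 200, decay = 0), ann),
      n_subsegments = n_subsegments
    ),
    class = "prepared_pipeline"
  )
}

#' Evaluate one pipeline configuration (the optimization objective)
#'
#' Implements the fitness computation: (1) undersample each majority class by
#' keeping its configured fraction of SOM-cluster members closest to the
#' cluster centers; (2) merge with all minority instances; (3) keep only the
#' masked features; (4) stratified k-fold cross-validation (default 10)
#' training one network per fold; (5) return the mean macro F1 across folds
#' (percent) as the fitness. A degenerate configuration (empty feature mask,
#' or a class left with fewer than 2 instances) scores 0 instead of raising,
#' so population-based search stays total.
#'
#' @param config A [decode_vector()] result (or raw 56-vector, decoded with
#'   default bounds).
#' @param prepared A [prepare_pipeline()] object.
#' @param seed Optional seed overriding the deterministic per-candidate seed
#'   derived from the prepared pipeline's master seed and the configuration.
#' @return An object of class `objective_result`: `mean_f1` (the fitness, in
#'   percent), `fold_metrics` tibble, pooled `confusion` report,
#'   `subset_size`, `n_features`, `degenerate`.
#' @export
evaluate_objective <- function(config, prepared, seed = NULL) {
  stopifnot(inherits(prepared, "prepared_pipeline"))
  if (is.numeric(config)) config <- decode_vector(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- seed %||% vector_seed(prepared$seed, c(
    config$grid_k, config$fractions, config$n_hidden, as.numeric(config$feature_mask)
  ))

  keep_rows <- prepared$minority_rows
  for (cls in prepared$majority) {
    rk <- cache_ranking(prepared$cache, cls, config$grid_k)
    keep_rows <- c(keep_rows, select_instances(rk$ranking, config$fractions[[cls]]))
  }
  keep_rows <- sort(keep_rows)
  labels <- droplevels(prepared$labels[keep_rows])

  degenerate <- sum(config$feature_mask) == 0 ||
    length(levels(labels)) < 2 || any(table(labels) < 2)
  if (degenerate) {
    warn("Degenerate configuration: fitness 0.")
    return(structure(
      list(
        mean_f1 = 0, fold_metrics = tibble(), confusion = NULL,
        subset_size = length(keep_rows), n_features = sum(config$feature_mask),
        degenerate = TRUE, config = config
      ),
      class = "objective_result"
    ))
  }

  X <- prepared$features[keep_rows, config$feature_mask, drop = FALSE]
  k <- prepared$folds
  # stratified folds: shuffle within class, then deal round-robin so every
  # fold receives its share of even the smallest class
  fold_id <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in levels(labels)) {
      rows <- which(labels == cls)
      rows <- rows[sample.int(length(rows))]
      fold_id[rows] <- rep(seq_len(k), length.out = length(rows))
    }
  })

  truth_all <- character(0)
  pred_all <- character(0)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_id == f
    if (!any(test)) next
    model <- train_ann(
      X[!test, , drop = FALSE], labels[!test],
      n_hidden = config$n_hidden,
      seed = derive_seed(seed, paste0("fold", f)),
      maxit = prepared$ann$maxit, decay = prepared$ann$decay
    )
    pred <- predict(model, X[test, , drop = FALSE])
    rep_f <- confusion_report(as.character(labels[test]), as.character(pred),
                              class_order = levels(labels))
    fold_rows[[f]] <- tibble(
      fold = f, n_test = sum(test),
      accuracy = rep_f$overall$accuracy,
      macro_sensitivity = rep_f$overall$macro_sensitivity,
      macro_specificity = rep_f$overall$macro_specificity,
      macro_precision = rep_f$overall$macro_precision,
      macro_f1 = rep_f$overall$macro_f1
    )
    truth_all <- c(truth_all, as.character(labels[test]))
    pred_all <- c(pred_all, as.character(pred))
  }
  fold_metrics <- bind_rows(fold_rows)
  structure(
    list(
      mean_f1 = mean(fold_metrics$macro_f1),
      fold_metrics = fold_metrics,
      confusion = confusion_report(truth_all, pred_all, class_order = levels(labels)),
      subset_size = length(keep_rows),
      n_features = sum(config$feature_mask),
      degenerate = FALSE,
      config = config
    ),
    class = "objective_result"
  )
}

#' @export
print.objective_result <- function(x, ...) {
  cat(sprintf(
    "<objective_result> mean macro F1 %.2f%% over %d folds, subset %d instances, %d features%s\n",
    x$mean_f1, nrow(x$fold_metrics), x$subset_size, x$n_features,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' @rdname evaluate_objective
#' @param x An `objective_result`.
#' @param ... Unused.
#' @export
tidy.objective_result <- function(x, ...) x$fold_metrics

#' @rdname evaluate_objective
#' @export
glance.objective_result <- function(x, ...) {
  tibble(
    mean_f1 = x$mean_f1, subset_size = x$subset_size,
    n_features = x$n_features, folds = nrow(x$fold_metrics),
    degenerate = x$degenerate
  )
}

#' Build a counting objective function over raw vectors
#'
#' Wraps [evaluate_objective()] as `f(raw) -> fitness` for the optimizers,
#' with an evaluation counter and a log of every call (auditable budget
#' accounting).
#'
#' @param prepared A [prepare_pipeline()] object.
#' @param bounds Representation bounds used for decoding.
#' @return A function with attributes; query calls with
#'   `environment(f)$evaluations`.
#' @export
pipeline_objective <- function(prepared, bounds = representation_bounds()) {
  evaluations <- 0L
  log <- list()
  f <- function(raw) {
    res <- evaluate_objective(decode_vector(raw, bounds), prepared)
    evaluations <<- evaluations + 1L
    log[[evaluations]] <<- c(evaluation = evaluations, fitness = res$mean_f1,
                             subset = res$subset_size)
    res$mean_f1
  }
  f
}

new_optimizer_run <- function(method, params, pop, fit, history, evals, seed) {
  best <- which.max(fit)
  structure(
    list(
      method = method, params = params,
      best_vector = pop[best, ], best_fitness = fit[best],
      population = pop, fitness = fit,
      history = history, evaluations = evals, seed = seed
    ),
    class = "optimizer_run"
  )
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf(
    "<optimizer_run> %s, %d evaluations, best fitness %.4g\n",
    x$method, x$evaluations, x$best_fitness
  ))
  invisible(x)
}

#' @rdname optimize_de
#' @param x An `optimizer_run`.
#' @param ... Unused.
#' @export
tidy.optimizer_run <- function(x, ...) x$history

#' @rdname optimize_de
#' @export
glance.optimizer_run <- function(x, ...) {
  tibble(
    method = x$method, evaluations = x$evaluations,
    best_fitness = x$best_fitness, seed = x$seed
  )
}

#' Differential evolution (DE/rand/1/bin), maximizing
#'
#' Uniform random initialization within bounds; for each target vector a
#' donor `x_r1 + F * (x_r2 - x_r3)` is built from three distinct random
#' others, combined by binomial crossover at rate `Cr` with one guaranteed
#' donor slot, clipped to the bounds, and kept if at least as fit (greedy
#' selection). Generations run until the evaluation budget is exhausted
#' (initial evaluations included, final generation completed).
#'
#' @param objective Function raw vector -> fitness (maximized).
#' @param bounds A bounds table with `lower`, `upper` columns.
#' @param n Population size (default 50).
#' @param F Mutation factor (default 0.5).
#' @param Cr Crossover rate (default 0.9).
#' @param budget Maximum objective evaluations (default 2000).
#' @param seed Integer seed.
#' @return An object of class `optimizer_run` with `best_vector`,
#'   `best_fitness`, the final `population`, and `history` (a tibble with
#'   one row per evaluation: `evaluation`, `fitness`, `best_so_far`).
#' @export
optimize_de <- function(objective, bounds, n = 50, F = 0.5, Cr = 0.9,
                        budget = 2000, seed) {
  if (n < 4) abort("DE needs a population of at least 4 (mutation draws 3 distinct others).")
  if (budget < n) abort("`budget` must cover at least the initial population.")
  lower <- bounds$lower
  upper <- bounds$upper
  d <- length(lower)
  hist_eval <- numeric(0)
  with_seed(as.integer(seed), {
    pop <- t(apply(matrix(runif(n * d), n, d), 1, function(u) lower + u * (upper - lower)))
    fit <- apply(pop, 1, objective)
    evals <- n
    hist_eval <- fit
    while (evals < budget) {
      for (i in seq_len(n)) {
        r <- sample(setdiff(seq_len(n), i), 3)
        donor <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
        jrand <- sample.int(d, 1)
        cross <- runif(d) < Cr
        cross[jrand] <- TRUE
        trial <- ifelse(cross, donor, pop[i, ])
        trial <- clip(trial, lower, upper)
        f_trial <- objective(trial)
        evals <- evals + 1L
        hist_eval <- c(hist_eval, f_trial)
        if (f_trial >= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
    }
    history <- tibble(
      evaluation = seq_along(hist_eval),
      fitness = hist_eval,
      best_so_far = cummax(hist_eval)
    )
    new_optimizer_run("DE", list(n = n, F = F, Cr = Cr, budget = budget),
                      pop, fit, history, evals, as.integer(seed))
  })
}

#' Particle swarm optimization with linearly decaying inertia, maximizing
#'
#' Standard global-best PSO: velocities update as
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with the inertia
#' weight decaying linearly from `wmax` to `wmin` over the planned
#' generations; positions are clipped to the bounds and velocities clamped
#' to the bound range. Stops when the evaluation budget is exhausted.
#'
#' @inheritParams optimize_de
#' @param wmax,wmin Inertia weight schedule (defaults 0.9, 0.4).
#' @param c1,c2 Cognitive and social acceleration constants (defaults 2, 2).
#' @return An `optimizer_run`; see [optimize_de()].
#' @export
optimize_pso <- function(objective, bounds, n = 50, wmax = 0.9, wmin = 0.4,
                         c1 = 2, c2 = 2, budget = 2000, seed) {
  if (budget < n) abort("`budget` must cover at least the initial population.")
  lower <- bounds$lower
  upper <- bounds$upper
  d <- length(lower)
  range <- upper - lower
  gens <- max(1, floor((budget - n) / n))
  with_seed(as.integer(seed), {
    pos <- t(apply(matrix(runif(n * d), n, d), 1, function(u) lower + u * range))
    vel <- matrix(0, n, d)
    fit <- apply(pos, 1, objective)
    evals <- n
    hist_eval <- fit
    pbest <- pos
    pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    gen <- 0L
    while (evals < budget) {
      gen <- gen + 1L
      w <- if (gens <= 1) wmin else wmax - (wmax - wmin) * (gen - 1) / (gens - 1)
      r1 <- matrix(runif(n * d), n, d)
      r2 <- matrix(runif(n * d), n, d)
      vel <- w * vel +
        c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, n, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-range, n, d, byrow = TRUE)),
                  matrix(range, n, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lower, n, d, byrow = TRUE)),
                  matrix(upper, n, d, byrow = TRUE))
      fit <- apply(pos, 1, objective)
      evals <- evals + n
      hist_eval <- c(hist_eval, fit)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      if (max(fit) > gbest_fit) {
        g <- which.max(fit)
        gbest <- pos[g, ]
        gbest_fit <- fit[g]
      }
    }
    history <- tibble(
      evaluation = seq_along(hist_eval),
      fitness = hist_eval,
      best_so_far = cummax(hist_eval)
    )
    run <- new_optimizer_run(
      "PSO", list(n = n, wmax = wmax, wmin = wmin, c1 = c1, c2 = c2, budget = budget),
      pbest, pbest_fit, history, evals, as.integer(seed)
    )
    run$best_vector <- gbest
    run$best_fitness <- gbest_fit
    run
  })
}
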