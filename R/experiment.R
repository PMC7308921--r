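#' Assemble and validate an experiment configuration
#'
#' One experiment = a data source, a filtering method, a metaheuristic with
#' its parameters, and a repetition count — the four benchmark experiments
#' are the grid {HL, wavelet} x {PSO, DE}. Defaults follow the benchmark
#' configuration (population 50, 2000 evaluations, DE F = 0.5 / Cr = 0.9,
#' PSO wmax = 0.9 / wmin = 0.4 / c1 = c2 = 2, ten repetitions).
#'
#' @param data Either a list `list(type = "synthetic", class_counts, noise)`
#'   or `list(type = "wfdb", paths, lead)` with base paths of WFDB-style text
#'   records.
#' @param filter `"hl"` or `"wavelet"`.
#' @param metaheuristic `"de"` or `"pso"`.
#' @param params Optimizer parameters; missing entries get the defaults
#'   above.
#' @param bounds Representation bounds (default [representation_bounds()]).
#' @param n_subsegments Feature subsegments per beat (default 10).
#' @param som_epochs SOM training epochs (default 100).
#' @param ann Classifier settings (`maxit`, `decay`).
#' @param repetitions Independent optimizer repetitions (default 10).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param outdir Optional directory for the report files.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(data = list(type = "synthetic"),
                              filter = c("hl", "wavelet"),
                              metaheuristic = c("de", "pso"),
                              params = list(),
                              bounds = representation_bounds(),
                              n_subsegments = 10,
                              som_epochs = 100,
                              ann = list(maxit = 200, decay = 0),
                              repetitions = 10,
                              seed,
                              outdir = NULL) {
  filter <- match.arg(filter)
  metaheuristic <- match.arg(metaheuristic)
  if (missing(seed)) abort("`seed` must be supplied.")
  stopifnot(is.list(data), data$type %in% c("synthetic", "wfdb", "beats"))
  defaults <- if (metaheuristic == "de") {
    list(n = 50, F = 0.5, Cr = 0.9, budget = 2000)
  } else {
    list(n = 50, wmax = 0.9, wmin = 0.4, c1 = 2, c2 = 2, budget = 2000)
  }
  params <- utils::modifyList(defaults, params)
  if (repetitions < 1) abort("`repetitions` must be at least 1.")
  structure(
    list(
      data = data, filter = filter, metaheuristic = metaheuristic,
      params = params, bounds = bounds, n_subsegments = n_subsegments,
      som_epochs = som_epochs, ann = ann, repetitions = repetitions,
      seed = as.integer(seed), outdir = outdir
    ),
    class = "experiment_config"
  )
}

# Materialize the configured data source as a labelled beat tibble.
experiment_beats <- function(config) {
  data <- config$data
  switch(data$type,
    beats = data$beats,
    synthetic = {
      counts <- data$class_counts %||% default_class_counts()
      noise <- data$noise %||% noise_config()
      labels <- rep(names(counts), counts)
      seq_seed <- derive_seed(config$seed, "beat_sequence")
      labels <- with_seed(seq_seed, labels[sample.int(length(labels))])
      rec <- generate_record(labels, noise = noise,
                             seed = derive_seed(config$seed, "record"))
      preprocess_record(rec, filter = config$filter)
    },
    wfdb = {
      recs <- lapply(data$paths, read_record_wfdb, lead = data$lead %||% "MLII")
      bind_rows(lapply(recs, preprocess_record, filter = config$filter))
    }
  )
}

#' Run one full optimization experiment
#'
#' Executes the pipeline end to end: data preparation (generation or
#' reading + filtering + normalization + segmentation), feature extraction
#' and lazy SOM caching, then `repetitions` independent metaheuristic runs
#' against the cross-validated macro-F1 objective, and finally a full
#' evaluation of the overall best solution. Fully reproducible from the
#' config's master seed; if `outdir` is set, all report files are written as
#' CSV/JSON.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_result`: `fitness_table` (one row
#'   per repetition plus the per-repetition best vectors), `best`
#'   (the winning `objective_result`, including its pooled confusion
#'   report), `runs` (the `optimizer_run` objects), `t_test`
#'   (if `repetitions >= 2`, against `mu0 = 98`), and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  beats <- experiment_beats(config)
  prepared <- prepare_pipeline(
    beats,
    n_subsegments = config$n_subsegments,
    seed = derive_seed(config$seed, "pipeline"),
    som_epochs = config$som_epochs,
    ann = config$ann
  )
  runs <- vector("list", config$repetitions)
  for (r in seq_len(config$repetitions)) {
    obj <- pipeline_objective(prepared, config$bounds)
    opt_seed <- derive_seed(config$seed, paste0("optimizer_rep", r))
    runs[[r]] <- if (config$metaheuristic == "de") {
      optimize_de(obj, config$bounds,
                  n = config$params$n, F = config$params$F,
                  Cr = config$params$Cr, budget = config$params$budget,
                  seed = opt_seed)
    } else {
      optimize_pso(obj, config$bounds,
                   n = config$params$n, wmax = config$params$wmax,
                   wmin = config$params$wmin, c1 = config$params$c1,
                   c2 = config$params$c2, budget = config$params$budget,
                   seed = opt_seed)
    }
  }
  fitness_table <- tibble(
    repetition = seq_len(config$repetitions),
    best_f1 = vapply(runs, function(x) x$best_fitness, 1),
    evaluations = vapply(runs, function(x) as.integer(x$evaluations), 1L)
  )
  best_rep <- which.max(fitness_table$best_f1)
  best <- evaluate_objective(
    decode_vector(runs[[best_rep]]$best_vector, config$bounds), prepared
  )
  t_test <- if (config$repetitions >= 2 && sd(fitness_table$best_f1) > 0) {
    one_sample_t(fitness_table$best_f1, mu0 = 98)
  }
  result <- structure(
    list(
      fitness_table = fitness_table, best = best, best_repetition = best_rep,
      runs = runs, t_test = t_test, config = config
    ),
    class = "experiment_result"
  )
  if (!is.null(config$outdir)) write_experiment_reports(result, config$outdir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s + %s filtering, %d repetition(s): mean best F1 %.2f%% (SD %.3f), overall best %.2f%%\n",
    toupper(x$config$metaheuristic), x$config$filter,
    nrow(x$fitness_table), mean(x$fitness_table$best_f1),
    sd(x$fitness_table$best_f1), x$best$mean_f1
  ))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @export
tidy.experiment_result <- function(x, ...) x$fitness_table

#' @rdname run_experiment
#' @export
glance.experiment_result <- function(x, ...) {
  tibble(
    metaheuristic = x$config$metaheuristic,
    filter = x$config$filter,
    repetitions = nrow(x$fitness_table),
    mean_f1 = mean(x$fitness_table$best_f1),
    sd_f1 = sd(x$fitness_table$best_f1),
    best_f1 = x$best$mean_f1,
    subset_size = x$best$subset_size,
    n_features = x$best$n_features
  )
}

#' Write the report bundle of an experiment
#'
#' Emits the repetition fitness table (with a mean/SD row), the best
#' decoded configuration (JSON), the best solution's confusion matrix and
#' per-class/overall metric tables, and each repetition's evaluation history
#' (for post-hoc budget auditing) as CSV files.
#'
#' @param result An `experiment_result`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_experiment_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ft <- result$fitness_table
  summary_rows <- data.frame(
    repetition = c("mean", "sd"),
    best_f1 = c(mean(ft$best_f1), stats::sd(ft$best_f1)),
    evaluations = c(mean(ft$evaluations), stats::sd(ft$evaluations))
  )
  ft_out <- rbind(
    data.frame(repetition = as.character(ft$repetition),
               best_f1 = ft$best_f1, evaluations = ft$evaluations),
    summary_rows
  )
  write.csv(ft_out, file.path(outdir, "fitness_table.csv"), row.names = FALSE)
  best_cfg <- result$best$config
  jsonlite::write_json(
    list(
      grid_k = best_cfg$grid_k,
      fractions = as.list(best_cfg$fractions),
      n_hidden = best_cfg$n_hidden,
      feature_mask = as.integer(best_cfg$feature_mask),
      mean_f1 = result$best$mean_f1,
      subset_size = result$best$subset_size
    ),
    file.path(outdir, "best_config.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(result$best$confusion)) {
    write.csv(result$best$confusion$matrix,
              file.path(outdir, "confusion_matrix.csv"))
    write.csv(result$best$confusion$per_class,
              file.path(outdir, "per_class_metrics.csv"), row.names = FALSE)
    write.csv(result$best$confusion$overall,
              file.path(outdir, "overall_metrics.csv"), row.names = FALSE)
  }
  for (r in seq_along(result$runs)) {
    write.csv(result$runs[[r]]$history,
              file.path(outdir, sprintf("history_rep%02d.csv", r)),
              row.names = FALSE)
  }
  invisible(outdir)
}
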