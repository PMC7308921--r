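#' Train a self-organizing map on beat waveforms
#'
#' Online Kohonen learning on a `grid_k` x `grid_k` rectangular grid:
#' competition by minimal Euclidean distance, Gaussian neighborhood
#' cooperation, and adaptation `w <- w + alpha * h * (x - w)`. The
#' neighborhood radius decays linearly from `grid_k / 2` to 1 and the
#' learning rate from 0.5 to 0.01 over the epochs; weights are initialized
#' from randomly drawn training instances. Fully deterministic under a fixed
#' seed.
#'
#' @param instances Numeric matrix (instances in rows) or a beat tibble with
#'   a `beat` list column.
#' @param grid_k Grid side, between 2 and 10 (`grid_k^2` neurons).
#' @param seed Integer seed.
#' @param epochs Training epochs (default 100).
#' @param alpha Learning-rate schedule `c(start, end)`.
#' @param radius Neighborhood-radius schedule `c(start, end)`; defaults to
#'   `c(grid_k / 2, 1)`.
#' @return An object of class `som_model`: list with `weights`
#'   (`grid_k^2` x dim matrix, the cluster centers), `grid` (neuron grid
#'   coordinates), `grid_k`, `seed`, `qe` (mean quantization error per
#'   epoch) and `training_params`.
#' @export
train_som <- function(instances, grid_k, seed, epochs = 100,
                      alpha = c(0.5, 0.01), radius = NULL) {
  X <- as_instance_matrix(instances)
  if (nrow(X) < 1) abort("At least one instance is required.")
  assert_scalar_number(grid_k, "grid_k")
  if (grid_k < 2 || grid_k > 10) abort("`grid_k` must be between 2 and 10.")
  grid_k <- as.integer(grid_k)
  radius <- radius %||% c(grid_k / 2, 1)
  k2 <- grid_k^2
  d <- ncol(X)
  n <- nrow(X)
  grid <- as.matrix(expand.grid(row = seq_len(grid_k), col = seq_len(grid_k)))
  # squared grid distances between all neuron pairs, reused every update
  gd2 <- as.matrix(stats::dist(grid))^2
  with_seed(as.integer(seed), {
    W0 <- X[sample.int(n, k2, replace = n < k2), , drop = FALSE]
    ord <- t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n)))
    fit <- som_train_cpp(
      t(X), t(W0), gd2, ord,
      alpha[1], alpha[2], radius[1], radius[2]
    )
    structure(
      list(
        weights = t(fit$weights), grid = grid, grid_k = grid_k,
        seed = as.integer(seed), qe = fit$qe,
        training_params = list(epochs = epochs, alpha = alpha, radius = radius)
      ),
      class = "som_model"
    )
  })
}

as_instance_matrix <- function(instances) {
  if (is.data.frame(instances) && "beat" %in% names(instances)) {
    do.call(rbind, instances$beat)
  } else if (is.matrix(instances)) {
    instances
  } else {
    abort("`instances` must be a matrix or a beat tibble with a `beat` column.")
  }
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "<som_model> %dx%d grid (%d neurons), input dim %d, final QE %.4g\n",
    x$grid_k, x$grid_k, nrow(x$weights), ncol(x$weights), x$qe[length(x$qe)]
  ))
  invisible(x)
}

#' Assign instances to SOM clusters and rank by distance to center
#'
#' Each instance joins the cluster of its best-matching neuron (the neuron
#' weight vector is the cluster center); within each cluster, instances are
#' sorted by ascending Euclidean distance to the center, so the farthest —
#' "noisy" — instances come last. Ties keep original instance order.
#'
#' @param som A trained [train_som()] model.
#' @param instances Matrix or beat tibble of the same dimension the SOM was
#'   trained on.
#' @return A tibble of class `ranked_clusters` with columns `neuron`,
#'   `instance` (row index into `instances`), `distance` and `rank`
#'   (ascending within neuron).
#' @export
assign_and_rank <- function(som, instances) {
  stopifnot(inherits(som, "som_model"))
  X <- as_instance_matrix(instances)
  if (ncol(X) != ncol(som$weights)) {
    abort(sprintf(
      "Instance dimension %d does not match SOM dimension %d.",
      ncol(X), ncol(som$weights)
    ))
  }
  W <- som$weights
  D <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * X %*% t(W)
  bmu <- max.col(-D, ties.method = "first")
  dist <- sqrt(pmax(D[cbind(seq_len(nrow(X)), bmu)], 0))
  out <- tibble(neuron = bmu, instance = seq_len(nrow(X)), distance = dist) |>
    arrange(.data$neuron, .data$distance, .data$instance) |>
    group_by(.data$neuron) |>
    mutate(rank = row_number()) |>
    ungroup()
  class(out) <- c("ranked_clusters", class(out))
  out
}

#' Select the closest fraction of each cluster
#'
#' The undersampling primitive: from every non-empty cluster, keeps the
#' `max(1, round(fraction * cluster_size))` instances closest to the cluster
#' center (round half away from zero), and returns the union. Selection is
#' monotone in `fraction`.
#'
#' @param ranked A [assign_and_rank()] result.
#' @param fraction Fraction in (0, 0.999].
#' @return Integer vector of selected instance indices (sorted).
#' @export
select_instances <- function(ranked, fraction) {
  assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 0.999) {
    abort("`fraction` must be in (0, 0.999].")
  }
  # per-cluster head of size max(1, round_half_away(fraction * n_j))
  out <- ranked |>
    group_by(.data$neuron) |>
    filter(row_number() <= max(1, round_half_away(fraction * n()))) |>
    ungroup()
  sort(out$instance)
}

#' Lazily trained cache of per-class SOM rankings
#'
#' The optimization objective needs the ranked clusters of every majority
#' class for whichever grid size a candidate solution requests. Clustering
#' is independent of the candidate, so each (class, grid size) pair is
#' trained at most once and cached; seeds are derived from the master seed
#' and the pair's tag.
#'
#' @param beats Beat tibble (list column `beat`, factor `label`).
#' @param classes Classes to cluster (default the majority classes).
#' @param seed Master seed.
#' @param epochs SOM training epochs (default 100).
#' @return An object of class `som_cache`; query it with [cache_ranking()].
#' @export
som_cache <- function(beats, classes = majority_classes(), seed, epochs = 100) {
  store <- new.env(parent = emptyenv())
  idx <- lapply(stats::setNames(nm = classes), function(cls) {
    which(as.character(beats$label) == cls)
  })
  structure(
    list(
      store = store, beats = beats, index = idx, classes = classes,
      seed = as.integer(seed), epochs = epochs
    ),
    class = "som_cache"
  )
}

#' Ranked clusters for one class at one grid size
#'
#' @param cache A [som_cache()].
#' @param class One of the cache's classes.
#' @param grid_k SOM grid side (2-10).
#' @return A list with `ranking` (a `ranked_clusters` tibble whose `instance`
#'   column indexes rows of the full beat tibble) and `som`.
#' @export
cache_ranking <- function(cache, class, grid_k) {
  stopifnot(inherits(cache, "som_cache"))
  if (!class %in% cache$classes) abort(sprintf("Class %s is not cached.", class))
  key <- sprintf("%s_k%d", class, as.integer(grid_k))
  if (!is.null(cache$store[[key]])) return(cache$store[[key]])
  rows <- cache$index[[class]]
  X <- do.call(rbind, cache$beats$beat[rows])
  som <- train_som(
    X, grid_k,
    seed = derive_seed(cache$seed, paste0("som_", key)),
    epochs = cache$epochs
  )
  ranking <- assign_and_rank(som, X)
  ranking$instance <- rows[ranking$instance]
  cache$store[[key]] <- list(ranking = ranking, som = som)
  cache$store[[key]]
}
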