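#' Round half away from zero
#'
#' Deterministic rounding used wherever the representation vector requires an
#' integer slot: 0.5 always moves away from zero, unlike [base::round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible child seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (SOM training, fold shuffling, network initialization, optimizer
#' draws) get their own streams by mixing the master seed with a short tag.
#' The result always fits in a 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the consumer stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(paste0(tag, ":", format(seed, scientific = FALSE)))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Seed derived from the numeric content of a vector, so that re-evaluating the
# same candidate solution is deterministic regardless of when it is visited.
vector_seed <- function(seed, x) {
  h <- as.integer(seed) %% 2147483647
  for (v in signif(x, 12)) {
    k <- abs(v) * 1e6
    h <- (h * 31 + (floor(k) %% 97911)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
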