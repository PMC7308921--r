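# Shared fixture builders; everything is generated in code, nothing on disk.

no_noise <- function() noise_config(0, 0, 0)

# Small clean beat set covering two majority and one minority class.
tiny_beats <- function(counts = c(N = 30, V = 25, E = 8), noise = no_noise(),
                       seed = 101) {
  generate_beats(counts, noise, seed = seed)
}

beat_matrix <- function(beats) do.call(rbind, beats$beat)

# 5-dimensional sphere surrogate: maximum 0 at the origin.
sphere_bounds <- function(d = 5) {
  tibble::tibble(
    slot = seq_len(d), name = paste0("x", seq_len(d)),
    lower = rep(-5, d), upper = rep(5, d), integer = rep(FALSE, d)
  )
}

neg_sphere <- function(x) -sum(x^2)

# Counting wrapper to audit objective-call budgets.
counting <- function(f) {
  calls <- 0L
  structure(function(x) {
    calls <<- calls + 1L
    f(x)
  }, env = environment())
}

calls_of <- function(f) environment(f)$calls
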