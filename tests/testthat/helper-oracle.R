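# Brute-force DTW oracle: exhaustively enumerates every admissible
# monotone-continuous boundary path over a local-cost matrix and returns the
# minimum path sum. Independent of the package's dynamic program (which it
# gates); only feasible for small M, N.
oracle_min_cost <- function(cost, window = Inf) {
  M <- nrow(cost)
  N <- ncol(cost)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (abs(i - j) > window) return(invisible())
    acc <- acc + cost[i, j]
    if (acc >= best) return(invisible())  # bound only; never skips optima
    if (i == M && j == N) {
      best <<- acc
      return(invisible())
    }
    if (i < M) recurse(i + 1L, j, acc)
    if (j < N) recurse(i, j + 1L, acc)
    if (i < M && j < N) recurse(i + 1L, j + 1L, acc)
  }
  recurse(1L, 1L, 0)
  best
}

# Random DTW test instance under a fixed seed: sequences plus a mixed-weight
# configuration (normalization off so the oracle sees the same sequences).
random_dtw_instance <- function(seed, max_len = 6L) {
  withr::with_seed(seed, {
    M <- sample(3:max_len, 1)  # >= 3 so derivative terms are defined
    N <- sample(3:max_len, 1)
    cfg <- dtw_config(
      alpha = sample(c(0, 0.5, 1), 1),
      beta = sample(c(0.5, 1, 2), 1),
      gamma = sample(c(0, 1), 1),
      eta = sample(c(0, 0.25), 1),
      window_fraction = NULL,
      normalize_inputs = FALSE
    )
    list(X = rnorm(M), Y = rnorm(N), config = cfg)
  })
}
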