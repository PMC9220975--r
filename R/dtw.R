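#' DTW configuration
#'
#' Weights of the hybrid local cost and the path constraints. The per-step
#' cost between `X[i]` and `Y[j]` is
#' `sqrt(alpha (i-j)^2 + beta (x_i-y_j)^2 + gamma (x'_i-y'_j)^2 + eta (x''_i-y''_j)^2)`;
#' with `alpha = gamma = eta = 0`, `beta = 1` it reduces to the classic
#' absolute value difference. Derivatives inside the alignment are per
#' sample, taken after optional per-sequence z-scoring, so the four terms
#' are commensurate and the weights are dimensionless.
#'
#' @param alpha weight of the index-shift term (default 0: R-peak anchoring
#'   already removes gross shift before projection).
#' @param beta weight of the value-difference term.
#' @param gamma weight of the slope-difference term.
#' @param eta weight of the concavity-difference term.
#' @param window_fraction Sakoe-Chiba half-width as a fraction of
#'   `max(M, N)`, or `NULL` for an unconstrained path.
#' @param step_pattern only `"SYMMETRIC1"` (steps (1,0), (0,1), (1,1)).
#' @param normalize_inputs z-score each sequence before costing? Default
#'   `TRUE`, absorbing amplitude drift between beats.
#' @return An object of class `scg_dtw_config`.
#' @export
dtw_config <- function(alpha = 0, beta = 1, gamma = 1, eta = 0.25,
                       window_fraction = 0.1, step_pattern = "SYMMETRIC1",
                       normalize_inputs = TRUE) {
  weights <- c(alpha = alpha, beta = beta, gamma = gamma, eta = eta)
  if (any(weights < 0) || !all(is.finite(weights))) {
    scg_abort("all DTW weights must be finite and >= 0", "scg_parameter_error")
  }
  if (sum(weights) <= 0) {
    scg_abort("at least one DTW weight must be positive", "scg_parameter_error")
  }
  if (!is.null(window_fraction) &&
      (window_fraction <= 0 || window_fraction > 1)) {
    scg_abort("window_fraction must be in (0, 1] or NULL", "scg_parameter_error")
  }
  step_pattern <- match.arg(step_pattern, "SYMMETRIC1")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, eta = eta,
         window_fraction = window_fraction, step_pattern = step_pattern,
         normalize_inputs = isTRUE(normalize_inputs)),
    class = "scg_dtw_config"
  )
}

#' First and second derivative of a sampled series
#'
#' Central differences in the interior, one-sided differences at the two
#' edges. Units are value per second and value per second squared.
#'
#' @param x numeric vector, length >= 3.
#' @param sampling_rate Hz; use 1 for per-sample differences.
#' @return A list with elements `d1` and `d2`, each `length(x)` long.
#' @export
derivative_series <- function(x, sampling_rate = 1) {
  n <- length(x)
  if (n < 3L) {
    scg_abort("derivative_series needs at least 3 samples", "scg_parameter_error")
  }
  dt <- 1 / sampling_rate
  d1 <- numeric(n)
  d1[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d1[1] <- (x[2] - x[1]) / dt
  d1[n] <- (x[n] - x[n - 1]) / dt
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d2[1] <- (x[3] - 2 * x[2] + x[1]) / dt^2
  d2[n] <- (x[n] - 2 * x[n - 1] + x[n - 2]) / dt^2
  list(d1 = d1, d2 = d2)
}

#' Hybrid local cost between two sequence elements
#'
#' @param X,Y numeric sequences (length >= 3 when `gamma` or `eta` is
#'   nonzero, so derivatives exist).
#' @param i,j 1-based indices into `X` and `Y`.
#' @param config an [dtw_config()]; `normalize_inputs` is ignored here (the
#'   sequences are costed as given).
#' @return a non-negative scalar.
#' @export
local_cost <- function(X, Y, i, j, config = dtw_config()) {
  if (i < 1 || i > length(X) || j < 1 || j > length(Y)) {
    scg_abort("local_cost index out of range", "scg_parameter_error")
  }
  acc <- config$alpha * (i - j)^2 + config$beta * (X[i] - Y[j])^2
  if (config$gamma > 0 || config$eta > 0) {
    dx <- derivative_series(X)
    dy <- derivative_series(Y)
    acc <- acc + config$gamma * (dx$d1[i] - dy$d1[j])^2 +
      config$eta * (dx$d2[i] - dy$d2[j])^2
  }
  sqrt(acc)
}

# Full M x N local-cost matrix, vectorized. Sequences are costed as given;
# callers handle normalization.
local_cost_matrix <- function(X, Y, config) {
  M <- length(X)
  N <- length(Y)
  acc <- matrix(0, M, N)
  if (config$alpha > 0) {
    acc <- acc + config$alpha * outer(seq_len(M), seq_len(N), `-`)^2
  }
  if (config$beta > 0) {
    acc <- acc + config$beta * outer(X, Y, `-`)^2
  }
  if (config$gamma > 0 || config$eta > 0) {
    dx <- derivative_series(X)
    dy <- derivative_series(Y)
    if (config$gamma > 0) {
      acc <- acc + config$gamma * outer(dx$d1, dy$d1, `-`)^2
    }
    if (config$eta > 0) {
      acc <- acc + config$eta * outer(dx$d2, dy$d2, `-`)^2
    }
  }
  sqrt(acc)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) x - mean(x) else (x - mean(x)) / s
}

#' Align two sequences by dynamic time warping
#'
#' Computes the warping path from `(1, 1)` to `(M, N)` under monotonicity,
#' continuity, boundary and (optionally) Sakoe-Chiba window constraints,
#' minimizing the path sum of the hybrid local cost; `total_cost` is the
#' mean per-step cost along that path. Backtracking tie-break is
#' deterministic: diagonal first, then the step advancing the `X` index.
#'
#' @param X,Y numeric vectors (length >= 2) or [signal_clip()] objects.
#' @param config an [dtw_config()].
#' @return An object of class `scg_warp_path`: `pairs` (K x 2 matrix of
#'   1-based index pairs), `K`, `total_cost` (mean per-step), `cost_sum`,
#'   `M`, `N`.
#' @export
dtw_align <- function(X, Y, config = dtw_config()) {
  if (inherits(X, "scg_clip")) X <- X$samples
  if (inherits(Y, "scg_clip")) Y <- Y$samples
  X <- as.numeric(X)
  Y <- as.numeric(Y)
  M <- length(X)
  N <- length(Y)
  if (M < 2L || N < 2L) {
    scg_abort("dtw_align needs sequences of length >= 2", "scg_parameter_error")
  }
  if (config$normalize_inputs) {
    X <- zscore(X)
    Y <- zscore(Y)
  }
  window <- Inf
  if (!is.null(config$window_fraction)) {
    window <- ceiling(config$window_fraction * max(M, N))
    if (window < abs(M - N)) {
      scg_abort(sprintf(
        "Sakoe-Chiba window (%d samples) narrower than the length difference |M-N| = %d",
        as.integer(window), abs(M - N)), "scg_infeasible_error")
    }
  }
  cost <- local_cost_matrix(X, Y, config)
  res <- dtw_dp(cost, window)
  if (!isTRUE(res$feasible)) {
    scg_abort("no admissible warping path under the configured window",
              "scg_infeasible_error")
  }
  K <- length(res$a)
  structure(
    list(pairs = cbind(a = res$a, b = res$b), K = K,
         total_cost = res$cost_sum / K, cost_sum = res$cost_sum,
         M = M, N = N),
    class = "scg_warp_path"
  )
}

#' Check the warping-path invariants
#'
#' Boundary (`(1,1)` to `(M,N)`), monotonicity, continuity (each step
#' advances at least one index, by at most 1 each), and the length bound
#' `max(M,N) <= K <= M + N - 1`.
#'
#' @param path an `scg_warp_path`.
#' @return `TRUE` if every invariant holds, else `FALSE`.
#' @export
validate_warp_path <- function(path) {
  p <- path$pairs
  K <- nrow(p)
  if (K != path$K) return(FALSE)
  if (p[1, 1] != 1 || p[1, 2] != 1) return(FALSE)
  if (p[K, 1] != path$M || p[K, 2] != path$N) return(FALSE)
  if (K > 1) {
    da <- diff(p[, 1])
    db <- diff(p[, 2])
    if (any(da < 0 | db < 0)) return(FALSE)           # monotone
    if (any(da > 1 | db > 1)) return(FALSE)           # continuous
    if (any(da + db < 1)) return(FALSE)               # every step advances
  }
  K >= max(path$M, path$N) && K <= path$M + path$N - 1
}

#' @export
print.scg_warp_path <- function(x, ...) {
  cat(sprintf("<scg_warp_path> %d x %d, K = %d, mean cost %.6g\n",
              x$M, x$N, x$K, x$total_cost))
  invisible(x)
}
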