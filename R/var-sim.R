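# Vector-autoregressive (VAR) process specification and simulation.
#
# The VAR is the generative counterpart of the Granger-causality estimand:
# x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t,  e_t ~ N(0, diag(noise_sd^2)).

#' Specify a stationary VAR process
#'
#' @param coeffs A single channel-by-channel coefficient matrix (lag order 1)
#'   or a list of such matrices, one per lag. Entry `[i, j]` is the influence
#'   of channel j at the given lag on channel i at the current time point.
#' @param noise_sd Innovation standard deviation, recycled to one value per
#'   channel.
#' @param labels Optional channel labels; defaults to the 14 canonical
#'   resting-state network symbols when the channel count is 14, otherwise
#'   `ch1..chn`.
#' @param seed Integer seed making simulation from this spec deterministic.
#'
#' @return An object of class `var_spec` with fields `coeffs` (list of lag
#'   matrices), `n_channels`, `order`, `noise_sd`, `labels`, `seed`.
#'
#' @details The process must be stable: the spectral radius of the companion
#'   matrix has to be strictly below 1, otherwise the spec is rejected with
#'   the offending radius reported.
#' @export
var_spec <- function(coeffs, noise_sd = 1, labels = NULL, seed = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || !length(coeffs)) {
    stopf("coeffs must be a coefficient matrix or a non-empty list of them")
  }
  n <- nrow(coeffs[[1]])
  for (A in coeffs) {
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n || !all(is.finite(A))) {
      stopf("every lag matrix must be a finite %d x %d matrix", n, n)
    }
  }
  if (n < 2) stopf("a VAR spec needs at least 2 channels, got %d", n)
  noise_sd <- rep_len(noise_sd, n)
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stopf("noise_sd must be positive and finite")
  }
  if (is.null(labels)) {
    labels <- if (n == 14) rsn_symbols() else paste0("ch", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    stopf("labels must be %d unique channel names", n)
  }
  spec <- structure(
    list(coeffs = coeffs, n_channels = n, order = length(coeffs),
         noise_sd = noise_sd, labels = labels, seed = seed),
    class = "var_spec"
  )
  rho <- spectral_radius(spec)
  if (rho >= 1) {
    stopf("VAR spec is not stationary: companion spectral radius %.4f >= 1", rho)
  }
  spec
}

#' Companion matrix of a VAR spec
#'
#' Stacks the lag matrices into the (n*p) x (n*p) companion form whose
#' eigenvalues determine stability.
#' @param spec A `var_spec`.
#' @return The companion matrix.
#' @export
companion_matrix <- function(spec) {
  n <- spec$n_channels
  p <- spec$order
  C <- matrix(0, n * p, n * p)
  C[seq_len(n), ] <- do.call(cbind, spec$coeffs)
  if (p > 1) {
    C[cbind(n + seq_len(n * (p - 1)), seq_len(n * (p - 1)))] <- 1
  }
  C
}

#' Spectral radius of a VAR companion matrix
#' @param spec A `var_spec`.
#' @return Largest eigenvalue modulus; < 1 means the process is stationary.
#' @export
spectral_radius <- function(spec) {
  max(Mod(eigen(companion_matrix(spec), only.values = TRUE)$values))
}

#' Simulate a VAR process
#'
#' Draws a single realization of the stationary VAR defined by `spec`,
#' discarding an initial burn-in so the emitted segment is (approximately)
#' a draw from the stationary distribution.
#'
#' @param spec A `var_spec`.
#' @param n_timepoints Number of time points to return.
#' @param burn_in Number of initial samples to discard (default 200).
#' @param seed Optional seed overriding `spec$seed`.
#' @return A `n_channels x n_timepoints` matrix with channel labels as row
#'   names. Deterministic given (spec, seed).
#' @export
#' @examples
#' sp <- var_spec(matrix(c(0, 0.5, 0, 0), 2, 2), seed = 1)
#' x <- simulate_var(sp, 100)
#' dim(x)
simulate_var <- function(spec, n_timepoints, burn_in = 200L, seed = NULL) {
  stopifnot(inherits(spec, "var_spec"))
  if (!is_count(n_timepoints)) stopf("n_timepoints must be a positive count")
  if (!is_count(burn_in, min = 0L)) stopf("burn_in must be a non-negative count")
  rho <- spectral_radius(spec)
  if (rho >= 1) {
    stopf("VAR spec is not stationary: companion spectral radius %.4f >= 1", rho)
  }
  if (is.null(seed)) seed <- spec$seed
  n <- spec$n_channels
  p <- spec$order
  total <- n_timepoints + burn_in
  with_seed(seed, {
    e <- matrix(stats::rnorm(n * (total + p), sd = spec$noise_sd), nrow = n)
    x <- matrix(0, n, total + p)
    for (t in (p + 1):(total + p)) {
      acc <- e[, t]
      for (l in seq_len(p)) acc <- acc + spec$coeffs[[l]] %*% x[, t - l]
      x[, t] <- acc
    }
    out <- x[, (p + burn_in + 1):(p + total), drop = FALSE]
    rownames(out) <- spec$labels
    out
  })
}
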