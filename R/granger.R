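# Pairwise (and conditional) Granger causality between multichannel time
# series that have been temporally concatenated across subjects.
#
# All F statistics are computed from the Gram matrix of the lagged design
# [1, X_lags, Y]. Because lag windows never cross subject boundaries, the
# group Gram matrix is the sum of per-subject Gram matrices, which makes
# group-label permutation tests cheap: each permutation only re-sums
# per-subject sufficient statistics.

#' Build the lagged regression design for a concatenated series
#'
#' Response rows are time points t with a complete p-lag history inside the
#' same subject segment; rows whose window crosses a subject boundary or
#' touches a censored time point are dropped.
#'
#' @param series channels x time matrix (possibly several subjects
#'   concatenated along time).
#' @param order VAR lag order p >= 1.
#' @param boundaries Integer vector of 1-based start columns of each subject
#'   segment (default `1`, a single subject).
#' @param censor_mask Optional logical vector flagging censored time points.
#' @return List with `Y` (rows x channels responses), `X` (rows x
#'   (channels*p) lag regressors, lag-1 block first), `rows` (response time
#'   indices), `n_obs`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 2)
#' d <- build_lagged_design(x, order = 2)
#' nrow(d$Y)  # 18
build_lagged_design <- function(series, order, boundaries = 1L,
                                censor_mask = NULL) {
  stopifnot(is.matrix(series))
  if (!is_count(order)) stopf("order must be a positive count")
  T_ <- ncol(series)
  n <- nrow(series)
  boundaries <- sort(unique(as.integer(boundaries)))
  if (boundaries[1] != 1L || any(boundaries > T_)) {
    stopf("boundaries must start at 1 and lie within the series")
  }
  seg_start <- boundaries
  seg_end <- c(boundaries[-1] - 1L, T_)
  if (any(seg_end - seg_start + 1L <= order)) {
    stopf("every subject segment must be longer than the lag order (%d)", order)
  }
  if (is.null(censor_mask)) censor_mask <- rep(FALSE, T_)
  if (length(censor_mask) != T_) stopf("censor mask misaligned")
  rows <- integer(0)
  for (k in seq_along(seg_start)) {
    cand <- (seg_start[k] + order):seg_end[k]
    ok <- vapply(cand, function(t) !any(censor_mask[(t - order):t]), TRUE)
    rows <- c(rows, cand[ok])
  }
  if (!length(rows)) stopf("no valid regression rows remain")
  Y <- t(series[, rows, drop = FALSE])
  X <- do.call(cbind, lapply(seq_len(order), function(l) {
    t(series[, rows - l, drop = FALSE])
  }))
  colnames(X) <- paste0(rep(rownames(series) %||% paste0("ch", 1:n), order),
                        ".l", rep(seq_len(order), each = n))
  list(Y = Y, X = X, rows = rows, n_obs = length(rows),
       order = order, n_channels = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gram (cross-product) summary of a lagged design
#'
#' Cross-product matrix of `[1, X, Y]`; sufficient for every restricted and
#' unrestricted OLS fit the Granger F statistics need.
#' @noRd
design_gram <- function(design) {
  Z <- cbind(1, design$X, design$Y)
  list(G = crossprod(Z), n_obs = design$n_obs,
       order = design$order, n_channels = design$n_channels)
}

#' Sum Gram summaries across subjects
#' @noRd
sum_grams <- function(grams) {
  G <- Reduce(`+`, lapply(grams, `[[`, "G"))
  list(G = G, n_obs = sum(vapply(grams, `[[`, 0L, "n_obs")),
       order = grams[[1]]$order, n_channels = grams[[1]]$n_channels)
}

# Residual sum of squares of y ~ Z[, cols] from a Gram matrix.
# G indexes: 1 = intercept, 1 + (1:(n*p)) = lags, 1 + n*p + (1:n) = responses.
rss_from_gram <- function(G, cols, ycol) {
  Sxx <- G[cols, cols, drop = FALSE]
  Sxy <- G[cols, ycol]
  b <- tryCatch(solve(Sxx, Sxy), error = function(e) {
    qr.solve(Sxx, Sxy, tol = 1e-12)
  })
  G[ycol, ycol] - sum(b * Sxy)
}

#' Fit an equation-wise VAR by ordinary least squares
#'
#' @param design Output of [build_lagged_design()].
#' @return List with `coefficients` ((1 + channels*p) x channels, intercept
#'   first), `rss` (per-equation residual sum of squares), `sigma`
#'   (residual covariance), `n_obs`.
#' @export
fit_var <- function(design) {
  Z <- cbind(`(Intercept)` = 1, design$X)
  if (nrow(Z) <= ncol(Z)) {
    stopf("need more rows (%d) than regressors (%d)", nrow(Z), ncol(Z))
  }
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    stopf("singular lagged design (rank %d < %d regressors); condition number %.3g",
          qrZ$rank, ncol(Z), kappa(crossprod(Z)))
  }
  coef <- qr.coef(qrZ, design$Y)
  resid <- qr.resid(qrZ, design$Y)
  rss <- colSums(resid^2)
  list(coefficients = coef, rss = rss,
       sigma = crossprod(resid) / design$n_obs,
       residuals = resid, n_obs = design$n_obs)
}

#' Select the VAR lag order by an information criterion
#'
#' Fits the full model at every candidate order on the row set valid at
#' `max_p` (so all candidates see identical data) and returns the arg-min of
#' the criterion computed from the residual covariance determinant.
#'
#' @param series channels x time matrix.
#' @param max_p Largest candidate order (default 5).
#' @param boundaries,censor_mask As in [build_lagged_design()].
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return The selected order (integer).
#' @export
select_order <- function(series, max_p = 5L, boundaries = 1L,
                         censor_mask = NULL, criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  if (!is_count(max_p)) stopf("max_p must be a positive count")
  design <- build_lagged_design(series, max_p, boundaries, censor_mask)
  n <- design$n_channels
  N <- design$n_obs
  ic <- vapply(seq_len(max_p), function(p) {
    sub <- design
    sub$X <- design$X[, seq_len(n * p), drop = FALSE]
    fit <- fit_var(sub)
    k <- p * n^2  # penalized parameters per the standard VAR criterion
    ld <- determinant(fit$sigma, logarithm = TRUE)$modulus
    pen <- if (criterion == "bic") log(N) / N else 2 / N
    as.numeric(ld) + pen * k
  }, 0)
  which.min(ic)
}

# Column indices (into the Gram) of the lag block of channel j
lag_cols <- function(j, n, p) 1L + (seq_len(p) - 1L) * n + j

#' Granger F statistic between all ordered channel pairs
#'
#' For each ordered pair (i, j), compares the restricted model of channel j
#' (its own lags only, for pairwise conditioning; all channels except i for
#' conditional) against the unrestricted model adding i's lags:
#' `F = ((RSS_r - RSS_u) / p) / (RSS_u / (n_obs - k_u))` with `k_u` the
#' unrestricted regressor count including the intercept. Negative values
#' arising from round-off are clipped to zero.
#'
#' @param series channels x time matrix (concatenated group series).
#' @param order VAR lag order p.
#' @param boundaries,censor_mask As in [build_lagged_design()].
#' @param conditioning `"pairwise"` (default; bivariate models) or
#'   `"conditional"` (all other channels included in both models).
#' @return An object of class `gc_matrix`: list with `f` (n x n F matrix,
#'   `NA` diagonal, entry `[i, j]` = evidence that channel i Granger-causes
#'   channel j), `order`, `dof`, `n_obs`, `conditioning`, `labels`.
#' @export
#' @examples
#' sp <- var_spec(matrix(c(0.3, 0.4, 0, 0.3), 2, 2), seed = 2)
#' x <- simulate_var(sp, 500)
#' gc_matrix(x, order = 1)$f
gc_matrix <- function(series, order, boundaries = 1L, censor_mask = NULL,
                      conditioning = c("pairwise", "conditional")) {
  conditioning <- match.arg(conditioning)
  design <- build_lagged_design(series, order, boundaries, censor_mask)
  gram <- design_gram(design)
  gc_from_gram(gram, conditioning = conditioning,
               labels = rownames(series))
}

#' Granger F statistics from a Gram summary
#' @noRd
gc_from_gram <- function(gram, conditioning = "pairwise", labels = NULL) {
  G <- gram$G
  n <- gram$n_channels
  p <- gram$order
  N <- gram$n_obs
  resp0 <- 1L + n * p
  if (conditioning == "pairwise" && p == 1L) {
    return(gc_pairwise_lag1(G, n, N, labels))
  }
  f <- matrix(NA_real_, n, n)
  clipped <- 0L
  if (conditioning == "pairwise") {
    k_u <- 1L + 2L * p
  } else {
    k_u <- 1L + n * p
  }
  if (N <= k_u) stopf("too few rows (%d) for %d regressors", N, k_u)
  all_lags <- 1L + seq_len(n * p)
  for (j in seq_len(n)) {
    ycol <- resp0 + j
    for (i in seq_len(n)) {
      if (i == j) next
      if (conditioning == "pairwise") {
        cols_r <- c(1L, lag_cols(j, n, p))
        cols_u <- c(cols_r, lag_cols(i, n, p))
      } else {
        cols_u <- c(1L, all_lags)
        cols_r <- setdiff(cols_u, lag_cols(i, n, p))
      }
      rss_u <- rss_from_gram(G, cols_u, ycol)
      rss_r <- rss_from_gram(G, cols_r, ycol)
      fij <- ((rss_r - rss_u) / p) / (rss_u / (N - k_u))
      if (is.na(fij)) fij <- 0
      if (fij < 0) {
        clipped <- clipped + 1L
        fij <- 0
      }
      f[i, j] <- fij
    }
  }
  if (clipped > 0L) {
    warnf("%d F statistic(s) clipped at 0 (RSS_r < RSS_u by round-off)", clipped)
  }
  if (!is.null(labels)) dimnames(f) <- list(labels, labels)
  structure(
    list(f = f, order = p, dof = c(p, N - k_u), n_obs = N,
         conditioning = conditioning, labels = labels),
    class = "gc_matrix"
  )
}

# Closed-form vectorized pairwise GC for lag order 1. Works on the
# intercept-augmented Gram by centering the cross-products, then applies
# the two-regressor OLS solution in closed form for every ordered pair at
# once. Algebraically identical to the generic subset-solve path (the
# oracle-equivalence tests exercise both).
gc_pairwise_lag1 <- function(G, n, N, labels = NULL) {
  k_u <- 3L
  if (N <= k_u) stopf("too few rows (%d) for %d regressors", N, k_u)
  idx_x <- 1L + seq_len(n)
  idx_y <- 1L + n + seq_len(n)
  sums <- G[1L, -1L]
  C <- G[-1L, -1L] - tcrossprod(sums) / N  # centered cross-products
  Sxx <- C[seq_len(n), seq_len(n)]
  Sxy <- C[seq_len(n), n + seq_len(n)]
  Syy <- diag(C[n + seq_len(n), n + seq_len(n)])
  dxx <- diag(Sxx)
  # restricted: y_j ~ own lag;  RSS_r[j] broadcast over sources
  rss_r <- Syy - diag(Sxy)^2 / dxx
  # unrestricted: y_j ~ own lag + source i lag, 2x2 normal equations
  a <- matrix(dxx[col(Sxx)], n, n)        # Sxx[j,j] by target column j
  b <- t(Sxx)                              # [i,j] -> Sxx[j,i]
  d <- matrix(dxx[row(Sxx)], n, n)        # Sxx[i,i]
  u <- matrix(diag(Sxy)[col(Sxy)], n, n)  # Sxy[j,j]
  v <- Sxy                                 # [i,j] -> Sxy[i,j]
  det <- a * d - b^2
  quad <- (d * u^2 - 2 * b * u * v + a * v^2) / det
  rss_u <- matrix(Syy[col(Sxy)], n, n) - quad
  f <- (matrix(rss_r[col(Sxy)], n, n) - rss_u) / (rss_u / (N - k_u))
  f[!is.finite(f) | f < 0] <- 0
  diag(f) <- NA_real_
  if (!is.null(labels)) dimnames(f) <- list(labels, labels)
  structure(
    list(f = f, order = 1L, dof = c(1L, N - k_u), n_obs = N,
         conditioning = "pairwise", labels = labels),
    class = "gc_matrix"
  )
}

#' Granger F statistic for a single ordered pair
#'
#' @inheritParams gc_matrix
#' @param source,target Channel indices or labels; must differ.
#' @return The F statistic (scalar, >= 0).
#' @export
gc_pair <- function(series, source, target, order, boundaries = 1L,
                    censor_mask = NULL,
                    conditioning = c("pairwise", "conditional")) {
  conditioning <- match.arg(conditioning)
  labs <- rownames(series)
  if (is.character(source)) source <- match(source, labs)
  if (is.character(target)) target <- match(target, labs)
  if (is.na(source) || is.na(target)) stopf("unknown channel label")
  if (source == target) stopf("source and target must differ")
  gm <- gc_matrix(series, order, boundaries, censor_mask, conditioning)
  gm$f[source, target]
}

#' Parametric p-values for a GC matrix
#'
#' Upper-tail F-distribution p-values at the matrix's degrees of freedom.
#' @param gc A `gc_matrix`.
#' @return n x n matrix of p-values (`NA` diagonal).
#' @export
gc_pvalues <- function(gc) {
  stopifnot(inherits(gc, "gc_matrix"))
  stats::pf(gc$f, gc$dof[1], gc$dof[2], lower.tail = FALSE)
}

#' Log-transformed view of a GC matrix for display
#'
#' @param gc A `gc_matrix`.
#' @param floor Values below `floor` are reported as `log(floor)`.
#' @return n x n matrix of log F values.
#' @export
gc_log_view <- function(gc, floor = 1e-8) {
  stopifnot(inherits(gc, "gc_matrix"))
  log(pmax(gc$f, floor))
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf(
    "gc_matrix: %d channels, order %d (%s), %d rows, dof (%d, %d)\n",
    nrow(x$f), x$order, x$conditioning, x$n_obs, x$dof[1], x$dof[2]))
  invisible(x)
}

#' Per-subject Gram summaries of a panel
#'
#' Preprocessing for permutation tests: one lagged-design Gram summary per
#' subject, so any regrouping of subjects only needs to re-sum them.
#' @noRd
panel_grams <- function(panel, order, censor_masks = NULL) {
  lapply(panel$subjects, function(s) {
    cm <- censor_masks[[s$id]]
    design_gram(build_lagged_design(s$data, order, censor_mask = cm))
  })
}
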