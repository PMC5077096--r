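# Granger causality: lagged designs, VAR fitting, order selection, and the
# F statistics against naive-regression oracles.

test_that("lagged design row counts follow subject boundaries and lags", {
  set.seed(1)
  x <- matrix(rnorm(2 * 20), 2)
  # 2 subjects x 10 points, p = 2 -> (10 - 2) * 2 = 16 rows
  d <- build_lagged_design(x, 2, boundaries = c(1, 11))
  expect_equal(d$n_obs, 16)
  # 1 subject, p = 1, length T -> T - 1 rows
  d1 <- build_lagged_design(x, 1)
  expect_equal(d1$n_obs, 19)
  # lag windows never cross a subject boundary: the design matrix rows for
  # the second subject start at column 11 + p
  expect_false(any(d$rows %in% c(11, 12)))
  expect_error(build_lagged_design(x, 10, boundaries = c(1, 11)), "longer")
})

test_that("fit_var recovers known coefficients and matches the QR oracle", {
  A <- matrix(c(0.5, 0.2, -0.3, 0.4), 2, 2)
  sp <- var_spec(A, seed = 3)
  x <- simulate_var(sp, 10000)
  d <- build_lagged_design(x, 1)
  fit <- fit_var(d)
  est <- t(fit$coefficients[-1, ])  # drop intercept; transpose to A layout
  expect_lt(max(abs(est - A)), 0.03)
  # RSS equals the projection-residual oracle
  Z <- cbind(1, d$X)
  oracle_rss <- colSums(qr.resid(qr(Z), d$Y)^2)
  expect_equal(fit$rss, oracle_rss, tolerance = 1e-8, ignore_attr = TRUE)
  # white noise: all coefficients within 3 SEs of zero
  sp0 <- var_spec(matrix(0, 2, 2), seed = 4)
  x0 <- simulate_var(sp0, 5000)
  d0 <- build_lagged_design(x0, 1)
  f0 <- fit_var(d0)
  se <- sqrt(diag(solve(crossprod(cbind(1, d0$X)))) %o%
               (f0$rss / (d0$n_obs - 3)))
  expect_true(all(abs(f0$coefficients) < 3.5 * se))
  # duplicated regressors are rejected
  ddup <- d
  ddup$X <- cbind(d$X, d$X[, 1])
  expect_error(fit_var(ddup), "singular")
})

test_that("BIC order selection finds the generating order", {
  hits1 <- 0; hits3 <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    x1 <- simulate_var(var_spec(matrix(c(0.5, 0.3, 0, 0.4), 2, 2)),
                       800, seed = 100 + s)
    hits1 <- hits1 + (select_order(x1, max_p = 4) == 1)
    # strong lag-3 structure
    sp3 <- var_spec(list(matrix(c(0.2, 0, 0, 0.2), 2, 2),
                         matrix(0, 2, 2),
                         matrix(c(0, 0.5, 0.5, 0), 2, 2)))
    x3 <- simulate_var(sp3, 800, seed = 200 + s)
    hits3 <- hits3 + (select_order(x3, max_p = 4) == 3)
  }
  expect_gte(hits1, n_rep - 1)
  expect_gte(hits3, n_rep - 1)
  # white noise picks the smallest candidate
  x0 <- simulate_var(var_spec(matrix(0, 2, 2), seed = 5), 500)
  expect_equal(select_order(x0, max_p = 4), 1L)
})

test_that("gc F statistics match the naive two-regression oracle", {
  set.seed(9)
  for (rep in 1:25) {
    A <- matrix(runif(4, -0.4, 0.4), 2, 2)
    sp <- tryCatch(var_spec(A), error = function(e) NULL)
    if (is.null(sp)) next
    x <- simulate_var(sp, 300, seed = rep)
    for (p in 1:2) {
      gm <- gc_matrix(x, order = p)
      expect_equal(gm$f[1, 2], naive_gc_pair(x, 1, 2, p), tolerance = 1e-8)
      expect_equal(gm$f[2, 1], naive_gc_pair(x, 2, 1, p), tolerance = 1e-8)
    }
  }
})

test_that("planted directed coupling produces one-sided large F", {
  hits_big <- 0; hits_small <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    sp <- var_spec(matrix(c(0.3, 0.5, 0, 0.3), 2, 2))  # ch1 -> ch2
    x <- simulate_var(sp, 2000, seed = 300 + s)
    gm <- gc_matrix(x, order = 1)
    q999 <- qf(0.999, gm$dof[1], gm$dof[2])
    q95 <- qf(0.95, gm$dof[1], gm$dof[2])
    hits_big <- hits_big + (gm$f[1, 2] > q999)
    hits_small <- hits_small + (gm$f[2, 1] < q95)
  }
  expect_equal(hits_big, n_rep)
  expect_gte(hits_small, n_rep - 1)
})

test_that("gc_matrix covers all ordered pairs and respects relabeling", {
  des <- group_design(seed = 1)
  x <- simulate_var(des$base_spec, 400, seed = 17)
  gm <- gc_matrix(x, order = 1)
  expect_equal(sum(!is.na(gm$f)), 14 * 13)
  expect_true(all(gm$f[!is.na(gm$f)] >= 0))
  # permuting channels permutes the matrix consistently
  perm <- sample(14)
  gmp <- gc_matrix(x[perm, ], order = 1)
  expect_equal(gmp$f, gm$f[perm, perm], tolerance = 1e-8)
  # 2 channels -> 2 off-diagonal entries
  gm2 <- gc_matrix(x[1:2, ], order = 1)
  expect_equal(sum(!is.na(gm2$f)), 2)
})

test_that("GC is invariant to per-channel affine rescaling", {
  x <- simulate_var(var_spec(matrix(c(0.3, 0.4, 0.1, 0.2), 2, 2), seed = 6),
                    500)
  gm <- gc_matrix(x, order = 1)
  y <- x * c(7, 0.03) + c(100, -5)
  gmy <- gc_matrix(y, order = 1)
  expect_equal(gmy$f, gm$f, tolerance = 1e-6)
})

test_that("pairwise and conditional variants agree on bivariate systems", {
  x <- simulate_var(var_spec(matrix(c(0.3, 0.4, 0.1, 0.2), 2, 2), seed = 2),
                    400)
  a <- gc_matrix(x, order = 1, conditioning = "pairwise")
  b <- gc_matrix(x, order = 1, conditioning = "conditional")
  expect_equal(a$f, b$f, tolerance = 1e-10)
  # and the generic pairwise path (p = 2) agrees with itself bivariate
  a2 <- gc_matrix(x, order = 2, conditioning = "pairwise")
  b2 <- gc_matrix(x, order = 2, conditioning = "conditional")
  expect_equal(a2$f, b2$f, tolerance = 1e-10)
})

test_that("parametric GC p-values are uniform under independence", {
  ps <- sapply(1:300, function(s) {
    x <- simulate_var(var_spec(matrix(0, 2, 2)), 150, seed = 4000 + s)
    gm <- gc_matrix(x, order = 1)
    gc_pvalues(gm)[1, 2]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("gc_pair resolves labels and validates the pair", {
  x <- simulate_var(var_spec(matrix(c(0.3, 0.5, 0, 0.3), 2, 2),
                             labels = c("RECN", "dDMN"), seed = 1), 500)
  f <- gc_pair(x, "RECN", "dDMN", order = 1)
  expect_equal(f, gc_matrix(x, 1)$f[1, 2])
  expect_error(gc_pair(x, "RECN", "RECN", 1), "differ")
  expect_error(gc_pair(x, "XXX", "dDMN", 1), "unknown")
})
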