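# Conditioning chain: volume dropping, detrending, confound regression,
# band-pass filtering, z-normalization, censoring, concatenation.

test_that("drop_initial_volumes removes exactly k leading points", {
  x <- matrix(seq_len(2 * 150), 2)
  expect_equal(ncol(drop_initial_volumes(x, 4)), 146)
  expect_identical(drop_initial_volumes(x, 0), x)
  expect_error(drop_initial_volumes(x, 150), "cannot drop")
})

test_that("detrending kills ramps, is idempotent, and matches projection", {
  t_ <- 1:200
  ramp <- rbind(3 + 0.5 * t_, -1 - 0.02 * t_)
  expect_lt(max(abs(detrend_linear(ramp))), 1e-10)
  # sine: result equals explicit projection onto {1, t} removed
  x <- matrix(sin(2 * pi * t_ / 40), 1)
  X <- cbind(1, t_)
  oracle <- x - t(X %*% solve(crossprod(X), crossprod(X, t(x))))
  expect_equal(detrend_linear(x), oracle, tolerance = 1e-12)
  # fixed point
  expect_equal(detrend_linear(oracle), oracle, tolerance = 1e-10)
  expect_lt(max(abs(rowMeans(detrend_linear(ramp + x[rep(1, 2), ])))), 1e-10)
})

test_that("confound regression leaves residuals orthogonal to regressors", {
  set.seed(2)
  T_ <- 120
  conf <- matrix(rnorm(T_ * 8), T_, 8,
                 dimnames = list(NULL, c(paste0("mot", 1:6), "wm", "csf")))
  x <- matrix(rnorm(3 * T_), 3)
  r <- regress_confounds(x, conf)
  expect_lt(max(abs(crossprod(t(r), conf))) / max(abs(x)), 1e-8)
  # a channel equal to a confound column is annihilated
  x2 <- rbind(conf[, 3], rnorm(T_))
  r2 <- regress_confounds(x2, conf)
  expect_lt(max(abs(r2[1, ])), 1e-10)
  # QR-projection oracle
  X <- cbind(1, conf)
  oracle <- t(qr.resid(qr(X), t(x)))
  expect_equal(r, oracle, tolerance = 1e-10)
  # collinear columns dropped with a warning, not an error
  expect_warning(regress_confounds(x, cbind(conf, conf[, 1])), "collinear")
})

test_that("band-pass keeps in-band sinusoids and crushes out-of-band ones", {
  tr <- 1  # Nyquist 0.5 Hz so 2x the high edge stays observable
  t_ <- seq_len(4096)
  amp_out <- function(f_in) {
    x <- matrix(sin(2 * pi * f_in * t_ * tr), 1)
    y <- bandpass(x, tr_seconds = tr)
    core <- 500:3500  # ignore filter transients
    max(abs(y[1, core]))
  }
  expect_gt(amp_out(0.05), 0.95)          # mid-band preserved
  expect_lt(amp_out(0.002), 1 / 10)       # below-band reduced >= 10x
  expect_lt(amp_out(0.3), 10^(-20 / 20))  # 2x high edge: >= 20 dB down
  expect_lt(amp_out(0.004), 10^(-20 / 20))  # 0.5x low edge: >= 20 dB down
  # white noise: output periodogram concentrates in the passband
  set.seed(5)
  w <- matrix(rnorm(8192), 1)
  y <- bandpass(w, tr_seconds = tr)
  sp <- spec.pgram(ts(y[1, ], frequency = 1 / tr), plot = FALSE, taper = 0)
  inband <- sp$freq >= 0.008 & sp$freq <= 0.15
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.9)
  deep <- sp$freq < 0.004 | sp$freq > 0.3
  expect_lt(sum(sp$spec[deep]) / sum(sp$spec), 0.01)
  expect_error(bandpass(w, 0.008, 0.3, tr_seconds = 2), "Nyquist")
})

test_that("znormalize standardizes and rejects constant channels", {
  set.seed(3)
  x <- matrix(rnorm(300, mean = 5, sd = 3), 3)
  z <- znormalize(x)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(znormalize(z), z, tolerance = 1e-10)
  xc <- rbind(x, 7)
  rownames(xc) <- c("a", "b", "c", "flat")
  expect_error(znormalize(xc), "flat")
})

test_that("censoring flags points and the lagged design drops their windows", {
  x <- matrix(rnorm(2 * 50), 2)
  cm <- censor_motion(x, rep(FALSE, 50))
  expect_false(any(cm$censor_mask))
  mask <- rep(FALSE, 50); mask[c(10, 20, 30)] <- TRUE
  cm <- censor_motion(x, mask)
  expect_equal(sum(cm$censor_mask), 3)
  expect_identical(cm$series, x)
  expect_error(censor_motion(x, rep(TRUE, 50)), "all time points")
  # one interior censored point at p = 1 removes exactly 2 regression rows
  mask1 <- rep(FALSE, 50); mask1[25] <- TRUE
  d0 <- build_lagged_design(x, 1)
  d1 <- build_lagged_design(x, 1, censor_mask = mask1)
  expect_equal(d0$n_obs - d1$n_obs, 2)
  # a censored block of length L at p = 1 removes L + 1 rows
  maskb <- rep(FALSE, 50); maskb[20:24] <- TRUE
  db <- build_lagged_design(x, 1, censor_mask = maskb)
  expect_equal(d0$n_obs - db$n_obs, 6)
})

test_that("group concatenation preserves order and marks boundaries", {
  panel <- generate_group_dataset(group_design(n_per_group = 2,
                                               n_timepoints = 146, seed = 1))
  g <- concatenate_by_group(panel)
  expect_equal(ncol(g$SDI$data), 292)
  expect_equal(g$SDI$boundaries, c(1L, 147L))
  expect_equal(ncol(g$control$data), 292)
  one <- ts_panel(panel$subjects[c(1, 3)], panel$channel_labels, 2)
  g1 <- concatenate_by_group(one)
  expect_equal(g1$SDI$boundaries, 1L)
  expect_identical(g1$SDI$data, panel$subjects[[1]]$data,
                   ignore_attr = TRUE)
})

test_that("the conditioning chain is recorded and stable under repetition", {
  panel <- generate_group_dataset(group_design(n_per_group = 2,
                                               n_timepoints = 600, seed = 8))
  once <- preprocess_panel(panel)
  expect_equal(once$log,
               c("drop4", "detrend", "bandpass[0.008,0.15]", "znormalize"))
  # Re-running the conditioning steps leaves the signal essentially the
  # same series: highly correlated, with only transition-band energy
  # re-attenuated (a Butterworth band-pass is not a projection, so exact
  # idempotence is not expected; mid-band content is untouched).
  twice <- preprocess_panel(once, drop_k = 0)
  a <- once$subjects[[1]]$data
  b <- twice$subjects[[1]]$data
  expect_gt(min(diag(cor(t(a), t(b)))), 0.99)
  # mid-band sinusoid passes a second application unchanged within 5%
  t_ <- seq_len(2048)
  x <- matrix(sin(2 * pi * 0.05 * t_), 1)
  y1 <- bandpass(x, tr_seconds = 1)
  y2 <- bandpass(y1, tr_seconds = 1)
  core <- 500:1500
  expect_lt(max(abs(y2[, core] - y1[, core])), 0.05)
  # the non-filter steps are exactly idempotent
  nf1 <- preprocess_panel(panel, filter = FALSE)
  nf2 <- preprocess_panel(nf1, drop_k = 0, filter = FALSE)
  expect_equal(nf1$subjects[[1]]$data, nf2$subjects[[1]]$data,
               tolerance = 1e-10)
})

test_that("subject order commutes with per-subject conditioning", {
  panel <- generate_group_dataset(group_design(n_per_group = 2,
                                               n_timepoints = 80, seed = 2))
  rev_panel <- panel
  rev_panel$subjects <- rev(panel$subjects)
  a <- preprocess_panel(panel, filter = FALSE)
  b <- preprocess_panel(rev_panel, filter = FALSE)
  expect_identical(a$subjects[[1]]$data,
                   b$subjects[[length(b$subjects)]]$data)
})
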