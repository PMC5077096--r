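# Synthetic cohort generator: VAR simulation, stationarity gate, planted
# deltas, HRF kernel, behavioral scores, volume rendering.

test_that("white-noise spec gives unit per-channel variance and determinism", {
  sp <- var_spec(matrix(0, 3, 3), noise_sd = 1, seed = 42)
  x <- simulate_var(sp, 10000)
  expect_equal(dim(x), c(3, 10000))
  expect_true(all(abs(apply(x, 1, var) - 1) < 0.05))
  expect_identical(x, simulate_var(sp, 10000))
})

test_that("lag-1 cross-covariance matches the Lyapunov-equation oracle", {
  A <- matrix(c(0.3, 0.5, 0, 0.3), 2, 2)  # ch1 drives ch2 with 0.5
  sp <- var_spec(A, seed = 7)
  x <- simulate_var(sp, 200000, burn_in = 500)
  Sigma <- lyapunov_cov(A, diag(2))
  cross_lag1_theory <- A %*% Sigma        # cov(x_t, x_{t-1})
  emp <- tcrossprod(x[, -1] - rowMeans(x), x[, -ncol(x)] - rowMeans(x)) /
    (ncol(x) - 2)
  expect_equal(emp, cross_lag1_theory, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_gt(cross_lag1_theory[2, 1], 0.4)  # the planted direction is large
})

test_that("non-stationary specs are rejected with the radius reported", {
  expect_error(var_spec(diag(1.05, 2)), "spectral radius")
  base <- var_spec(matrix(c(0.5, 0.4, 0.4, 0.5), 2, 2),
                   labels = c("A", "B"))
  expect_error(
    apply_delta_edges(base, data.frame(from = "A", to = "B", delta = 5)),
    "spectral radius")
})

test_that("group dataset has the designed structure and records truth", {
  des <- group_design(n_per_group = 3, n_timepoints = 60, seed = 5)
  panel <- generate_group_dataset(des)
  groups <- sapply(panel$subjects, `[[`, "group")
  expect_equal(sum(groups == "SDI"), 3)
  expect_equal(sum(groups == "control"), 3)
  expect_equal(panel$channel_labels, rsn_symbols())
  expect_equal(ncol(panel$subjects[[1]]$data), 60)
  expect_equal(panel$metadata$truth_edges$from, c("RECN", "dDMN", "SMN"))
  # determinism
  panel2 <- generate_group_dataset(des)
  expect_identical(panel$subjects[[1]]$data, panel2$subjects[[1]]$data)
  # n_per_group = 1 is a valid panel but group inference refuses it
  p1 <- generate_group_dataset(group_design(n_per_group = 1,
                                            n_timepoints = 60, seed = 5))
  expect_length(p1$subjects, 2)
  expect_error(permute_group_labels(p1, n_perm = 20), "at least 2")
})

test_that("SDI subjects carry the planted coupling, controls do not", {
  des <- group_design(n_per_group = 1, n_timepoints = 30, seed = 9)
  A_base <- des$base_spec$coeffs[[1]]
  A_sdi <- des$sdi_spec$coeffs[[1]]
  lab <- des$base_spec$labels
  d <- A_sdi - A_base
  expect_equal(d[match("dDMN", lab), match("RECN", lab)], 0.15)
  expect_equal(d[match("BGN", lab), match("dDMN", lab)], 0.15)
  expect_equal(d[match("VSN", lab), match("SMN", lab)], 0.15)
  expect_equal(sum(abs(d) > 0), 3)
})

test_that("HRF kernel has canonical shape and convolution is causal/linear", {
  h <- hrf_kernel(2)
  expect_equal(max(h), 1)
  expect_equal(which.max(h), 4L)  # samples at 0,2,4,6 s; peak lands on 6 s
  expect_lt(h[9], 0)              # undershoot near 16 s
  # impulse response equals the kernel
  x <- matrix(0, 1, 30); x[1, 1] <- 1
  y <- hrf_convolve(x, 2)
  expect_equal(as.vector(y)[seq_along(h)], h, tolerance = 1e-12)
  # constant input -> constant * kernel sum (after the transient)
  xc <- matrix(1, 1, 60)
  yc <- hrf_convolve(xc, 2)
  expect_equal(yc[1, 40], sum(h), tolerance = 1e-10)
  # white-noise autocorrelation matches a direct convolution oracle
  set.seed(1)
  w <- matrix(rnorm(500), 1)
  yw <- hrf_convolve(w, 2)
  direct <- sapply(seq_len(500), function(t) {
    ks <- 0:min(t - 1, length(h) - 1)
    sum(h[ks + 1] * w[1, t - ks])
  })
  expect_equal(as.vector(yw), direct, tolerance = 1e-8)
})

test_that("behavior scores hit reference group means and recover couplings", {
  des <- group_design(n_per_group = 50, n_timepoints = 60, seed = 3)
  panel <- generate_group_dataset(des)
  strengths <- panel_strengths(panel)
  beh <- generate_behavior(panel, strengths, seed = 11)
  ref <- behavior_reference()
  for (k in seq_len(nrow(ref))) {
    sc <- ref$scale[k]
    m_sdi <- mean(beh[[sc]][beh$group == "SDI"])
    se <- ref$sd_sdi[k] / sqrt(50)
    expect_lt(abs(m_sdi - ref$mean_sdi[k]), 2.5 * se)
  }
  # planted negative RECN coupling to BIS-11 is recovered with the right sign
  res <- regress_strength(strengths[, "RECN"], beh[["BIS-11"]])
  expect_lt(res$r, 0)
  # determinism
  beh2 <- generate_behavior(panel, strengths, seed = 11)
  expect_identical(beh, beh2)
  # unknown network in coupling rejected
  bad <- behavior_spec(couplings = list("BAS" = list(list(network = "XXX",
                                                          sign = 1))))
  expect_error(generate_behavior(panel, strengths, bad), "unknown network")
})

test_that("uncoupled scores are independent of strengths across seeds", {
  des <- group_design(n_per_group = 30, n_timepoints = 60, seed = 3)
  panel <- generate_group_dataset(des)
  strengths <- panel_strengths(panel)
  spec0 <- behavior_spec(couplings = list())
  ps <- sapply(1:40, function(s) {
    beh <- generate_behavior(panel, strengths, spec0, seed = s)
    regress_strength(strengths[, "RECN"], beh[["BIS-11"]])$p_raw
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("render_volumes is maps x courses plus noise and round-trips", {
  set.seed(4)
  maps <- qr.Q(qr(matrix(rnorm(64 * 2), 64, 2)))  # orthonormal maps
  courses <- matrix(rnorm(2 * 30), 2, 30)
  vol <- render_volumes(maps, courses, noise_sd = 0, grid_dim = c(4, 4, 4))
  y <- matrix(vol, 64, 30)
  # noiseless: regression of volumes on maps returns the courses exactly
  rec <- solve(crossprod(maps), crossprod(maps, y))
  expect_equal(rec, courses, tolerance = 1e-10)
  expect_error(render_volumes(maps, matrix(0, 3, 5)), "components")
})
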