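# Network-of-interest definition: PCA reduction, MDL source counting,
# group ICA, template matching, dual regression, network strength.

test_that("PCA reduction is exact at full rank and tracks eigenvalues", {
  set.seed(1)
  # rank-3 data, k = 3 -> exact reconstruction
  U <- matrix(rnorm(200 * 3), 200, 3)
  V <- matrix(rnorm(40 * 3), 40, 3)
  X <- U %*% t(V)
  r <- pca_reduce(X, k = 3, center = FALSE)
  expect_equal(r$reduced %*% t(r$basis), X, tolerance = 1e-8)
  # k above rank capped with a warning
  expect_warning(pca_reduce(X, k = 10, center = FALSE), "rank")
  # explained variance matches a direct eigensolve of the covariance
  Y <- matrix(rnorm(300 * 20), 300, 20)
  ry <- pca_reduce(Y, k = 5)
  Yc <- sweep(Y, 2, colMeans(Y))
  ev <- eigen(crossprod(Yc) / 300, symmetric = TRUE)$values
  expect_equal(ry$eigenvalues[1:5], ev[1:5], tolerance = 1e-8)
  # reconstruction error equals the discarded eigenvalue mass
  err <- sum((Yc - ry$reduced %*% t(ry$basis))^2) / 300
  expect_equal(err, sum(ev[-(1:5)]), tolerance = 1e-6)
  expect_error(pca_reduce(Y, k = 0), "positive")
})

test_that("MDL counts planted sources and is scale invariant", {
  set.seed(2)
  S <- matrix(rnorm(5 * 3000), 5)
  A <- matrix(rnorm(34 * 5), 34, 5)
  X <- A %*% S + 0.01 * matrix(rnorm(34 * 3000), 34)
  expect_equal(estimate_n_components_mdl(X), 5L)
  expect_equal(estimate_n_components_mdl(10 * X), 5L)
  # isotropic noise only -> at most 1
  N0 <- matrix(rnorm(20 * 3000), 20)
  expect_lte(estimate_n_components_mdl(N0), 1L)
})

test_that("group ICA recovers super-Gaussian spatial sources", {
  set.seed(3)
  v <- 2000
  # sparse (super-Gaussian) spatial sources
  s1 <- rnorm(v)^3
  s2 <- rnorm(v)^3
  S <- cbind(s1, s2)
  M <- matrix(c(1, 0.4, 0.3, 1), 2, 2)
  X <- S %*% t(M)
  cs <- group_ica(X, 2, seed = 5)
  cors <- abs(cor(cs$maps, scale(S)))
  # best match per source > 0.99 up to permutation/sign
  expect_gt(max(cors[, 1]), 0.99)
  expect_gt(max(cors[, 2]), 0.99)
  # maps are z-scored with non-negative skewness
  expect_lt(max(abs(colMeans(cs$maps))), 1e-8)
  skews <- apply(cs$maps, 2, function(m) mean((m - mean(m))^3) / sd(m)^3)
  expect_true(all(skews >= 0))
  # determinism given seed; stability across seeds up to permutation
  cs2 <- group_ica(X, 2, seed = 5)
  expect_identical(cs$maps, cs2$maps)
  cs3 <- group_ica(X, 2, seed = 9)
  match_cor <- apply(abs(cor(cs$maps, cs3$maps)), 1, max)
  expect_true(all(match_cor > 0.95))
})

test_that("template matching is injective, tie-broken, order-invariant", {
  set.seed(4)
  v <- 500
  templates <- matrix(rnorm(v * 14), v, 14,
                      dimnames = list(NULL, rsn_symbols()))
  noise <- matrix(rnorm(v * 14, sd = 0.1), v, 14)
  comps <- templates + noise
  m <- match_templates(comps, templates)
  expect_equal(unname(m$assignment), 1:14)
  expect_true(all(diag(m$correlations) > 0.9))
  # injectivity: no component claimed twice
  expect_false(anyDuplicated(m$assignment) > 0)
  # shuffling component order permutes but preserves the assignment
  perm <- sample(14)
  m2 <- match_templates(comps[, perm], templates)
  expect_equal(unname(perm[m2$assignment]), unname(m$assignment))
  # tie: a component equally near two templates resolves by template order
  t2 <- cbind(A = c(1, 0, 0, 1, 0, 2), B = c(0, 1, 0, 0, 1, 2))
  comp1 <- t2[, "A"] + t2[, "B"]  # symmetric, equally correlated with both
  mt <- match_templates(cbind(comp1, comp1), t2)
  expect_equal(unname(mt$assignment["A"]), 1L)
  expect_equal(unname(mt$assignment["B"]), 2L)
  # fewer components than templates -> partial assignment with warning
  expect_warning(mp <- match_templates(comps[, 1:5], templates), "partial")
  expect_equal(sum(!is.na(mp$assignment)), 5)
})

test_that("dual regression recovers planted courses and maps", {
  set.seed(5)
  v <- 800; T_ <- 146
  maps <- cbind(rnorm(v)^3, rnorm(v)^3)
  courses <- matrix(rnorm(2 * T_), 2, T_)
  clean <- maps %*% courses
  br <- back_reconstruct(clean, maps)
  expect_gt(min(abs(diag(cor(br$time_courses, t(courses))))), 0.999)
  expect_gt(min(abs(diag(cor(br$subject_maps, maps)))), 0.999)
  # noise at signal SD still recovers structure
  noisy <- clean + matrix(rnorm(v * T_, sd = sd(clean)), v, T_)
  brn <- back_reconstruct(noisy, maps)
  expect_gt(min(abs(diag(cor(brn$time_courses, t(courses))))), 0.8)
  # orthonormal maps: spatial regression equals projection
  Q <- qr.Q(qr(matrix(rnorm(v * 2), v, 2)))
  y <- Q %*% courses
  expect_equal(back_reconstruct(y, Q)$time_courses, t(crossprod(Q, y)),
               tolerance = 1e-8)
  # collinear maps trigger the ridge fallback (both regression stages warn)
  w <- capture_warnings(back_reconstruct(clean, cbind(maps, maps[, 1])))
  expect_true(any(grepl("collinear", w)))
})

test_that("network strength is the mean subject beta and scales linearly", {
  sm <- cbind(a = rep(2.5, 10), b = 1:10)
  expect_equal(noi_strength(sm, 1), 2.5)
  expect_equal(noi_strength(sm, "b", labels = c("a", "b")), 5.5)
  expect_equal(noi_strength(2 * sm, 1), 5)  # linearity
  expect_error(noi_strength(sm, 1, labels = c(NA, "b")), "unlabeled")
  expect_error(noi_strength(sm, "z", labels = c("a", "b")), "labeled")
})

test_that("full volumetric path recovers planted network time courses", {
  set.seed(6)
  v <- 1728  # 12^3 grid
  grid <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  blob <- function(cx, cy, cz) {
    exp(-((grid$x - cx)^2 + (grid$y - cy)^2 + (grid$z - cz)^2) / 6)
  }
  maps <- cbind(blob(3, 3, 6), blob(9, 9, 6))
  courses <- matrix(rnorm(2 * 100), 2, 100)
  vol <- render_volumes(maps, courses, noise_sd = 0.2,
                        grid_dim = c(12, 12, 12), seed = 8)
  y <- matrix(vol, v, 100)
  cs <- group_ica(y, 2, seed = 2)
  templates <- maps
  colnames(templates) <- c("RECN", "dDMN")
  m <- match_templates(cs, templates)
  expect_true(all(!is.na(m$assignment)))
  # recovered maps correlate strongly with the planted blobs
  for (k in 1:2) {
    expect_gt(abs(cor(cs$maps[, m$assignment[k]], templates[, k])), 0.95)
  }
  br <- back_reconstruct(y, cs$maps)
  for (k in 1:2) {
    expect_gt(abs(cor(br$time_courses[, m$assignment[k]], courses[k, ])),
              0.9)
  }
})
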