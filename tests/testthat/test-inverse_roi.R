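test_that("the standardized inverse is linear and homogeneous", {
  hm <- make_toy_headmodel(n_sensors = 10, grid_shape = c(3, 3, 2), seed = 2)
  op <- build_inverse(hm, alpha_reg = 0)
  z <- localize(op, matrix(0, 10, 4))
  expect_equal(z$raw, matrix(0, 18, 4), ignore_attr = TRUE)
  expect_equal(z$standardized, matrix(0, 18, 4), ignore_attr = TRUE)

  set.seed(3)
  x <- apply_average_reference(matrix(rnorm(10 * 3), 10, 3))
  a <- localize(op, x); b <- localize(op, 2.5 * x)
  expect_equal(b$raw, 2.5 * a$raw, tolerance = 1e-9)
  expect_equal(b$standardized, 2.5^2 * a$standardized, tolerance = 1e-9)
  # time-constant input -> time-constant estimate
  xc <- x[, c(1, 1, 1)]
  sc <- localize(op, xc)$standardized
  expect_equal(sc[, 1], sc[, 3], tolerance = 1e-12)
  expect_error(localize(op, matrix(0, 7, 2)), "mismatch")
})

test_that("localize matches an explicit matrix-product oracle on a small toy", {
  hm <- make_toy_headmodel(n_sensors = 6, grid_shape = c(2, 5, 1), seed = 5)
  op <- build_inverse(hm, alpha_reg = 0.01)
  set.seed(8)
  x <- apply_average_reference(matrix(rnorm(6 * 7), 6, 7))
  est <- localize(op, x)
  L <- hm$leadfield
  H <- diag(6) - 1 / 6
  M <- L %*% t(L) + 0.01 * H
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  Minv <- e$vectors[, keep] %*% diag(1 / e$values[keep]) %*% t(e$vectors[, keep])
  K <- t(L) %*% Minv
  expect_equal(est$raw, K %*% x, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(est$standardized, (K %*% x)^2 / diag(K %*% L),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the unregularized standardized inverse has zero localization error at every voxel", {
  hm <- make_toy_headmodel(n_sensors = 6, grid_shape = c(4, 4, 3), seed = 7)
  op <- build_inverse(hm, alpha_reg = 0)
  n_vox <- ncol(hm$leadfield)
  hits <- vapply(seq_len(n_vox), function(v) {
    est <- localize(op, hm$leadfield[, v, drop = FALSE])
    which.max(est$standardized[, 1]) == v
  }, logical(1))
  expect_true(all(hits))
})

test_that("ROI time courses are plain voxel means", {
  hm <- make_toy_headmodel(n_sensors = 8, grid_shape = c(3, 2, 2), seed = 3)
  op <- build_inverse(hm)
  set.seed(4)
  est <- localize(op, apply_average_reference(matrix(rnorm(8 * 5), 8, 5)))
  expect_equal(roi_timecourse(est, 4L), est$standardized[4, ])
  roi <- c(1, 3, 5, 7, 9)
  expect_equal(roi_timecourse(est, roi),
               colMeans(est$standardized[roi, ]), tolerance = 1e-12)
  expect_equal(roi_timecourse(est, roi, "raw"), colMeans(est$raw[roi, ]),
               tolerance = 1e-12)
  expect_error(roi_timecourse(est, integer(0)), "empty")
})

test_that("the max-t permutation test is empty under identical conditions and finds planted effects", {
  set.seed(6)
  A <- matrix(abs(rnorm(20 * 8)), 20, 8)
  res <- voxel_permutation_ttest(A, A, n_perm = 99, seed = 2,
                                 normalize_subjects = FALSE)
  expect_equal(res$n_supra, 0L)

  # planted stronger activity in voxels 1:4
  B <- A; B[1:4, ] <- B[1:4, ] * 3 + 1
  res2 <- voxel_permutation_ttest(B, A, n_perm = 199, seed = 3,
                                  normalize_subjects = FALSE)
  expect_true(all(res2$suprathreshold %in% 1:4))
  expect_gt(res2$n_supra, 0L)
  # critical t monotone in alpha
  res_strict <- voxel_permutation_ttest(B, A, n_perm = 199, alpha = 0.01,
                                        seed = 3, normalize_subjects = FALSE)
  expect_gte(res_strict$critical_t, res2$critical_t)
  expect_true(all(res_strict$suprathreshold %in% res2$suprathreshold))
})

test_that("paired t inside the voxel test matches t.test", {
  set.seed(9)
  A <- matrix(rnorm(6 * 10), 6); B <- matrix(rnorm(6 * 10), 6)
  res <- voxel_permutation_ttest(A, B, n_perm = 9, seed = 1,
                                 normalize_subjects = FALSE)
  oracle <- vapply(1:6, function(v)
    unname(t.test(A[v, ], B[v, ], paired = TRUE)$statistic), numeric(1))
  expect_equal(res$t, oracle, tolerance = 1e-10)
})

test_that("JZS Bayes factors favor the null at t = 0, decrease in |t| and grow with n", {
  bf0 <- jzs_paired_bf01(0, n = 38)
  expect_gt(bf0$bf01, 1)
  tgrid <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(tgrid, function(t0) jzs_paired_bf01(t0, n = 20)$bf01, numeric(1))
  expect_true(all(diff(bfs) < 0))
  bfn <- vapply(c(5, 10, 20, 40), function(n0)
    jzs_paired_bf01(0, n = n0)$bf01, numeric(1))
  expect_true(all(diff(bfn) > 0))
  # consistency between the difference-vector and (t, n) entry points
  set.seed(2)
  d <- rnorm(15, 0.3)
  t0 <- mean(d) / (sd(d) / sqrt(15))
  expect_equal(jzs_paired_bf01(d)$bf01, jzs_paired_bf01(t0, n = 15)$bf01,
               tolerance = 1e-8)
})

test_that("quadrature BF01 agrees with a Monte-Carlo marginal-likelihood oracle", {
  set.seed(123)
  n_draw <- 1e5
  for (case in list(c(t = 0, n = 10), c(t = 1.5, n = 12), c(t = 3, n = 38))) {
    t0 <- case["t"]; n0 <- case["n"]; nu <- n0 - 1
    delta <- rcauchy(n_draw, 0, sqrt(2) / 2)
    li <- suppressWarnings(dt(t0, df = nu, ncp = delta * sqrt(n0)))
    m1 <- mean(li); se <- sd(li) / sqrt(n_draw)
    bf01_mc <- dt(t0, df = nu) / m1
    got <- jzs_paired_bf01(t0, n = n0)$bf01
    # 3 MC standard errors on the marginal likelihood scale
    expect_lt(abs(dt(t0, df = nu) / got - m1), 3 * se)
    expect_equal(got, unname(bf01_mc), tolerance = 0.02)
  }
})

test_that("windowed ROI Bayes factors support the null for identical conditions", {
  hm <- make_toy_headmodel(n_sensors = 12, grid_shape = c(3, 3, 2), seed = 6)
  cfg <- sim_config(n_subjects = 8, n_channels = 12, sfreq = 64,
                    epoch_ms = 250, seed = 4)
  sim <- simulate_source_study(hm, effect = "none", cfg = cfg, n_segments = 3)
  op <- build_inverse(hm, alpha_reg = 0)
  win <- data.frame(map = 1:3,
                    onset = sim$truth$boundaries$cC[1:3],
                    offset = sim$truth$boundaries$cC[2:4])
  tab <- windowed_roi_bayes(sim$dataset, op, hm$roi$ACC,
                            windows = list(congruent = win, incongruent = win))
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$bf01 > 0))
  expect_error(windowed_roi_bayes(sim$dataset, op, hm$roi$ACC,
                                  windows = list(
                                    congruent = transform(win, offset = offset + 500),
                                    incongruent = win)),
               "outside the epoch")
})
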