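test_that("TCT returns p = 1 for a single subject and floor p for a shared noiseless template", {
  mont <- tiny_montage(10)
  arr <- array(0, c(10, 8, 1, 4))
  set.seed(3)
  base <- matrix(rnorm(10 * 8), 10, 8)
  for (ci in 1:4) arr[, , 1, ci] <- base
  ds <- study_dataset(center_ch(arr), mont, sfreq = 100)
  out <- tct(ds, "cC", n_perm = 50, seed = 1)
  expect_equal(out$p, rep(1, 8))

  sim <- tiny_study(seed = 6, noise = noiseless_spec())
  out2 <- tct(sim$dataset, "cC", n_perm = 99, alpha = 0.05, seed = 2)
  expect_equal(out2$p, rep(1 / 100, ncol(sim$dataset$data[, , 1, 1])))
})

test_that("TCT p values are roughly uniform for independent random topographies", {
  mont <- tiny_montage(16)
  n_rep <- 40; n_t <- 10
  ps <- c()
  for (i in 1:n_rep) {
    set.seed(1000 + i)
    arr <- array(rnorm(16 * n_t * 6 * 4), c(16, n_t, 6, 4))
    ds <- study_dataset(center_ch(arr), mont, sfreq = 100)
    ps <- c(ps, tct(ds, "cC", n_perm = 99, seed = i)$p)
  }
  rate <- mean(ps <= 0.05)
  n <- length(ps)   # 400 independent timepoint tests
  expect_lt(abs(rate - 0.05), 2.6 * sqrt(0.05 * 0.95 / n) + 1e-9)
})

test_that("TANOVA is degenerate (p = 1) when all cells carry identical data", {
  mont <- tiny_montage(8)
  set.seed(4)
  base <- matrix(rnorm(8 * 6), 8, 6)
  arr <- array(0, c(8, 6, 3, 4))
  for (s in 1:3) for (ci in 1:4) arr[, , s, ci] <- base
  ds <- study_dataset(center_ch(arr), mont, sfreq = 100)
  out <- tanova(ds, "congruency", n_perm = 60, seed = 2)
  expect_equal(out$p, rep(1, 6))
})

test_that("TANOVA equals the exhaustive-enumeration oracle on a 2-subject toy", {
  mont <- tiny_montage(8)
  set.seed(9)
  arr <- center_ch(array(rnorm(8 * 5 * 2 * 4), c(8, 5, 2, 4)))
  ds <- study_dataset(arr, mont, sfreq = 100)
  out <- tanova(ds, "congruency", scheme = "paired_swap", exhaustive = TRUE,
                normalize = TRUE, seed = 1)
  expect_equal(out$n_perm, 4L)   # 2 subjects x swap/no-swap

  # independent oracle: enumerate the 4 swap patterns directly
  X <- arr
  for (s in 1:2) for (ci in 1:4) {
    g <- sqrt(colMeans(X[, , s, ci]^2))
    X[, , s, ci] <- sweep(X[, , s, ci], 2, g, "/")
  }
  stat_for <- function(swapped) {
    # swapped: logical per subject; congruency effect topography GFP per t
    eff <- 0
    for (s in 1:2) {
      idx <- if (swapped[s]) c(2, 1, 4, 3) else 1:4
      w <- c(-0.5, 0.5, -0.5, 0.5)[idx]
      eff <- eff + (X[, , s, 1] * w[1] + X[, , s, 2] * w[2] +
                      X[, , s, 3] * w[3] + X[, , s, 4] * w[4])
    }
    sqrt(colMeans((eff / 2)^2))
  }
  obs <- stat_for(c(FALSE, FALSE))
  stats <- rbind(stat_for(c(FALSE, FALSE)), stat_for(c(TRUE, FALSE)),
                 stat_for(c(FALSE, TRUE)), stat_for(c(TRUE, TRUE)))
  p_oracle <- colMeans(sweep(stats, 2, obs, `>=`))
  expect_equal(out$p, p_oracle, tolerance = 1e-12)
  expect_equal(out$observed, obs, tolerance = 1e-12)
})

test_that("p values follow the +1 convention and are reproducible from the seed", {
  sim <- tiny_study(seed = 31, n_subjects = 4)
  a <- tanova(sim$dataset, "congruency", n_perm = 37, seed = 12)
  b <- tanova(sim$dataset, "congruency", n_perm = 37, seed = 12)
  expect_identical(a$p, b$p)
  expect_identical(a$perm_stats, b$perm_stats)
  expect_true(all(a$p >= 1 / 38 & a$p <= 1))
  expect_true(all(abs(a$p * 38 - round(a$p * 38)) < 1e-9))
})

test_that("duration control reports nothing when no point is significant and grows with alpha", {
  sim <- tiny_study(seed = 41, n_subjects = 4, stretch_ms = 0)
  out <- tanova(sim$dataset, "congruency", n_perm = 60, alpha = 0.01, seed = 3)
  out$p[] <- 1
  dc <- duration_control(out)
  expect_equal(nrow(dc$significant_runs), 0L)

  # loosening alpha never decreases the duration threshold
  for (s in 1:4) {
    sim2 <- tiny_study(seed = 50 + s, n_subjects = 4, stretch_ms = 0)
    o <- tanova(sim2$dataset, "congruency", n_perm = 99, alpha = 0.05,
                seed = 60 + s)
    thr_small <- duration_control(o, alpha = 0.01)$duration_threshold
    thr_large <- duration_control(o, alpha = 0.05)$duration_threshold
    expect_true(thr_large >= thr_small)
  }
  expect_error(duration_control(structure(list(perm_stats = NULL),
                                          class = "permutation_outcome")),
               "not retained")
})

test_that("every reported duration-control run is significant throughout and long enough", {
  sim <- tiny_study(seed = 43, k = 4, stretch_ms = 60)
  out <- tanova(sim$dataset, "congruency", n_perm = 199, alpha = 0.05, seed = 7)
  dc <- duration_control(out)
  if (nrow(dc$significant_runs) > 0) {
    for (ri in seq_len(nrow(dc$significant_runs))) {
      run <- dc$significant_runs[ri, ]
      expect_true(all(out$p[run["start"]:(run["end"] - 1)] < 0.05))
      expect_gte(run["end"] - run["start"], dc$duration_threshold)
    }
  } else skip("no significant window at this seed (structure checked elsewhere)")
})

test_that("microstate parameter tests are degenerate for identical conditions", {
  mont <- tiny_montage(12)
  P <- make_templates(mont, 3, seed = 2)
  set.seed(5)
  base <- P[, rep(1:3, each = 6)] * 2
  arr <- array(0, c(12, 18, 3, 4))
  for (s in 1:3) for (ci in 1:4) arr[, , s, ci] <- base
  ds <- study_dataset(center_ch(arr), mont, sfreq = 100)
  model <- structure(list(maps = P, k = 3, polarity_sensitive = TRUE),
                     class = "microstate_model")
  res <- microstate_param_test(ds, model, n_perm = 40, seed = 3)
  expect_true(all(res$p == 1))
})

test_that("microstate parameter test equals the exhaustive oracle on a 3-subject toy", {
  mont <- tiny_montage(10)
  P <- make_templates(mont, 2, seed = 4)
  set.seed(11)
  n_t <- 12
  arr <- array(0, c(10, n_t, 3, 4))
  for (s in 1:3) for (ci in 1:4) {
    split <- sample(4:8, 1)
    lab <- rep(1:2, c(split, n_t - split))
    arr[, , s, ci] <- P[, lab] * 2 + 0.3 * matrix(rnorm(10 * n_t), 10)
  }
  ds <- study_dataset(center_ch(arr), mont, sfreq = 100)
  model <- structure(list(maps = P, k = 2, polarity_sensitive = TRUE),
                     class = "microstate_model")
  res <- microstate_param_test(ds, model, params = "duration",
                               effect = "congruency", scheme = "paired_swap",
                               exhaustive = TRUE, seed = 1)
  expect_equal(res$n_perm, 8L)   # 2^3 sign patterns

  # oracle: enumerate the 8 swap patterns, refit level grand means by a
  # brute-force contiguous split search
  dur_of <- function(U) {
    # best single split for 2 ordered maps maximizing GFP-weighted fit
    W <- crossprod(P, U) / nrow(U)
    tot <- vapply(1:(n_t - 1), function(s)
      sum(W[1, 1:s]) + sum(W[2, (s + 1):n_t]), numeric(1))
    s <- which.max(tot)
    dt <- 1000 / 100
    c(s * dt, (n_t - s) * dt)
  }
  stat_for <- function(sw) {
    inc <- cong <- 0
    for (s in 1:3) {
      cells <- if (sw[s]) list(c(1, 3), c(2, 4)) else list(c(2, 4), c(1, 3))
      inc <- inc + (arr[, , s, cells[[1]][1]] + arr[, , s, cells[[1]][2]]) / 2
      cong <- cong + (arr[, , s, cells[[2]][1]] + arr[, , s, cells[[2]][2]]) / 2
    }
    abs(dur_of(inc / 3) - dur_of(cong / 3))
  }
  pats <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  stats <- t(apply(pats, 1, stat_for))
  obs <- stat_for(c(FALSE, FALSE, FALSE))
  p_oracle <- colMeans(sweep(stats, 2, obs, `>=`))
  expect_equal(unname(res$p[, "duration"]), unname(p_oracle), tolerance = 1e-12)
})

test_that("a planted duration stretch drives the stretched map's duration p to the floor", {
  p_per_seed <- vapply(1:5, function(s) {
    sim <- tiny_study(seed = 600 + s, n_subjects = 10, k = 4, stretch_ms = 60)
    Xtr <- cbind(grand_mean(sim$dataset, cells = "cC")$values,
                 grand_mean(sim$dataset, cells = "cI")$values)
    model <- cluster_kmeans(Xtr, 4, n_init = 8, seed = s,
                            blocks = rep(1:2, each = ncol(Xtr) / 2))
    res <- microstate_param_test(sim$dataset, model, params = "duration",
                                 n_perm = 199, seed = 700 + s)
    res$p[, "duration"]
  }, numeric(4))
  # stretched map 3 (and its complement map 4) detected, early maps not
  expect_lte(median(p_per_seed[3, ]), 0.025)
  expect_gt(median(p_per_seed[1, ]), 0.1)
  expect_gt(median(p_per_seed[2, ]), 0.1)
})
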