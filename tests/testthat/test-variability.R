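test_that("raw NV equals 1 when variance equals mean, and in the empty limit", {
  # rows {0, 1}: pointwise mean 0.5 = pointwise variance 0.5
  m <- manual_sdf_matrix(rbind(rep(0, 6), rep(1, 6)))
  nv <- nv_series(m, mode = "raw_eq1")
  expect_equal(nv$nv, rep(1, 6), tolerance = 1e-12)

  # all-empty trials: regularizer-only limit k*eps / (k*eps') = 1
  empty <- manual_trial_set(list(numeric(0), numeric(0), numeric(0)))
  nv0 <- nv_series(compute_sdf(empty), mode = "raw_eq1")
  expect_equal(nv0$nv, rep(1, length(nv0$time_grid)))

  # regularizers enter exactly as k*eps and k*eps'
  cst <- nv_constants(k = 0.2, eps = 0.05, eps_prime = 0.02)
  nv2 <- nv_series(m, constants = cst, mode = "raw_eq1")
  expect_equal(nv2$nv, rep((0.2 * 0.05 + 0.5) / (0.2 * 0.02 + 0.5), 6))
})

test_that("kernel correction matches brute-force smoothed-Poisson simulation", {
  spec <- kernel_spec(sigma = 30, dt = 1)
  # closed form scaling: c = 1000 * dt * sum(k^2) ~ 1000/(2 sigma sqrt(pi))
  expect_equal(kernel_correction(spec), 1000 / (2 * 30 * sqrt(pi)),
               tolerance = 1e-3)
  # doubling sigma halves the correction
  expect_equal(kernel_correction(kernel_spec(sigma = 60)) /
                 kernel_correction(spec), 0.5, tolerance = 1e-3)
  # near-delta kernel approaches the 1 ms count-bin Fano scale (c -> 1000/dt...
  # normalized: for sigma << dt the discrete kernel is a single bin of height
  # 1/dt, so c = 1000 * dt * (1/dt)^2 = 1000/dt)
  expect_equal(kernel_correction(kernel_spec(sigma = 0.05, dt = 1)), 1000,
               tolerance = 1e-6)

  # brute force: many-trial homogeneous Poisson, E[Var(SDF)]/E[Mean(SDF)] = c
  ts <- simulate_trialset(rate_profile("constant", baseline_rate = 20),
                          noise_spec("none"), n_trials = 2000, seed = 14)
  ms <- mean_sdf(compute_sdf(ts, spec))
  expect_equal(mean(ms$var) / mean(ms$mean), kernel_correction(spec),
               tolerance = 0.03)
  # and therefore calibrated NV of a pure Poisson process is unity
  nv <- nv_series(compute_sdf(ts, spec))
  expect_gt(mean(nv$nv), 0.98)
  expect_lt(mean(nv$nv), 1.02)
})

test_that("count Fano is ~0 for identical trains, ~1 for Poisson, and matches the noisy closed form", {
  det <- manual_trial_set(list(c(100, 300, 700), c(100, 300, 700),
                               c(100, 300, 700)))
  f0 <- count_fano(det, window = 500, step = 250)  # every window occupied
  expect_true(all(f0$nv < 0.01))   # ~ k*eps / (k*eps' + mean)
  expect_identical(f0$mode, "count_fano")
  # spikeless windows sit at the regularizer-only limit k*eps/(k*eps') = 1
  f1 <- count_fano(manual_trial_set(list(100, 100)), window = 100, step = 100)
  expect_true(all(f1$nv[f1$time_grid > 300] == 1))

  ts <- simulate_trialset(rate_profile("constant", baseline_rate = 20),
                          noise_spec("none"), n_trials = 1000, seed = 15)
  f1 <- count_fano(ts, window = 100, step = 50)
  expect_equal(mean(f1$nv), 1, tolerance = 0.05)

  tsn <- simulate_trialset(rate_profile("constant", baseline_rate = 20),
                           noise_spec("additive_offset", sigma = 10),
                           n_trials = 1000, seed = 16)
  f6 <- count_fano(tsn, window = 1000 - 1e-6)
  expect_equal(mean(f6$nv), expected_noisy_fano(20, 10, 1), tolerance = 0.15)

  expect_error(count_fano(ts, window = 2000), "larger than the data span")
  expect_error(count_fano(det, window = 0.5), ">= 1 ms")
})

test_that("noisy-Poisson NV exceeds 1 while pure stays at 1 (100 trials)", {
  pure <- make_fixture("pure_constant", seed = 17)
  noisy <- make_fixture("noisy_constant", seed = 17)
  nv_p <- nv_series(compute_sdf(align_trials(pure$trialset)))
  nv_n <- nv_series(compute_sdf(align_trials(noisy$trialset)))
  expect_lt(abs(mean(nv_p$nv) - 1), 0.15)
  expect_gt(mean(nv_n$nv), 1.15)
  expect_true(all(nv_p$nv >= 0))
})

test_that("rate-level binning partitions time bins and orders NV inversely to rate", {
  # constant true rate: every bin lands in the top level; empty levels are
  # reported with n = 0, not dropped
  fx <- make_fixture("pure_constant", seed = 18)
  m <- compute_sdf(align_trials(fx$trialset))
  nv <- nv_series(m)
  rl <- rate_level_nv(nv, rep(20, length(nv$time_grid)))
  expect_equal(nrow(rl), 3)
  expect_equal(rl$n, c(length(nv$time_grid), 0, 0))
  expect_true(all(is.na(rl$nv_mean[2:3])))

  # inverse NV-rate relation on a noisy task-epoch set
  fx2 <- make_fixture("task_epoch_noisy", seed = 1, n_trials = 500)
  m2 <- compute_sdf(align_trials(fx2$trialset))
  rl2 <- rate_level_nv(nv_series(m2), mean_sdf(m2)$mean)
  expect_equal(sum(rl2$n), length(m2$time_grid))
  expect_gt(rl2$nv_mean[3], rl2$nv_mean[1])  # low-rate level > top level
  # closed-form per-level expectation: NV ~ 1 + var_eff / (c * lambda_level)
  cc <- kernel_correction(m2$kernel)
  o <- clipped_normal_moments(5, 5)
  exp_low <- 1 + o$var / (cc * o$mean)
  expect_equal(rl2$nv_mean[3], exp_low, tolerance = 0.1)
  exp_top <- 1 + 25 / (cc * 45)
  expect_equal(rl2$nv_mean[1], exp_top, tolerance = 0.1)

  expect_error(rate_level_nv(nv_series(m2), rep(0, length(m2$time_grid))),
               "positive")
  expect_error(rate_level_nv(nv_series(m2), 1:3), "time grid")
})

test_that("level-binned NV is non-increasing in level rate in expectation", {
  # average the per-level NV over several independent 500-trial sets
  res <- sapply(1:6, function(s) {
    fx <- make_fixture("task_epoch_noisy", seed = 100 + s, n_trials = 500)
    m <- compute_sdf(align_trials(fx$trialset))
    rate_level_nv(nv_series(m), mean_sdf(m)$mean)$nv_mean
  })
  avg <- rowMeans(res)   # top, mid, low
  expect_true(all(diff(avg) > 0))
})

test_that("pooling averages NV series and reveals the post-onset decline", {
  fx <- make_fixture("task_epoch_noisy", seed = 19)
  m <- compute_sdf(align_trials(fx$trialset))
  nv <- nv_series(m)

  single <- pool_nv(list(nv))
  expect_equal(single$nv_mean, nv$nv)
  expect_true(all(is.na(single$nv_se)))

  two <- pool_nv(list(nv, nv))
  expect_equal(two$nv_mean, nv$nv)
  expect_equal(two$nv_se, rep(0, length(nv$nv)))

  units <- lapply(1:20, function(s) {
    fxs <- make_fixture("task_epoch_noisy", seed = 200 + s)
    nv_series(compute_sdf(align_trials(fxs$trialset)))
  })
  pooled <- pool_nv(units)
  pre <- pooled$time_ms >= -300 & pooled$time_ms < 0
  post <- pooled$time_ms >= 0 & pooled$time_ms < 300
  expect_gt(mean(pooled$nv_mean[pre]), mean(pooled$nv_mean[post]))

  short <- nv_series(compute_sdf(align_trials(fx$trialset),
                                 window = c(-100, 100)))
  expect_error(pool_nv(list(nv, short)), "time grid")
})

test_that("calibrated SDF-NV agrees with the matched-window count Fano", {
  w_eff <- 2 * 30 * sqrt(pi)  # effective averaging window of the kernel, ms
  for (name in c("pure_constant", "noisy_constant")) {
    fx <- make_fixture(name, seed = 20, n_trials = 500)
    tsa <- align_trials(fx$trialset)
    nv <- nv_series(compute_sdf(tsa))
    cf <- count_fano(tsa, window = w_eff, step = 25)
    expect_equal(mean(nv$nv), mean(cf$nv), tolerance = 0.1)
  }
})
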