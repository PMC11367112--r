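test_that("GHK x Boltzmann evaluation matches closed form and its limits", {
  # zero at the reversal potential for arbitrary parameters
  for (erev in c(-110, -90, -60))
    expect_equal(eval_ghk_boltzmann(erev, 1.7, erev, -25.4, 9.6), 0)

  # removable singularity at V = 0: series and direct form agree
  v_near <- c(-0.49, -0.1, 0.1, 0.49)
  direct <- oracle_ghk(v_near, 1, -90, -25.4, 9.6)
  expect_equal(eval_ghk_boltzmann(v_near, 1, -90, -25.4, 9.6), direct,
               tolerance = 1e-10)
  i0 <- eval_ghk_boltzmann(0, 1, -90, -25.4, 9.6)
  expect_true(is.finite(i0))
  expect_equal(i0, mean(oracle_ghk(c(-1e-6, 1e-6), 1, -90, -25.4, 9.6)),
               tolerance = 1e-9)

  # agreement with an independent evaluation at the control parameters
  expect_equal(eval_ghk_boltzmann(40, 1, -90, -25.4, 9.6),
               oracle_ghk(40, 1, -90, -25.4, 9.6), tolerance = 1e-12)

  expect_error(eval_ghk_boltzmann(40, 1, -90, -25.4, -2), "positive")
})

test_that("I-V fitting recovers generating parameters and resists local minima", {
  v <- seq(-140, 40, by = 10)
  truth <- list(gmax = 0.25, erev = -90, v_half = -25.4, k = 9.6)
  i <- eval_ghk_boltzmann(v, truth$gmax, truth$erev, truth$v_half, truth$k)
  fit <- fit_iv_ghk_boltzmann(v, i)
  expect_true(fit$converged)
  expect_equal(fit$v_half, truth$v_half, tolerance = 1e-6)
  expect_equal(fit$k, truth$k, tolerance = 1e-6)
  expect_equal(fit$gmax, truth$gmax, tolerance = 1e-6)
  expect_equal(fit$erev, truth$erev, tolerance = 1e-4)
  expect_equal(eval_ghk_boltzmann(fit$erev, fit$gmax, fit$erev,
                                  fit$v_half, fit$k), 0)

  expect_error(fit_iv_ghk_boltzmann(v, rep(0, length(v))), "degenerate")
  expect_error(fit_iv_ghk_boltzmann(v[1:5], i[1:5]), "at least 6")

  # grid-initialized fit reaches the same minimum as a random multi-start
  withr::with_seed(99, {
    hits <- 0
    for (rep in 1:10) {
      inoisy <- i + rnorm(length(v), 0, 0.15)
      mine <- fit_iv_ghk_boltzmann(v, inoisy)
      sse_mine <- mine$residual_norm^2
      ms <- oracle_multistart_iv(v, inoisy, n_starts = 8)
      if (sse_mine <= ms$sse * (1 + 1e-6)) hits <- hits + 1
    }
    expect_gte(hits, 9)
  })
})

test_that("normalized conductance curve follows the Boltzmann", {
  fit <- list(v_half = -25.4, k = 9.6)
  expect_equal(gnorm_curve(fit, -25.4), 0.5)
  expect_equal(gnorm_curve(fit, 1e4), 1, tolerance = 1e-12)
  expect_equal(gnorm_curve(fit, -10), stats::plogis((-10 + 25.4) / 9.6),
               tolerance = 1e-12)
  g <- gnorm_curve(fit, seq(-140, 40, 10))
  expect_true(all(diff(g) > 0) && all(g > 0 & g < 1))
})

test_that("F-V Boltzmann fitting recovers, flags degeneracy, and matches a grid oracle", {
  v <- seq(-140, 40, by = 10)
  y <- boltzmann(v, -42.5, 16.8)
  fit <- fit_boltzmann_fv(v, y)
  expect_equal(fit$v_half, -42.5, tolerance = 1e-6)
  expect_equal(fit$k, 16.8, tolerance = 1e-6)

  flat <- fit_boltzmann_fv(v, rep(0.5, length(v)))
  expect_false(flat$identifiable)
  expect_error(fit_boltzmann_fv(v[1:3], y[1:3]), "at least 4")

  # optimizer minimum agrees with a brute-force lattice search
  withr::with_seed(4, {
    yn <- y + rnorm(length(v), 0, 0.03)
    fit <- fit_boltzmann_fv(v, yn)
    grid <- expand.grid(v_half = seq(-60, -20, by = 0.5),
                        k = seq(10, 25, by = 0.5))
    sse <- vapply(seq_len(nrow(grid)), function(r)
      sum((yn - boltzmann(v, grid$v_half[r], grid$k[r]))^2), numeric(1))
    best <- grid[which.min(sse), ]
    expect_lt(abs(fit$v_half - best$v_half), 0.5)
    expect_lt(abs(fit$k - best$k), 0.5)
    expect_lte(fit$residual_norm^2, min(sse) + 1e-9)
  })
})

test_that("exponential activation fits recover time constants and order components", {
  t <- seq(0, 248, by = 0.2)
  y <- 4 * (1 - exp(-t / 20)) + 0.3
  fit <- fit_single_exp_activation(t, y)
  expect_equal(fit$tau_act, 20, tolerance = 1e-9)
  expect_equal(fit$i0, 4, tolerance = 1e-9)
  expect_false(fit$flagged)

  flat <- fit_single_exp_activation(t, rep(1, length(t)))
  expect_true(flat$flagged)
  expect_equal(flat$i0, 0)

  withr::with_seed(8, {
    yn <- y + rnorm(length(t), 0, 0.2)   # SNR ~ 20
    expect_equal(fit_single_exp_activation(t, yn)$tau_act, 20,
                 tolerance = 0.05)
  })

  yd <- 0.9 * (1 - exp(-t / 5)) + 0.1 * (1 - exp(-t / 50)) + 0.05
  dfit <- fit_double_exp_activation(t, yd)
  expect_equal(dfit$tau_fast, 5, tolerance = 1e-6)
  expect_equal(dfit$tau_slow, 50, tolerance = 1e-6)
  expect_equal(dfit$fast_amplitude_fraction, 0.9, tolerance = 1e-6)
  expect_lt(dfit$tau_fast, dfit$tau_slow)
  expect_false(dfit$flagged)

  # single-exponential input degenerates one amplitude
  sfit <- fit_double_exp_activation(t, y)
  expect_true(sfit$flagged)
})

test_that("F-V fits are translation-equivariant", {
  v <- seq(-140, 40, by = 10)
  withr::with_seed(21, {
    y <- boltzmann(v, -42.5, 16.8) + rnorm(length(v), 0, 0.02)
  })
  ref <- fit_boltzmann_fv(v, y)
  for (delta in c(-15, 15)) {
    shifted <- fit_boltzmann_fv(v + delta, y)
    expect_equal(shifted$v_half, ref$v_half + delta, tolerance = 1e-6)
    expect_equal(shifted$k, ref$k, tolerance = 1e-6)
  }
})

test_that("fitted slope factors stay positive under noise", {
  v <- seq(-140, 40, by = 10)
  withr::with_seed(31, {
    for (rep in 1:5) {
      y <- boltzmann(v, -40, 15) + rnorm(length(v), 0, 0.05)
      expect_gt(fit_boltzmann_fv(v, y)$k, 0)
      i <- eval_ghk_boltzmann(v, 0.25, -90, -25, 10) + rnorm(length(v), 0, 0.2)
      expect_gt(fit_iv_ghk_boltzmann(v, i)$k, 0)
    }
  })
})

test_that("relative amplitudes normalize to the daily control mean", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    day_id = c("d1", "d1", "d1", "d2", "d2", "d2"),
    treatment = c("control", "control", "cer", "control", "control", "cer"),
    peak_i_40 = c(10, 14, 6, 20, 28, 12))
  out <- relative_amplitudes(cells)
  # single-day controls average exactly 1
  d1c <- out$relative_amplitude[out$day_id == "d1" & out$treatment == "control"]
  expect_equal(mean(d1c), 1)
  # treated at half the daily control mean -> 0.5
  expect_equal(out$relative_amplitude[3], 0.5)
  # identical treated/control ratios on different days agree
  expect_equal(out$relative_amplitude[3], out$relative_amplitude[6])

  bad <- cells
  bad$treatment[4:5] <- "cer"
  expect_error(relative_amplitudes(bad), "d2")
})

test_that("kinetics fits recover the dominant fast component of fluorescence", {
  # noiseless default signal: the amplitude split is recovered exactly
  gt <- gating_ground_truth()
  t <- seq(0, 249.8, by = 0.2)
  g <- gt$fast_fraction * (1 - exp(-t / gt$tau_fast(0))) +
    (1 - gt$fast_fraction) * (1 - exp(-t / gt$tau_slow(0)))
  fit <- fit_double_exp_activation(t, gt$dff_max * boltzmann(0, gt$v_half_f, gt$k_f) * g)
  expect_equal(fit$fast_amplitude_fraction, gt$fast_fraction,
               tolerance = 1e-6)

  # closed loop at the default noise level: the minor component's amplitude
  # sits near the noise floor, so the per-fit amplitude split scatters with
  # a left skew; the median fit stays fast-dominated while the mean is
  # dragged a few points below the generating fraction
  cfg <- cohort_config("control", 6, gating_ground_truth(), seed = 1)
  res <- analyze_cohort(simulate_cohort(cfg), kinetics = TRUE)
  expect_gt(median(res$fluor_kinetics$fast_fraction), 0.85)
  expect_gt(mean(res$cells$mean_fast_fraction), 0.75)
  # recovered time constants are ordered and inside the resolvable range
  expect_true(all(res$fluor_kinetics$tau_fast < res$fluor_kinetics$tau_slow))
  # current activation time constants track the generating map
  ck <- res$current_kinetics[res$current_kinetics$converged &
                               !res$current_kinetics$flagged, ]
  gt_tau <- gating_ground_truth()$tau_act(ck$v)
  expect_lt(median(abs(ck$tau_act - gt_tau) / gt_tau), 0.1)
})

test_that("cohort fits recover generating midpoints within the group dispersion", {
  # scaled-down replicate check of closed-loop parameter recovery
  for (seed in c(11, 12)) {
    r <- recover_condition_midpoints("control", seed = seed)
    p <- condition_params("control")
    expect_lt(abs(r$mean_v_half_f - p$v_half_f), 2.5 * p$sem_v_half_f)
    expect_lt(abs(r$mean_v_half_g - p$v_half_g), 2.5 * p$sem_v_half_g)
  }
})
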