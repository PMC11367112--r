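test_that("gaussian filter has unit DC gain, normalized kernel and the right cutoff", {
  expect_equal(gaussian_filter_trace(rep(3.5, 200), 1000, 5000),
               rep(3.5, 200), tolerance = 1e-12)

  impulse <- c(rep(0, 100), 1, rep(0, 100))
  out <- gaussian_filter_trace(impulse, 500, 5000)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_true(which.max(out) == 101)  # zero phase

  # sine at the cutoff attenuated to -3 dB (within 5%)
  rate <- 5000; fc <- 250
  t <- seq(0, 1, by = 1 / rate)[-1]
  x <- sin(2 * pi * fc * t)
  y <- gaussian_filter_trace(x, fc, rate)
  att <- oracle_sine_amplitude(y, fc, rate) / oracle_sine_amplitude(x, fc, rate)
  expect_equal(att, 10^(-3 / 20), tolerance = 0.05)

  expect_error(gaussian_filter_trace(x, 2500, 5000), "Nyquist")
})

test_that("leak estimation recovers an ohmic line and ignores channel current", {
  p <- make_default_protocol()
  quiet <- gating_ground_truth(gmax = 0, noise_sd_current = 0,
                               noise_sd_fluor = 0)
  ss <- simulate_sweep_set(quiet, p, seed = 1)
  leak <- estimate_leak(ss)
  expect_equal(leak$conductance, quiet$leak_conductance, tolerance = 1e-10)
  expect_equal(leak$offset, 0, tolerance = 1e-10)

  # with the channel present, open probability below -80 mV is negligible
  gt <- gating_ground_truth(noise_sd_current = 0, noise_sd_fluor = 0)
  leak2 <- estimate_leak(simulate_sweep_set(gt, p, seed = 1))
  expect_equal(leak2$conductance, gt$leak_conductance, tolerance = 0.01)

  expect_error(estimate_leak(ss, fit_range = c(-140, -140)), "at least 2")
})

test_that("leak subtraction zeroes ohmic sweeps and is an identity at zero leak", {
  p <- short_protocol()
  quiet <- gating_ground_truth(gmax = 0, noise_sd_current = 0,
                               noise_sd_fluor = 0)
  ss <- simulate_sweep_set(quiet, p, seed = 1)
  corr <- subtract_leak(ss, list(offset = 0, conductance = quiet$leak_conductance))
  expect_equal(max(abs(corr)), 0, tolerance = 1e-12)
  expect_equal(subtract_leak(ss, list(offset = 0, conductance = 0)),
               ss$current)
})

test_that("leak estimation and subtraction are idempotent", {
  gt <- gating_ground_truth(noise_sd_fluor = 0)
  ss <- simulate_sweep_set(gt, seed = 3)
  leak1 <- estimate_leak(ss)
  once <- subtract_leak(ss, leak1)
  ss2 <- ss
  ss2$current <- once
  leak2 <- estimate_leak(ss2)
  twice <- subtract_leak(ss2, leak2)
  # second pass changes traces by far less than the noise floor
  expect_lt(max(abs(twice - once)), gt$noise_sd_current / 10)
})

test_that("photobleach correction recovers additive signals over a bleaching baseline", {
  n <- 500
  base_idx <- 1:100
  baseline <- 1000 * exp(-0.0004 * seq_len(n))
  expect_equal(correct_photobleach(baseline, baseline, base_idx),
               rep(mean(baseline[base_idx]), n))
  boxcar <- c(rep(0, 200), rep(25, 200), rep(0, 100))
  corrected <- correct_photobleach(baseline + boxcar, baseline, base_idx)
  expect_equal(corrected - mean(baseline[base_idx]), boxcar, tolerance = 1e-12)
  expect_error(correct_photobleach(baseline, baseline[-1], base_idx),
               "same length")
})

test_that("dF/F conversion and summary extraction behave per definition", {
  trace <- c(rep(100, 50), rep(102, 50))
  dff <- compute_dff(trace, 1:50)
  expect_equal(dff[100], 2)
  expect_equal(compute_dff(rep(7, 100), 1:50), rep(0, 100))
  expect_error(compute_dff(rep(-1, 100), 1:50), "positive")

  # gain invariance
  f <- 800 + cumsum(rnorm(200, sd = 0.1))
  expect_equal(compute_dff(3 * f, 1:40), compute_dff(f, 1:40),
               tolerance = 1e-12)

  pulse_idx <- 51:100
  expect_equal(extract_steady_state_dff(dff, pulse_idx), 2)
  expect_equal(extract_steady_state_dff(rep(0, 100), pulse_idx), 0)

  tm <- seq(0, 99) * 0.2
  rise <- c(rep(0, 50), 5 * (1 - exp(-(seq_len(50) * 0.2) / 2)))
  # monotone rise: peak sits at the end of the edge-guarded search window
  guard_end <- max(which(tm[pulse_idx] <= tm[pulse_idx[50]] - 2))
  expect_equal(extract_peak_current(rise, pulse_idx, tm, margin_ms = 2),
               rise[pulse_idx[guard_end]])
  expect_equal(extract_peak_current(rep(0, 100), pulse_idx, tm), 0)
})

test_that("zero-noise processing reproduces the generator's closed forms", {
  p <- make_default_protocol()
  gt <- gating_ground_truth(noise_sd_current = 0, noise_sd_fluor = 0)
  ss <- simulate_sweep_set(gt, p, seed = 1)
  t <- ss$time_ms
  pulse_idx <- pulse_indices(p)

  # unfiltered chain against exact per-sample closed forms
  corr <- subtract_leak(ss, list(offset = 0,
                                 conductance = gt$leak_conductance))
  margin <- 2
  t0 <- t[pulse_idx[1]]; t1 <- t[pulse_idx[length(pulse_idx)]]
  win <- pulse_idx[t[pulse_idx] >= t0 + margin & t[pulse_idx] <= t1 - margin]
  tend <- t[win[length(win)]] - p$pre_pulse_duration
  for (j in seq_along(ss$test_potentials)) {
    v <- ss$test_potentials[j]
    peak <- extract_peak_current(corr[, j], pulse_idx, t, margin)
    iss <- eval_ghk_boltzmann(v, gt$gmax, gt$erev, gt$v_half_g, gt$k_g)
    expected <- iss * (1 - exp(-tend / gt$tau_act(v)))
    expect_equal(peak, expected, tolerance = 1e-9)
  }

  base_idx <- which(t >= p$pre_pulse_duration - 50 & t < p$pre_pulse_duration)
  for (j in c(5, 12, 19)) {
    v <- ss$test_potentials[j]
    fc <- correct_photobleach(ss$fluorescence[, j], ss$fluorescence[, 1],
                              base_idx)
    ssdff <- extract_steady_state_dff(compute_dff(fc, base_idx), pulse_idx)
    # closed-form window mean of the double-exponential deflection
    tprime <- t[pulse_idx] - p$pre_pulse_duration
    g <- gt$fast_fraction * (1 - exp(-tprime / gt$tau_fast(v))) +
      (1 - gt$fast_fraction) * (1 - exp(-tprime / gt$tau_slow(v)))
    gb <- gt$fast_fraction * (1 - exp(-tprime / gt$tau_fast(-140))) +
      (1 - gt$fast_fraction) * (1 - exp(-tprime / gt$tau_slow(-140)))
    dff_v <- gt$dff_max * boltzmann(v, gt$v_half_f, gt$k_f)
    dff_b <- gt$dff_max * boltzmann(-140, gt$v_half_f, gt$k_f)
    nwin <- length(pulse_idx)
    keep <- seq.int(nwin - ceiling(0.1 * nwin) + 1, nwin)
    bleach <- exp(-gt$bleach_rate * t[pulse_idx][keep] / 1000)
    bleach_base <- mean(exp(-gt$bleach_rate * t[base_idx] / 1000))
    expected <- mean(bleach / bleach_base *
                       (dff_v * g[keep] - dff_b * gb[keep]))
    expect_equal(ssdff, expected, tolerance = 1e-9)
  }
})

test_that("full processing recovers generator summary points within noise", {
  gt <- gating_ground_truth()
  ss <- simulate_sweep_set(gt, seed = 7)
  proc <- process_sweep_set(ss)
  iss40 <- eval_ghk_boltzmann(40, gt$gmax, gt$erev, gt$v_half_g, gt$k_g)
  expect_equal(proc$peak_current[19], iss40, tolerance = 3 * gt$noise_sd_current / iss40)
  dff40 <- gt$dff_max * boltzmann(40, gt$v_half_f, gt$k_f)
  expect_equal(proc$steady_state_dff[19], dff40, tolerance = 0.05)
  # residual bleach drift in a no-signal sweep stays well under the signal
  expect_lt(abs(proc$steady_state_dff[2]), 0.05 * gt$dff_max)
})
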