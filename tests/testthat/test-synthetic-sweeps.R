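test_that("default protocol matches the recording convention", {
  p <- make_default_protocol()
  expect_length(test_potentials(p), 19)
  expect_equal(length(pulse_indices(p)), 1250)
  expect_equal(test_potentials(p)[1], -140)
  expect_equal(test_potentials(p)[19], 40)
  expect_equal(p$holding_potential, -100)

  expect_length(test_potentials(voltage_protocol(test_step = 20)), 10)
  expect_length(test_potentials(voltage_protocol(test_start = 0, test_end = 0)), 1)
  expect_error(voltage_protocol(test_step = 13), "divisible")
  expect_error(voltage_protocol(test_step = -10))
})

test_that("current sweeps follow leak + GHK x Boltzmann exponential rise", {
  p <- make_default_protocol()
  quiet <- function(...) gating_ground_truth(noise_sd_current = 0,
                                             noise_sd_fluor = 0, ...)
  # zero conductance: leak only
  gt0 <- quiet(gmax = 0)
  tr <- simulate_current_sweep(gt0, p, v = -20)
  expect_equal(tr, gt0$leak_conductance * command_voltage(p, -20))

  # at the reversal potential with no leak the pulse current vanishes
  gt <- quiet(leak_conductance = 0)
  expect_equal(simulate_current_sweep(gt, p, v = -90),
               rep(0, protocol_n_samples(p)))

  # value one time constant after onset equals Iss * (1 - 1/e)
  gt20 <- quiet(leak_conductance = 0, tau_act = function(v) 20)
  tr <- simulate_current_sweep(gt20, p, v = 0)
  i_at_tau <- tr[which.min(abs(protocol_times(p) - (p$pre_pulse_duration + 20)))]
  iss <- oracle_ghk(1e-9 + 0, gt20$gmax, gt20$erev, gt20$v_half_g, gt20$k_g)
  expect_equal(i_at_tau, iss * (1 - exp(-1)), tolerance = 1e-7)

  expect_error(simulate_current_sweep(gt, p, v = 80), "outside")
  expect_error(simulate_current_sweep(
    quiet(tau_act = function(v) -1), p, v = 0), "positive")
})

test_that("fluorescence sweeps follow the double-exponential Boltzmann model", {
  p <- make_default_protocol()
  gt <- gating_ground_truth(noise_sd_fluor = 0, noise_sd_current = 0,
                            bleach_rate = 0)
  # far below the F-V midpoint the deflection is under 1% of dff_max
  tr <- simulate_fluorescence_sweep(gt, p, v = -140)
  defl <- 100 * abs(max(tr) - gt$f0) / gt$f0
  expect_lt(defl, 0.01 * gt$dff_max)

  # with fast time constants the plateau reaches dff_ss exactly
  gt_fast <- gating_ground_truth(noise_sd_fluor = 0, noise_sd_current = 0,
                                 bleach_rate = 0,
                                 tau_fast = function(v) 1,
                                 tau_slow = function(v) 2)
  tr <- simulate_fluorescence_sweep(gt_fast, p, v = 40)
  plateau <- 100 * (tr[max(pulse_indices(p))] - gt_fast$f0) / gt_fast$f0
  dff_ss <- gt_fast$dff_max * boltzmann(40, gt_fast$v_half_f, gt_fast$k_f)
  expect_equal(plateau, dff_ss, tolerance = 1e-9)

  # fast_fraction = 1 degenerates to a single exponential
  gt1 <- gating_ground_truth(noise_sd_fluor = 0, noise_sd_current = 0,
                             bleach_rate = 0, fast_fraction = 1)
  tr <- simulate_fluorescence_sweep(gt1, p, v = 0)
  idx <- pulse_indices(p)
  tprime <- protocol_times(p)[idx] - p$pre_pulse_duration
  dff_ss <- gt1$dff_max * boltzmann(0, gt1$v_half_f, gt1$k_f)
  manual <- gt1$f0 * (1 + dff_ss / 100 * (1 - exp(-tprime / gt1$tau_fast(0))))
  expect_equal(tr[idx], manual, tolerance = 1e-12)
})

test_that("steady-state current is monotone in voltage above the reversal potential", {
  gt <- gating_ground_truth()
  v <- seq(-85, 40, by = 1)
  iss <- eval_ghk_boltzmann(v, gt$gmax, gt$erev, gt$v_half_g, gt$k_g)
  expect_true(all(diff(iss) >= 0))
})

test_that("cohort simulation is reproducible and honours zero variability", {
  p <- short_protocol()
  cfg <- cohort_config("control", 3, gating_ground_truth(), protocol = p,
                       seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a[[2]]$current, b[[2]]$current)
  expect_identical(a[[3]]$fluorescence, b[[3]]$fluorescence)

  # no cell_to_cell_sd: all cells share the generating parameters
  pars <- vapply(a, function(ss) c(ss$ground_truth$v_half_g,
                                   ss$ground_truth$k_f,
                                   ss$ground_truth$gmax), numeric(3))
  expect_true(all(apply(pars, 1, function(x) diff(range(x)) == 0)))

  cfg_var <- cohort_config("control", 3, gating_ground_truth(), protocol = p,
                           cell_to_cell_sd = list(v_half_g = 4), seed = 42)
  vh <- vapply(simulate_cohort(cfg_var),
               function(ss) ss$ground_truth$v_half_g, numeric(1))
  expect_gt(diff(range(vh)), 0)
})

test_that("probe intensity generators invert their formulas exactly at zero noise", {
  # isotropic case: Ivv equals Ivh when G = 1
  q0 <- simulate_polarized_intensities(0, g_true = 1, noise_sd = 0, n = 2)
  expect_equal(q0$ivv, q0$ivh)

  # round-trip identities at reported group values
  for (r_true in c(0.283, 0.300, 0.295)) {
    q <- simulate_polarized_intensities(r_true, g_true = 1.13, noise_sd = 0,
                                        n = 3)
    g <- g_factor(q$ihv, q$ihh)
    expect_equal(g, rep(1.13, 3), tolerance = 1e-12)
    expect_equal(anisotropy(q$ivv, q$ivh, g), rep(r_true, 3),
                 tolerance = 1e-12)
  }
  # near the r -> 1 pole the construction stays finite and positive
  q <- simulate_polarized_intensities(0.9999, noise_sd = 0, n = 1)
  expect_true(is.finite(q$ivv) && q$ivv > 0)
  expect_equal(q$ivv / (1.1 * q$ivh), (1 + 2 * 0.9999) / (1 - 0.9999),
               tolerance = 1e-9)
  expect_error(simulate_polarized_intensities(1.2), "r_true")
  expect_error(simulate_polarized_intensities(-0.5), "r_true")

  p0 <- simulate_gp_intensities(0, noise_sd = 0, n = 2)
  expect_equal(p0$i_blue, p0$i_red)
  for (gp_true in c(0.182, 0.202, 0.192)) {
    pr <- simulate_gp_intensities(gp_true, noise_sd = 0, n = 3)
    expect_equal(generalized_polarization(pr$i_blue, pr$i_red),
                 rep(gp_true, 3), tolerance = 1e-12)
  }
  pr <- simulate_gp_intensities(-0.5, noise_sd = 0, n = 1)
  expect_equal(pr$i_blue / pr$i_red, 1 / 3, tolerance = 1e-12)
  expect_error(simulate_gp_intensities(1), "gp_true")
})

test_that("image generator produces exact-ratio rings, masks and seeds", {
  img <- simulate_ratio_images(2.0, n_cells = 4, image_size = c(160, 160),
                               background_level = 0, noise_sd = 0, seed = 5)
  ring <- img$membrane_true
  expect_true(all(abs(img$channel_blue[ring] / img$channel_red[ring] - 2) < 1e-12))
  expect_equal(max(img$labels_true), 4)
  expect_equal(sum(img$seeds$kind == "cell"), 4)
  expect_gte(sum(img$seeds$kind == "background"), 1)

  # determinism
  img2 <- simulate_ratio_images(2.0, n_cells = 4, image_size = c(160, 160),
                                background_level = 0, noise_sd = 0, seed = 5)
  expect_identical(img$channel_red, img2$channel_red)

  # degenerate and impossible geometries
  empty <- simulate_ratio_images(2.0, n_cells = 0, image_size = c(128, 128),
                                 seed = 1)
  expect_true(all(empty$labels_true == 0))
  expect_error(extract_membrane_mask(empty$labels_true), "no cells")
  expect_error(simulate_ratio_images(2.0, n_cells = 3,
                                     image_size = c(40, 40), seed = 1),
               "too small")
})
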