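#' Closed-loop midpoint recovery for one study condition
#'
#' Simulates a cohort at a condition's ground-truth parameters
#' ([condition_cohort_config()]), runs the full trace-processing and fitting
#' pipeline, and summarises the recovered Boltzmann midpoints. This is the
#' study's core verification loop: the recordings themselves are not
#' deposited, so every stage is validated by recovering known generating
#' parameters.
#'
#' @inheritParams condition_params
#' @param seed Integer RNG seed for the cohort.
#' @param n_cells Number of cells; defaults to the condition's group size.
#' @param kinetics Also fit activation kinetics.
#' @return List with `cells` (per-cell table), `mean_v_half_f`,
#'   `mean_v_half_g`, `sem_v_half_f`, `sem_v_half_g` and (with kinetics) the
#'   kinetics tables.
#' @export
recover_condition_midpoints <- function(condition, seed, n_cells = NULL,
                                        kinetics = FALSE) {
  cfg <- condition_cohort_config(condition, seed = seed, n_cells = n_cells)
  cohort <- simulate_cohort(cfg)
  res <- analyze_cohort(cohort, kinetics = kinetics)
  cells <- res$cells
  sem <- function(x) sd(x) / sqrt(length(x))
  out <- list(cells = cells,
              mean_v_half_f = mean(cells$v_half_f),
              sem_v_half_f = sem(cells$v_half_f),
              mean_v_half_g = mean(cells$v_half_g),
              sem_v_half_g = sem(cells$v_half_g),
              mean_k_f = mean(cells$k_f),
              mean_k_g = mean(cells$k_g))
  if (kinetics) {
    out$current_kinetics <- res$current_kinetics
    out$fluor_kinetics <- res$fluor_kinetics
    out$mean_fast_fraction <- mean(cells$mean_fast_fraction, na.rm = TRUE)
  }
  out
}

#' Day-structured relative-amplitude study
#'
#' Simulates one recording day holding control cells and ceramide-treated
#' cells whose maximal conductance is scaled by the treated group's relative
#' current amplitude, then runs leak correction, +40 mV peak extraction and
#' daily-control normalization.
#'
#' @param seed Integer RNG seed.
#' @param treated Condition label of the treated group.
#' @param n_control,n_treated Group sizes (defaults: the study's amplitude
#'   group sizes).
#' @return List with `cells` (incl. `relative_amplitude`) and
#'   `mean_relative_amplitude` of the treated group.
#' @export
run_amplitude_study <- function(seed, treated = "cer", n_control = NULL,
                                n_treated = NULL) {
  pc <- condition_params("control")
  pt <- condition_params(treated)
  n_control <- n_control %||% pc$n_amplitude
  n_treated <- n_treated %||% pt$n_amplitude
  sd_frac_c <- pc$sem_rel_amplitude * sqrt(pc$n_amplitude)
  sd_frac_t <- pt$sem_rel_amplitude * sqrt(pt$n_amplitude)
  gt_c <- gating_ground_truth()
  gt_t <- gating_ground_truth(gmax = gt_c$gmax * pt$rel_amplitude,
                              v_half_g = pt$v_half_g, k_g = pt$k_g,
                              v_half_f = pt$v_half_f, k_f = pt$k_f)
  cfg_c <- cohort_config("control", n_control, gt_c,
                         cell_to_cell_sd = list(gmax_frac = sd_frac_c),
                         seed = seed, day_id = "day1")
  cfg_t <- cohort_config(treated, n_treated, gt_t,
                         cell_to_cell_sd = list(gmax_frac = sd_frac_t),
                         seed = seed + 1L, day_id = "day1")
  cohort <- c(simulate_cohort(cfg_c), simulate_cohort(cfg_t))
  cells <- analyze_cohort(cohort)$cells
  cells <- relative_amplitudes(cells)
  list(cells = cells,
       mean_relative_amplitude =
         mean(cells$relative_amplitude[cells$treatment == treated]))
}

#' Closed-loop membrane-probe recovery
#'
#' Generates synthetic spectrofluorometer intensity sets at a condition's
#' ground-truth anisotropy or generalized polarization and recomputes the
#' probe statistic per sample.
#'
#' @inheritParams condition_params
#' @param assay `"anisotropy"` (TMA-DPH quadruples) or `"gp"` (Laurdan
#'   emission pairs).
#' @param seed Integer RNG seed.
#' @param n Number of samples (default: the study's probe group size).
#' @param g_true G-factor used for quadruple generation.
#' @param noise_sd Multiplicative intensity noise SD.
#' @return List with `values` (per-sample statistic) and `mean`.
#' @export
run_probe_study <- function(condition, assay = c("anisotropy", "gp"), seed,
                            n = NULL, g_true = 1.1,
                            noise_sd = if (assay == "anisotropy") 0.005 else 0.01) {
  assay <- match.arg(assay)
  p <- condition_params(condition)
  n <- n %||% p$n_probe
  if (assay == "anisotropy") {
    quads <- simulate_polarized_intensities(p$anisotropy, g_true = g_true,
                                            noise_sd = noise_sd, n = n,
                                            seed = seed)
    vals <- anisotropy_from_quadruples(quads, g_mode = "per_sample")$r
  } else {
    pairs <- simulate_gp_intensities(p$gp, noise_sd = noise_sd, n = n,
                                     seed = seed)
    vals <- gp_from_pairs(pairs)$gp
  }
  list(values = vals, mean = mean(vals))
}

#' Closed-loop imaging-ratio recovery for one condition
#'
#' Generates synthetic two-channel image pairs at a condition's ground-truth
#' excitation ratio and runs the full dipole-imaging pipeline (seeded
#' watershed, membrane masking, background subtraction, pixelwise ratio) on
#' each, returning the per-image mean ratios.
#'
#' @inheritParams condition_params
#' @param seed Base RNG seed; image `i` uses `seed + i - 1`.
#' @param n_images Number of image pairs (default: the study's image count).
#' @param n_cells_range Cells per image, drawn uniformly from this range.
#' @param image_size,background_level,noise_sd,band_width_px See
#'   [simulate_ratio_images()] / [segment_ratio_image()].
#' @return List with `image_means` (one per image) and `mean_ratio`.
#' @export
run_dipole_study <- function(condition, seed, n_images = NULL,
                             n_cells_range = c(30, 40),
                             image_size = c(512, 512),
                             background_level = 50, noise_sd = 3,
                             band_width_px = 3) {
  p <- condition_params(condition)
  n_images <- n_images %||% p$n_images
  means <- vapply(seq_len(n_images), function(i) {
    n_cells <- withr::with_seed(seed + i - 1L,
                                sample(seq(n_cells_range[1], n_cells_range[2]), 1))
    img <- simulate_ratio_images(p$rexc, n_cells = n_cells,
                                 image_size = image_size,
                                 background_level = background_level,
                                 noise_sd = noise_sd, seed = seed + i - 1L)
    run_dipole_image(img, band_width_px = band_width_px)$rexc$mean_ratio
  }, numeric(1))
  list(image_means = means, mean_ratio = mean(means))
}

#' Run the complete synthetic study
#'
#' Executes every closed-loop recovery of the synthetic study from one master
#' seed: F-V and G-V midpoint recovery for the conditions with reported
#' midpoints, the day-structured relative-amplitude study, the anisotropy and
#' generalized-polarization recoveries, and the three imaging-ratio
#' recoveries. Sub-seeds for the individual stages are derived
#' deterministically from the master seed.
#'
#' @param seed Master integer seed.
#' @param n_images Images per condition for the dipole stage (default 20,
#'   the study's image count).
#' @return Named list of recovered group means, each a list with `value` and
#'   `n` (cells, samples or images entering the mean).
#' @export
run_full_study <- function(seed, n_images = NULL) {
  base <- (as.integer(seed) %% 100000L) * 1000L
  fv_ctrl <- recover_condition_midpoints("control", seed = base + 1L)
  gv_ctrl <- recover_condition_midpoints("control", seed = base + 2L)
  fv_cer <- recover_condition_midpoints("cer", seed = base + 3L)
  fv_glc <- recover_condition_midpoints("glccer", seed = base + 4L)
  gv_cer <- recover_condition_midpoints("cer", seed = base + 5L)
  amp <- run_amplitude_study(seed = base + 6L)
  r_ctrl <- run_probe_study("control", "anisotropy", seed = base + 7L)
  r_cer <- run_probe_study("cer", "anisotropy", seed = base + 8L)
  gp_cer <- run_probe_study("cer", "gp", seed = base + 9L)
  dp_ctrl <- run_dipole_study("control", seed = base + 100L,
                              n_images = n_images)
  dp_cer <- run_dipole_study("cer", seed = base + 200L,
                             n_images = n_images)
  dp_glc <- run_dipole_study("glccer", seed = base + 300L,
                             n_images = n_images)
  list(
    fv_vhalf_control = list(value = fv_ctrl$mean_v_half_f,
                            n = nrow(fv_ctrl$cells)),
    gv_vhalf_control = list(value = gv_ctrl$mean_v_half_g,
                            n = nrow(gv_ctrl$cells)),
    fv_vhalf_cer = list(value = fv_cer$mean_v_half_f, n = nrow(fv_cer$cells)),
    fv_vhalf_glccer = list(value = fv_glc$mean_v_half_f,
                           n = nrow(fv_glc$cells)),
    gv_vhalf_cer = list(value = gv_cer$mean_v_half_g, n = nrow(gv_cer$cells)),
    rel_amplitude_cer = list(
      value = amp$mean_relative_amplitude,
      n = sum(amp$cells$treatment == "cer")),
    anisotropy_control = list(value = r_ctrl$mean, n = length(r_ctrl$values)),
    anisotropy_cer = list(value = r_cer$mean, n = length(r_cer$values)),
    gp_cer = list(value = gp_cer$mean, n = length(gp_cer$values)),
    rexc_control = list(value = dp_ctrl$mean_ratio,
                        n = length(dp_ctrl$image_means)),
    rexc_cer = list(value = dp_cer$mean_ratio,
                    n = length(dp_cer$image_means)),
    rexc_glccer = list(value = dp_glc$mean_ratio,
                       n = length(dp_glc$image_means)))
}

#' Draw per-cell midpoint samples for the three conditions
#'
#' Lightweight sampler used for significance-pattern replication: draws
#' per-cell F-V (or G-V) midpoints directly from each condition's
#' between-cell distribution without simulating traces.
#'
#' @param which `"f"` or `"g"`: which relationship's midpoints to draw.
#' @param seed Integer RNG seed.
#' @return Data frame with `value` and `group`.
#' @export
draw_condition_midpoints <- function(which = c("f", "g"), seed) {
  which <- match.arg(which)
  withr::with_seed(seed, {
    out <- lapply(c("control", "cer", "glccer"), function(cond) {
      p <- condition_params(cond)
      mu <- if (which == "f") p$v_half_f else p$v_half_g
      sem <- if (which == "f") p$sem_v_half_f else p$sem_v_half_g
      data.frame(value = rnorm(p$n_cells, mu, sem * sqrt(p$n_cells)),
                 group = cond)
    })
    do.call(rbind, out)
  })
}
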