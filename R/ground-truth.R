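#' Ground-truth gating parameters for the synthetic generator
#'
#' Collects every parameter the sweep simulator needs: the steady-state
#' conductance model (GHK rectification x Boltzmann), the fluorescence
#' steady-state Boltzmann, activation time constants as functions of voltage,
#' and the nuisance terms (leak, bleach, noise).
#'
#' Voltage dependence of the time constants is a synthetic convention: the
#' experimental values are only displayed graphically, so the defaults decay
#' mono-exponentially with depolarization, matching the qualitative pattern of
#' faster activation at more positive potentials.
#'
#' @param gmax Maximal conductance (microsiemens).
#' @param erev Reversal potential (mV).
#' @param v_half_g,k_g Half-activation voltage and slope factor of the
#'   conductance Boltzmann (mV).
#' @param v_half_f,k_f Half-activation voltage and slope factor of the
#'   fluorescence Boltzmann (mV).
#' @param tau_act Function of voltage (mV) returning the current activation
#'   time constant (ms).
#' @param tau_fast,tau_slow Functions of voltage returning the fast and slow
#'   fluorescence activation time constants (ms); `tau_fast(V) < tau_slow(V)`
#'   is required over the protocol range.
#' @param fast_fraction Amplitude fraction of the fast fluorescence component,
#'   in (0, 1]; the experimental signal is dominated (>85%) by the fast
#'   component.
#' @param dff_max Maximal steady-state dF/F (percent; magnitude).
#' @param dff_sign Sign of the depolarization-evoked fluorescence deflection
#'   (+1 or -1); the saturating deflection direction is a convention.
#' @param f0 Pre-pulse baseline fluorescence (a.u.).
#' @param leak_conductance Ohmic leak conductance (microsiemens).
#' @param bleach_rate Mono-exponential photobleaching rate (1/s).
#' @param noise_sd_current Additive Gaussian current noise SD (microamperes).
#' @param noise_sd_fluor Multiplicative Gaussian fluorescence noise SD,
#'   as a fraction of the instantaneous intensity.
#' @param capacitive_amplitude Amplitude of an optional 1-ms decaying
#'   capacitive spike at the pulse edges (microamperes per 100 mV of step);
#'   0 disables it (default).
#' @return An object of class `gating_ground_truth`.
#' @export
gating_ground_truth <- function(gmax = 0.25, erev = -90,
                                v_half_g = -25.4, k_g = 9.6,
                                v_half_f = -42.5, k_f = 16.8,
                                tau_act = function(v) 2 + 10 * exp(-(v + 10) / 50),
                                tau_fast = function(v) 4 + 8 * exp(-(v + 10) / 50),
                                tau_slow = function(v) 4 * (4 + 8 * exp(-(v + 10) / 50)),
                                fast_fraction = 0.9,
                                dff_max = 10, dff_sign = 1, f0 = 1000,
                                leak_conductance = 0.01,
                                bleach_rate = 0.02,
                                noise_sd_current = 0.1,
                                noise_sd_fluor = 0.005,
                                capacitive_amplitude = 0) {
  stopifnot(k_g > 0, k_f > 0, gmax >= 0, fast_fraction > 0, fast_fraction <= 1,
            f0 > 0, dff_sign %in% c(-1, 1), bleach_rate >= 0,
            noise_sd_current >= 0, noise_sd_fluor >= 0)
  vgrid <- seq(-140, 40, by = 10)
  if (any(tau_act(vgrid) <= 0) || any(tau_fast(vgrid) <= 0) ||
      any(tau_slow(vgrid) <= 0))
    stop("time constants must be positive over the protocol range")
  if (any(tau_fast(vgrid) >= tau_slow(vgrid)))
    stop("tau_fast must be strictly smaller than tau_slow at every voltage")
  structure(list(gmax = gmax, erev = erev,
                 v_half_g = v_half_g, k_g = k_g,
                 v_half_f = v_half_f, k_f = k_f,
                 tau_act = tau_act, tau_fast = tau_fast, tau_slow = tau_slow,
                 fast_fraction = fast_fraction,
                 dff_max = dff_max, dff_sign = dff_sign, f0 = f0,
                 leak_conductance = leak_conductance,
                 bleach_rate = bleach_rate,
                 noise_sd_current = noise_sd_current,
                 noise_sd_fluor = noise_sd_fluor,
                 capacitive_amplitude = capacitive_amplitude),
            class = "gating_ground_truth")
}

#' Study-condition parameter presets
#'
#' Group-level parameters of the three experimental conditions (untreated
#' control, C16-ceramide "cer" and C16-glucosylceramide "glccer") used as
#' ground truth by the synthetic study: Boltzmann midpoints and slopes of the
#' conductance-voltage (G-V) and fluorescence-voltage (F-V) relationships with
#' their reported SEM and group sizes, the relative current amplitude (maximal
#' conductance scale), the TMA-DPH anisotropy, the Laurdan generalized
#' polarization, and the di-8-ANEPPS excitation ratio.
#'
#' Between-cell SDs are reconstructed from the reported SEM as `SEM * sqrt(n)`
#' so that simulated cohorts reproduce the reported dispersion.
#'
#' @param condition One of `"control"`, `"cer"`, `"glccer"`.
#' @return A list of group parameters.
#' @export
condition_params <- function(condition = c("control", "cer", "glccer")) {
  condition <- match.arg(condition)
  tab <- list(
    control = list(
      n_cells = 12,
      v_half_g = -25.4, sem_v_half_g = 1.2, k_g = 9.6, sem_k_g = 0.5,
      v_half_f = -42.5, sem_v_half_f = 1.0, k_f = 16.8, sem_k_f = 0.4,
      rel_amplitude = 1.000, sem_rel_amplitude = 0.041, n_amplitude = 14,
      anisotropy = 0.283, gp = 0.182, n_probe = 9,
      rexc = 0.620, n_images = 20),
    cer = list(
      n_cells = 10,
      v_half_g = -17.1, sem_v_half_g = 1.3, k_g = 11.5, sem_k_g = 0.9,
      v_half_f = -35.7, sem_v_half_f = 0.9, k_f = 17.7, sem_k_f = 0.4,
      rel_amplitude = 0.637, sem_rel_amplitude = 0.036, n_amplitude = 12,
      anisotropy = 0.300, gp = 0.202, n_probe = 9,
      rexc = 0.598, n_images = 20),
    glccer = list(
      n_cells = 11,
      v_half_g = -18.2, sem_v_half_g = 1.9, k_g = 9.8, sem_k_g = 0.5,
      v_half_f = -42.7, sem_v_half_f = 0.7, k_f = 17.4, sem_k_f = 0.4,
      rel_amplitude = 0.707, sem_rel_amplitude = 0.044, n_amplitude = 12,
      anisotropy = 0.295, gp = 0.192, n_probe = 9,
      rexc = 0.647, n_images = 20))
  c(list(condition = condition), tab[[condition]])
}

#' Synthetic cohort configuration
#'
#' Bundles everything [simulate_cohort()] needs: the shared ground truth, the
#' voltage protocol, the number of cells, per-parameter between-cell SDs and
#' the RNG seed (recorded in the output metadata).
#'
#' @param treatment_label Group label (e.g. "control").
#' @param n_cells Number of cells to simulate (>= 1).
#' @param ground_truth A [gating_ground_truth()] giving the group means.
#' @param protocol A [voltage_protocol()].
#' @param cell_to_cell_sd Named list of between-cell SDs; recognised names are
#'   `v_half_g`, `k_g`, `v_half_f`, `k_f` (mV) and `gmax_frac` (SD of the
#'   multiplicative conductance scale). Unlisted parameters do not vary.
#' @param seed Integer RNG seed.
#' @param day_id Recording-day label (for daily-control normalization).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(treatment_label, n_cells, ground_truth,
                          protocol = make_default_protocol(),
                          cell_to_cell_sd = list(), seed = 1L,
                          day_id = "day1") {
  stopifnot(n_cells >= 1, inherits(ground_truth, "gating_ground_truth"),
            inherits(protocol, "voltage_protocol"))
  known <- c("v_half_g", "k_g", "v_half_f", "k_f", "gmax_frac")
  if (length(cell_to_cell_sd) && !all(names(cell_to_cell_sd) %in% known))
    stop("unknown cell_to_cell_sd entries: ",
         paste(setdiff(names(cell_to_cell_sd), known), collapse = ", "))
  structure(list(treatment_label = treatment_label, n_cells = n_cells,
                 ground_truth = ground_truth, protocol = protocol,
                 cell_to_cell_sd = cell_to_cell_sd,
                 seed = as.integer(seed), day_id = day_id),
            class = "cohort_config")
}

#' Cohort configuration for a named study condition
#'
#' Builds a [cohort_config()] whose ground truth and between-cell variability
#' reproduce one of the study conditions (see [condition_params()]): Boltzmann
#' parameters set to the group means, between-cell SD equal to `SEM * sqrt(n)`,
#' and the maximal conductance scaled by the group's relative current
#' amplitude.
#'
#' @inheritParams condition_params
#' @param seed Integer RNG seed.
#' @param n_cells Number of cells; defaults to the group size of the condition.
#' @param gmax_control Control-group maximal conductance (microsiemens).
#' @param day_id Recording-day label.
#' @return A [cohort_config()].
#' @export
condition_cohort_config <- function(condition, seed, n_cells = NULL,
                                    gmax_control = 0.25, day_id = "day1") {
  p <- condition_params(condition)
  n_cells <- n_cells %||% p$n_cells
  gt <- gating_ground_truth(gmax = gmax_control * p$rel_amplitude,
                            v_half_g = p$v_half_g, k_g = p$k_g,
                            v_half_f = p$v_half_f, k_f = p$k_f)
  cohort_config(
    treatment_label = p$condition, n_cells = n_cells, ground_truth = gt,
    cell_to_cell_sd = list(
      v_half_g = p$sem_v_half_g * sqrt(p$n_cells),
      k_g = p$sem_k_g * sqrt(p$n_cells),
      v_half_f = p$sem_v_half_f * sqrt(p$n_cells),
      k_f = p$sem_k_f * sqrt(p$n_cells),
      gmax_frac = p$sem_rel_amplitude * sqrt(p$n_amplitude)),
    seed = seed, day_id = day_id)
}
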