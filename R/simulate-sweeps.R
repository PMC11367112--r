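#' Simulate one current sweep
#'
#' Current is the sum of an ohmic leak through the commanded voltage, a
#' channel current that rises mono-exponentially during the pulse towards the
#' GHK x Boltzmann steady state at the test potential, an optional decaying
#' capacitive spike at the pulse edges, and additive Gaussian noise.
#'
#' @param gt A [gating_ground_truth()].
#' @param protocol A [voltage_protocol()].
#' @param v Test potential of the sweep (mV); must lie within the protocol
#'   range.
#' @param seed Optional integer seed; when given, the sweep is generated under
#'   a local RNG state and is fully reproducible.
#' @return Numeric vector of current samples (microamperes).
#' @export
simulate_current_sweep <- function(gt, protocol, v, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_current_sweep(gt, protocol, v)))
  stopifnot(inherits(gt, "gating_ground_truth"), inherits(protocol, "voltage_protocol"))
  if (v < protocol$test_start - 1e-9 || v > protocol$test_end + 1e-9)
    stop("test potential outside the protocol range")
  if (protocol$sample_rate <= 0) stop("sample_rate must be positive")
  tau <- gt$tau_act(v)
  if (tau <= 0) stop("tau_act must be positive")
  t <- protocol_times(protocol)
  idx <- pulse_indices(protocol)
  vcmd <- command_voltage(protocol, v)
  i <- gt$leak_conductance * vcmd
  iss <- eval_ghk_boltzmann(v, gt$gmax, gt$erev, gt$v_half_g, gt$k_g)
  tprime <- t[idx] - protocol$pre_pulse_duration
  i[idx] <- i[idx] + iss * (1 - exp(-tprime / tau))
  if (gt$capacitive_amplitude > 0) {
    dv <- (v - protocol$holding_potential) / 100
    amp <- gt$capacitive_amplitude * dv
    i[idx] <- i[idx] + amp * exp(-tprime)
    post <- setdiff(seq_along(t), seq_len(max(idx)))
    post <- post[post > max(idx)]
    if (length(post))
      i[post] <- i[post] - amp * exp(-(t[post] - t[max(idx)]))
  }
  if (gt$noise_sd_current > 0)
    i <- i + rnorm(length(i), 0, gt$noise_sd_current)
  i
}

#' Simulate one fluorescence sweep
#'
#' The baseline intensity `f0` decays mono-exponentially with the bleach rate
#' over the whole sweep. During the pulse the intensity is deflected by a
#' voltage-dependent steady-state dF/F (Boltzmann in the test potential)
#' approached as the sum of a fast and a slow saturating exponential, with the
#' fast component carrying `fast_fraction` of the amplitude. Noise is
#' multiplicative Gaussian.
#'
#' @inheritParams simulate_current_sweep
#' @return Numeric vector of fluorescence samples (a.u.).
#' @export
simulate_fluorescence_sweep <- function(gt, protocol, v, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_fluorescence_sweep(gt, protocol, v)))
  stopifnot(inherits(gt, "gating_ground_truth"), inherits(protocol, "voltage_protocol"))
  if (v < protocol$test_start - 1e-9 || v > protocol$test_end + 1e-9)
    stop("test potential outside the protocol range")
  tf <- gt$tau_fast(v); ts <- gt$tau_slow(v)
  if (tf <= 0 || ts <= 0) stop("fluorescence time constants must be positive")
  t <- protocol_times(protocol)
  idx <- pulse_indices(protocol)
  dff_ss <- gt$dff_sign * gt$dff_max *
    boltzmann(v, gt$v_half_f, gt$k_f)          # percent
  g <- numeric(length(t))
  tprime <- t[idx] - protocol$pre_pulse_duration
  g[idx] <- gt$fast_fraction * (1 - exp(-tprime / tf)) +
    (1 - gt$fast_fraction) * (1 - exp(-tprime / ts))
  f <- gt$f0 * exp(-gt$bleach_rate * t / 1000) * (1 + dff_ss / 100 * g)
  if (gt$noise_sd_fluor > 0)
    f <- f * (1 + rnorm(length(f), 0, gt$noise_sd_fluor))
  f
}

#' Simulate a full sweep set for one cell
#'
#' @inheritParams simulate_current_sweep
#' @param cell_id,treatment_label,day_id Metadata labels.
#' @return A `sweep_set`: shared time base, test potentials, and current /
#'   fluorescence sample matrices (samples x sweeps), with the generating
#'   ground truth attached as metadata.
#' @export
simulate_sweep_set <- function(gt, protocol = make_default_protocol(),
                               cell_id = "cell1", treatment_label = "control",
                               day_id = "day1", seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_sweep_set(
    gt, protocol, cell_id, treatment_label, day_id)))
  vs <- test_potentials(protocol)
  cur <- vapply(vs, function(v) simulate_current_sweep(gt, protocol, v),
                numeric(protocol_n_samples(protocol)))
  flu <- vapply(vs, function(v) simulate_fluorescence_sweep(gt, protocol, v),
                numeric(protocol_n_samples(protocol)))
  sweep_set(cell_id = cell_id, treatment_label = treatment_label,
            day_id = day_id, protocol = protocol, test_potentials = vs,
            current = cur, fluorescence = flu, ground_truth = gt)
}

#' Construct a sweep set
#'
#' Container for the time-aligned two-channel recordings of one cell: one
#' current and one fluorescence trace per test potential on a shared time
#' base.
#'
#' @param cell_id,treatment_label,day_id Metadata labels.
#' @param protocol A [voltage_protocol()].
#' @param test_potentials Strictly increasing test potentials (mV).
#' @param current,fluorescence Sample matrices (samples x sweeps).
#' @param ground_truth Optional [gating_ground_truth()] metadata.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(cell_id, treatment_label, day_id, protocol,
                      test_potentials, current, fluorescence,
                      ground_truth = NULL) {
  current <- as.matrix(current); fluorescence <- as.matrix(fluorescence)
  n <- protocol_n_samples(protocol)
  stopifnot(nrow(current) == n, nrow(fluorescence) == n,
            ncol(current) == length(test_potentials),
            ncol(fluorescence) == length(test_potentials),
            !is.unsorted(test_potentials, strictly = TRUE))
  structure(list(cell_id = cell_id, treatment_label = treatment_label,
                 day_id = day_id, protocol = protocol,
                 test_potentials = test_potentials,
                 time_ms = protocol_times(protocol),
                 current = current, fluorescence = fluorescence,
                 ground_truth = ground_truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set %s (%s, %s): %d sweeps x %d samples\n",
              x$cell_id, x$treatment_label, x$day_id,
              length(x$test_potentials), nrow(x$current)))
  invisible(x)
}

#' Simulate a cohort of cells
#'
#' Draws per-cell parameters from the ground truth perturbed by independent
#' Gaussian between-cell variability (truncated to valid ranges), then
#' simulates a full sweep set per cell. The true per-cell parameters and the
#' seed are stored in each sweep set's metadata; identical configurations give
#' bit-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List of `sweep_set` objects.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sdl <- config$cell_to_cell_sd
  gt0 <- config$ground_truth
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_cells), function(i) {
      gt <- gt0
      perturb <- function(x, sd, lower = -Inf) {
        if (is.null(sd) || sd == 0) return(x)
        max(x + rnorm(1, 0, sd), lower)
      }
      gt$v_half_g <- perturb(gt0$v_half_g, sdl$v_half_g)
      gt$k_g <- perturb(gt0$k_g, sdl$k_g, lower = 1)
      gt$v_half_f <- perturb(gt0$v_half_f, sdl$v_half_f)
      gt$k_f <- perturb(gt0$k_f, sdl$k_f, lower = 1)
      if (!is.null(sdl$gmax_frac) && sdl$gmax_frac > 0)
        gt$gmax <- gt0$gmax * max(1 + rnorm(1, 0, sdl$gmax_frac), 0.05)
      ss <- simulate_sweep_set(
        gt, config$protocol,
        cell_id = sprintf("%s_%02d", config$treatment_label, i),
        treatment_label = config$treatment_label, day_id = config$day_id)
      ss$seed <- config$seed
      ss
    })
  })
}
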