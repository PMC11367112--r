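#' Zero-phase Gaussian low-pass filter
#'
#' Smooths a trace with a symmetric Gaussian kernel whose temporal SD is
#' chosen so that the filter's -3 dB amplitude point equals `cutoff_hz`
#' (`sigma = sqrt(log(2)) / (2 * pi * cutoff)` seconds). The kernel is
#' normalised to unit sum (DC gain 1) and the trace is reflected at both ends
#' so the output has the input's length.
#'
#' @param trace Numeric vector.
#' @param cutoff_hz -3 dB cutoff frequency (Hz); must be below Nyquist.
#' @param sample_rate_hz Sampling rate (Hz).
#' @return Filtered trace, same length as the input.
#' @export
gaussian_filter_trace <- function(trace, cutoff_hz, sample_rate_hz) {
  stopifnot(cutoff_hz > 0, sample_rate_hz > 0)
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency")
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_hz) * sample_rate_hz  # samples
  hw <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-hw):hw)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(trace)
  if (n <= hw + 1) return(trace)
  padded <- c(rev(trace[2:(hw + 1)]), trace, rev(trace[(n - hw):(n - 1)]))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(hw + 1):(hw + n)])
}

#' Estimate the ohmic leak from subthreshold sweeps
#'
#' Fits an ordinary least-squares line through (test potential, mean pulse
#' current) over the sweeps whose test potential falls in `fit_range`, a
#' range where channel open probability is negligible.
#'
#' @param sweeps A `sweep_set`.
#' @param fit_range `c(lo, hi)` voltage range of qualifying sweeps (mV).
#' @param margin_ms Initial pulse interval excluded from the mean (ms),
#'   guarding against capacitive transients.
#' @return List with `offset` (microamperes) and `conductance`
#'   (microsiemens).
#' @export
estimate_leak <- function(sweeps, fit_range = c(-140, -80), margin_ms = 2) {
  stopifnot(inherits(sweeps, "sweep_set"))
  sel <- which(sweeps$test_potentials >= fit_range[1] &
                 sweeps$test_potentials <= fit_range[2])
  if (length(sel) < 2)
    stop("need at least 2 sweeps with test potential in the leak fit range")
  idx <- pulse_indices(sweeps$protocol)
  t <- sweeps$time_ms
  idx <- idx[t[idx] >= sweeps$protocol$pre_pulse_duration + margin_ms]
  v <- sweeps$test_potentials[sel]
  i_mean <- colMeans(sweeps$current[idx, sel, drop = FALSE])
  fit <- lm(i_mean ~ v)
  list(offset = unname(coef(fit)[1]), conductance = unname(coef(fit)[2]))
}

#' Subtract the leak current from every sweep
#'
#' `corrected(t) = raw(t) - (offset + conductance * V_command(t))`, using the
#' commanded voltage at each sample.
#'
#' @param sweeps A `sweep_set`.
#' @param leak_params List with `offset` and `conductance` (see
#'   [estimate_leak()]).
#' @return Matrix of leak-corrected currents (samples x sweeps).
#' @export
subtract_leak <- function(sweeps, leak_params) {
  stopifnot(is.finite(leak_params$offset), is.finite(leak_params$conductance))
  out <- sweeps$current
  for (j in seq_along(sweeps$test_potentials)) {
    vcmd <- command_voltage(sweeps$protocol, sweeps$test_potentials[j])
    out[, j] <- out[, j] - (leak_params$offset + leak_params$conductance * vcmd)
  }
  out
}

#' Photobleach correction by baseline-trace subtraction
#'
#' Subtracts a baseline fluorescence trace exhibiting no voltage-dependent
#' change (same bleach envelope) and restores the absolute level by adding
#' back the baseline's mean over the pre-pulse window, so that subsequent
#' dF/F denominators stay meaningful.
#'
#' @param fluor_trace,baseline_trace Traces on the same time base.
#' @param baseline_idx Sample indices of the pre-pulse baseline window.
#' @return Corrected trace.
#' @export
correct_photobleach <- function(fluor_trace, baseline_trace, baseline_idx) {
  if (length(fluor_trace) != length(baseline_trace))
    stop("trace and baseline must have the same length")
  fluor_trace - baseline_trace + mean(baseline_trace[baseline_idx])
}

#' Fractional fluorescence change (dF/F, percent)
#'
#' `100 * (trace - F) / F` with `F` the mean over the pre-pulse baseline
#' window.
#'
#' @param trace Bleach-corrected fluorescence trace.
#' @param baseline_idx Sample indices of the baseline window.
#' @return dF/F trace in percent.
#' @export
compute_dff <- function(trace, baseline_idx) {
  f <- mean(trace[baseline_idx])
  if (!is.finite(f) || f <= 0)
    stop("baseline fluorescence must be positive")
  100 * (trace - f) / f
}

#' Peak current of one sweep
#'
#' Signed extremum of the (filtered, leak-corrected) current within the pulse
#' window. The capacitive-exclusion margin is applied at both pulse edges:
#' step transients (and the filter's smearing of the voltage steps) occur at
#' the onset and at the offset alike.
#'
#' @param trace Corrected current trace.
#' @param pulse_idx Sample indices of the pulse.
#' @param time_ms Sample times (ms).
#' @param margin_ms Pulse-edge interval to exclude (ms).
#' @return Peak current (microamperes, signed).
#' @export
extract_peak_current <- function(trace, pulse_idx, time_ms, margin_ms = 2) {
  t0 <- time_ms[pulse_idx[1]]
  t1 <- time_ms[pulse_idx[length(pulse_idx)]]
  idx <- pulse_idx[time_ms[pulse_idx] >= t0 + margin_ms &
                     time_ms[pulse_idx] <= t1 - margin_ms]
  seg <- trace[idx]
  seg[which.max(abs(seg))]
}

#' Steady-state dF/F of one sweep
#'
#' Mean of the dF/F trace over the final fraction of the pulse.
#'
#' @param dff_trace dF/F trace (percent).
#' @param pulse_idx Sample indices of the pulse.
#' @param steady_frac Final fraction of the pulse to average (default 10%).
#' @return Steady-state dF/F (percent).
#' @export
extract_steady_state_dff <- function(dff_trace, pulse_idx, steady_frac = 0.1) {
  n <- length(pulse_idx)
  idx <- pulse_idx[seq.int(max(1L, n - ceiling(steady_frac * n) + 1L), n)]
  mean(dff_trace[idx])
}

#' Process a raw sweep set into analysis-ready traces and summary points
#'
#' Runs the standard pre-processing chain: zero-phase Gaussian filtering of
#' both channels, leak estimation over subthreshold sweeps and subtraction,
#' photobleach correction of the fluorescence by subtracting a baseline sweep
#' (by default the most hyperpolarized sweep, which carries no
#' voltage-dependent signal), dF/F conversion against a pre-pulse baseline
#' window, and per-sweep extraction of peak current and steady-state dF/F.
#'
#' @param sweeps A `sweep_set`.
#' @param filter_hz Gaussian filter -3 dB cutoff (Hz); `NULL` disables
#'   filtering.
#' @param leak_range Voltage range of the leak fit (mV).
#' @param margin_ms Capacitive-exclusion margin after pulse onset (ms).
#' @param baseline_ms Length of the pre-pulse baseline window (ms),
#'   immediately preceding pulse onset.
#' @param steady_frac Final fraction of the pulse averaged for the
#'   steady-state dF/F.
#' @param baseline_sweep Index of the sweep used as the bleach-correction
#'   baseline (default 1, the most hyperpolarized).
#' @param baseline_filter_hz Bandwidth of the smoothing applied to the
#'   bleach-correction baseline trace before subtraction. The baseline sweep
#'   carries no voltage-dependent signal, only the slow bleach envelope, so
#'   heavy smoothing loses nothing while keeping the baseline's shot noise
#'   out of every corrected trace; `NULL` subtracts the raw trace.
#' @param peak_filter_hz Bandwidth of the additional smoothing applied to the
#'   leak-corrected current for peak detection only. Extremum picking on a
#'   wide-band trace rides the largest noise excursion and inflates the
#'   near-zero subthreshold points of the I-V relationship; for a
#'   non-inactivating current whose peak sits on the activation plateau,
#'   heavier smoothing before cursor placement is the standard remedy. The
#'   pulse-edge exclusion for the peak search widens with the smoothing
#'   kernel.
#' @return An object of class `processed_sweep_set` with elements `parent`,
#'   `leak`, `corrected_current`, `dff`, `peak_current`, `steady_state_dff`
#'   and the processing parameters.
#' @export
process_sweep_set <- function(sweeps, filter_hz = 1000,
                              leak_range = c(-140, -80), margin_ms = 2,
                              baseline_ms = 50, steady_frac = 0.1,
                              baseline_sweep = 1L, baseline_filter_hz = 20,
                              peak_filter_hz = 100) {
  stopifnot(inherits(sweeps, "sweep_set"))
  rate <- sweeps$protocol$sample_rate
  flu <- sweeps$fluorescence
  if (!is.null(filter_hz)) {
    flu <- apply(flu, 2, gaussian_filter_trace, cutoff_hz = filter_hz,
                 sample_rate_hz = rate)
  }
  leak <- estimate_leak(sweeps, fit_range = leak_range,
                        margin_ms = margin_ms)
  corrected_raw <- subtract_leak(sweeps, leak)
  corrected <- corrected_raw
  if (!is.null(filter_hz))
    corrected <- apply(corrected_raw, 2, gaussian_filter_trace,
                       cutoff_hz = filter_hz, sample_rate_hz = rate)
  peak_trace <- corrected
  peak_margin_ms <- margin_ms
  if (!is.null(peak_filter_hz)) {
    peak_trace <- apply(corrected_raw, 2, gaussian_filter_trace,
                        cutoff_hz = peak_filter_hz, sample_rate_hz = rate)
    peak_margin_ms <- max(margin_ms, 600 / peak_filter_hz)
  }

  t <- sweeps$time_ms
  pre_end <- sweeps$protocol$pre_pulse_duration
  baseline_idx <- which(t >= pre_end - baseline_ms & t < pre_end)
  if (!length(baseline_idx))
    stop("baseline window does not overlap the pre-pulse segment")
  pulse_idx <- pulse_indices(sweeps$protocol)

  base_trace <- flu[, baseline_sweep]
  if (!is.null(baseline_filter_hz))
    base_trace <- gaussian_filter_trace(base_trace, baseline_filter_hz, rate)
  dff <- matrix(NA_real_, nrow(flu), ncol(flu))
  for (j in seq_len(ncol(flu))) {
    corr <- correct_photobleach(flu[, j], base_trace, baseline_idx)
    dff[, j] <- compute_dff(corr, baseline_idx)
  }
  peaks <- vapply(seq_len(ncol(peak_trace)), function(j)
    extract_peak_current(peak_trace[, j], pulse_idx, t, peak_margin_ms),
    numeric(1))
  ss_dff <- vapply(seq_len(ncol(dff)), function(j)
    extract_steady_state_dff(dff[, j], pulse_idx, steady_frac), numeric(1))

  structure(list(parent = sweeps, leak = leak,
                 corrected_current = corrected, dff = dff,
                 peak_current = peaks, steady_state_dff = ss_dff,
                 params = list(filter_hz = filter_hz, leak_range = leak_range,
                               margin_ms = margin_ms,
                               peak_filter_hz = peak_filter_hz,
                               peak_margin_ms = peak_margin_ms,
                               baseline_ms = baseline_ms,
                               steady_frac = steady_frac,
                               baseline_sweep = baseline_sweep,
                               baseline_filter_hz = baseline_filter_hz)),
            class = "processed_sweep_set")
}

#' @export
print.processed_sweep_set <- function(x, ...) {
  cat(sprintf("Processed sweep set %s: leak g = %.4g uS, offset = %.4g uA\n",
              x$parent$cell_id, x$leak$conductance, x$leak$offset))
  invisible(x)
}
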