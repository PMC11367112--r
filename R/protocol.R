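#' Voltage-step protocol description
#'
#' A `voltage_protocol` describes a family of depolarizing step sweeps applied
#' from a common holding potential: one sweep per test potential, each sweep
#' consisting of a pre-pulse segment at the holding potential, the test pulse,
#' and a post-pulse segment back at the holding potential.
#'
#' @param holding_potential Holding potential between and around pulses (mV).
#' @param test_start,test_end,test_step First/last test potential and step
#'   increment (mV). `test_end - test_start` must be divisible by `test_step`.
#' @param pulse_duration Test-pulse duration (ms).
#' @param inter_sweep_interval Interval between consecutive sweeps (s); carried
#'   as metadata only.
#' @param sample_rate Sampling frequency (Hz).
#' @param pre_pulse_duration,post_pulse_duration Durations of the segments at
#'   the holding potential before and after the pulse (ms).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_potential = -100,
                             test_start = -140, test_end = 40, test_step = 10,
                             pulse_duration = 250, inter_sweep_interval = 30,
                             sample_rate = 5000,
                             pre_pulse_duration = 100, post_pulse_duration = 50) {
  stopifnot(test_step > 0, sample_rate > 0, pulse_duration > 0,
            pre_pulse_duration >= 0, post_pulse_duration >= 0,
            test_end >= test_start)
  if (abs(((test_end - test_start) / test_step) %% 1) > 1e-9)
    stop("(test_end - test_start) must be divisible by test_step")
  structure(list(holding_potential = holding_potential,
                 test_start = test_start, test_end = test_end,
                 test_step = test_step,
                 pulse_duration = pulse_duration,
                 inter_sweep_interval = inter_sweep_interval,
                 sample_rate = sample_rate,
                 pre_pulse_duration = pre_pulse_duration,
                 post_pulse_duration = post_pulse_duration),
            class = "voltage_protocol")
}

#' Default TEVCF step protocol
#'
#' 250-ms test pulses from -140 to +40 mV in 10-mV increments (19 sweeps)
#' delivered every 30 s from a -100 mV holding potential, sampled at 5 kHz.
#'
#' @return A [voltage_protocol()].
#' @export
make_default_protocol <- function() voltage_protocol()

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("Voltage protocol: hold %g mV; %g..%g mV by %g mV (%d sweeps); %g ms pulse; %g Hz\n",
              x$holding_potential, x$test_start, x$test_end, x$test_step,
              length(test_potentials(x)), x$pulse_duration, x$sample_rate))
  invisible(x)
}

#' Test potentials of a protocol
#' @param protocol A [voltage_protocol()].
#' @return Numeric vector of test potentials (mV), strictly increasing.
#' @export
test_potentials <- function(protocol) {
  seq(protocol$test_start, protocol$test_end, by = protocol$test_step)
}

#' Sample time base of one sweep
#' @param protocol A [voltage_protocol()].
#' @return Time of each sample since sweep start (ms).
#' @export
protocol_times <- function(protocol) {
  n <- protocol_n_samples(protocol)
  (seq_len(n) - 1) / protocol$sample_rate * 1000
}

protocol_n_samples <- function(protocol) {
  total_ms <- protocol$pre_pulse_duration + protocol$pulse_duration +
    protocol$post_pulse_duration
  round(total_ms * protocol$sample_rate / 1000)
}

#' Sample indices of the test pulse
#' @param protocol A [voltage_protocol()].
#' @return Integer indices (into [protocol_times()]) falling inside the pulse.
#' @export
pulse_indices <- function(protocol) {
  t <- protocol_times(protocol)
  which(t >= protocol$pre_pulse_duration &
          t < protocol$pre_pulse_duration + protocol$pulse_duration)
}

#' Commanded voltage at every sample of a sweep
#' @param protocol A [voltage_protocol()].
#' @param test_potential Test potential of the sweep (mV).
#' @return Numeric vector, one voltage per sample (mV).
#' @export
command_voltage <- function(protocol, test_potential) {
  v <- rep(protocol$holding_potential, protocol_n_samples(protocol))
  v[pulse_indices(protocol)] <- test_potential
  v
}
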