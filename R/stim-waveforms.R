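#' Stimulation waveforms
#'
#' Constructors for the stimulus waveforms used throughout the package: the
#' sinusoidal tACS waveform, the biphasic pulse train used for artifact-free
#' EEG entrainment, and the "assumed" phase ramp used for stimulation-OFF
#' control conditions. A `stim_waveform` carries both the sampled current (mA)
#' and its instantaneous phase in radians on `[0, 2*pi)`.
#'
#' The phase convention is fixed package-wide: phase 0 lies at the
#' positive-going zero crossing, so a sine waveform equals
#' `peak_amplitude * sin(phase)`.
#'
#' @name stim_waveforms
NULL

new_stim_waveform <- function(kind, frequency, peak_amplitude, sample_rate,
                              samples, phase, phase_width = NA_real_,
                              pulse_times = NULL) {
  structure(list(
    kind = kind,
    frequency = frequency,
    peak_amplitude = peak_amplitude,
    phase_width = phase_width,
    sample_rate = sample_rate,
    time = (seq_along(samples) - 1) / sample_rate,
    samples = samples,
    phase = phase,
    pulse_times = pulse_times
  ), class = "stim_waveform")
}

#' Sinusoidal stimulation waveform
#'
#' @param frequency Stimulation frequency in Hz.
#' @param peak_amplitude Peak amplitude in mA (not peak-to-peak).
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz; must be at least `10 * frequency`.
#' @return A `stim_waveform` with `kind = "sine"`, sampled current in mA and
#'   an exact analytic phase ramp starting at 0.
#' @examples
#' w <- make_sine(10, 1, 1, 4096)
#' w$samples[round(0.025 * 4096) + 1]  # ~ sin(pi/2) = 1 mA
#' @export
make_sine <- function(frequency, peak_amplitude, duration, sample_rate) {
  check_positive(frequency, "frequency")
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  if (sample_rate < 10 * frequency)
    stop("sample_rate must be at least 10 * frequency", call. = FALSE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  phase <- (2 * pi * frequency * t) %% (2 * pi)
  new_stim_waveform("sine", frequency, peak_amplitude, sample_rate,
                    samples = peak_amplitude * sin(phase), phase = phase)
}

#' Biphasic pulse-train stimulation waveform
#'
#' One charge-balanced biphasic rectangular pulse (anodic phase first, then an
#' equal-width cathodic phase, no interphase gap) per stimulation period. The
#' phase series is the sawtooth ramp rising linearly from 0 to `2*pi` between
#' consecutive pulses.
#'
#' @inheritParams make_sine
#' @param phase_width Width of each pulse phase in milliseconds.
#' @return A `stim_waveform` with `kind = "biphasic_pulse"` and the pulse
#'   onset times in `$pulse_times`.
#' @examples
#' w <- make_pulse_train(20, 6.33, 0.44, 1, 30000)
#' sum(w$samples)  # charge balanced, ~0
#' @export
make_pulse_train <- function(frequency, peak_amplitude, phase_width,
                             duration, sample_rate) {
  check_positive(frequency, "frequency")
  check_positive(duration, "duration")
  check_positive(phase_width, "phase_width")
  period_ms <- 1000 / frequency
  if (2 * phase_width >= period_ms)
    stop("biphasic pulse (2 * phase_width) must fit within one period",
         call. = FALSE)
  w_samp <- round(phase_width / 1000 * sample_rate)
  if (w_samp < 4)
    stop("sample_rate must resolve phase_width with at least 4 samples",
         call. = FALSE)
  n <- round(duration * sample_rate)
  n_pulses <- floor(duration * frequency)
  samples <- numeric(n)
  pulse_times <- (seq_len(n_pulses) - 1) / frequency
  for (t0 in pulse_times) {
    i0 <- round(t0 * sample_rate)
    samples[i0 + seq_len(w_samp)] <- peak_amplitude
    samples[i0 + w_samp + seq_len(w_samp)] <- -peak_amplitude
  }
  phase <- assumed_phase(frequency, duration, sample_rate,
                         event_times = pulse_times)
  new_stim_waveform("biphasic_pulse", frequency, peak_amplitude, sample_rate,
                    samples = samples, phase = phase,
                    phase_width = phase_width, pulse_times = pulse_times)
}

#' Simulated (OFF-condition) stimulation waveform
#'
#' During stimulation-OFF control conditions no current reaches the subject,
#' but an assumed phase ramp at the nominal frequency is still needed to
#' construct cycle or phase-difference histograms. The sampled current is
#' identically zero.
#'
#' @inheritParams make_sine
#' @return A `stim_waveform` with `kind = "off_simulated"` and zero current.
#' @export
make_off_waveform <- function(frequency, duration, sample_rate) {
  w <- make_sine(frequency, 0, duration, sample_rate)
  w$kind <- "off_simulated"
  w
}

#' Assumed stimulus phase ramp
#'
#' Builds the phase time-series used when no physically recorded stimulus
#' phase exists. With `event_times` (pulse triggers) the phase is a sawtooth
#' rising linearly from 0 at each event to `2*pi` at the next; outside the
#' first/last event the neighbouring inter-event interval is extrapolated.
#' Without events the phase is a uniform ramp at `frequency` starting at 0 —
#' the convention for stimulation-OFF conditions, where a sine wave at the
#' stimulus frequency is assumed present but not stimulating.
#'
#' @param frequency Nominal frequency in Hz (used without `event_times`, and
#'   to extrapolate beyond the last event).
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param event_times Optional strictly increasing pulse times in seconds
#'   (at least 2).
#' @return Numeric phase series in radians on `[0, 2*pi)`.
#' @export
assumed_phase <- function(frequency, duration, sample_rate,
                          event_times = NULL) {
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  if (is.null(event_times))
    return((2 * pi * frequency * t) %% (2 * pi))
  if (length(event_times) < 2)
    stop("event_times mode needs at least 2 events", call. = FALSE)
  if (any(diff(event_times) <= 0))
    stop("event_times must be strictly increasing", call. = FALSE)
  ev <- event_times
  # unwrapped phase is piecewise linear through (ev[k], 2*pi*(k-1));
  # extrapolate before the first and after the last event
  k <- findInterval(t, ev)
  k[k < 1L] <- 1L
  k[k >= length(ev)] <- length(ev) - 1L
  up <- 2 * pi * (k - 1 + (t - ev[k]) / (ev[k + 1L] - ev[k]))
  up %% (2 * pi)
}

#' Charge delivered per stimulus phase
#'
#' For a biphasic pulse each phase delivers `peak_amplitude * phase_width`
#' (mA x ms = microcoulomb-scale, reported in mC). For a sine wave one phase
#' is a half-cycle with charge `peak_amplitude / (pi * frequency)`
#' (mA x s = mC). Simulated OFF waveforms deliver zero charge.
#'
#' @param w A `stim_waveform`.
#' @return Charge per stimulus phase in mC.
#' @examples
#' charge_per_phase(make_pulse_train(20, 6.33, 0.44, 1, 30000))  # 0.0028 mC
#' charge_per_phase(make_sine(20, 2.5, 1, 4096))                 # 0.0398 mC
#' @export
charge_per_phase <- function(w) {
  stopifnot(inherits(w, "stim_waveform"))
  if (length(w$samples) < w$sample_rate / w$frequency)
    stop("waveform must contain at least one full period", call. = FALSE)
  switch(w$kind,
    biphasic_pulse = w$peak_amplitude * w$phase_width / 1000,
    sine = w$peak_amplitude / (pi * w$frequency),
    off_simulated = 0,
    stop("unknown waveform kind: ", w$kind, call. = FALSE)
  )
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> kind=%s f=%.3g Hz A=%.3g mA fs=%g Hz n=%d\n",
              x$kind, x$frequency, x$peak_amplitude, x$sample_rate,
              length(x$samples)))
  invisible(x)
}
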