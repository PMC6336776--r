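#' Synthetic data generators
#'
#' Every analysis stage in the package can be exercised without recorded
#' data: these generators produce spike trains, tremor accelerometry, EEG,
#' laminar-probe voltages and voxel fields whose statistical structure
#' matches what the corresponding analysis assumes, with controllable ground
#' truth (modulation depth, locked fraction, field strength). All generators
#' are pure functions of their parameters and `seed`.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a bursting spike train with controllable phase locking
#'
#' Emulates slow oscillatory "bursting" multiunit activity recorded in motor
#' cortex under anesthesia: a stimulation-OFF segment of homogeneous Poisson
#' firing followed by a stimulation-ON segment of inhomogeneous Poisson
#' firing whose rate is `baseline_rate * (1 + mod_depth *
#' sin(lock_harmonic * phase))`, generated by thinning against the
#' `baseline_rate * (1 + mod_depth)` envelope. The unbinned phase-locking of
#' the ON rate profile has the closed form `mod_depth / 2`.
#'
#' @param baseline_rate Mean firing rate in Hz.
#' @param mod_depth Modulation depth in `[0, 1]`.
#' @param lock_freq Locking (stimulation) frequency in Hz.
#' @param lock_harmonic 1 to lock at the stimulation frequency, 2 to lock at
#'   its double (some neurons entrain at twice the tACS frequency).
#' @param duration_off,duration_on Segment durations in seconds (default
#'   1 min OFF immediately followed by 1 min ON).
#' @param seed Integer seed.
#' @return A `spike_train`: sorted spike times (s), per-spike OFF/ON labels,
#'   the OFF/ON windows and the embedded stimulation waveform reference.
#' @export
simulate_spike_train <- function(baseline_rate, mod_depth, lock_freq,
                                 lock_harmonic = 1, duration_off = 60,
                                 duration_on = 60, seed = NULL) {
  if (mod_depth < 0 || mod_depth > 1)
    stop("mod_depth must lie in [0, 1]", call. = FALSE)
  check_positive(baseline_rate, "baseline_rate")
  check_positive(lock_freq, "lock_freq")
  stopifnot(lock_harmonic %in% c(1, 2))
  with_seed(seed, {
    n_off <- stats::rpois(1, baseline_rate * duration_off)
    t_off <- sort(stats::runif(n_off, 0, duration_off))
    # thinning: candidates at the envelope rate, accept in proportion to the
    # instantaneous rate; ON-segment phase 0 at ON onset
    env <- baseline_rate * (1 + mod_depth)
    n_cand <- stats::rpois(1, env * duration_on)
    t_cand <- sort(stats::runif(n_cand, 0, duration_on))
    rate <- baseline_rate *
      (1 + mod_depth * sin(lock_harmonic * 2 * pi * lock_freq * t_cand))
    keep <- stats::runif(n_cand) < rate / env
    t_on <- t_cand[keep]
    times <- c(t_off, duration_off + t_on)
    condition <- factor(rep(c("OFF", "ON"), c(length(t_off), length(t_on))),
                        levels = c("OFF", "ON"))
    structure(list(
      times = times,
      condition = condition,
      off_window = c(0, duration_off),
      on_window = c(duration_off, duration_off + duration_on),
      stim_frequency = lock_freq,
      lock_harmonic = lock_harmonic,
      unit_id = 1L
    ), class = "spike_train")
  })
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes (%d OFF / %d ON), stim %.3g Hz\n",
              length(x$times), sum(x$condition == "OFF"),
              sum(x$condition == "ON"), x$stim_frequency))
  invisible(x)
}

#' Simulate triaxial accelerometer tremor with a phase-locked component
#'
#' Emulates postural tremor measured with a triaxial accelerometer. The
#' dominant axis is a mixture of a free tremor oscillation whose phase
#' performs a Wiener random walk around `2*pi*tremor_freq*t` and a component
#' locked to the stimulus phase, plus white noise; the other two axes carry
#' attenuated copies with independent noise. `locked_fraction = 0` gives
#' unentrained tremor, `locked_fraction = 1` perfect entrainment.
#'
#' With `plan` (see [session_plan()]) the recording follows the session
#' structure and `locked_fraction` may be a named vector per condition,
#' e.g. `c(OFF = 0, LOW = 0.2, HIGH = 0.5)`; gaps get the OFF value.
#'
#' @param tremor_freq Tremor (and stimulation) frequency in Hz.
#' @param locked_fraction Fraction in `[0, 1]` of the tremor oscillation
#'   locked to the stimulus phase; scalar, or named by condition with `plan`.
#' @param noise_sd White-noise SD relative to unit tremor amplitude.
#' @param duration Duration in seconds (ignored when `plan` is given).
#' @param fs Sample rate in Hz (nominal 4096).
#' @param phase_diffusion Wiener phase-walk diffusion (rad^2/s) of the free
#'   tremor component.
#' @param plan Optional session plan data frame (condition, duration_s,
#'   repetition).
#' @param condition Condition label when no plan is given.
#' @param seed Integer seed.
#' @return A `tremor_recording`: matrix `acc` (n x 3), `fs`, and a
#'   `segments` data frame (start_s, end_s, condition, repetition).
#' @export
simulate_tremor <- function(tremor_freq, locked_fraction, noise_sd = 0.5,
                            duration = 60, fs = 4096,
                            phase_diffusion = 2, plan = NULL,
                            condition = "ON", seed = NULL) {
  if (any(locked_fraction < 0 | locked_fraction > 1))
    stop("locked_fraction must lie in [0, 1]", call. = FALSE)
  check_positive(tremor_freq, "tremor_freq")
  if (is.null(plan))
    plan <- data.frame(condition = condition, duration_s = duration,
                       repetition = 1L)
  with_seed(seed, {
    total <- sum(plan$duration_s)
    n <- round(total * fs)
    t <- (seq_len(n) - 1) / fs
    # per-sample locked fraction follows the plan
    lf <- numeric(n)
    seg <- plan
    seg$start_s <- cumsum(c(0, plan$duration_s))[seq_len(nrow(plan))]
    seg$end_s <- seg$start_s + seg$duration_s
    for (i in seq_len(nrow(seg))) {
      idx <- which(t >= seg$start_s[i] & t < seg$end_s[i])
      cnd <- as.character(seg$condition[i])
      lf[idx] <- if (length(locked_fraction) == 1L) locked_fraction
        else if (cnd %in% names(locked_fraction)) locked_fraction[[cnd]]
        else locked_fraction[["OFF"]]
    }
    # free tremor: phase random walk around the nominal tremor frequency
    dphi <- stats::rnorm(n, 0, sqrt(phase_diffusion / fs))
    phi_free <- 2 * pi * tremor_freq * t + cumsum(dphi)
    phi_stim <- 2 * pi * tremor_freq * t  # stimulus phase ramp
    x <- (1 - lf) * sin(phi_free) + lf * sin(phi_stim) +
      stats::rnorm(n, 0, noise_sd)
    acc <- cbind(
      ax = x,
      ay = 0.3 * ((1 - lf) * sin(phi_free) + lf * sin(phi_stim)) +
        stats::rnorm(n, 0, noise_sd),
      az = 0.15 * ((1 - lf) * sin(phi_free) + lf * sin(phi_stim)) +
        stats::rnorm(n, 0, noise_sd)
    )
    structure(list(
      acc = acc, fs = fs, tremor_freq = tremor_freq,
      segments = seg[, c("start_s", "end_s", "condition", "repetition")]
    ), class = "tremor_recording")
  })
}

#' Simulate single-channel EEG with a pulse-locked beta response
#'
#' Background activity is 1/f-shaped ("pink") noise plus white noise plus a
#' free beta oscillation with drifting phase; the entrained component is
#' `locked_amp * sin(phase)` where phase is the sawtooth stimulus phase of
#' the pulse train; each pulse additionally injects a brief two-sample
#' biphasic artifact of amplitude `artifact_amp`.
#'
#' @param beta_freq Beta frequency in Hz (16-30).
#' @param locked_amp Amplitude (microvolt) of the pulse-locked component.
#' @param pulse_train A `stim_waveform` from [make_pulse_train()], or `NULL`
#'   for an OFF recording (assumed phase at `beta_freq` is still stored).
#' @param noise_sd White-noise SD (microvolt).
#' @param pink_sd Pink-noise SD (microvolt).
#' @param free_beta_amp Amplitude of the unentrained beta oscillation.
#' @param artifact_amp Artifact amplitude (microvolt) added at each pulse.
#' @param duration Duration in seconds.
#' @param fs Sample rate in Hz (nominal 4096).
#' @param seed Integer seed.
#' @return An `eeg_recording`: `eeg` (microvolt), `fs`, `pulse_times` (s),
#'   `stim_frequency`.
#' @export
simulate_eeg <- function(beta_freq, locked_amp, pulse_train = NULL,
                         noise_sd = 1, pink_sd = 2, free_beta_amp = 1,
                         artifact_amp = 0, duration = 60, fs = 4096,
                         seed = NULL) {
  if (beta_freq < 16 || beta_freq > 30)
    stop("beta_freq must lie in the 16-30 Hz beta band", call. = FALSE)
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    eeg <- pink_noise(n, fs, pink_sd) + stats::rnorm(n, 0, noise_sd)
    dphi <- stats::rnorm(n, 0, sqrt(2 / fs))
    eeg <- eeg + free_beta_amp * sin(2 * pi * beta_freq * t + cumsum(dphi))
    if (is.null(pulse_times <- pulse_train$pulse_times)) {
      stim_phase <- assumed_phase(beta_freq, duration, fs)
      stim_freq <- beta_freq
    } else {
      pulse_times <- pulse_times[pulse_times < duration]
      stim_phase <- assumed_phase(pulse_train$frequency, duration, fs,
                                  event_times = pulse_times)
      stim_freq <- pulse_train$frequency
      if (locked_amp != 0) eeg <- eeg + locked_amp * sin(stim_phase)
      if (artifact_amp != 0) {
        i0 <- round(pulse_times * fs) + 1L
        i0 <- i0[i0 + 1L <= n]
        eeg[i0] <- eeg[i0] + artifact_amp
        eeg[i0 + 1L] <- eeg[i0 + 1L] - artifact_amp
      }
    }
    structure(list(eeg = eeg, fs = fs, pulse_times = pulse_times,
                   stim_frequency = stim_freq, beta_freq = beta_freq),
              class = "eeg_recording")
  })
}

# 1/f amplitude-shaped noise, seed-deterministic, scaled to SD `sd`
pink_noise <- function(n, fs, sd = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)    # symmetric shaping keeps the series real
  X <- X / f
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Simulate a 32-channel laminar probe recording in a known field
#'
#' Each channel's voltage (microvolt) is `field_strength * depth * sin(2 *
#' pi * stim_freq * t)` plus noise and optional spike transients, i.e. a
#' linear potential gradient along each of the probe's three contact
#' columns. With contacts 25 micrometre apart, a 1 V/m field separates
#' adjacent contacts by 25 microvolt of oscillation amplitude.
#'
#' @param field_strength Electric field along the probe axis in V/m.
#' @param stim_freq Stimulation frequency in Hz.
#' @param spike_amp Amplitude of randomly inserted spike transients
#'   (microvolt); 0 disables them.
#' @param noise_sd Broadband noise SD (microvolt).
#' @param duration Duration in seconds.
#' @param fs Sample rate in Hz (nominal 30000).
#' @param seed Integer seed.
#' @return A `probe_recording`: `voltages` (n x 32, microvolt), `fs`,
#'   `contacts` data frame (channel, column, depth_um with 25 um spacing),
#'   `stim_frequency`.
#' @export
simulate_probe <- function(field_strength, stim_freq, spike_amp = 0,
                           noise_sd = 5, duration = 10, fs = 30000,
                           seed = NULL) {
  if (field_strength < 0)
    stop("field_strength must be non-negative", call. = FALSE)
  contacts <- probe_geometry()
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    carrier <- sin(2 * pi * stim_freq * t)
    v <- matrix(stats::rnorm(n * 32L, 0, noise_sd), n, 32L)
    for (ch in seq_len(32L)) {
      # V/m x um = uV
      amp_uv <- field_strength * contacts$depth_um[ch]
      v[, ch] <- v[, ch] + amp_uv * carrier
    }
    if (spike_amp > 0) {
      n_spk <- stats::rpois(1, 2 * duration)
      idx <- sample.int(n - 3L, n_spk)
      for (i in idx) v[i + 0:2, ] <- v[i + 0:2, ] +
          spike_amp * c(1, -2, 1)
    }
    structure(list(voltages = v, fs = fs, contacts = contacts,
                   stim_frequency = stim_freq),
              class = "probe_recording")
  })
}

#' Laminar probe contact geometry
#'
#' 32 contacts in three columns with constant 25 micrometre vertical spacing
#' within each column (11 + 11 + 10 contacts spanning 275 um).
#'
#' @return Data frame with `channel`, `column` (1-3) and `depth_um`.
#' @export
probe_geometry <- function() {
  per_col <- c(11L, 11L, 10L)
  data.frame(
    channel = seq_len(32L),
    column = rep(1:3, per_col),
    depth_um = unlist(lapply(per_col, function(k) 25 * (seq_len(k) - 1)))
  )
}

#' Simulate a scalar voxel field
#'
#' A voxel field of electric-field magnitudes with known distribution, for
#' testing the fixed-volume top-field summary.
#'
#' @param n_voxels Number of voxels.
#' @param voxel_volume Volume per voxel in mm^3.
#' @param values Optional explicit voxel values (V/m); otherwise drawn from
#'   a lognormal distribution.
#' @param tissue Tissue label.
#' @param seed Integer seed.
#' @return A `voxel_field`: `values` (V/m, non-negative), `voxel_volume`,
#'   `tissue`.
#' @export
simulate_voxel_field <- function(n_voxels, voxel_volume = 1, values = NULL,
                                 tissue = "gray_matter", seed = NULL) {
  check_positive(voxel_volume, "voxel_volume")
  if (n_voxels * voxel_volume < 10)
    stop("total volume must be at least 10 mm^3", call. = FALSE)
  with_seed(seed, {
    if (is.null(values))
      values <- stats::rlnorm(n_voxels, meanlog = -1, sdlog = 0.8)
    if (length(values) != n_voxels || any(values < 0))
      stop("values must be non-negative and of length n_voxels",
           call. = FALSE)
    structure(list(values = values, voxel_volume = voxel_volume,
                   tissue = tissue), class = "voxel_field")
  })
}
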