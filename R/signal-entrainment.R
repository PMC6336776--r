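#' Tremor and EEG entrainment analysis
#'
#' The continuous-signal pipeline: bandpass + PCA preprocessing of triaxial
#' accelerometry, Hilbert instantaneous phase, 30-bin phase-difference
#' histograms quantified with the same PLV statistic as the spike analysis,
#' EEG preprocessing for pulsed stimulation, the Fourier amplitude at the
#' stimulation frequency, and pulse-locked cycle averages.
#'
#' @name signal_entrainment
NULL

# zero-phase 2nd-order Butterworth bandpass (forward-backward, so the
# effective magnitude order doubles but phase distortion cancels)
butter_bandpass <- function(x, fs, low, high) {
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Preprocess triaxial tremor accelerometry
#'
#' Each axis is bandpass filtered 3-30 Hz with a second-order Butterworth
#' filter (applied forward-backward, i.e. zero-phase, so that no
#' filter-induced phase shift can bias the downstream phase-difference
#' histograms), then principal component analysis is applied across the
#' three filtered axes and the first component's time course returned. PC1
#' is oriented to correlate positively with the filtered axis of largest
#' variance (the sign is irrelevant to PLV; fixing it makes runs
#' reproducible).
#'
#' @param rec A `tremor_recording`, or an n x 3 numeric matrix.
#' @param fs Sample rate in Hz (taken from `rec` if it is a recording).
#' @param band Passband in Hz.
#' @return Numeric vector: the first principal component of the filtered
#'   axes.
#' @export
preprocess_tremor <- function(rec, fs = NULL, band = c(3, 30)) {
  if (inherits(rec, "tremor_recording")) {
    acc <- rec$acc
    fs <- rec$fs
  } else acc <- as.matrix(rec)
  stopifnot(ncol(acc) == 3, !is.null(fs))
  if (fs <= 2 * band[2])
    stop("sample rate must exceed twice the analysis band", call. = FALSE)
  filt <- apply(acc, 2, butter_bandpass, fs = fs, low = band[1],
                high = band[2])
  vars <- apply(filt, 2, stats::var)
  if (any(vars == 0))
    stop("degenerate axis with zero variance; PCA undefined", call. = FALSE)
  pc <- stats::prcomp(filt, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  ref <- filt[, which.max(vars)]
  if (stats::cor(pc1, ref) < 0) pc1 <- -pc1
  pc1
}

#' Peak frequency from epoch-averaged power spectral density
#'
#' Splits the record into non-overlapping epochs, averages the per-epoch
#' rectangular-window periodograms, and returns the frequency of maximum
#' power within `band`. Used both for the individual tremor frequency
#' (3-30 Hz) and the individual beta peak (16-30 Hz).
#'
#' @param x Numeric signal.
#' @param fs Sample rate in Hz.
#' @param band Frequency band (Hz) searched for the peak.
#' @param epoch Epoch length in seconds (frequency resolution `1/epoch`).
#' @return Peak frequency in Hz. If the in-band spectrum is flat (maximum
#'   under twice the in-band median), the attribute `low_prominence` is
#'   `TRUE` and a warning is raised.
#' @export
peak_frequency <- function(x, fs, band = c(3, 30), epoch = 1) {
  m <- round(epoch * fs)
  n_ep <- floor(length(x) / m)
  if (n_ep < 10)
    stop("record must contain at least 10 epochs", call. = FALSE)
  psd <- numeric(m)
  for (k in seq_len(n_ep)) {
    seg <- x[((k - 1) * m + 1):(k * m)]
    psd <- psd + Mod(stats::fft(seg - mean(seg)))^2
  }
  psd <- psd / n_ep
  freqs <- (seq_len(m) - 1) * fs / m
  in_band <- freqs >= band[1] & freqs <= band[2]
  pk <- which.max(psd[in_band])
  out <- freqs[in_band][pk]
  lp <- max(psd[in_band]) < 2 * stats::median(psd[in_band])
  if (lp) warning("no prominent spectral peak in band", call. = FALSE)
  attr(out, "low_prominence") <- lp
  out
}

# discrete analytic signal via the FFT half-spectrum method
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert instantaneous phase
#'
#' Phase of the discrete analytic signal. The input should be narrowband
#' (bandpassed) for the instantaneous phase to be meaningful. Samples within
#' `edge_cycles` cycles of either end (where the analytic signal suffers
#' wrap-around edge effects) are flagged in `edge` for optional exclusion;
#' the cycle length is taken from the dominant spectral component.
#'
#' @param x Numeric narrowband signal.
#' @param fs Sample rate in Hz.
#' @param edge_cycles Number of cycles flagged at each edge (default 2).
#' @return A `phase_series`: `phase` (radians in `[0, 2*pi)`), `fs`,
#'   `source = "hilbert"`, logical `edge` flags.
#' @export
hilbert_phase <- function(x, fs, edge_cycles = 2) {
  if (all(x == 0)) stop("all-zero signal has no phase", call. = FALSE)
  n <- length(x)
  a <- analytic_signal(x - mean(x))
  # + pi/2 aligns with the package-wide sine convention (phase 0 at the
  # positive-going zero crossing), so hilbert_phase(sin(phi)) returns phi
  phase <- (Arg(a) + pi / 2) %% (2 * pi)
  spec <- Mod(stats::fft(x - mean(x))[seq_len(floor(n / 2))])
  f_dom <- max((which.max(spec) - 1) * fs / n, fs / n)
  n_edge <- min(ceiling(edge_cycles * fs / f_dom), floor(n / 2))
  edge <- rep(FALSE, n)
  if (n_edge > 0) edge[c(seq_len(n_edge), n - seq_len(n_edge) + 1L)] <- TRUE
  structure(list(phase = phase, fs = fs, source = "hilbert", edge = edge),
            class = "phase_series")
}

#' Wrap a raw phase vector into a `phase_series`
#'
#' For stimulus phase ramps ([assumed_phase()], sawtooth pulse phase or the
#' exact phase stored in a `stim_waveform`).
#'
#' @param phase Phase in radians.
#' @param fs Sample rate in Hz.
#' @param source Label: "sawtooth" or "assumed".
#' @return A `phase_series` with no edge flags.
#' @export
as_phase_series <- function(phase, fs, source = "assumed") {
  structure(list(phase = phase %% (2 * pi), fs = fs, source = source,
                 edge = rep(FALSE, length(phase))), class = "phase_series")
}

#' Phase-difference histogram between stimulus and signal phase
#'
#' The per-sample wrapped phase difference between the two series is binned
#' into `n_bins` bins and normalized by the total number of samples, giving
#' the probability that a particular stimulus-signal phase difference
#' occurs; the PLV of this histogram quantifies entrainment (0 = uniform
#' differences, 1 = constant difference).
#'
#' Samples flagged as edge samples in either series are excluded.
#'
#' @param stim_phase,signal_phase `phase_series` of equal length and sample
#'   rate (raw numeric phase vectors are accepted).
#' @param n_bins Number of bins (default 30).
#' @return A `phase_histogram`.
#' @export
phase_difference_histogram <- function(stim_phase, signal_phase,
                                       n_bins = 30) {
  if (!inherits(stim_phase, "phase_series"))
    stim_phase <- as_phase_series(stim_phase, fs = NA_real_)
  if (!inherits(signal_phase, "phase_series"))
    signal_phase <- as_phase_series(signal_phase, fs = NA_real_)
  if (length(stim_phase$phase) != length(signal_phase$phase))
    stop("phase series must have equal length", call. = FALSE)
  keep <- !(stim_phase$edge | signal_phase$edge)
  dphi <- (stim_phase$phase[keep] - signal_phase$phase[keep]) %% (2 * pi)
  counts <- bin_phases(dphi, n_bins)
  mass <- counts / sum(counts)
  new_phase_histogram(mass, counts = counts, n_bins = n_bins)
}

#' Preprocess single-channel EEG recorded during pulsed stimulation
#'
#' Bandpass 0.3-100 Hz (zero-phase Butterworth). Because the biphasic
#' stimulation artifact is confined to two samples and to high frequencies,
#' this step removes it; when `pulse_times` are supplied the residual
#' artifact is quantified as the excess power in 2-ms windows around each
#' pulse relative to the rest of the record, before and after filtering.
#'
#' @param rec An `eeg_recording`, or a numeric signal.
#' @param fs Sample rate in Hz (taken from `rec` if it is a recording).
#' @param pulse_times Pulse times in seconds (taken from `rec` if present).
#' @param band Passband in Hz.
#' @return Filtered signal; if pulses were given, attribute
#'   `artifact_report` holds `raw_excess`, `filtered_excess` (power ratios
#'   vs. the off-pulse baseline) and `residual_fraction` =
#'   filtered excess / raw excess.
#' @export
eeg_preprocess <- function(rec, fs = NULL, pulse_times = NULL,
                           band = c(0.3, 100)) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$eeg
    fs <- rec$fs
    if (is.null(pulse_times)) pulse_times <- rec$pulse_times
  } else x <- as.numeric(rec)
  stopifnot(!is.null(fs))
  if (fs <= 200)
    stop("sample rate must exceed 200 Hz for the 0.3-100 Hz band",
         call. = FALSE)
  y <- butter_bandpass(x, fs, band[1], band[2])
  if (!is.null(pulse_times) && length(pulse_times)) {
    win <- round(0.002 * fs)  # 2 ms around each pulse
    idx <- unique(unlist(lapply(round(pulse_times * fs) + 1L,
                                function(i) i + seq_len(2L * win) - win)))
    idx <- idx[idx >= 1 & idx <= length(x)]
    excess <- function(z) {
      base <- mean(z[-idx]^2)
      if (base == 0) return(Inf)
      mean(z[idx]^2) / base
    }
    raw_e <- excess(x - mean(x))
    fil_e <- excess(y)
    attr(y, "artifact_report") <- list(
      raw_excess = raw_e, filtered_excess = fil_e,
      residual_fraction = max(fil_e - 1, 0) / max(raw_e - 1, .Machine$double.eps))
  }
  y
}

#' Fourier amplitude at a given frequency
#'
#' Amplitude (`2 * |X(f)| / N` convention, so a pure sinusoid of amplitude a
#' over an integer number of cycles returns a) of the discrete Fourier
#' component nearest `f`, computed over the whole record.
#'
#' @param x Numeric signal.
#' @param fs Sample rate in Hz.
#' @param f Target frequency in Hz (below Nyquist).
#' @return Amplitude in the units of `x`.
#' @export
fourier_amplitude_at <- function(x, fs, f) {
  n <- length(x)
  if (f >= fs / 2) stop("frequency is above Nyquist", call. = FALSE)
  if (n < 10 * fs / f)
    stop("record must span at least 10 cycles of f", call. = FALSE)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(x)[k + 1L]) / n
}

#' Pulse-locked cycle average
#'
#' Averages epochs aligned to every stimulation pulse, each spanning
#' `n_cycles` stimulation periods, with a per-sample 95% confidence band.
#'
#' @param x Numeric signal.
#' @param fs Sample rate in Hz.
#' @param pulse_times Pulse times in seconds.
#' @param frequency Stimulation frequency in Hz (defines the period).
#' @param n_cycles Number of cycles per epoch (default 3).
#' @return List with `time` (s), `mean`, `ci_low`, `ci_high`, `n_epochs`.
#' @export
cycle_average <- function(x, fs, pulse_times, frequency, n_cycles = 3) {
  len <- round(n_cycles * fs / frequency)
  starts <- round(pulse_times * fs) + 1L
  starts <- starts[starts + len - 1L <= length(x)]
  if (length(starts) < 2)
    stop("need at least 2 complete epochs", call. = FALSE)
  ep <- vapply(starts, function(i) x[i:(i + len - 1L)], numeric(len))
  m <- rowMeans(ep)
  se <- apply(ep, 1, stats::sd) / sqrt(ncol(ep))
  list(time = (seq_len(len) - 1) / fs, mean = m,
       ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
       n_epochs = ncol(ep))
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz (%s), %d edge-flagged\n",
              length(x$phase), x$fs, x$source, sum(x$edge)))
  invisible(x)
}
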