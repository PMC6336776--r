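#' Phase histograms and the phase-locking value
#'
#' Entrainment is quantified with a single statistic throughout the package:
#' the phase-locking value (PLV), the modulus of the complex resultant of
#' phase-binned probability mass,
#' \deqn{PLV = | \sum_b R_b e^{i \theta_b} |,}
#' where \eqn{\theta_b} is the centre of phase bin b and \eqn{R_b} the
#' probability mass in that bin. PLV is 1 when all mass falls in one bin and
#' exactly 0 for mass spread equally over the (equally spaced) bins.
#'
#' Bin convention: `n_bins` half-open bins `[2*pi*k/n, 2*pi*(k+1)/n)` with
#' centres at `(k + 0.5) * 2*pi/n`.
#'
#' @name phase_histogram
NULL

new_phase_histogram <- function(mass, counts = NULL, rate = NULL,
                                n_bins = length(mass)) {
  centers <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  h <- structure(list(n_bins = n_bins, bin_centers = centers, mass = mass,
                      counts = counts, rate = rate, plv = NA_real_),
                 class = "phase_histogram")
  h$plv <- plv(h)
  h
}

#' Construct a phase histogram from explicit probability mass
#'
#' @param mass Numeric vector of per-bin probability mass; must sum to 1
#'   (or be all zero for the degenerate empty case).
#' @return A `phase_histogram` with its PLV.
#' @examples
#' phase_histogram(c(1, rep(0, 29)))$plv   # 1
#' phase_histogram(rep(1 / 30, 30))$plv    # 0
#' @export
phase_histogram <- function(mass) {
  if (any(mass < 0)) stop("mass must be non-negative", call. = FALSE)
  tot <- sum(mass)
  if (tot > 0 && abs(tot - 1) > 1e-8)
    stop("mass must be normalized to sum to 1", call. = FALSE)
  new_phase_histogram(mass)
}

#' Phase-locking value of a phase histogram
#'
#' Modulus of the bin-weighted complex resultant. Shared by the spike,
#' tremor and EEG pipelines. An all-zero (empty) histogram has PLV 0 so that
#' population summaries stay total.
#'
#' @param hist A `phase_histogram`.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(hist) {
  stopifnot(inherits(hist, "phase_histogram"))
  tot <- sum(hist$mass)
  if (tot == 0) return(0)
  if (abs(tot - 1) > 1e-8)
    stop("histogram mass is not normalized", call. = FALSE)
  Mod(sum(hist$mass * exp(1i * hist$bin_centers)))
}

# bin phases (radians, any range) into n equally spaced bins on [0, 2*pi)
bin_phases <- function(phi, n_bins) {
  phi <- phi %% (2 * pi)
  b <- floor(phi / (2 * pi) * n_bins) + 1L
  b[b > n_bins] <- n_bins  # guards phi == 2*pi after rounding
  tabulate(b, nbins = n_bins)
}

#' Cycle histogram of a spike train over stimulus phase
#'
#' Assigns each spike the stimulus phase at which it occurred, pools across
#' all stimulus cycles into `n_bins` bins, and normalizes the counts across
#' the whole condition to probability mass. The spike rate per phase bin
#' (count / time spent in that bin) is retained as an auxiliary view of the
#' same histogram; the PLV always uses the probability mass.
#'
#' @param spike_times Spike times in seconds.
#' @param frequency Stimulus frequency in Hz; the phase at time t is
#'   `2*pi*frequency*(t - t0)` (mod 2*pi).
#' @param t0 Time of phase zero (segment onset for assumed OFF phase).
#' @param duration Segment duration in seconds (for the rate view); inferred
#'   from the spike span if missing.
#' @param n_bins Number of phase bins (30 throughout the source analyses).
#' @return A `phase_histogram` with counts, mass, rate per bin and PLV.
#' @export
cycle_histogram <- function(spike_times, frequency, t0 = 0,
                            duration = NULL, n_bins = 30) {
  check_positive(frequency, "frequency")
  if (is.null(duration))
    duration <- if (length(spike_times)) diff(range(spike_times)) + 1e-9
      else 1 / frequency
  if (duration < 1 / frequency)
    stop("segment must span at least one stimulus period", call. = FALSE)
  counts <- bin_phases(2 * pi * frequency * (spike_times - t0), n_bins)
  tot <- sum(counts)
  mass <- if (tot > 0) counts / tot else numeric(n_bins)
  rate <- counts / (duration / n_bins)
  new_phase_histogram(mass, counts = counts, rate = rate, n_bins = n_bins)
}

#' OFF/ON phase-locking contrast for one unit
#'
#' Builds the ON-condition cycle histogram at the stimulation frequency and
#' the OFF-condition histogram with an assumed phase ramp at the same
#' stimulus period (phase 0 at OFF-segment onset: a sine at the stimulus
#' frequency is assumed present but not stimulating), then takes
#' `plv_dif = plv_on - plv_off`.
#'
#' @param train A `spike_train` with OFF and ON condition labels.
#' @param frequency Stimulus frequency in Hz; defaults to the train's.
#' @param n_bins Number of phase bins.
#' @return List with `plv_off`, `plv_on`, `plv_dif` and both histograms.
#' @export
off_on_contrast <- function(train, frequency = NULL, n_bins = 30) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(frequency)) frequency <- train$stim_frequency
  if (!all(c("OFF", "ON") %in% levels(train$condition)) ||
      !any(train$condition == "OFF") || !any(train$condition == "ON"))
    stop("train must contain both OFF and ON spikes", call. = FALSE)
  t_off <- train$times[train$condition == "OFF"]
  t_on <- train$times[train$condition == "ON"]
  h_off <- cycle_histogram(t_off, frequency, t0 = train$off_window[1],
                           duration = diff(train$off_window), n_bins = n_bins)
  h_on <- cycle_histogram(t_on, frequency, t0 = train$on_window[1],
                          duration = diff(train$on_window), n_bins = n_bins)
  list(plv_off = h_off$plv, plv_on = h_on$plv,
       plv_dif = h_on$plv - h_off$plv,
       hist_off = h_off, hist_on = h_on)
}

#' Select the entrainment frequency (fundamental vs. double)
#'
#' Some neurons entrain at double the tACS frequency. The ON-condition PLV
#' is computed at both the stimulation frequency and its double; the
#' frequency with the higher ON PLV is selected for all further analysis
#' (ties go to the fundamental).
#'
#' @param train A `spike_train` with an ON segment.
#' @param stim_freq Stimulation frequency in Hz; defaults to the train's.
#' @param n_bins Number of phase bins.
#' @return List with `frequency` (the selection), `plv_f`, `plv_2f` and both
#'   histograms.
#' @export
select_entrainment_frequency <- function(train, stim_freq = NULL,
                                         n_bins = 30) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(stim_freq)) stim_freq <- train$stim_frequency
  if (!any(train$condition == "ON"))
    stop("train must contain an ON segment", call. = FALSE)
  t_on <- train$times[train$condition == "ON"]
  h1 <- cycle_histogram(t_on, stim_freq, t0 = train$on_window[1],
                        duration = diff(train$on_window), n_bins = n_bins)
  h2 <- cycle_histogram(t_on, 2 * stim_freq, t0 = train$on_window[1],
                        duration = diff(train$on_window), n_bins = n_bins)
  list(frequency = if (h2$plv > h1$plv) 2 * stim_freq else stim_freq,
       plv_f = h1$plv, plv_2f = h2$plv, hist_f = h1, hist_2f = h2)
}

#' Mean spike rate of a segment
#'
#' @param spike_times Spike times in seconds.
#' @param duration Segment duration in seconds.
#' @return Rate in Hz (0 for an empty segment).
#' @export
spike_rate <- function(spike_times, duration) {
  check_positive(duration, "duration")
  length(spike_times) / duration
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d bins, PLV = %.4f\n", x$n_bins, x$plv))
  invisible(x)
}
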