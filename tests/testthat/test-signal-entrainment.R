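test_that("tremor preprocessing recovers a single-axis oscillation", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 8 * t)
  eps <- 1e-6 * rnorm(length(t))  # break exact zero variance on dead axes
  acc <- cbind(x, eps, eps)
  pc1 <- preprocess_tremor(acc, fs = fs)
  expect_gt(abs(cor(pc1, x)), 0.999)
  # identical signal on all axes: PC1 explains essentially all variance
  pc <- prcomp(cbind(x, x, x) + rnorm(3 * length(x), 0, 1e-6))
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.999)
  expect_error(preprocess_tremor(cbind(x, 0 * x, 0 * x), fs = fs),
               "degenerate")
})

test_that("bandpass attenuates out-of-band contaminants by >= 20 dB", {
  fs <- 512
  t <- (0:(20 * fs - 1)) / fs
  tone8 <- sin(2 * pi * 8 * t)
  tone50 <- sin(2 * pi * 50 * t)
  acc <- cbind(tone8 + tone50, 1e-6 * rnorm(length(t)),
               1e-6 * rnorm(length(t)))
  pc1 <- preprocess_tremor(acc, fs = fs)
  a8 <- fourier_amplitude_at(pc1, fs, 8)
  a50 <- fourier_amplitude_at(pc1, fs, 50)
  expect_gt(20 * log10(a8 / a50), 20)
})

test_that("peak frequency finds the dominant in-band component", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  expect_equal(as.numeric(peak_frequency(sin(2 * pi * 22 * t), fs,
                                         c(16, 30))), 22)
  x <- sin(2 * pi * 8 * t) + 0.2 * sin(2 * pi * 25 * t)
  expect_equal(as.numeric(peak_frequency(x, fs, c(3, 30))), 8)
  expect_error(peak_frequency(sin(2 * pi * 8 * t[1:(2 * fs)]), fs,
                              c(3, 30)), "10 epochs")
  expect_warning(peak_frequency(rnorm(30 * fs), fs, c(3, 30)),
                 "prominent")
})

test_that("simulated beta peak is recovered under pink noise", {
  hits <- vapply(1:25, function(s) {
    e <- simulate_eeg(22.08, 0, NULL, noise_sd = 0.5, pink_sd = 1,
                      free_beta_amp = 3, duration = 30, fs = 512, seed = s)
    abs(peak_frequency(e$eeg, 512, c(16, 30)) - 22.08) <= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Hilbert phase tracks frequency and relative offsets", {
  fs <- 1024
  t <- (0:(10 * fs - 1)) / fs
  hp <- hilbert_phase(sin(2 * pi * 10 * t), fs)
  central <- which(!hp$edge)
  # phase derivative equals 2*pi*10 rad/s in the interior
  slope <- diff(unwrap_phase(hp$phase[central])) * fs / (2 * pi)
  expect_equal(median(slope), 10, tolerance = 1e-3)
  # cos leads sin by pi/2
  hc <- hilbert_phase(cos(2 * pi * 10 * t), fs)
  d <- (hc$phase[central] - hp$phase[central]) %% (2 * pi)
  expect_equal(median(d), pi / 2, tolerance = 0.01)
  expect_error(hilbert_phase(rep(0, 100), fs), "all-zero")
})

test_that("mean phase-derivative frequency matches the spectral peak", {
  e <- simulate_eeg(22, 0, NULL, noise_sd = 0.2, pink_sd = 0.5,
                    free_beta_amp = 3, duration = 30, fs = 512, seed = 8)
  beta <- hilbert_phase(
    as.numeric(signal::filtfilt(signal::butter(2, c(16, 30) / 256), e$eeg)),
    512)
  f_phase <- mean(diff(unwrap_phase(beta$phase[!beta$edge]))) * 512 / (2 * pi)
  f_spec <- as.numeric(peak_frequency(e$eeg, 512, c(16, 30)))
  expect_equal(f_phase, f_spec, tolerance = 0.02 * f_spec)
})

test_that("phase-difference histogram endpoints and offset invariance", {
  fs <- 512
  ph <- as_phase_series(assumed_phase(8, 30, fs), fs)
  # identical phases: all mass in one bin, PLV 1
  h <- phase_difference_histogram(ph, ph)
  expect_equal(h$plv, 1)
  expect_equal(sum(h$mass > 0), 1)
  expect_error(phase_difference_histogram(ph,
    as_phase_series(assumed_phase(8, 10, fs), fs)), "equal length")
  # adding a constant offset to either series leaves PLV unchanged
  set.seed(6)
  noisy <- as_phase_series(ph$phase + rnorm(length(ph$phase), 0, 0.7), fs)
  base <- phase_difference_histogram(ph, noisy)$plv
  for (off in c(0.3, 1.7)) {
    shifted <- as_phase_series(noisy$phase + off, fs)
    expect_lt(abs(phase_difference_histogram(ph, shifted)$plv - base),
              0.01)
    expect_true(base >= 0 && base <= 1)
  }
  # offset by an exact bin width rotates the histogram: PLV unchanged
  rot <- as_phase_series(noisy$phase + 2 * pi / 30, fs)
  expect_equal(phase_difference_histogram(ph, rot)$plv, base,
               tolerance = 1e-9)
})

test_that("binned phase-difference PLV matches the unbinned resultant", {
  set.seed(17)
  for (k in c(0.5, 2)) {
    dphi <- rnorm(5000, 1, k)
    a <- as_phase_series(rep(0, 5000), 512)
    b <- as_phase_series(-dphi, 512)
    binned <- phase_difference_histogram(a, b)$plv
    expect_equal(binned, mrl_oracle(dphi) * bin_attenuation(30),
                 tolerance = 0.01)
  }
})

test_that("unentrained tremor PLV sits below the surrogate null band", {
  fs <- 256
  rec <- simulate_tremor(8, 0, noise_sd = 0.5, duration = 60, fs = fs,
                         seed = 14)
  tp <- hilbert_phase(preprocess_tremor(rec), fs)
  sp <- as_phase_series(assumed_phase(8, 60, fs), fs)
  observed <- phase_difference_histogram(sp, tp)$plv
  # phase-randomized surrogates preserve the signal's autocorrelation
  x <- preprocess_tremor(rec)
  n <- length(x)
  null_plv <- vapply(1:40, function(i) {
    X <- fft(x)
    rot <- exp(2i * pi * runif(n))
    half <- 2:(floor(n / 2))
    X[half] <- X[half] * rot[half]
    X[n - half + 2] <- Conj(X[half])
    xs <- Re(fft(X, inverse = TRUE)) / n
    phase_difference_histogram(sp, hilbert_phase(xs, fs))$plv
  }, numeric(1))
  expect_lt(observed, quantile(null_plv, 0.95) + 0.1)
})

test_that("EEG preprocessing removes pulse artifacts but keeps beta", {
  fs <- 1024
  ps <- list(frequency = 20, pulse_times = (0:(20 * 30 - 1)) / 20)
  art <- simulate_eeg(20, 0, ps, noise_sd = 0.05, pink_sd = 0,
                      free_beta_amp = 0, artifact_amp = 100,
                      duration = 30, fs = fs, seed = 3)
  y <- eeg_preprocess(art)
  rep_art <- attr(y, "artifact_report")
  expect_gt(rep_art$raw_excess, 10)
  expect_lt(rep_art$residual_fraction, 0.01)
  # a 22 Hz component passes with < 1% amplitude change
  t <- (0:(30 * fs - 1)) / fs
  tone <- sin(2 * pi * 22 * t)
  y22 <- eeg_preprocess(tone + 5, fs = fs)  # DC offset also removed
  expect_equal(fourier_amplitude_at(y22, fs, 22), 1, tolerance = 0.01)
  expect_lt(abs(mean(y22)), 0.05)
})

test_that("Fourier amplitude recovers exact-bin sinusoids and flags errors", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  expect_equal(fourier_amplitude_at(3.2 * sin(2 * pi * 25 * t), fs, 25), 3.2)
  expect_equal(fourier_amplitude_at(numeric(10 * fs) , fs, 25), 0)
  expect_error(fourier_amplitude_at(t, fs, 600), "Nyquist")
  expect_error(fourier_amplitude_at(t[1:100], fs, 25), "10 cycles")
  # amplitude in noise within 3x the neighboring-bin noise floor
  set.seed(23)
  x <- 2 * sin(2 * pi * 25 * t) + rnorm(length(t))
  X <- 2 * Mod(fft(x)) / length(x)
  k <- 25 * length(x) / fs
  floor_se <- sd(X[(k - 20):(k + 20)][-21])
  expect_lt(abs(fourier_amplitude_at(x, fs, 25) - 2), 3 * floor_se)
})

test_that("cycle averages converge on the locked component", {
  fs <- 1024
  f <- 16
  dur <- 40
  t <- (0:(dur * fs - 1)) / fs
  locked <- 0.6 * sin(2 * pi * f * t)
  pulses <- (0:(dur * f - 2)) / f
  set.seed(31)
  x <- locked + rnorm(length(t), 0, 1)
  ca <- cycle_average(x, fs, pulses, f)
  truth <- 0.6 * sin(2 * pi * f * ca$time)
  expect_lt(sqrt(mean((ca$mean - truth)^2)), 3 / sqrt(ca$n_epochs))
  # three full cycles per epoch: spectral argmax of the mean epoch at f
  spec <- Mod(fft(ca$mean))[2:floor(length(ca$mean) / 2)]
  f_axis <- (2:floor(length(ca$mean) / 2) - 1) * fs / length(ca$mean)
  expect_equal(f_axis[which.max(spec)], f, tolerance = 0.5)
  # pure noise: mean epoch mostly inside its own confidence band
  y <- rnorm(length(t))
  can <- cycle_average(y, fs, pulses, f)
  expect_gt(mean(abs(can$mean) <= (can$ci_high - can$ci_low) / 2), 0.9)
  expect_error(cycle_average(x, fs, pulses[1], f), "2 complete epochs")
})
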