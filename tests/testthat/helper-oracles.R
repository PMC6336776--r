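# Independent oracles used across tests. These re-derive quantities by the
# most direct route available (unbinned statistics, brute-force enumeration,
# numerical integration) and never call the code paths they check.

# unbinned mean resultant length of a set of phases
mrl_oracle <- function(phi) Mod(mean(exp(1i * phi)))

# attenuation of an n-bin histogram relative to the unbinned resultant for
# phases smoothly distributed within bins: sinc(pi / n)
bin_attenuation <- function(n_bins) sin(pi / n_bins) / (pi / n_bins)

# brute-force fixed-volume top-field mean: explicit loop over ranked voxels
top_volume_oracle <- function(values, voxel_volume, target) {
  v <- sort(values, decreasing = TRUE)
  vol <- 0
  total <- 0
  k <- 0
  while (vol < target) {
    k <- k + 1
    vol <- vol + voxel_volume
    total <- total + v[k]
  }
  total / k
}

# unwrap a phase series (cumulative correction of 2*pi jumps)
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# numerical half-cycle charge of a sampled waveform (mA at fs Hz -> mC)
numeric_half_cycle_charge <- function(samples, fs, frequency) {
  half <- round(fs / frequency / 2)
  sum(abs(samples[seq_len(half)])) / fs
}
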