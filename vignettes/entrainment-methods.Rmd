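---
title: "Quantifying entrainment to rhythmic electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying entrainment to rhythmic electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

## The problem

Transcranial alternating-current stimulation (tACS) passes a weak sinusoidal
current through scalp electrodes with the aim of entraining cortical
oscillations. Whether the observed motor effects are *transcranial* (the
weak field in cortex acting on neurons directly) or *transcutaneous*
(electrical excitation of peripheral nerves in the skin, relayed centrally)
can only be separated by measuring entrainment under controlled montages,
scalp anesthesia, and matched stimulation waveforms. `entrainr` implements
the complete measurement chain for this question: spike-train entrainment in
animal recordings, tremor entrainment from accelerometry, EEG entrainment to
pulsed stimulation, direct electric-field estimation from laminar probes,
and the statistical contrasts that compare conditions — together with
synthetic-data generators so that every stage can be validated against known
ground truth.

## The phase-locking value

One statistic quantifies entrainment everywhere in the package. Phases (of
spikes relative to the stimulus cycle, or per-sample stimulus–signal phase
differences) are pooled into $n = 30$ equal bins on $[0, 2\pi)$ with
probability mass $R_b$ and centres $\theta_b$, and

$$\mathrm{PLV} = \Bigl|\sum_b R_b\, e^{i\theta_b}\Bigr|.$$

If all mass falls in one bin, $\mathrm{PLV} = 1$; mass spread equally over
the equally spaced bins cancels exactly and gives $\mathrm{PLV} = 0$.
Binning attenuates the unbinned mean resultant length by
$\mathrm{sinc}(\pi/30) \approx 0.9945$ for smooth phase distributions — a
negligible bias that the test suite verifies against an unbinned oracle.

Bin edges are half-open, $[2\pi k/30,\, 2\pi(k+1)/30)$, with centres at
$(k + \tfrac12)\,2\pi/30$; the bin convention is shared by the spike and
phase-difference pipelines. Empty histograms return PLV 0 rather than `NaN`
so population summaries stay total.

```{r plv-endpoints}
phase_histogram(c(1, rep(0, 29)))$plv   # perfect locking
phase_histogram(rep(1 / 30, 30))$plv    # uniform: exact cancellation
```

## Stimulus waveforms and phase conventions

`make_sine()` builds the sinusoidal stimulus with an exact analytic phase
ramp; the package-wide convention places phase 0 at the positive-going zero
crossing, so the waveform equals $A\sin(\phi)$. `hilbert_phase()` is aligned
to the same convention (the raw analytic-signal angle is shifted by
$\pi/2$), so the Hilbert phase of a clean sine equals its analytic ramp. The
stimulus phase origin is arbitrary for every statistic here — PLV is
invariant to constant phase offsets — but one consistent convention keeps
the pipelines comparable.

`make_pulse_train()` builds the pulsed stimulus used for artifact-free EEG
entrainment: one rectangular biphasic pulse per period, anodic phase first,
equal phase widths, no interphase gap (the minimal shape consistent with a
stated width per phase), hence exactly charge balanced. Its phase is the
sawtooth rising linearly from 0 to $2\pi$ between consecutive pulses.
`assumed_phase()` provides the stimulation-OFF convention: a uniform ramp at
the nominal frequency starting at 0 at segment onset, equivalent to assuming
a sine at the stimulus frequency is present but not stimulating.

Charge per stimulus phase is closed-form: $A\,w$ for a rectangular pulse
phase of width $w$, and $\int_0^{T/2} A \sin \mathrm{d}t = A/(\pi f)$ for a
sine half-cycle; with milliamps and milliseconds/seconds these come out
directly in mC:

```{r charge}
charge_per_phase(make_pulse_train(20, 6.33, 0.44, 1, 30000))
charge_per_phase(make_sine(20, 2.5, 1, 4096))
```

The pulsed waveform delivers under 10% of the sinewave charge per phase at
matched sensation — the motivation for using it when the recording channel
cannot tolerate a sinusoidal artifact.

## Synthetic data: what it emulates and what it does not

The generators are the package's test bed; their defaults encode the experimental
conditions the analyses were designed for.

* **Spike trains** (`simulate_spike_train()`): 1 min of homogeneous Poisson
  firing (OFF) followed by 1 min of inhomogeneous Poisson firing (ON) with
  rate $r(1 + m \sin(h\phi))$, simulated by thinning against the
  $r(1 + m)$ envelope — exact, and with the useful closed form that the
  phase distribution's resultant is $m/2$. The harmonic $h \in \{1, 2\}$
  models neurons that entrain at double the stimulation frequency.
* **Tremor** (`simulate_tremor()`): the dominant accelerometer axis mixes a
  free tremor oscillation, whose phase performs a Wiener walk (default
  diffusion 2 rad²/s, giving a realistic drifting rhythm with ~1 s phase
  memory) around the nominal tremor frequency, with a stimulus-locked
  sinusoid, in proportion `locked_fraction`, plus white noise; the other two
  axes are attenuated copies with independent noise. A fixed-frequency OFF
  tremor at exactly the stimulation frequency would never decorrelate from
  the assumed stimulus phase and would spuriously inflate null PLV — the
  phase walk is what makes the OFF condition an honest null.
* **EEG** (`simulate_eeg()`): 1/f-shaped noise (spectral shaping of white
  noise) plus white noise plus a drifting free beta oscillation; the
  entrained component follows the sawtooth pulse phase, and each pulse adds
  a two-sample biphasic artifact.
* **Probe voltages** (`simulate_probe()`): a linear potential gradient along
  each of the three 25-µm-spaced contact columns
  (1 V/m ⇒ 25 µV per contact step), plus noise and optional spike
  transients.
* **Voxel fields** (`simulate_voxel_field()`): lognormal field magnitudes
  with known ordering, for the fixed-volume hot-spot summary.

None of these are biophysical models: there is no limb biomechanics, no
neuron model, no conductive head. Passing tests therefore demonstrate that
the *analysis* recovers known ground truth under the statistical structure
the analyses assume — not that real tissue behaves like the generators. In
particular the amplitude→entrainment dose–response is an input
(`locked_fraction`, `locked_amp`), not a prediction.

## The analysis chains

**Spikes.** `cycle_histogram()` assigns each spike the stimulus phase at
its time and normalizes counts over the condition; the spike rate per bin
(count over time spent in the bin) is kept as a second view of the same
histogram, but PLV always uses probabilities. `off_on_contrast()` builds
the OFF histogram with the assumed phase at the ON stimulus period and
reports `plv_dif = plv_on − plv_off`.
`select_entrainment_frequency()` compares the ON PLV at the stimulation
frequency and its double and selects the larger, with ties resolved to the
fundamental (the conservative choice; a tie carries no evidence for
harmonic entrainment). The selected frequency is applied to both OFF and
ON histograms so the contrast is like-for-like.

**Tremor.** Axes are bandpassed 3–30 Hz with a second-order Butterworth
filter applied forward–backward. Zero-phase filtering is a deliberate
choice: a one-way filter would add a frequency-dependent phase shift to the
tremor but not to the stimulus ramp, biasing every phase-difference
histogram; the cost is that the effective magnitude response is
fourth-order. PCA across the three filtered axes extracts the dominant
tremor direction; PC1's sign is fixed by positive correlation with the
highest-variance axis (PLV is sign-invariant; the convention only
stabilizes regeneration). Instantaneous phases of tremor and stimulus are
subtracted per sample, wrapped to $[0, 2\pi)$, binned, and summarized by
PLV.

**Hilbert edges.** The discrete analytic signal wraps around the record
ends, so two cycles at each segment edge are flagged and excluded from
histograms by default (configurable via `edge_cycles`). The cycle length
for flagging is taken from the dominant spectral component.

**EEG.** `eeg_preprocess()` bandpasses 0.3–100 Hz, which removes the brief
pulse artifact; when pulse times are known the residual is quantified as
excess power in 2-ms windows around pulses relative to the rest of the
record. The instantaneous EEG phase is extracted after an additional 16–30
Hz bandpass: a broadband signal has no meaningful single instantaneous
phase, so band-limiting to the beta band is required for the Hilbert step
even though the artifact filter alone defines the "clean" signal.
`fourier_amplitude_at()` returns the `2|X(f)|/N` amplitude of the whole
record's FFT bin nearest the stimulation frequency, and `cycle_average()`
gives the pulse-locked mean over three-cycle epochs with a 95% band.

**Spectral peaks.** `peak_frequency()` averages rectangular-window
periodograms over non-overlapping 1-s epochs (resolution 1 Hz by default;
the epoch length is configurable, and the estimator is deliberately the
simplest consistent with epoch averaging). A flat in-band spectrum (max
under twice the in-band median) raises a low-prominence warning rather than
an error.

**Electric fields.** `channel_amplitudes()` Fourier-transforms each of the
32 unfiltered probe channels at the stimulation frequency;
`estimate_field()` fits a least-squares slope of amplitude against depth
per contact column (µV/µm = V/m) and averages the three column magnitudes.
Least squares was chosen over adjacent differencing because it is exact on
a noiseless gradient, coincides with differencing for two contacts, and is
more robust otherwise; the sign is discarded because only field magnitudes
are compared. `scale_field()` applies the linearity of the field in the
injected current. `top_volume_mean()` ranks voxels high to low and averages
the smallest set reaching the target volume (default 10 mm³), including the
final voxel whole — the simplest reading of "the number of voxels needed" —
which upper-bounds the fractional-voxel variant by at most one voxel's
worth of volume.

## Statistics

`wilcoxon_signed_rank()` and `wilcoxon_rank_sum()` wrap the exact/
approximate machinery of `stats::wilcox.test` but always report the
normal-approximation Z (with tie correction) alongside, since Z values are
the comparable scale across sample sizes. Zero differences are discarded
(Wilcoxon's rule). Bonferroni correction multiplies by the stated number of
comparisons and caps at 1. One-sided contrasts always test
"more entrainment under stimulation". `cohens_d_paired()` divides the mean
paired difference by the SD of the differences. `fit_plv_model()` fits the
repeated-measures designs with a subject random intercept via REML
(`lme4`), reporting Wald normal-approximation p-values for fixed effects —
the simplest inference consistent with reporting a coefficient table; with
`random_intercept = FALSE` it reduces to OLS. `diagnostics()` provides the
KS normality check on the standardized sample and a two-sided Grubbs
outlier test (implemented directly from the t-distribution bound).

## Experiment pipelines and problem sizes

`run_experiment()` binds generators to analyses for five designs; all
randomness descends from one master seed, and `write_results()` emits a
tidy table plus a JSON manifest from which a run can be regenerated
exactly.

* `exp1`: units × three amplitude groups, OFF/ON spike contrasts, signed
  rank per group (Bonferroni n = 3), linear model `plv_dif ~ amplitude`.
* `exp2a`: 12 subjects × 2 days (saline vs. scalp anesthesia) × one 12-min
  session of three 4-min sequences
  (60 s LOW – 15 s gap – 30 s OFF – 15 s gap – 60 s HIGH – 15 s gap –
  30 s OFF – 15 s gap, LOW/HIGH order counterbalanced), giving
  12 × 2 × 3 × 3 = 216 PLV rows; mixed model
  `plv ~ amplitude × anesthesia + (1 | subject)` and nine post-hoc signed
  ranks. The two 30-s OFF blocks of a sequence are concatenated into one
  OFF estimate per repetition.
* `exp2b`: two groups of six patients (anesthesia at ~4.67 mA vs. none at
  2 mA), five OFF and five ON 1-min recordings in random order, per-group
  signed rank and paired Cohen's d.
* `exp3`: the exp2a session without the anesthesia factor;
  `plv ~ amplitude + (1 | subject)`.
* `exp4`: 12 subjects × 15 recordings (5 per OFF/LOW/HIGH, random order) of
  pulsed stimulation at the individual beta peak; per recording a PLV and
  the Fourier amplitude at the stimulation frequency;
  `plv ~ amplitude + (1 | subject)` and post-hoc contrasts (n = 3).

Default tremor/EEG sample rates in the pipeline configs are 512 Hz and
1024 Hz with 60-s exp4 recordings — the package's choice of problem size
for routine regeneration, ample for analysis bands below 100 Hz; the
generators themselves default to the nominal acquisition rates (4096 Hz
accelerometry/EEG, 30 kHz probe), and every rate and duration is a config
key. Subject-level frequencies and amplitudes are drawn around the default population
means (tremor 8.70 ± 0.62 Hz, HIGH amplitude 2.192 ± 0.499 mA; beta
22.08 ± 1.87 Hz, pulsed HIGH 6.33 mA with LOW half of it; patient tremor
3.33/3.75 ± 0.52 Hz). The per-condition locked fractions
(e.g. OFF 0, LOW 0.15, HIGH 0.4 without anesthesia; near 0 with) have no
empirical reference values — no amplitude→entrainment transfer function
exists to copy — they are chosen to give the qualitative dose–response the
designs probe, and are exposed directly in the config.

```{r exp3, eval = FALSE}
run <- run_experiment("exp3", seed = 7)
aggregate(plv ~ condition, run$results, mean)
run$model
```

## Numerical choices and degenerate inputs

* Phases are wrapped with `%%`, and values rounding to exactly $2\pi$ are
  assigned to the last bin; times landing exactly on a bin edge follow
  floating-point rounding, which only matters for artificial grid-aligned
  inputs.
* Exact Wilcoxon p-values are used for n ≤ 25 without ties; with ties the
  tie-corrected normal approximation is used (the exact distribution is not
  defined under ties).
* Zero-spike segments, all-zero signals, constant axes, zero-variance
  difference vectors and single-contact columns each produce a defined
  result or a targeted error, never silent `NaN`s.
* `fit_plv_model()` with near-zero subject variance returns a boundary
  ("singular") REML fit; its fixed effects then coincide with OLS, which
  the tests check.

## Limitations

The generators share the analyses' modelling assumptions (sinusoidal locked
components, stationary noise), so they cannot detect misspecification that
real recordings might expose — e.g. non-sinusoidal tremor waveforms,
amplitude–phase coupling, or slow electrode drift. PLV inference across
autocorrelated samples is deliberately descriptive: significance in the
pipelines comes from between-condition contrasts across subjects, never
from treating samples within a recording as independent. The head-model
side of field estimation is out of scope: only the voxel-field summary of
an externally computed field is implemented.
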