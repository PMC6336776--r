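# entrainr

Quantifying neural and tremor entrainment to rhythmic electrical
stimulation.

Transcranial alternating-current stimulation (tACS) drives a weak
sinusoidal current through scalp electrodes; whether its motor effects act
through the cortex directly (transcranial) or through electrical excitation
of skin nerves (transcutaneous) is decided by measuring *entrainment* —
how strongly spikes, tremor or EEG lock to the stimulus phase — under
controlled montages and conditions. `entrainr` implements that measurement
chain end to end, for electrophysiologists and human-neuroscience labs
analysing stimulation experiments:

* **Phase-locking value (PLV).** Phases are pooled into 30 bins with mass
  R_b and centres θ_b, and PLV = |Σ_b R_b e^{iθ_b}|: 1 when all mass falls
  in one bin, exactly 0 for uniform mass. The same statistic serves
  spike-train cycle histograms and stimulus–signal phase-difference
  histograms.
* **Spike pipeline:** cycle histograms over stimulus phase, OFF/ON
  contrasts with an assumed OFF-phase ramp, selection between the
  stimulation frequency and its double, spike rates.
* **Tremor pipeline:** 3–30 Hz zero-phase Butterworth filtering, PCA across
  accelerometer axes, Hilbert instantaneous phase, 30-bin phase-difference
  histograms.
* **EEG pipeline:** 0.3–100 Hz artifact-removing preprocessing for biphasic
  pulsed stimulation, sawtooth pulse phase, Fourier amplitude at the
  stimulation frequency, pulse-locked cycle averages, and per-phase charge
  accounting (pulse: A·w; sine half-cycle: A/(πf)).
* **Field estimation:** per-channel Fourier amplitudes on a 32-contact
  laminar probe, least-squares depth gradients per contact column (V/m),
  linear scaling in current, and the fixed-volume top-field voxel summary.
* **Statistics:** Wilcoxon signed-rank/rank-sum with Z statistics and
  Bonferroni capping, paired Cohen's d, linear mixed models with subject
  random intercepts, KS normality and Grubbs outlier diagnostics.
* **Synthetic data + pipelines:** generators with controllable ground truth
  (modulation depth, locked fraction, field strength) and
  `run_experiment()` drivers that rebuild each supported experimental design from one seed.

## Worked example

Spike entrainment for one synthetic unit — 1 min Poisson firing (OFF), then
1 min firing modulated at depth 0.8 by a 1.5 Hz stimulus (ON):

```r
library(entrainr)
st <- simulate_spike_train(baseline_rate = 20, mod_depth = 0.8,
                           lock_freq = 1.5, seed = 42)
st
#> <spike_train> 2432 spikes (1247 OFF / 1185 ON), stim 1.5 Hz
ct <- off_on_contrast(st)
sprintf("PLV OFF = %.3f, ON = %.3f, dif = %.3f",
        ct$plv_off, ct$plv_on, ct$plv_dif)
#> "PLV OFF = 0.023, ON = 0.392, dif = 0.369"
```

The ON PLV sits near the closed-form m/2 = 0.4 for a (1 + m·sin) rate
profile, while the OFF PLV is at the finite-sample null — the unit is
entrained by the stimulus, not by chance.

A whole tremor experiment (six subjects here; amplitude coded
OFF/LOW/HIGH = 0/1/2):

```r
run <- run_experiment("exp3", config = list(n_subjects = 6, fs = 256),
                      seed = 7)
aggregate(plv ~ condition, run$results, mean)
#>   condition       plv
#> 1      HIGH 0.5930419
#> 2       LOW 0.2135922
#> 3       OFF 0.1692991
run$model
#> <plv_model_fit> plv ~ amplitude_level + (1 | subject)
#>              term estimate      se      z         p
#> 1     (Intercept)   0.1134 0.02484  4.567 4.944e-06
#> 2 amplitude_level   0.2119 0.01810 11.706 1.190e-31
#> random-intercept variance: 0.0004256
```

Tremor entrainment increases with stimulation amplitude, and the mixed
model attributes it to a positive amplitude effect over and above subject
baselines.

## Layout

* `R/` — waveforms, generators, spike/signal entrainment, field
  estimation, statistics, pipelines, text I/O.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (unbinned resultants, brute-force enumeration,
  surrogate nulls).
* `vignettes/entrainment-methods.Rmd` — the model, conventions, design
  choices and limitations in full.
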