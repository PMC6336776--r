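Package: entrainr
Title: Quantifying Neural and Tremor Entrainment to Rhythmic Electrical
    Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for entrainment of neural and motor signals to
    transcranial or transcutaneous alternating-current stimulation (tACS).
    Implements cycle histograms and the phase-locking value (mean resultant
    length of phase-binned probability mass) for spike trains, Hilbert-phase
    phase-difference histograms for postural tremor, steady-state EEG
    entrainment to biphasic pulse trains, electric-field estimation from
    laminar probe voltages, a fixed-volume top-field voxel summary, and the
    accompanying statistical contrasts (Wilcoxon tests with Bonferroni
    correction, paired Cohen's d, linear mixed models with subject random
    intercepts). A synthetic-data module generates spike trains, tremor,
    EEG, probe voltages and voxel fields with controllable phase locking so
    every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
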