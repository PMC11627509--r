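# shepadapt

Contextual adaptation and decoding of Shepard-tone sequences in simulated
auditory cortex.

A Shepard tone — a complex of equal-amplitude, octave-spaced partials — has
a well-defined *pitch class* on a 12-semitone circle (440 Hz ↦ pitch class
0) but an ambiguous pitch height. Two Shepard tones half an octave apart
are heard bistably as an ascending or a descending step, and a preceding
*bias* sequence drawn from the 5 semitones above or below the first tone
reliably determines the percept. `shepadapt` is a synthetic test bed for
the cortical account of this effect, aimed at auditory/computational
neuroscientists: it generates the stimulus paradigms, simulates adapting
neural populations, and runs the population decoders and
direction-selectivity analyses that connect adaptation to the percept.

The core model is a two-layer rate model: mid-level units with von Mises
Shepard tuning

    M_j(φ) = exp( cos(2π/12 (φ − φ_j)) / ((2π/12) σ_j)² ) / M_total

drive cortical cells through Shepard spectrotemporal receptive fields
(SSTRFs) whose thalamocortical synapses depress locally:

    R_i(t) = 1/J Σ_j Σ_τ SSTRF_i(τ, j) (1 − A_ij(t)) T_j(t − τ)
    A_ij  ← clip( (A_ij + F_A · d_ij · (1 − A_ij)) (1 − F_R), 0, 1 )

with `F_R` set so adaptation recovers with a 1.2 s time constant and `F_A`
calibrated so the population onset response over a bias train decays with
a 3.9-stimulus time constant. Direction-selective cells carry an extra
SSTRF lobe at 150–250 ms lags (peak 0.25, offset 3 st below the best pitch
class for up-preferring cells, above for down-preferring). Two readouts
are contrasted: decoding the represented pitch class (PCA pitch-circle and
complex-domain population vector) exposes a *repulsive* shift away from
the bias, while a directionality-weighted decoder over near-tone cells
predicts the percept itself.

## Worked example

```r
library(shepadapt)

cfg <- run_config(cohort = cohort_config(n = 200L), seed = 11,
                  run_tuning = FALSE, run_ablations = FALSE)
rep <- run_all(cfg)
print(rep)
```

```
== Shepard-tone adaptation pipeline report ==
Units selected: 191 / 200
Training-set decode: circular correlation 0.941, aligned Pearson r 0.990
Bias-induced decoded shift: mean 0.465 st away from bias (n = 192 test tones)
  by bias length:
    L = 5   +0.434 st (SEM 0.028)
    L = 10  +0.495 st (SEM 0.023)
Adapting fraction: 0.91; build-up tau 12.98 stimuli; plateau 34.3%; recovery tau 1.20 s
Directional prediction accuracy (fraction of conditions):
   role length   correct
1 test1      5 0.8125000
2 test2      5 0.7083333
3 test1     10 0.7291667
4 test2     10 0.5833333
Near-tone ANOVA p-values:
List of 1
 $ full: num 1.73e-10
```

Reading the report: 191 of 200 simulated units pass the driven/tuned
selection; the pitch-circle decoder tracks the training tones tightly
(aligned Pearson r = 0.990); the decoded pitch of the ambiguous pair is
shifted ~0.4–0.5 st *away* from the bias, more for 10-tone than 5-tone
biases — the repulsive effect that rules out a circular-distance account
of the percept. The directional decoder predicts the defined percept well
above chance (best for the first tone), and the near-tone ANOVA confirms
that up- vs down-preferring cells near the test tones are differentially
adapted. The build-up time constant printed here is inflated by the
directional cells' late response component at the first bias position; the
methods vignette (`vignettes/shepadapt-methods.Rmd`) explains this and the
calibration behind `F_A`/`F_R`.

Individual stages are exported directly: `generate_biased_pair_set()`,
`generate_biased_tuning_set()`, `to_spectrogram()`, `make_population()`,
`run_dynamic_model()`, `simulate_experiment()`, `select_units()`,
`fit_pca_circle()` / `decode_pitch()`, `population_vector_decode()`,
`measure_bias_shift()`, `estimate_sstrf()`, `directionality_index()`,
`directional_decode()`, `differential_response_map()`, `near_tone_test()`,
`psth_windows()`, `classify_response_type()`, `recovery_fit()`,
`biased_tuning()`, `tuning_halfwidth()`, `calibrate()`.

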