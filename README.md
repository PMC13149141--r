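# crvcoupling

Cardio-respiratory-vascular (CRV) coupling analysis of synchronous
physiological recordings in R.

Heart rate, breathing and arterial pressure form a coupled oscillator
network: respiration modulates heart period (respiratory sinus arrhythmia)
and pulse pressure (the respiratory pump), while baroreflex loops and the
~0.1 Hz Mayer wave tie pressure and heart period together. `crvcoupling`
measures the joint dynamics of this network from a few minutes of
synchronous single-lead ECG, thoracic-effort respiration and continuous
blood pressure. It is aimed at physiologists and biosignal researchers who
want reproducible coupling metrics — strength *and* complexity — plus the
standard HRV/respiratory/hemodynamic feature set and cohort statistics,
without stitching together half a dozen tools.

## The method in brief

For each record the pipeline produces four cleaned series on one 8 Hz grid
(respiration effort, R-R intervals, systolic and diastolic pressure), then:

1. **Ensemble empirical mode decomposition** of each series (noise
   amplitude 0.2 SD, 100-member ensemble, fixed 8 sifting iterations).
2. **Mode selection**: the highest-energy respiration mode is the
   reference; for RRI/SBP/DBP the mode whose mean Hilbert instantaneous
   frequency is closest to the reference is taken as its
   respiration-matched component.
3. **Sliding-window phase synchronization** for the five pairs RSP-RRI,
   RSP-SBP, RSP-DBP, SBP-RRI, DBP-RRI: in windows of T = 50 s stepped by
   1 s,

   `rho_i = | (1/T) ∫ exp(i Δφ(t)) dt |  ∈ [0, 1]`

   with Δφ the 1:1 instantaneous phase difference. The time-mean of each
   series is the pairwise **coupling strength**.
4. **Refined composite multiscale entropy** (m = 2, r = 0.15 SD, scales
   1–3) of each synchronization series, averaged over scales, is the
   pairwise **coupling complexity**.
5. **Composite totals**

   `rho_total = rho_RSP-RRI + (rho_RSP-SBP + rho_RSP-DBP)/2 + (rho_SBP-RRI + rho_DBP-RRI)/2`

   and identically for `C_total`.

Cohort statistics: one-way ANOVA with Bonferroni-corrected pairwise
comparisons over all 10 group pairs, and Spearman rank-correlation
matrices between coupling and physiological features.

Because synchronized multi-channel recordings of this kind are rarely
shareable, the package includes a synthetic-record generator
(respiratory phase oscillator + integrate-and-fire heart + per-beat
pressure model) with exact ground truth and five group presets (HA0–HA4)
that impose recoverable gradients; every pipeline stage is validated
against that truth. See the methods vignette
(`vignettes/crv-coupling-methods.Rmd`) for the full account.

## Worked example

```r
library(crvcoupling)

rec <- simulate_record(crv_params(duration = 300, seed = 42,
                                  coupling_jitter = 0.3),
                       subject_id = "S1", group_label = "HA1")
prep <- preprocess_record(rec, apply_notch = FALSE)  # synthetic: no mains hum
cp <- coupling_profile(prep$rsp, prep$rri, prep$sbp, prep$dbp, seed = 1)
print(cp)
```

```
<coupling_profile>
  dominant respiration frequency: 0.249 Hz 
           RSP-RRI RSP-SBP RSP-DBP SBP-RRI DBP-RRI
strength     0.949   0.961   0.930   0.922   0.879
complexity   0.603   0.584   1.157   0.650   0.851
  rho_total = 2.795   C_total = 2.225   (grouping: primary)
```

The respiration reference sits at the generated breathing rate (0.25 Hz).
With mild coupling jitter (0.3 rad) all five pairs remain strongly phase
locked (strengths above 0.85), so the composite `rho_total` stays near its
ceiling of 3. Raising `coupling_jitter` lowers the strengths
monotonically.

A full feature row (HRV, respiration, hemodynamics, coupling) for the same
record:

```r
row <- run_record(rec, seed = 1, apply_notch = FALSE)
round(unlist(row[c("MeanRR", "SDNN", "LF_HF", "SampEn", "BR", "BR_CV",
                   "SBP", "DBP", "rho_total", "C_total")]), 3)
```

```
   MeanRR      SDNN     LF_HF    SampEn        BR     BR_CV       SBP       DBP 
  998.247    37.257     0.355     1.748     0.249     0.038   114.602    69.365 
rho_total   C_total 
    2.795     2.225 
```

Mean R-R ≈ 998 ms matches the default 60 bpm heart rate; SDNN combines the
50 ms RSA, the 25 ms low-frequency modulation and the broadband HRV noise;
the generated breathing rate and baseline pressures are recovered to
within a fraction of a percent.

Cohorts: `simulate_cohort(n_per_group = 12, seed = 1)` →
`run_cohort()` → `anova_bonferroni()` / `spearman_matrix()`. A thin CLI
wrapper for both steps is installed at `inst/cli/crv.R`.

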