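# emgcoh

Tools for quantifying **central common drive** and **functional reciprocal
inhibition** from surface electromyography, aimed at motor-control and
rehabilitation physiologists working with paired intramuscular EMG
recordings, stimulus-locked H-reflex sweeps and dynamometer torque traces.

Two analyses form the core:

1. **Intramuscular EMG–EMG coherence.** Two electrode sites over the same
   muscle (e.g. proximal and distal tibialis anterior) pick up partially
   independent motor-unit populations. Rhythmic synaptic input shared across
   the motoneuron pool appears as coherence between the rectified,
   unit-variance-normalised EMGs. For signals *x*, *y* split into *L*
   disjoint segments of *T* samples, the package estimates autospectra
   *f<sub>xx</sub>(λ)*, *f<sub>yy</sub>(λ)*, cross-spectrum
   *f<sub>xy</sub>(λ)* and

   - coherence *R²<sub>xy</sub>(λ) = |f<sub>xy</sub>|² / (f<sub>xx</sub>
     f<sub>yy</sub>)* with its independence-null 95% limit
     *1 − 0.05<sup>1/(L−1)</sup>*,
   - phase *Φ<sub>xy</sub>(λ)* and the cumulant density *q<sub>xy</sub>(u)*
     (time-domain synchronisation, ±250 ms) with a flat ±1.96·√Var null band,
   - a cross-talk QC rule (broad-band coherence AND a significant cumulant
     peak at near-zero lag),
   - segment-weighted **pooled coherence** per group, the pooled cumulant,
     and the per-frequency **χ² difference-of-coherence test** between two
     groups built on arctanh-stabilised pooled coherency,
   - alpha (5–15 Hz) and beta (15–35 Hz) **coherence areas** (summed
     per-bin coherence, log₁₀-transformed) with Student's *t* group
     comparison and Pearson correlations.

2. **H-reflex suppression at movement onset.** Soleus H-reflexes evoked at
   rest and at the onset of dorsiflexion, each normalised to the maximal
   M-response (M<sub>max</sub>), quantify the ability to suppress antagonist
   motoneuron excitability: `percent_suppression = 100·(rest − onset)/rest`.
   Supporting functions cover M<sub>max</sub> recruitment plateaus,
   peak-to-peak window amplitudes, a group × state mixed ANOVA, MVC peak
   torque, rate of force development over the first 200 ms (RFD₂₀₀),
   countermovement rejection and a cocontraction index.

A seeded synthetic-data module generates inputs with the statistical
structure these analyses assume — motor-unit pools sharing a band-limited
oscillatory drive (with optional electrode cross-talk), H-reflex sweep sets
with configurable suppression, and torque trials — so every stage of the
pipeline can be validated end to end.

## Worked example

```r
library(emgcoh)

# simulate a 2-minute static contraction with moderate common drive
rec <- simulate_common_drive_emg(drive_sim_config(kappa = 0.6, seed = 1))
x <- condition_emg(rec$samples[, "TA_prox"], rec$fs, band = NULL)
y <- condition_emg(rec$samples[, "TA_dist"], rec$fs, band = NULL)
est <- estimate_spectra(x, y, resolution_hz = 1)
est
#> <spectral_estimate> L=120 segments of T=2000 samples (1 Hz resolution)
#>   95% coherence limit 0.0249; 18 of 1-60 Hz bins above it

cum <- cumulant_density(est)
crosstalk_qc(est, cum)
#> <crosstalk_report> broadband fraction 0.30; peak at +5.5 ms (zero-lag: no) -> clean

coherence_band_areas(est)$beta
#> <band_area> 15-35 Hz (21 bins): area 0.6708, log10 -0.173
```

18 of the 60 bins between 1 and 60 Hz exceed the 95% limit (3 would be
expected by chance), the cumulant peaks at +5.5 ms — a distinct, nonzero
conduction lag, so the coherence is not electrode cross-talk — and the beta
band carries a coherence area of 0.67 (log₁₀ ≈ −0.17).

Group-level comparison of strong- versus weak-drive records:

```r
analyse <- function(kappa, seed) {
  r <- simulate_common_drive_emg(drive_sim_config(kappa = kappa,
                                                  duration_s = 60, seed = seed))
  estimate_spectra(condition_emg(r$samples[, 1], r$fs, band = NULL),
                   condition_emg(r$samples[, 2], r$fs, band = NULL))
}
con <- lapply(1:8, function(i) analyse(0.6, 100 + i))
cp  <- lapply(1:8, function(i) analyse(0.2, 200 + i))
chi2_difference_test(con, cp)
#> <coherence_difference> df=1, 95% threshold 3.84; 15 of 60 1-60 Hz bins differ
```

and the reflex side:

```r
sets <- simulate_hreflex_dataset(hreflex_sim_config(n_subjects_per_group = 3,
                                                    seed = 5))
suppression_result(extract_reflex_amplitudes(sets[[1]]),
                   extract_reflex_amplitudes(sets[[2]]))
#> <suppression_result> S01: H 53.8% M_max at rest -> 32.8% at onset (39.0% suppression)
```

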