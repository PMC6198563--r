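---
title: "Methods: intramuscular coherence, reflex suppression and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intramuscular coherence, reflex suppression and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgcoh)
```

This vignette documents the statistical machinery in `emgcoh`: the estimator
conventions, the generative model behind the synthetic-data module, the
defaults of every tunable parameter, and the design decisions taken where
the methodology left genuine choices open. Nothing here states an empirical
result that the package's test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Signal model and preprocessing

Surface EMG from two electrode sites over the same muscle is treated, after
conditioning, as a pair of realisations of stationary zero-mean time series
$x$ and $y$. Conditioning is a fixed pipeline — band-pass (optional for
simulated data, which is band-limited at source), full-wave rectification,
then normalisation to zero mean and unit variance — recorded step by step in
the signal's `provenance` attribute. Rectification converts the
interference EMG into a signal whose modulations track motor-unit firing
times; normalisation makes records of different gain commensurate before
pooling.

Two conventions are fixed deliberately:

* **Population variance (1/N).** "Unit variance" is enforced at the level of
  the realisation itself, so `sum(x^2)/N == 1` exactly. The difference from
  the $1/(N-1)$ convention is immaterial at $N \geq 10^5$ samples but must
  be pinned down for exact tests.
* **Zero-phase filtering.** The band-pass is applied forward and backward
  (Butterworth via `signal::filtfilt`). A causal filter would add a
  frequency-dependent group delay to each channel, which would bias exactly
  the quantity the time-domain analysis reads out (the cumulant lag).

## 2. Disjoint-segment spectral estimation

`estimate_spectra()` splits both signals into $L$ disjoint, non-overlapping,
untapered segments of $T = f_s / \Delta$ samples (resolution $\Delta$,
default 1 Hz, so $T = 2000$ at $f_s = 2$ kHz; a trailing partial segment is
discarded) and averages per-segment periodograms:

$$\hat f_{ab}(\lambda_k) = \frac{1}{L T^2} \sum_{l=1}^{L}
  \overline{A_l(\lambda_k)}\, B_l(\lambda_k),$$

with $A_l, B_l$ the segment DFTs. This scaling makes the full-axis sum of
$\hat f_{xx}$ equal the segment-mean signal power (discrete Parseval), which
the test suite checks to $10^{-6}$ relative error. The
$\overline{A}\,B$ orientation means a **positive** cumulant lag and a phase
slope of $-2\pi\,\tau$ both indicate that $y$ lags $x$ by $\tau$.

Coherence, phase and the confidence limit follow directly:
$R^2_{xy} = |\hat f_{xy}|^2/(\hat f_{xx}\hat f_{yy})$,
$\Phi_{xy} = \arg \hat f_{xy}$, and under independence the per-bin null
distribution of $R^2$ is $\mathrm{Beta}(1, L-1)$, so the upper 95% limit
$1 - 0.05^{1/(L-1)}$ is exact for this estimator class — the reason for
choosing plain disjoint rectangular segments over tapered or overlapped
variants. No zero-padding is used, keeping bin centres at integer
frequencies for a 1 Hz resolution.

Numerical details: each segment is demeaned before its DFT. Demeaning
annihilates exactly the DC coefficient, whose floating-point residue is
therefore cleared explicitly; the DC bin then carries zero spectra and zero
coherence rather than a $0/0$ artifact. Reported frequencies run from 0 to
Nyquist; all band statistics and QC are restricted to 1–60 Hz.

## 3. Cumulant density and its null band

`cumulant_density()` inverts the estimated cross-spectrum over the full
(two-sided) frequency axis and restricts lags to ±250 ms. Under the
independence null the variance of the cumulant estimate is lag-constant.
With the scaling above it is

$$\widehat{\mathrm{Var}}(q) = \frac{1}{L} \sum_{k=0}^{T-1}
  \hat f_{xx}(\lambda_k)\, \hat f_{yy}(\lambda_k),$$

derived by pairing Hermitian-symmetric bins (each interior bin contributes
twice the half-variance of its real projection) and verified by Monte-Carlo
coverage before the constant was frozen into tests: for independent
unit-variance channels, ~95% of lags fall inside
$\pm 1.96\sqrt{\widehat{\mathrm{Var}}}$ (the suite asserts ≥ 93% on
average). Exact ties in the peak search resolve toward the smallest
absolute lag.

## 4. Cross-talk quality control

Volume-conducted cross-talk mimics common drive, but with a distinctive
signature: coherence across a broad frequency range combined with a
synchronisation peak at essentially zero lag. `crosstalk_qc()` flags a
record when the fraction of 1–60 Hz bins above the coherence limit exceeds
`broadband_threshold` (default 0.5) **and** the cumulant peak exceeds its
upper confidence limit within `zero_lag_ms` (default 3 ms) of zero.
Genuine common drive fails the second condition whenever the two recording
sites see distinct conduction delays — with the simulator's default 5 and
12 ms delays the peak sits near +7 ms.

## 5. Pooled coherence and the χ² difference test

Pooling operates on normalised per-record coherencies
$\hat c_i = \hat f_{xy,i} / \sqrt{\hat f_{xx,i} \hat f_{yy,i}}$, weighted by
segment counts:

$$\hat c_{\mathrm{pool}}(\lambda) = \frac{\sum_i L_i \hat c_i(\lambda)}
  {\sum_i L_i}, \qquad R^2_{\mathrm{pool}} = |\hat c_{\mathrm{pool}}|^2,$$

with the confidence limit evaluated at $L = \sum_i L_i$. Working on
coherencies (rather than summing raw spectra) keeps records with different
power scales commensurate, consistent with unit-variance preprocessing; the
raw-spectra alternative remains available via
`pool_coherence(..., method = "spectra")` for sensitivity analysis. The
pooled cumulant inverts $\hat c_{\mathrm{pool}}$ on the same normalised
basis, with null variance $1/(T \sum_i L_i)$ per lag. One consequence,
verified in the tests: for a single record the pooled cumulant equals the
individual cumulant only up to the whitening by the autospectra — peak
location agrees to within a sample, amplitudes differ slightly.

The between-group comparison stabilises each group's pooled coherency
modulus as $z_g = \mathrm{arctanh}\,|\hat c_{\mathrm{pool},g}|$, whose
large-sample variance is $1/(2\sum_i L_i)$. With weights
$w_g = 2 \sum_i L_i$,

$$\chi^2(\lambda) = \sum_g w_g\, (z_g - \bar z_w)^2,
  \qquad \bar z_w = \frac{\sum_g w_g z_g}{\sum_g w_g},$$

is compared per frequency with the 95% point of $\chi^2_{g-1}$ ($g = 2$
groups here, so df = 1). No correction for multiple testing across
frequencies is applied; each bin is read against its own 95% threshold, the
per-frequency presentation conventional for pooled-coherence group
comparisons.

**Domain of validity.** The arctanh approximation requires the pooled
coherency modulus to be resolved away from zero (roughly
$|c|\sqrt{2\sum L} \gtrsim 3$). Monte-Carlo calibration during development
showed the test holds its 5% size on Gaussian coherent pairs and on
simulated EMG groups with a strong common drive, but becomes *conservative*
(rejection ≈ 3%) where pooled $|c| \approx 0.1$, because the modulus of a
near-zero complex estimate folds to a Rayleigh-like distribution. It is
never anticonservative. The validation suite therefore evaluates the 5%
type-I property under a strong-drive null — both groups at coupling 0.8,
15 records of 30 s per group, 100 replicate experiments, frequencies 8–33 Hz
(the interior of the driven 5–35 Hz range) — and checks power separately
(coupling 0.6 vs 0.2, 60 s records, significance concentrated in the beta
band). At 30 s the beta-band significant fraction under that contrast
straddles one half; 60 s records resolve it clearly, which is why the power
study uses the longer records.

## 6. Band areas and group statistics

`band_area()` sums per-bin coherence over a band and reports
$\log_{10}$ of the area; the log transform symmetrises the right-skewed
area distributions before Student's *t*. Log base 10 keeps typical areas of
order 0.1–1.5 on a convenient scale. The alpha and beta bands share the
15 Hz endpoint; to avoid double counting, the convenience wrapper
`coherence_band_areas()` assigns the boundary bin to beta only (alpha sums
[5, 15) Hz, beta [15, 35] Hz), making the two areas exactly additive over
[5, 35]. Zero areas have undefined logs and are excluded from group
comparisons with an explicit count — silent imputation would bias group
means. Correlations are ordinary Pearson product-moment tests.

## 7. Reflex and force metrics

All reflex amplitudes are window-restricted peak-to-peak values (samples in
$[t_0, t_1)$) normalised to M$_{\max}$. Defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| M-wave window | 5–25 ms post-stimulus | standard soleus direct-response latency |
| H-reflex window | 25–55 ms post-stimulus | standard soleus monosynaptic latency |
| M$_{\max}$ plateau tolerance | 1% relative increase over the final two intensity steps | "no further increase" needs a quantitative proxy |
| envelope smoothing | 50 ms moving average | conventional for cocontraction envelopes |
| countermovement threshold | 2% of trial peak torque | a "visible drop" needs a quantitative proxy |
| onset detection | baseline mean + 2 SD sustained ≥ 10 ms, 500 ms baseline | standard threshold rule |

`percent_suppression` is $100(\text{rest} - \text{onset})/\text{rest}$;
negative values signal facilitation. The group × state analysis is a mixed
two-way ANOVA (between = group, within = state) fitted through `aov` with
an `Error(subject)` stratum and cross-checked in the tests against a
hand-rolled sums-of-squares oracle (for a two-level within factor the
interaction F equals the one-way F on per-subject state differences). When
no subject shows any state difference the within-subject sums of squares
are pure floating-point residue; the interaction F is then reported as an
exact zero. Post-hoc within-group comparisons are paired *t*-tests without
multiplicity correction — a documented, switchable choice. RFD$_{200}$ is
the secant slope over the first 200 ms after onset,
$(\tau(t_{on}+0.2) - \tau(t_{on}))/0.2$.

## 8. The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, under the study conditions the analyses target.

**Common-drive EMG.** Each channel has its own pool of
`n_units_per_channel` (default 40) motor units — no shared units, mirroring
electrode placements separated beyond muscle-fibre length, so coherence can
only arise from shared *input*. Unit $i$ of channel $c$ fires as an
inhomogeneous point process with rate

$$r_{c,i}(t) = r_0 \cdot \max\!\big(0,\; 1 + g\,[\kappa\, s_c(t) +
  (1-\kappa)\,\xi_{c,i}(t)]\big),$$

where $s$ is one shared band-limited Gaussian drive (default 40% of its
power in 5–15 Hz, 60% in 15–35 Hz, matching the alpha-plus-dominant-beta
profile of static-contraction recordings), delayed per channel by
`drive_delay_ms` (default 5 and 12 ms — conduction to proximal and distal
sites), the $\xi_{c,i}$ are independent band-limited noises, $r_0$ = 10 Hz
(a typical sustained motor-unit rate), and $g$ = 0.5 sets the modulation
depth; the $\max(0,\cdot)$ keeps rates valid. Spike trains are convolved
with a biphasic action-potential kernel (first derivative of a Gaussian,
10 ms) with unit-to-unit amplitude heterogeneity, plus additive noise.
Channel 2 can be contaminated as $y' = y + c_{\mathrm{xt}} x$ to emulate
cross-talk. The record default is 120 s at 2 kHz — a two-minute static
contraction — giving $L = 120$ segments at 1 Hz resolution. $\kappa$ has no
empirical anchor; it is the abstract coupling knob, calibrated only
qualitatively (κ ≈ 0.6 produces individual coherence plots and band areas
of the magnitude seen in healthy static contractions, κ ≈ 0.2 markedly
weaker ones).

*Sampling.* Rates are band-limited below 35 Hz, so they are synthesised at
a decimated inner rate (≥ 4× the top band edge) and each unit's spike times
are drawn by exact time-rescaling inversion of the piecewise-linear
integrated rate, then binned at the full 2 kHz. This is statistically
equivalent to per-sample Bernoulli thinning at spike probabilities of
~0.005 per sample, but an order of magnitude faster, which the
Monte-Carlo validation depends on. All randomness flows from one master
seed through a documented splitting rule (`seed`, stream index), so every
record is bit-reproducible.

**H-reflex sweeps.** Every sweep holds fixed biphasic M and H templates
scaled to drawn amplitudes plus baseline noise. The M amplitude is held at
`m_target_pct` = 10% of M$_{\max}$ (SD 1%) — emulating the
stimulation-intensity control that keeps afferent input comparable across
states. The resting H-reflex mean is 40% of M$_{\max}$ (between-subject SD
15%, trial SD 5%), and the onset-state mean is scaled by
$1 - \text{suppression fraction}$ (default 0.37). 15 trials per state per
subject, 15 subjects, M$_{\max}$ = 8 mV, 80 ms sweeps at 2 kHz; baseline
noise 0.02 mV, small against the 0.8 mV M-wave so that peak-to-peak
extraction stays essentially unbiased. These defaults are the targeted
study conditions: resting H around 40% M$_{\max}$ with ~37% suppression for
control-like subjects, suppression 0 for the impaired-like configuration.

**Torque trials.** A smoothstep rise $\tau = P(3u^2 - 2u^3)$,
$u = (t - t_{on})/T_r$, with $T_r = 1.5P/\dot\tau_{\max}$ so the maximal
slope equals `rise_rate` exactly, exactly silent baseline before the onset
at 1 s, an optional Gaussian countermovement dip centred 150 ms pre-onset,
and additive noise. The compact support makes the nominal onset a genuine
ground truth for onset-detection validation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: nonstationarity (fatigue, drifting contraction
level), tremor peaks, motor-unit synchronisation beyond a single shared
drive, recruitment/derecruitment, stimulus artifacts, movement artifacts,
and powerline interference. The validation demonstrates that the estimators
and tests behave correctly *given* the assumed stationary common-drive
structure; it cannot certify robustness to violations of stationarity.

## 9. Problem sizes used in the validation suite

The suite favours a few deep, seeded Monte-Carlo checks over many shallow
ones. The main simulation scales, chosen as the package's own validation
design: confidence-limit coverage over 50 replicates of 120 s records;
cumulant coverage over 20 replicates of 30 s signal pairs; χ² type-I over
100 replicate two-group experiments (15 × 30 s records per group); χ² power
over 4 replicates at 60 s; kappa-monotonicity over 30 replicates per
coupling level at 60 s; suppression recovery at 10³–10⁴ trials per state.

## 10. Known limitations

* The χ² difference test is conservative at frequencies where pooled
  coherence is near zero (see §5); significance maps should be read inside
  the physiologically driven bands.
* Band areas are computed on individual-record coherence; pooled-estimate
  areas are available by passing a `pooled_coherence` to `band_area()` but
  the group *t*-test is defined on individual records.
* The reader for sampled signals expects the package's own CSV + JSON
  sidecar layout; vendor acquisition formats are out of scope.
* The mixed ANOVA covers the two-group × two-state design only.
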