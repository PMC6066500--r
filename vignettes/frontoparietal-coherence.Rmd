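---
title: "Resting-state frontoparietal coherence and visuomotor tracking gains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state frontoparietal coherence and visuomotor tracking gains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

After a hemiparetic stroke, the response to visuomotor training varies widely
between patients, and predictors of individual treatment response are needed.
One candidate predictor is resting-state functional connectivity between
ipsilesional primary motor cortex (iM1) and the lateral parietal cortex
(iPAR), measured with dense-array EEG as magnitude-squared coherence in the
high beta band (20–30 Hz). `fpcoh` implements that analysis end to end:

1. **Preprocess** a resting EEG recording: re-reference to the common
   average, low-pass at 50 Hz with zero phase, cut into non-overlapping 1-s
   epochs, detrend each epoch, reject epochs by peak amplitude, and remove
   artifact components found by Infomax independent component analysis
   (ICA).
2. **Estimate coherence** between the iM1 seed (a named lead plus its six
   immediate neighbors) and the 21-lead iPAR region, in five bands, together
   with six control circuits.
3. **Score pursuit-tracking sessions** (Success Rate and Error Rate),
   calibrate each subject's training speed from a sigmoidal speed–accuracy
   curve, and express learning as pre-to-post percent change.
4. **Relate brain to behavior** with nonparametric statistics: Spearman rank
   correlations (exact permutation p-values at small n) of baseline
   coherence against tracking gains, Wilcoxon signed-rank change tests, and
   a secondary analysis excluding subjects with lesions in the measured
   regions.

No individual-level recordings are published for the cohort this analysis
emulates, so the package ships a synthetic-cohort generator whose ground
truth is known in closed form; every stage is validated against it.

## Coherence estimation

For leads $x$ and $y$ the magnitude-squared coherence at frequency $f$ is

$$C_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

with auto- and cross-spectra estimated by averaging Hann-windowed
periodograms over the kept 1-s epochs (a Welch estimator whose segments are
the epochs). One-second epochs fix a 1 Hz bin spacing; a band value is the
arithmetic mean of per-bin coherence over all bins with
$f_{lo} \le f \le f_{hi}$, endpoints inclusive, so the 20–30 Hz band spans
11 bins. Band edges are the conventional delta 1–4, theta 4–8, alpha 8–13,
low beta 13–20 and high beta 20–30 Hz; they are configurable because the
exact edges below the primary band are a convention, not a finding.

Region-pair coherence is the mean of $C_{xy}$ over all cross-region lead
pairs (7 × 21 = 147 for the primary circuit), with any lead shared between
the two regions excluded from pairing. Averaging coherence over pairs was
chosen over first averaging the signals within each region: pair averaging
commutes with the bounds of the estimator and does not cancel sources with
opposing polarities across a region. The alternative (coherence between
region-mean signals) is available via `coherence_table(aggregate =
"roi_mean")` for sensitivity analysis.

With $M$ kept epochs the estimator has an $O(1/M)$ positive bias for
uncoupled signals (about 0.006 at $M = 180$); tests therefore check
estimates against analytic values with tolerances an order of magnitude
above that bias. Coherence requires $M \ge 2$ (it is identically 1 at
$M = 1$), and a band bin with zero auto-power is an error rather than a
silent `NaN`.

## Preprocessing chain

The chain order is fixed and logged in a provenance list: average
re-reference → 50 Hz low-pass → 1-s epoching with per-lead linear detrend →
peak-amplitude epoch rejection → ICA → component rejection →
reconstruction.

* **Low-pass.** The contract is stated in decibels: −3 dB at 50 Hz, a 10 Hz
  tone within ±0.5 dB, a 100 Hz tone attenuated by at least 20 dB, zero
  phase. The default realization applies the squared magnitude of a
  4th-order Butterworth (what forward–backward filtering of that design
  yields) in the frequency domain across all leads at once; a per-lead
  `signal::filtfilt` realization is available. The two differ slightly in
  roll-off shape near the corner (bilinear prewarping of the IIR design);
  both meet the contract.
* **Epoch rejection.** Visual inspection is not reproducible, so an
  explicit criterion replaces it: an epoch is dropped when any lead exceeds
  100 µV peak absolute amplitude (default, configurable). Rejection clears
  a kept-mask; data are never modified.
* **ICA.** Extended Infomax (natural-gradient learning with a per-component
  sub/super-Gaussian switch), fitted on the concatenation of kept epochs
  after reduction to `n_components` principal components. The default
  component count is the data rank up to 64 — under the average reference
  the rank is one less than the lead count. The fit is stochastic-gradient,
  so a seed is mandatory and is the only source of randomness
  (block-order shuffling). The initial learning rate (0.05, annealed 3% per
  pass, halved on divergence) was chosen for reliable isolation of
  high-amplitude artifact components; at much smaller rates the blink
  component tends to split across two components.
* **Component rejection.** Two automatic rules: a component is
  *single-channel* when one lead carries more than `tau_single = 0.8` of
  the summed absolute topography weight, and *muscle-band* when more than
  `tau_muscle = 0.5` of its 1–50 Hz source power lies in 35–50 Hz. Both
  thresholds are exposed; "occurred in one channel" is interpreted as
  topography dominance rather than time-series locality. Stereotyped
  artifacts (blinks, eye movements, heart rhythm) are flagged by template:
  topography correlation above 0.9 with a frontal low-frequency template
  (spectral centroid ≤ 6 Hz) or with a smooth whole-array gradient whose
  source shows an autocorrelation peak at the expected cardiac period
  (~1.2 Hz); short autocorrelation lags are ignored because low-pass
  smoothness makes them high for every component.
* **Reconstruction.** Flagged components are removed by signal-space
  projection: the data are projected off the span of the flagged mixing
  columns. With a reduced-rank decomposition the ICA source time courses
  carry leaked background noise, so literally subtracting
  `mixing %*% sources` leaves a residual proportional to that leakage;
  projection removes everything in the artifact's spatial subspace at the
  cost of the (small) neural content lying along it, the standard trade-off
  of projection-based cleaning. The literal subtraction is available as
  `method = "subtract"`. With nothing flagged the input is returned
  unchanged; flagging every component is an error.

ICA is fitted on epochs that survived amplitude rejection (not on all
data): the rejected epochs contain exactly the high-amplitude activity that
distorts the whitening statistics.

## The synthetic cohort

The generator's purpose is verifiability: every recording comes with the
coherence its mixing model implies in closed form.

**EEG model.** A single band-limited source $s(t)$ with flat spectral
density across 19.5–30.5 Hz (half a bin wider than the 20–30 Hz analysis
band, so edge bins see full source power despite Hann leakage) is projected
with weight 1 onto the iM1 leads and weight $\gamma \in [0,1]$ onto the
iPAR leads. Every lead carries an independent $1/f$ background spanning
1–50 Hz. For integer-frequency bin $f$ with source-to-background power
ratio $\kappa_f$, the implied lead-pair coherence is

$$C_f(\gamma) = \frac{(\gamma \kappa_f)^2}
{(\kappa_f + 1)(\gamma^2 \kappa_f + 1)},$$

and the band value is the mean over the 11 bins. `gamma_for_coherence()`
inverts this map, so recovery tests can target coherence values directly.

The source's scalp projection is *zero-sum*: a weak uniform negative return
field over leads outside every configured region balances the positive
region weights. Real cortical source fields integrate to approximately
zero over a dense array; without this property the common-average reference
subtracts a share of the source from every lead, which both attenuates the
primary-circuit coherence and leaks spurious, coupling-dependent coherence
into control circuits. The ground truth stores the coherence implied both
by the raw mixing and after average re-referencing (the latter adds the
small noise covariance that subtracting the noise mean induces).

Scales: background band power 4 µV² per lead within the analysis band
(total background SD ≈ 6 µV, a realistic resting amplitude), and
`band_snr = 16` (per-bin source power at weight 1 relative to mean per-bin
background power), which makes analytic coherence values up to ≈ 0.88
attainable so that recovery targets spanning [0, 0.8] are representable.
The per-subject coupling range defaults to [0.05, 0.6]; the emulated study
reports no coherence distribution, so this is a free choice documented
here, not a calibration.

**Artifacts** reproduce the four removed classes by spectral and
topographic signature only: blink bursts (Gaussian pulses, ~15/min, 80 µV,
frontal Gaussian topography), broadband muscle (85% of power in 35–50 Hz
with a shelf down to 15 Hz, 30 µV, a posterior-lateral edge patch placed on
the same side as the parietal region so that muscle genuinely contaminates
the primary measurement), an exactly periodic cardiac component (biphasic
12-ms pulses at 1.2 Hz, 15 µV, fixed smooth gradient topography over all
leads), and a single-lead spike train (60 µV). Blink amplitude is kept
below the 100 µV epoch-rejection limit deliberately: blinks are what the
ICA stage is for, while epochs destroyed by overt muscle are for the
amplitude rule.

**Montage.** A centered hexagonal grid with `n_rings` rings
(`1 + 3r(r-1)` leads; 10 rings = 271 leads emulates a dense ~256-lead
net). Region lead sets are configuration, not vendor geometry: the motor
seed is the center lead plus its six neighbors, the parietal region the 21
leads nearest a posterior-lateral centroid, and the six control regions are
placed at nominal centroids with primary-region leads excluded so control
circuits measure different cortex. Contralesional regions mirror across a
nominal midline; a JSON config can replace all of this, including
per-subject mirroring for right-hemisphere lesions.

**Tracking.** The target follows a four-lobed rose curve
$r(\theta) = A\sin(2\theta)$ — a cloverleaf — traversed at constant path
speed (arc length tabulated and inverted), sampled at 30 samples/s. The
cursor is a lagged pursuit with isotropic Gaussian jitter:
lag $= 0.12/(1+\text{skill})$ s and jitter SD
$= 50\,(v/150)^{1.8}/(1+\text{skill})$ px. The superlinear speed dependence
is what bends the success-rate-versus-speed curve into a sigmoid running
from ~100 down to ~0; the exponent 1.8 places the self-consistent operating
point at the calibrated training speed near a 60% success rate, matching
the emulated study's baseline. A sample is a success when the
cursor–target distance is *strictly* below 32 px; the Error Rate weights
each distance by its magnitude, implemented as the mean distance clipped at
`d_ref = 128` px (four success radii) and expressed as a percent of
`d_ref`. The exact reference the original scoring used is not recoverable,
so `d_ref` is exposed for sensitivity analysis; the chosen score is
bounded, monotone in accuracy, and antitone to the success rate.

**Calibration.** Eight 30-s rounds of increasing speed are scored and a
decreasing four-parameter logistic
$sr(v) = L + (U - L)/(1 + e^{(v - v_{50})/s})$ is least-squares fitted
(`minpack.lm`). The maximum-error speed is where the fitted curve has
descended to within 5% of its span above the lower asymptote (closed form
$v_{50} + s\ln 19$), and the training speed is 60% of it — exactly, by
construction. Round duration is a synthetic default; the emulated protocol
does not state one.

**Coupling-to-gain link.** Each subject's true relative SR gain is
$\Delta_i = a + b\gamma_i + \varepsilon_i$ with defaults $a = -3.2$,
$b = 84$, $\mathrm{sd}(\varepsilon) = 17.4$ (percent). These were set once
so that, with the default coupling range, the cohort-level gain
distribution (~24 ± 22%) and the strength of the coupling–gain rank
correlation (~0.6) are of the reported magnitude. The post-training skill
realizing $\Delta_i$ is found by root-finding on the skill-to-battery-SR
map using common random numbers (the same jitter draws across skill
levels), so the inversion is exact up to the score's step size; gains that
would require SR > 100 are clipped and flagged. Per-subject seeds are
independent substreams of the master seed, so adding a subject never
perturbs existing ones.

## Statistics

Spearman's coefficient is the Pearson correlation of mid-ranks. For
$n \le 9$ the two-sided p-value is exact, by enumeration of all $n!$
permutations of one margin (conditioning on the observed rank multisets);
above that, the $t$ approximation with $n - 2$ degrees of freedom is used.
The Wilcoxon signed-rank test drops zero differences (the classic
reduction), assigns mid-ranks to ties, and for $n \le 20$ computes the
exact two-sided p from the full distribution over the $2^n$ sign
assignments (by convolution); beyond that, the normal approximation with
tie correction. The crossover sizes were chosen so that cohorts of the
emulated study's size (n = 12, and n = 8 after lesion exclusion) are
handled exactly or near-exactly, and every result records which method
produced it.

The prediction analysis tests each circuit × band at per-test α = 0.05
with no multiple-comparison correction, mirroring the emulated analysis; a
Holm-adjusted column is emitted alongside for the reader but does not drive
the headline decision. The lesion-excluded cohort repeats the analysis
after dropping subjects whose infarct overlaps any critical region by any
nonzero amount (no percentage cutoff is stated for "damage", so the default
is any overlap, with a configurable minimum). Lesion masks are consumed
already co-registered; a space-tag equality check guards against comparing
volumes in different spaces, and registration itself is out of scope.

## What the tests do and do not show

The test suite validates the estimator against closed forms (self-coherence,
scale invariance, the 0.25 equal-power case, the $1/M$ bias bound),
parameter recovery (median coherence error ≤ 0.03 at 180 s over coupling
targets 0, 0.25, 0.5, 0.8 on a 61-lead grid), artifact robustness (≥ 90%
artifact-energy removal and ICA-chain accuracy gains in ≥ 90% of 50
replicates on a 127-lead grid at 60 s), scoring and calibration oracles,
exact-test enumeration oracles and type-I error (5% ± 3% over 400 null
cohorts), and end-to-end recovery with circuit specificity (100 cohorts of
12 subjects at 30 s and 125 samples/s; the EEG sampling rate and duration
are reduced where the property under test does not depend on them, keeping
the full suite's runtime moderate — the acquisition-scale defaults of
1000 samples/s × 180 s are exercised by the generator's contracts and the
analytic-recovery block at 180 s).

Passing these tests shows the pipeline is a faithful, well-calibrated
implementation of the stated analysis on data *from this generator*. The
generator is a linear mixing model: it has no volume conduction or head
model, its background is Gaussian $1/f$ (ICA separability of real neural
rhythms is not tested), its artifacts match real ones only in spectrum and
topography, and its hexagonal montage is not a vendor net. Nothing here
validates the clinical claim that coherence predicts training response in
patients; the published cohort-level numbers cannot be regenerated without
the individual data, which were never released.

## Reproducing the headline numbers

`scripts/acceptance.R` simulates one full seeded study (12 subjects,
127-lead montage, 60-s EEG at 250 samples/s with all four artifact classes,
calibration and pre/post tracking, four subjects given region-overlapping
lesions), runs the complete ICA-cleaned pipeline, and writes the
cohort-level quantities — mean SR/ER gains with Wilcoxon p-values, primary
and control circuit Spearman correlations for the full and lesion-excluded
cohorts, the coherence-recovery error against ground truth, and the
training-speed ratio — to JSON. See the README for invocation.
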