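---
title: "cardioKit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioKit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioKit)
```

# What the package computes

cardioKit implements the computational pipeline of a three-arm rodent
myocardial-infarction study design (sham, infarcted, infarcted + treated;
n = 8 per arm): reconstruction of intraventricular pressure differences and
gradients (IVPD/IVPG) from color M-mode echocardiographic velocity maps, ECG
fiducial measurement and heart-rate-variability (HRV) analysis with
rat-specific conventions, gross-lesion image quantification, and the cohort
statistics layer. Because raw in-vivo recordings of such studies are rarely
deposited, every input modality has a synthetic phantom generator that
carries its own ground truth; the test suite and the acceptance script
validate the pipeline against those truths and against closed-form
solutions.

# Pressure reconstruction from color M-mode velocity maps

## Model

Along the apex-to-base scanline, blood velocity $v(s,t)$ and relative
pressure $P(s,t)$ obey the one-dimensional Euler equation

$$\frac{\partial P}{\partial s}
  = -\rho\left(\frac{\partial v}{\partial t}
  + v\,\frac{\partial v}{\partial s}\right),$$

whose two right-hand terms are the *inertial* (local acceleration) and
*convective* (spatial advection) contributions. Integrating in $s$ from the
apex (the zero-pressure reference — only relative pressures are meaningful)
gives the pressure field; the total IVPD at time $t$ is
$P(\text{base},t)-P(\text{apex},t)$, and IVPG = IVPD divided by the LV
length $L$ (the same $L$ for all segments, which preserves additivity).

Conventions, fixed throughout:

* space index 1 = apex, last index = base (mitral valve); velocities in
  cm/s, positive toward the base, so early-diastolic inflow is negative;
* IVPD$(t) = P(\text{base},t) - P(\text{apex},t)$, positive during normal
  early-diastolic suction (apical pressure below basal pressure);
* segments as fractions of $L$ from the apex: apical $[0,\tfrac13]$, mid
  $[\tfrac13,\tfrac23]$, basal $[\tfrac23,1]$, mid-to-apical
  $[0,\tfrac23]$ — the one-third basal / two-thirds mid-apical rule;
* blood density $\rho = 1060$ kg/m³ (standard whole blood; configurable);
  1 mmHg = 133.322 Pa;
* peaks are maxima of the *signed* profile inside the analysis window,
  reported at sample resolution, earliest time winning ties.

## Discretization

Central differences in both axes (one-sided at boundaries) and cumulative
trapezoidal integration in space: a standard second-order scheme. The test
suite verifies roughly fourth-fold error reduction per grid halving against
an independent high-resolution quadrature of the closed-form phantom
(three refinement levels, 16×64 to 64×512), and exact agreement
(±0.5%) with the two closed-form solutions: the spatially uniform ramp
$v = at$ (IVPD $=-\rho a L$) and the steady shear $v = ks$
(IVPD $=-\rho k^2 L^2/2$).

Segment boundaries rarely coincide with grid rows; boundary pressures are
linearly interpolated, which keeps segmental additivity
(basal + mid + apical = total) exact by telescoping.

## De-aliasing

Color-Doppler velocities wrap modulo $2V_{nyq}$. The de-aliaser unwraps
along the time axis within each spatial row, then reconciles rows through
the first time column. This recovers any field whose true inter-sample
change stays below $V_{nyq}$ and whose flow-onset sample lies inside the
Nyquist interval — the usual situation for an M-mode record that starts
before inflow. When the unwrapped field still contains jumps at or above
$V_{nyq}$, the result carries an explicit warning flag rather than failing
silently; resolution is genuinely impossible in that regime. The paired
`encodeAliasing()` operator makes the round trip testable to machine
precision.

The optional Savitzky–Golay smoothing step (`preprocessVelocity`) exists
because derivatives of noisy Doppler data amplify noise; it reproduces
polynomials up to the chosen order exactly and is off by default.

## Diastolic window

The analysis window is normally supplied by the operator (aortic-valve
closure to end-diastole). `detectDiastolicWindow()` offers a convenience
detection from the spatial-mean velocity magnitude: the window starts at
the last time before the dominant crest at which the signal sits at the 5%
floor (the working definition of "zero" for a noisy trace) and ends at the
first return below 5% after the last wave. An explicit window always
overrides detection.

# The velocity phantom

The default template is a bimodal E/A inflow: two Gaussian waves in time
(peak speeds 77.01 and 37.73 cm/s — healthy-control means; width
$\sigma$ = 12 ms; crest separation 60 ms), delayed linearly with distance
from the base at a propagation speed of 40 cm/s (a typical rodent flow
propagation velocity), under a smoothstep spatial envelope that vanishes at
the apex. Everything is closed-form differentiable, so the ground-truth
IVPD comes from quadrature of the analytic Euler integrand at 10× spatial
resolution — never from the discrete pipeline under test. LV length
defaults to 1.6 cm, a typical adult-rat apex-to-valve distance.

# ECG: phantom and measurement

The ECG phantom is a periodic sum of Gaussian bumps (P, Q, R, S, T) with
exactly known fiducials; dynamical ECG models were rejected because exact
fiducial ground truth is the point. Wave widths follow a
10%-of-peak convention: a wave of nominal duration $d$ has
$\sigma = d/(2\sqrt{2\ln 10})$, so its 10% crossings sit exactly $d$
apart. The measurement operation uses the same 10% threshold-crossing
definition (linearly interpolated between samples), making nominal
durations recoverable to fractions of a millisecond on clean traces —
sub-sample agreement is a consistency check of both sides, not a
circularity: detection, baseline estimation, and search windows are all
independent of the generator.

R peaks are detected by band-pass (5–60 Hz), squared derivative, moving
integration, a quantile threshold, and a 60 ms refractory period; peak
positions are refined on a lightly smoothed trace because the R apex is
locally flat and raw argmax jitters under wideband noise. The baseline is
the mode of the voltage distribution (the isoelectric line), robust to the
duty cycle of the waves. Defaults reproduce healthy-rat values: 275.4 bpm,
P 20 ms, PR 52 ms, QRS 22 ms, R 0.94 mV at 2 kHz.

# HRV analysis

## Definitions

RR intervals in ms throughout; powers in ms². SDRR uses the $n-1$
denominator; CVRR = SDRR / mean RR; RMSSD over successive differences of
*unflagged adjacent* pairs; pRR50 = percentage of successive differences
above 50 ms (the threshold is configurable, but the name fixes the
default). Rat spectral bands: VLF 0–0.15 Hz, LF 0.15–1.5 Hz, HF 1.5–5 Hz;
total power spans 0–5 Hz, so the three bands partition the total exactly —
band integrals interpolate the PSD at the exact band edges to keep the
partition additive to machine precision.

The spectral estimator resamples the unflagged beat series to an evenly
spaced tachogram (cubic interpolation, 20 Hz), removes a linear trend, and
averages Hann-windowed 60 s Welch segments at 50% overlap, scaled so the
PSD integral equals the signal variance (Parseval; verified in the tests
against an analytic sinusoid).

## The RR phantom and what it can and cannot emulate

The phantom modulates the instantaneous heart period with one sinusoid per
band at physiologic frequencies — VLF 0.08 Hz (slow humoral/thermal
drift), LF 0.45 Hz (vasomotor), HF 1.55 Hz (respiration of an anesthetized
rat, ≈ 93 breaths/min) — with amplitudes set so each band carries its
target power ($a^2/2$ per component). Each interval equals the modulation
evaluated at its own beat time (an implicit equation solved per beat,
smallest root), so emitted RR values are *exact samples* of a band-limited
signal; the ground-truth "realized" band powers are obtained by
least-squares projection of the emitted sequence onto the known sinusoid
basis — an oracle independent of the Welch pipeline.

Beat-interval sampling imposes a physical limit: content above half the
beat rate (≈ 2.3 Hz at the default 218 ms mean RR) cannot be represented,
which is why the HF component sits at the low end of its band, where
anesthetized-rat respiration actually lives. Even there, cubic
interpolation at a third of the beat rate attenuates power by ≈ 14%; the
pipeline's HF estimates are accordingly biased low against the ground
truth, and the tests document that bias rather than hiding it. A further
caveat inherited from the emulated study conditions: the default band
powers sum to ≈ 2850 ms² (SD ≈ 53 ms), which is internally inconsistent
with the quoted time-domain variability of the same animals (SDRR ≈ 26 ms,
CVRR ≈ 0.18). The generator reproduces the printed values as stated; the
inconsistency is a property of the source numbers, not of the pipeline.
Real rat RR series additionally contain broadband noise, nonstationarity
and trends that the sinusoidal phantom does not emulate, so passing tests
demonstrate estimator correctness on band-limited signals, not performance
on arbitrary in-vivo data.

## Ectopic beats

Ectopy is excluded from every statistic. The filter flags intervals
deviating more than 30% (default) from the running median of 11
neighbours; after a premature (short) flagged interval, the following
interval — the compensatory pause — is flagged too. Flagging more than 20%
of a record raises a data-quality warning. The phantom injects isolated
premature-plus-compensatory pairs (40% shortening, keeping the emitted
deviation above the 30% definition with margin against modulation jitter)
with ground-truth labels; recall ≥ 0.9 at zero false flags on
moderate-variability series (≈ 300 ms² total band power, consistent with
an SDRR of ≈ 17 ms). At the full default band powers the intrinsic
beat-to-beat modulation itself exceeds 30%, and no deviation filter can
separate ectopy from modulation — a detectability limit, documented here;
the synthetic study therefore injects no ectopics by default and uses a
0.70 study-level threshold.

# Image quantification

Gross-lesion metrics over an operator-supplied (or phantom) mask: mean
gray value, integrated density (the plain sum of pixel values), and median
(lower-middle convention for even counts, matching integer-histogram
medians of common image tools). Pixel values are used exactly as stored
(0–255); a "reverse 1–255" display scale sometimes described for such
scores conflicts with standard raster storage and is deliberately not
applied. Stained-cell counting scores DAB brown as $R-\max(G,B)$,
thresholds, labels 8-connected components and applies a size filter —
a channel-difference heuristic chosen over full color deconvolution
because it is phantom-verifiable and dependency-light. Ordinal histology
scores (four criteria, 0–4 each) are summed to a per-section composite
(0–16) and summarized per group as median and IQR; composites feed the
same nonparametric comparison machinery as every other parameter.

# Statistics layer

* **Normality** is screened per group with Shapiro–Wilk and reported, not
  used as a gate.
* **Omnibus**: the default is Kruskal–Wallis. The emulated study names a
  "repeated one-way ANOVA … using the Friedman test" for three independent
  groups; the Friedman test presumes a blocked (repeated-measures) layout,
  which independent cohorts do not have, so Kruskal–Wallis is the
  statistically valid default and Friedman remains an explicit option for
  genuinely matched designs (blocks = within-group subject order).
* **Post hoc**: Dunn's rank-sum z tests with the standard tie correction,
  Bonferroni-adjusted over the tested contrasts (the named source does not
  specify a correction; Bonferroni is the conservative reading).
  Both unadjusted and adjusted p-values are reported. Note a consequence
  worth knowing: for three groups of 8 with completely separated adjacent
  groups, the adjacent-contrast Dunn z is 2.26 (p = 0.024 unadjusted,
  0.071 after Bonferroni) — adjacent contrasts can be individually
  significant yet fail the adjusted threshold.
* **Associations**: Spearman's rank correlation (mid-ranks for ties) next
  to the OLS coefficient of determination, shaped like the study's
  correlation/regression tables.
* **Relative quantification**: per subject, ΔCt = Ct(gene) − Ct(reference);
  ΔΔCt centers on the *mean* control-group ΔCt (the aggregation is not
  specified by the method's common descriptions; the mean is the usual
  choice); fold = $2^{-\Delta\Delta Ct}$. Group summaries give arithmetic
  mean, SD and geometric mean — the geometric mean is the unbiased
  summary on the log scale and is what the recovery tests check.
* **Sample size**: smallest total $N$ (multiple of $k$) with noncentral-F
  power $\ge$ target, $\lambda = f^2 N$. With Cohen's $f = 0.90$,
  $\alpha = 0.05$ and power 0.95 the answer is $N = 24$ (8 per group) —
  consistent with the emulated study's stated effect size and animal
  count, whose $\alpha$ and power were not printed; all inputs are exposed
  rather than hard-coded.

```{r sample-size}
anovaSampleSize(0.90, alpha = 0.05, power = 0.95, kGroups = 3)
```

# The synthetic study

`runSyntheticStudy()` draws per-subject echo parameters from the three-arm
design tables, uses each subject's own E/A velocities to drive its velocity
phantom (so IVPG indices correlate with inflow velocity by construction),
draws ECG and HRV phantom parameters from the per-group designs, scores a
per-subject lesion image, runs a qPCR plate and a histology scoring round,
and then applies the statistics layer to everything. Stage outputs are
plain CSV plus one JSON report with a provenance block (seed, config hash);
nothing in the report body depends on wall-clock time, so a fixed seed
gives byte-identical output — asserted in the tests. Per-subject phantom
parameters jitter around group means with a log-normal CV of 8%, a typical
between-animal variability for such measurements.

Problem sizes in the shipped tests are chosen for a desk-scale run: the
study tests use 100 s RR records, 12 s ECG traces and 32×128 velocity
grids; module tests use 10-minute RR records where spectral resolution
matters and a 64×512 grid where convergence is measured. All sizes are
configuration values, not limits of the implementation.

# Known limitations

* The Euler reconstruction is one-dimensional; no 2-D/3-D pressure mapping.
* De-aliasing cannot resolve fields whose true inter-sample change reaches
  the Nyquist velocity; it warns instead.
* The HF spectral bias of the tachogram estimator (−14% at the default
  heart rate) is intrinsic to cubic resampling of beat-sampled data near
  its Nyquist limit.
* The ectopic filter cannot detect ectopy when intrinsic variability
  exceeds its deviation threshold (see above).
* Phantoms are smooth and band-limited by design; they validate numerics
  and contracts, not robustness to arbitrary clinical artifacts.
* Vendor Doppler formats, DICOM, whole-slide images and proprietary
  ECG-file formats are out of scope; inputs are plain text/PNG.
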