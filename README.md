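# cardioKit

Intraventricular pressure gradients, heart rate variability and lesion
scoring for rodent myocardial-infarction studies.

Non-invasive assessment of diastolic function in small-animal infarction
models leans on two instrument-heavy analyses that are rarely available as
open, testable code: reconstruction of **intraventricular pressure
differences/gradients (IVPD/IVPG)** from color M-mode echocardiographic
velocity maps, and **heart-rate-variability (HRV)** analysis with
rat-specific spectral bands. cardioKit implements both, together with the
surrounding study machinery — ECG fiducial measurement, gross-lesion image
metrics, stained-cell counting, ordinal histology scores, qPCR relative
quantification and the nonparametric cohort statistics — and a synthetic
phantom generator for every input modality so the whole pipeline is
verifiable against known ground truth.

## The core computation

Along the apex-to-base scanline, relative pressure follows the
one-dimensional Euler equation

    dP/ds = -rho * ( dv/dt + v * dv/ds )

split into inertial and convective parts, integrated in space from the apex
(pressure reference). Total IVPD(t) = P(base,t) − P(apex,t); segmental
IVPDs use the one-third basal / two-thirds mid-apical segmentation;
IVPG = IVPD / LV length. Velocity fields are first de-aliased (Nyquist
unwrapping along time with a spatial consistency pass). HRV uses SDRR,
CVRR, RMSSD and pRR50 in the time domain and Welch band powers over the
rat bands VLF 0–0.15, LF 0.15–1.5, HF 1.5–5 Hz on a 20 Hz cubic-resampled
tachogram. The statistics layer provides Shapiro–Wilk screening,
Kruskal–Wallis (or Friedman) omnibus tests with Dunn's Bonferroni-adjusted
post hoc, Spearman correlation beside regression R², 2^−ΔΔCt fold changes,
and noncentral-F ANOVA sample-size estimation.

## Worked example

```r
library(cardioKit)

## transmitral velocity phantom at healthy-rat defaults (E 77 cm/s),
## aliased, de-aliased, reconstructed, profiled
ph    <- generateVelocityPhantom(phantomSpec(seed = 42))
field <- dealiasVelocity(encodeAliasing(ph$field))
res   <- ivpdProfiles(eulerPressureField(field), detectDiastolicWindow(field))
res
#> IVPGResult: window [0.01691, 0.144] s, L = 1.6 cm
#>        segment ivpd_mmHg ivpg_mmHg_cm  time_s
#>          total   0.50371      0.31482 0.02442
#>          basal   0.43564      0.27227 0.02348
#>  mid_to_apical   0.29038      0.18149 0.03726
#>            mid   0.27358      0.17099 0.03695
#>         apical   0.08438      0.05274 0.05229

## 10-minute RR phantom at the healthy-group band-power targets
rr <- generateRRSeries(phantomSpec(seed = 42, rrDurationS = 600))
hrvAnalysis(rr$rr, filter = FALSE)
#> HRVReport
#>   time domain:  SDRR 54.82 ms, CVRR 0.2629, RMSSD 80.80 ms, pRR50 70.17 %
#>   freq domain:  total 2548.4, VLF 159.4, LF 527.4, HF 1861.5 ms^2 (bands 0/0.15/1.5/5 Hz)
```

The peak total IVPD of ~0.50 mmHg (IVPG 0.31 mmHg/cm) is an early-diastolic
suction gradient of physiologic rat magnitude; its time and the segmental
peaks come from the signed profiles inside the detected diastolic window.
The HRV report recovers the phantom's VLF/LF targets closely and the HF
target with the expected resampling attenuation (see the methods vignette
for why beat-interval sampling bounds HF recovery).

A full simulated three-arm study (24 subjects, all modalities, comparisons
and association tables, deterministic for a fixed seed):

```r
report <- runSyntheticStudy(list(seed = 1), outDir = "study_out")
report$comparisons$EF$pairwise    # Dunn contrasts for ejection fraction
```

or from a shell: `Rscript inst/scripts/run_study.R --seed 1 --out study_out`.

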