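# gratiokit

Aggregate g-ratio mapping and lesion-stratified biomarker analysis for
quantitative MRI studies of myelin integrity.

## What this is for

In demyelinating disease, myelin thinning inside white-matter lesions can
be quantified in vivo as an *aggregate g-ratio* — the voxel-level ratio of
inner axonal radius to outer fibre radius — by combining magnetization
transfer saturation (MTsat) and NODDI diffusion imaging:

```
g   = (1 + MVF / AVF)^(-1/2)
MVF = k * delta_app                      (k calibrated on healthy-control WM)
AVF = (1 - MVF) * (1 - viso) * vic
```

Higher g means thinner myelin relative to axon calibre; healthy cerebral
white matter sits near 0.7. Whether myelin damage inside lesions tracks
axonal damage can then be asked at the cohort level by relating lesional
g-ratios to plasma neurofilament light chain (NfL), stratified by lesion
load.

`gratiokit` implements that entire chain as tested, reusable R code for
methodologists and imaging scientists who need to validate it without
subject data:

* **Digital phantom** — ground-truth tissue maps; forward simulation of
  the SPGR triplet (full steady state), two-shell NODDI diffusion
  (Watson-dispersed stick + tortuosity zeppelin + free water, via a
  Legendre/Gauss-Legendre spherical-convolution kernel), FLAIR-like
  lesion contrast, and Rician noise — plus a subject-level cohort
  generator with configurable NfL dependence on lesion volume and
  lesional g-ratio.
* **MT relaxometry** — apparent R1/T1, amplitude, MTsat and MTR maps; the
  standard small-angle estimator (with its approximation bias computed in
  closed form) and an exact steady-state inversion.
* **NODDI fitting** — deterministic lattice-initialized, bounded
  Levenberg-Marquardt fit of `viso`, `vic`, ODI and fibre direction.
* **g-ratio pipeline** — control calibration of `k`, MVF/AVF/g maps with
  validity tracking, regional medians and comparable histograms for
  lesions vs normal-appearing white matter (NAWM).
* **Lesion masking** — robust (median/MAD) intensity thresholding with
  connected-component filtering, NAWM exclusion ring, lesion load as
  % of intracranial volume.
* **Cohort analysis** — Wilcoxon signed-rank, Mann-Whitney U, Spearman,
  Fisher exact (all with explicit exact-enumeration conventions), the
  control-mean + 3 SD elevated-NfL rule, and lesion-load / g-ratio
  stratified contingency analysis with sensitivity thresholds.

Standard formats are supported throughout: NIfTI-1 volumes, FSL-dialect
`bval`/`bvec` gradient tables, CSV cohort tables, JSON configs and
reports. A thin CLI (`inst/exec/gratiokit`) wraps the main stages
(`phantom`, `mtsat`, `noddi`, `segment`, `gratio`, `analyze`).

## Worked example

Simulate a lesion-free control phantom at SNR 40, calibrate `k` on its
NAWM, then run the full estimation chain on a phantom whose lesion tissue
implies g = 0.610, embedded in NAWM implying g = 0.570:

```r
library(gratiokit)
protocol <- default_protocol()      # PDw/T1w/MTw SPGR + b = 700/2000 DWI

control <- simulate_phantom(phantom_spec(snr = 40, lesions = list(),
                                         seed = 1001), protocol)
rx <- fit_relaxometry(control$volumes$pdw, control$volumes$t1w,
                      control$volumes$mtw, protocol,
                      mask = control$masks$nawm)
k <- calibrate_k(rx$delta_app, control$masks$nawm & rx$valid,
                 target = list(type = "median_mvf", value = 0.415))
#> k = 10.2341   (ground truth 10; the excess absorbs the small-angle
#>                estimator bias, which is proportional to MTsat)

study <- simulate_phantom(phantom_spec(snr = 40, seed = 1), protocol)
res <- run_gratio_pipeline(study, k)
res$summary$wml
#> <regional_summary> WML: median g 0.6097 (IQR 0.5909-0.6376), n = 246
res$summary$nawm
#> <regional_summary> NAWM: median g 0.5738 (IQR 0.5473-0.5994), n = 2026
```

Both regional medians land within a few thousandths of their ground-truth
values despite noise, estimator approximation and model fitting. The
cohort-level analysis runs on a simulated (or real, CSV-loaded) subject
table:

```r
cohort <- simulate_cohort(n_patients = 73, n_controls = 63, seed = 1)
report <- run_full_analysis(cohort)
report
#> == Cohort g-ratio / neurofilament analysis ==
#> patients 73 (excluded 0), controls 63
#> median g: WML 0.609 vs NAWM 0.572
#> median NfL: patients 7.17 vs controls 4.78 pg/ml; elevated (> 10.05 pg/ml): 25/73 (34%)
#>   paired_g_wilcoxon            p = 4.478e-13
#>   ...
#> stratified @ 0.5% ICV (low n=33, substantial n=40):
#>   low:         4/14 vs 1/19, Fisher p = 0.1376
#>   substantial: 16/22 vs 4/18, Fisher p = 0.003641
#> all tests two-sided at alpha = 0.05 with no multiple-testing correction
```

The stratified lines read "elevated-NfL count / stratum size" for the
abnormal (> median) versus normal (<= median) lesional g-ratio groups: in
this draw the association between high lesional g-ratio and elevated NfL
is concentrated in the substantial-lesion-load stratum, the pattern the
generator encodes. `write_analysis_report()` saves the full report as
JSON + Markdown.

See `vignettes/gratio-phantom-methods.Rmd` for the forward models,
estimator conventions, calibration details and design decisions.

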