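---
title: "Methods: EEG alpha spectral analysis and resting-state connectivity by APOE genotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG alpha spectral analysis and resting-state connectivity by APOE genotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`alphaconn` implements a complete desk-scale analysis of how the APOE ε4
genotype relates to two resting-state readouts of brain physiology: the
spectral composition of the EEG alpha rhythm, and ROI-to-ROI functional
connectivity of BOLD fMRI. Because raw recordings of this kind are rarely
shareable, the package pairs every analysis stage with a synthetic
generator that carries full ground truth, so each estimator can be
validated end to end.

## The scientific model

**EEG branch.** Resting EEG is dominated by the alpha rhythm (8–13 Hz),
whose *individual alpha peak frequency* (IAPF) declines with age and is a
candidate marker of preclinical Alzheimer-type change. The analysis
quantifies, per channel:

* **1-Hz subband relative power.** For every 4-s epoch, the power in each
  1-Hz bin of 8–13 Hz is divided by the total power in the 2–35 Hz
  analysis band, giving a fraction $x \in (0,1)$, which is transformed as
  $\log\!\big(x/(1-x)\big)$ (natural log) to compensate skewness, then
  averaged over epochs.
* **IAPF.** The frequency of the maximum of the epoch-averaged power
  spectrum restricted to 8–13 Hz.

**fMRI branch.** ROI time series are denoised the way connectivity
toolboxes do it: regression on 24 motion parameters (6 raw, 6 backward
differences, their 12 squares), 10 aCompCor components (top-5 PCA time
courses of white-matter and CSF noise-ROI blocks), and one spike regressor
per volume whose framewise displacement exceeds the subject's 97th
percentile; residuals are then band-passed to 0.01–0.1 Hz. Connectivity is
the pairwise Pearson correlation over uncensored volumes, Fisher
transformed ($z = \operatorname{atanh} r$, capped at $\pm 6$).

**Inference.** Genotype and age-group effects on subband power and IAPF
use a univariate mixed repeated-measures ANOVA (split-plot sums of
squares); post-hoc cell comparisons use Duncan's multiple-range test;
edge-wise genotype contrasts use pooled two-sample *t* statistics on
Fisher-z values with Benjamini–Hochberg FDR control, plus per-group
one-sample tests of mean $z \neq 0$; correlations are compared with the
Fisher r-to-z statistic
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

## What the synthetic generators emulate

`generate_cohort()` draws ages uniformly on 26–79 years (threshold 50
splits younger/older), assigns sex at a 1:2 M:W ratio, and gives every
subject a true IAPF on a genotype-specific age line: intercept 10.2 Hz at
age 40, slope −0.010 Hz/yr for non-carriers and −0.030 Hz/yr for carriers,
with 0.8 Hz residual SD. These defaults reproduce the *sign and ordering*
of the age–IAPF correlations seen in such cohorts (carriers decline
faster), not any particular printed value; no published effect sizes exist
for the subband power differences, so those are calibrated to sign only.

`synth_eeg()` builds each channel in the frequency domain: a $1/f$
background (exponent 1.0) plus a Gaussian-profile alpha component centred
at the subject's true IAPF, both with complex-Gaussian coefficients. The
result is an amplitude-modulated narrow-band process — alpha that waxes
and wanes — rather than a pure sinusoid, so the estimator faces realistic
spectral leakage and epoch-to-epoch variability. Alpha gain is graded
across the scalp with an occipital maximum (occipital ≈ 2× frontal), as in
eyes-closed recordings. The default spectral width of the alpha profile is
0.25 Hz SD (≈ 0.6 Hz FWHM): real resting alpha peaks are narrow and stable
within a session, and this width is the operating point at which the
fixed-resolution estimator (4-s epochs, 0.25 Hz bins) resolves the peak to
one bin in ≥ 95% of channels whenever the peak rises at least 3× above the
background — the recovery guarantee the test suite enforces. Default
amplitudes put the weakest channels at peak SNR ≈ 3.6 and occipital
channels at ≈ 14.

`synth_bold()` draws ROI series from a multivariate normal whose
correlation matrix is $I + C$ with $C$ the genotype's coupling matrix:
carriers get positive interhemispheric couplings (lateral-visual /
parietal-operculum / salience, +0.25), non-carriers a negative
hippocampus–posterior-parietal coupling (−0.25). Shared AR(1) nuisance
components load on ROI and noise-ROI series alike, and head motion is a
bounded random walk. Not emulated: hemodynamic convolution, image-space
artifacts, eye blinks or EMG on the EEG side. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every artifact of real recordings.

Every subject owns an RNG stream derived from (master seed, subject id),
so growing the cohort never perturbs existing subjects' data.

## Numerical choices

* **Spectral estimator:** mean periodogram over non-overlapping 4-s
  epochs with a Hann taper (leakage control); the relative-power bins are
  right-open so the thirty-three 1-Hz bins of 2–35 Hz partition the total
  exactly (to 1e−9 and better).
* **IAPF:** reported at the native 0.25 Hz bin resolution with ties
  broken toward the lower frequency and no interpolation, keeping the
  estimate exactly reproducible; maxima on the 8 or 13 Hz boundary are
  flagged rather than rejected.
* **Logit clamping:** fractions at 0 or 1 are clamped to 1e−6 with a
  warning.
* **Artifact rejection:** the visual screening of real studies is
  replaced by an optional ±100 µV amplitude threshold per epoch.
* **Filters:** zero-phase (forward–backward) Butterworth; order 4 for the
  2–35 Hz EEG band, order 2 for the 0.01–0.1 Hz BOLD band. Regression
  precedes filtering (regress-then-filter); scrubbing is realized as spike
  regressors rather than deletion so the filter runs on a regular grid,
  and censored volumes provably have zero leverage on connectivity.
* **FD:** Power-style sum of absolute backward differences with a 50-mm
  head radius; the censoring percentile is computed per subject.
* **ANOVA:** Type III sums of squares via sum-to-zero contrasts and
  term deletion (robust to unbalanced genotype groups); between effects
  tested against the subject-within-groups mean square, each within
  effect against its own subject × effect stratum; covariates (sex) enter
  the between stratum only; no sphericity correction (uncorrected
  univariate df are reported, flagged in the result metadata).
* **Duncan:** critical values from the studentized-range quantile at
  protection level $1-(1-\alpha)^{p-1}$ for a span of $p$ means; the
  harmonic mean of the two cell sizes replaces $n$ for unbalanced cells; a
  pair is significant only if every enclosing range is.
* **Edge contrast:** "paired" two-group comparison of independent
  genotype groups is statistically inconsistent as stated in the source
  literature; the package implements the standard GLM two-sample contrast
  (pooled-variance *t*) on Fisher-z edges and documents it as such.
* **BH-FDR:** step-up adjustment (the conventional choice where the
  procedure is unnamed), delegated to `stats::p.adjust`.
* **Fisher z cap:** |z| ≤ 6 with degenerate (zero-variance) ROIs flagged
  as undefined instead of propagating infinities.

## Open design points and how they were resolved

* Whether IAPF should be computed per channel or on an occipital subset
  is left as analysis freedom: `estimate_iapf()` is per channel, and the
  pipeline's ANOVA aggregates channels into the eight scalp region pairs
  with a hemisphere factor, so either view is recoverable from the output
  tables.
* The log base of the logit transform is unspecified in the source
  literature; the natural log is used (a pure scale change that cannot
  affect F statistics or p-values in linear models).
* The "Beta" column of edge tables is the raw mean Fisher-z difference,
  not a standardized coefficient.
* Bivariate regression coefficients are not offered as an edge measure;
  correlation-based z is the sole one.

## Problem sizes

The defaults mirror the emulated study: 91 + 46 subjects, 150-s EEG at
256 Hz (37 epochs), an fMRI subgroup of 23 + 14 subjects at 400 volumes
and TR 1.5 s. The test suite and the acceptance script run the heavier
calibration studies at reduced but statistically adequate sizes chosen by
us: 50 recordings for IAPF recovery, 1000 null replicates for ANOVA
type-I calibration, 200 null connectomes and 100 planted-effect seeds for
edge-inference calibration, and a 28-subject end-to-end determinism run.

## Known limitations

* The ANOVA requires a balanced within-subject design (as the pipeline
  always produces); missing cells abort with an error rather than being
  imputed.
* Degrees of freedom follow the fitted design; printed df from legacy
  GLM software that enters covariates differently need not match.
* The synthetic BOLD model plants contemporaneous correlations only — no
  lagged coupling, no hemodynamic blurring — so connectivity recovery
  results do not speak to causal or lagged analyses.
* EDF input is not supported; recordings interchange as delimited
  matrices with a JSON sidecar (`write_eeg_matrix()`).

## Example

```{r example}
library(alphaconn)
run <- run_pipeline(default_config(seed = 1), output_dir = "run1")
run$tables$age_iapf_correlation
head(run$tables$edge_contrast)
```
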