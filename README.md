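# alphaconn

EEG alpha spectral analysis and resting-state fMRI connectivity by APOE
genotype, as a tested, config-driven R pipeline.

## The problem

The APOE ε4 allele is the strongest common genetic risk factor for
late-onset Alzheimer's disease. Long before any clinical symptom, two
resting-state readouts of brain physiology are suspected to shift in ε4
carriers (E4+): the EEG alpha rhythm slows — the individual alpha peak
frequency (IAPF) declines faster with age and the upper alpha subbands
(11–13 Hz) lose relative power — and the correlation structure of
spontaneous BOLD fluctuations between brain regions (resting-state
functional connectivity, rsFC) reorganizes, with stronger positive
interhemispheric couplings and a weakened negative hippocampus–parietal
coupling. `alphaconn` is for researchers who want this entire analysis
chain — spectral EEG features, CONN-style BOLD denoising and Fisher-z
connectivity, and the associated inference — as reproducible, unit-tested
code, together with synthetic cohort/EEG/BOLD generators that carry full
ground truth so every estimator can be validated.

## The statistics at the core

* **Subband relative power.** Per 4-s epoch and channel,
  x = P(band) / P(2–35 Hz) for each 1-Hz bin of 8–13 Hz, transformed as
  log[x/(1−x)] and averaged over epochs.
* **IAPF.** argmax over 8–13 Hz of the epoch-averaged power spectrum, at
  0.25 Hz resolution.
* **Denoising.** Regression on 24 motion parameters + 10 aCompCor
  components + spike regressors for volumes whose framewise displacement
  exceeds the subject's 97th percentile; zero-phase 0.01–0.1 Hz band-pass;
  connectivity z = atanh(Pearson r) on uncensored volumes.
* **Inference.** Mixed repeated-measures ANOVA (split-plot sums of
  squares, Type III), Duncan multiple-range post-hoc tests, pooled
  two-sample t contrasts on Fisher-z edges with Benjamini–Hochberg FDR,
  correlation tests with t-based p-values, and the Fisher r-to-z
  comparison z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)).

## Worked example

```r
library(alphaconn)
run <- run_pipeline(default_config(seed = 1))
run$tables$age_iapf_correlation
#>   genotype      r        p  n fisher_z_vs_other fisher_p_one_sided
#> 1  E4minus -0.130 0.221139 91              2.51            0.00608
#> 2   E4plus -0.535 0.000129 46             -2.51            0.00608
head(run$tables$edge_contrast[, 1:6], 3)
#>      roi_i roi_j  beta    T    p_unc    p_fdr
#> 1 VisLat_R SMG_R 0.324 8.53 4.60e-10 2.07e-08
#> 2 VisLat_R  PO_L 0.259 8.22 1.10e-09 2.47e-08
#> 3   Hipp_L PPC_R 0.218 7.22 2.02e-08 3.03e-07
```

The first table shows the age–IAPF correlation per genotype on a default
synthetic cohort (91 non-carriers, 46 carriers): carriers decline much
faster with age (r = −0.54 vs −0.13), and the one-sided Fisher r-to-z
comparison of the two correlations is significant (p = 0.006). The edge
table ranks ROI pairs by the genotype contrast on Fisher-z connectivity:
the top rows recover exactly the couplings the generator planted —
positive interhemispheric visual/opercular/salience edges stronger in
carriers, and the hippocampus–parietal edge whose negative coupling
exists only in non-carriers (hence a positive carrier-minus-non-carrier
beta).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/alphaconn.R run-all --seed 1 --out run1
Rscript inst/cli/alphaconn.R report --out run1
```

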