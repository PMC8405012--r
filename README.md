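# hrnv

Heart rate n-variability (HRnV) analysis and cross-validated clinical risk
modelling in R.

## The problem

Conventional heart rate variability (HRV) summarises the beat-to-beat
fluctuation of R-R intervals (RRIs) extracted from an ECG, and is a
non-invasive correlate of autonomic regulation used to risk-stratify acutely
ill patients — for example, predicting 30-day in-hospital mortality among
emergency-department sepsis patients from a five-minute single-lead tracing.
A single five-minute recording, however, yields only one HRV parameter set.

HRnV multiplies the information extracted from the same tracing. From an RRI
sequence of length L, define for window width n and stride m (1 ≤ m ≤ n):

    RRnI_m[k] = RRI[km] + RRI[km+1] + ... + RRI[km+n-1],   k = 0, 1, ...

with element count `floor((L − n)/m) + 1`. When m = n the windows do not
overlap (the RRnI sequence, giving HRnV parameters); when m < n they overlap
(giving HRnV_m parameters). All `N(N+1)/2` configurations up to n = N are
analysed; with the package default N = 3 that is six parameter sets — HRV,
HR2V1, HR2V, HR3V1, HR3V2, HR3V — each comprising 26 measures across the
time domain (mean NN, SDNN, mean/SD HR, RMSSD, skewness, kurtosis,
triangular index, NN50/pNN50 and, for n > 1, NN50n/pNN50n whose threshold
scales to 50·n ms), the frequency domain (Lomb–Scargle band powers in the
VLF/LF/HF bands, normalised units, LF/HF), and nonlinear measures
(Poincaré SD1/SD2, sample and approximate entropy, DFA α1/α2).

Downstream, the package implements the standard clinical modelling chain on
a per-patient cohort table: normality-gated baseline comparisons (pooled t /
Mann–Whitney U; Yates χ² / Fisher's exact by the expected-count rule; median
imputation), a univariable logistic screen (p < 0.2), Pearson-correlation
collinearity pruning (|r| ≥ 0.8, weaker member dropped), backward stepwise
multivariable logistic regression (removal endpoint p ≥ 0.1), and 10-fold
cross-validated ROC/AUC evaluation — with selection re-run inside every
training fold — against NEWS, MEWS and qSOFA early-warning comparators.

Because no patient data ship with the package, a first-class synthetic-data
module generates seeded IPFM (integral pulse frequency modulation)
tachograms with controllable LF/HF structure, template ECGs for end-to-end
QRS-detection tests, and two-group cohorts from a known logistic generative
model, so every stage is testable against planted ground truth.

## Worked example

```r
library(hrnv)

spec <- tachogram_spec(duration_s = 300, mean_hr = 82,
                       lf_amp = 0.04, hf_amp = 0.05, noise_sd = 6, seed = 42)
rri <- generate_rri(spec)
rri
#> <rri_sequence> ipfm-seed42: 410 intervals, 300.0 s, mean 731.6 ms

tab <- compute_all(rri, n_max = 3)
tab[, c("label","n","m","mean_nn","sdnn","rmssd","nn50n","lf_hf","sd1","sampen","dfa_a1")]
#>   label n m mean_nn  sdnn  rmssd nn50n  lf_hf   sd1 sampen dfa_a1
#> 1   HRV 1 1   731.6 32.50  29.17    NA 0.7546 20.62 1.3879 0.9013
#> 2 HR2V1 2 1  1463.3 58.15  48.35     1 1.0162 34.19 0.9879 0.9749
#> 3  HR2V 2 2  1463.3 58.00  82.41    59 0.9818 58.27 0.7843 0.4253
#> 4 HR3V1 3 1  2194.9 73.84  54.90     0 1.7770 38.82 0.8306 1.1220
#> 5 HR3V2 3 2  2194.6 73.84  95.50    31 1.7100 67.53 0.6410 0.4866
#> 6  HR3V 3 3  2194.3 74.71 115.87    39 0.4851 81.93 1.4975 0.1835
```

Mean NN scales with n, mean HR divides by n, and NN50n is absent for the
n = 1 (conventional HRV) row, where it is undefined.

A synthetic cohort with five planted signal features, the selection
pipeline, and a leakage-free cross-validated AUC:

```r
co <- generate_cohort(cohort_spec(n_patients = 342, prevalence = 0.19, seed = 42))
m <- build_hrnv_model(co, feature_cols = sprintf("feat_%02d", 1:25))
m$trace$retained
#> feat_01 feat_02 feat_03 feat_04 feat_05 feat_09 feat_25 age temperature gcs

cv <- kfold_out_of_fold_scores(
  co, hrnv_recipe(sprintf("feat_%02d", 1:25),
                  adjust_vars = c("age","temperature","sbp","heart_rate","gcs")),
  k = 10, seed = 42)
ci <- auc_ci(cv$scores, co$outcome)
sprintf("cross-validated AUC %.3f (95%% CI %.3f-%.3f, %s)",
        ci$auc, ci$ci_low, ci$ci_high, ci$method)
#> "cross-validated AUC 0.812 (95% CI 0.754-0.870, delong)"
```

All five planted features are recovered (with two false inclusions at this
seed, the expected behaviour of a p < 0.1 stepwise endpoint), and the
out-of-fold AUC reflects the planted signal strength.

## Command line

A thin CLI wraps the R API (see `inst/exec/hrnv`): `simulate` (JSON config →
RRI/ECG/cohort files), `extract` (RRI file → wide feature CSV), and
`analyze --baseline` (cohort CSV → baseline comparison table).

## Scope

Short-recording (5-minute) analysis only: no 24-hour parameters (SDANN),
no multiscale entropy, no arrhythmia classification, no SOFA/APACHE II
computation (their laboratory inputs are out of scope; precomputed scores
can be supplied as columns). See `vignettes/hrnv-methods.Rmd` for the
model, defaults, numerical choices and limitations.
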