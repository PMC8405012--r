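---
title: "HRnV methods: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRnV methods: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrnv)
```

This vignette is the package's own account of the science it implements:
what is computed, under which assumptions, which defaults matter, and where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Combined-interval sequences

Given an R-R interval sequence of length $L$ (ms), the combined sequence for
window width $n$ and stride $m$ ($1 \le m \le n$) is

$$\mathrm{RR}_n\mathrm{I}_m[k] \;=\; \sum_{j=km}^{km+n-1} \mathrm{RRI}[j],
\qquad k = 0, \dots, \left\lfloor \tfrac{L-n}{m} \right\rfloor .$$

$m = n$ gives non-overlapping windows; $m < n$ overlapping ones. Trailing
intervals that cannot fill a complete window are dropped — every emitted
value is a true sum of $n$ measured intervals, at the cost of up to $n - 1$
discarded beats. Each element is time-stamped with the *end* time of its
window; the stamp only matters to the spectral estimator, and any consistent
convention within a sequence gives the same band structure.

With the upper limit $N = 3$ (appropriate to five-minute recordings, where
larger $n$ leaves too few non-overlapping elements) there are
$N(N+1)/2 = 6$ configurations, labelled HRV, HR2V1, HR2V, HR3V1, HR3V2,
HR3V.

## 2. The parameter suite

Each configuration yields 26 parameters (24 for $n = 1$, which has no
NN50n/pNN50n). Definitions and the defaults that matter:

* **Time domain.** Mean NN and SDNN in ms of the combined values; mean/SD
  heart rate as the bpm of the *combined* interval (so the $(n,n)$ set's
  mean HR is the single-beat rate divided by $n$); RMSSD as the uncentred
  root mean square of successive differences; skewness $m_3/m_2^{3/2}$ and
  kurtosis $m_4/m_2^2$ (non-excess, the convention of the common HRV
  toolboxes). NN50 counts $|\Delta| > 50$ ms; for $n > 1$, NN50n counts
  $|\Delta| > 50n$ ms, since a combined interval is $n$ times longer and its
  successive differences scale accordingly. **pNN50/pNN50n denominator:**
  the number of successive differences (count minus one), not the element
  count; the published footnote is ambiguous between the two, so the choice
  is explicit and configurable (`pnn_denominator`).
* **Triangular index.** Element count divided by the modal bin count of the
  interval histogram at a fixed 7.8125 ms (1/128 s) bin width. The width is
  *not* rescaled with $n$ (matching the fixed-discretisation behaviour of
  the standard tools) and is configurable.
* **Frequency domain.** A classical Lomb–Scargle periodogram evaluated on
  the sequence's own uneven time axis — no resampling, hence no interpolation
  bias — at frequencies $k/(T\,\mathrm{ofac})$ up to the HF band edge, with
  oversampling factor 4. Ordinates are normalised so that summing them times
  $2/(N\,\mathrm{ofac})$ approximates the series variance (a Parseval-style
  check asserted in the tests), giving band powers in ms². Band edges
  default to the short-recording convention VLF 0.0033–0.04, LF 0.04–0.15,
  HF 0.15–0.4 Hz; the same absolute bands are applied to every $n$ (whether
  the original analyses rescaled bands for combined sequences is not
  determinable; rescaling can be expressed through `spectral_bands()`).
  Total power is the sum of the three band integrals; normalised units
  divide LF and HF by their sum and are flagged undefined when LF + HF = 0.
* **Poincaré.** SD1 is *defined* as RMSSD$/\sqrt{2}$ (uncentred), making
  the identity SD1 = RMSSD$/\sqrt 2$ exact by construction; the mean-centred
  variant differs only through the mean successive difference, negligible
  for stationary tachograms but visible on a deterministic ramp (where the
  centred variant is 0 and this one is $|\mathrm{step}|/\sqrt 2$). SD2 is
  the sample SD of $(x_{i+1}+x_i)/\sqrt 2$. The ratio is flagged when SD2
  is zero.
* **Entropies.** Template length $m = 2$, tolerance $0.2\,\mathrm{sd}$ of
  the analysed sequence, Chebyshev distance with ties included
  ($\le r$). SampEn excludes self-matches; when no $(m+1)$-template pair
  matches — the typical fate of a short non-overlapping HR2V/HR3V sequence —
  the estimator diverges, and the package reports a fixed sentinel (1000)
  plus a `degenerate` flag instead of an unbounded value, so the blow-up is
  visible but cannot silently dominate downstream statistics. ApEn includes
  self-matches ($\Phi(m)-\Phi(m+1)$) and is exactly 0 for a constant
  sequence.
* **DFA.** Integrate the mean-centred series, detrend linearly per
  non-overlapping box, regress log RMS fluctuation on log box size: α1 over
  boxes 4–16, α2 over 16–64 (toolbox convention). An exponent is flagged
  missing when fewer than 3 of its scales admit at least 2 boxes, rather
  than extrapolated. A caveat asserted in the tests: for uncorrelated noise
  the short-scale estimate is biased upward (≈ 0.55–0.65), a known property
  of small-scale DFA; the theoretical exponent 0.5 is recovered on the
  long-scale range.

Per-parameter failures (short sequences, zero variance) are flagged in a
`flags` column and never abort the vector — mirroring how short combined
sequences behave in practice.

## 3. ECG processing

The QRS detector is a Pan–Tompkins-style chain: running-mean high-pass
(200 ms), 30 ms smoothing (noise low-pass), derivative, squaring, 150 ms
integration, then a *segment-wise* adaptive threshold (30% of the local
2.5 s maximum, short trailing remainders merged) with a 200 ms refractory
period and refinement to the local raw-signal maximum. The segment-wise
threshold is what keeps the detector usable when part of a recording is
corrupted: a single global threshold would be dominated by high-power noise
segments. The original study delegated detection to an external toolbox
without stating parameters, so the detector sits behind one interface and
exact replication of that preprocessing is not attempted.

Signal quality follows the 30% exclusion rule: 10 s windows are labelled by
the mean correlation of their detected beats against the record-wide median
beat template (threshold 0.5, chosen to separate white-noise windows from
template beats cleanly); a recording is usable when at most 30% of windows
are flagged. Optional interval cleaning (`clean_rri`) drops intervals
outside 300–2000 ms or deviating more than 20% from an 11-beat running
median; it is off for synthetic tests, which have no ectopy.

## 4. The synthetic world

`generate_rri` uses integral pulse frequency modulation: beats fire at the
integer crossings of the integral of
$r(t) = (\mathrm{HR}/60)(1 + a_{LF}\sin 2\pi f_{LF} t + a_{HF}\sin 2\pi
f_{HF} t)$. IPFM was chosen because its band powers are controlled directly
by $a_{LF}, a_{HF}$ — exactly the quantities the spectral estimator must
recover — and amplitudes are rate-fractional so the same spec scales across
heart rates. Defaults (300 s, 0.1/0.25 Hz, amplitudes 0.05, 5 ms beat
noise) are conventional short-recording values: the source study does not
characterise its patients' spectral content, so these are a stated choice,
not a fit. Zero modulation and zero noise give an exactly metronomic
tachogram (SDNN = 0), used as an analytic anchor in the tests.

`generate_cohort` draws covariates from marginals shaped like the published
two-group table (age ≈ N(67, 16), heart rate ≈ N(114, 24), etc.), latent
standard-normal features, and the binary outcome from a logistic model
whose intercept is calibrated by root-finding so the expected prevalence
equals the spec (default 0.19); degenerate single-class draws are redrawn
at most 100 times, then error. Group contrasts (the dead being older,
colder, more hypotensive) emerge by conditioning, as in the observational
design. The default plants log-OR 0.7 per SD on the first five of 25
features — the "strong planted signal" world used by the recovery criteria.
The slow `feature_mode = "tachogram"` additionally drives each patient's HF
modulation from the first latent and computes the full feature block from
the generated tachogram, exercising the entire measurement path.

What a green test does **not** establish: real ECG morphology (P/T waves,
ectopy, artefact classes beyond white noise), real feature correlation
structure (latents are independent; real HRnV features are strongly
mutually correlated, which is why the collinearity-pruning stage exists),
or calibration of the generator to any patient population.

## 5. Cohort statistics

Continuous variables gate on a Lilliefors-style normality check: the KS
statistic against a normal with estimated mean/SD, with a parametric Monte
Carlo p-value (2000 replicates, internally seeded and restored) because the
textbook KS null is wrong under estimated parameters. Both groups normal →
pooled two-tailed Student t; otherwise Mann–Whitney U with normal
approximation and midranks. Categorical variables use Fisher's exact test
(full hypergeometric enumeration) when any expected count is below 5, else
the Yates-corrected χ² — the operationalisation of "where appropriate".
Reconstructions of the published baseline table from its printed counts
match its printed p-values to three decimals under the Yates χ² throughout,
including the ICU row whose smallest expected count is ≈ 4.4 — a documented
calibration finding, suggesting the corrected χ² was used there too. The
corrected χ² and the exact test can still differ by several hundredths in
the mid-p region even at large expected counts; the suite asserts tracking
bands and concordant significance calls rather than a hundredth-level
identity. Median imputation fills continuous missing values with the column
median and categorical ones with the mode, on the full table before any
split (a strict fold-wise mode is the natural extension; the cap on
per-variable missingness defaults to the sub-0.3% regime the procedure is
intended for).

## 6. Selection pipeline and evaluation

The modelling chain is: univariable logistic screen of the feature block at
p < 0.2 → add clinical adjustment covariates (age, temperature, systolic
BP, heart rate, GCS) → iterative collinearity pruning (at each step the
most correlated remaining pair with $|r| \ge 0.8$ loses its larger-p
member; ties break to the larger p then the lexicographically later name) →
backward stepwise elimination by Wald p at endpoint 0.1, removed variables
never re-entering. Open choices resolved here: the correlation threshold is
unstated in the source and defaults to 0.8 (configurable, logged in the
elimination record); the adjustment covariates enter as ordinary
candidates rather than being forced to stay, because the published final
model lacks several of them — `force_vars` provides the other reading.
Wald p-values drive elimination, consistent with reported per-variable
statistics. Separation is detected by coefficient/SE divergence and flagged
unestimable rather than ridge-penalised, matching a plain ML fit.
Continuous predictors are not standardised (odds ratios are per unit).

Cross-validation is stratified 10-fold (each class dealt round-robin, fold
sizes within one of $n/k$), with the *entire* selection pipeline re-run
inside every training fold by default, so variable selection cannot leak
into the evaluation; `mode = "paper"` selects once on the full data and
refits only coefficients per fold, a reading the original description also
permits and which yields optimistic AUCs. AUC is the Mann–Whitney
pair-ordering statistic (ties half), identical to the trapezoidal area; its
CI defaults to DeLong's placement variance (the source does not state its
method) with a stratified 2000-replicate bootstrap as the alternative and
the automatic fallback under degenerate variance. NEWS, MEWS and qSOFA are
pure band lookups validated against their published tables; consciousness
maps from GCS (alert iff 15; for MEWS, 13–14 voice, 9–12 pain, <9
unresponsive). One table-level conflict is resolved in favour of the
published banding: a respiratory rate of 15–20 scores 1 on MEWS, so a
"all-zero MEWS" patient needs RR 9–14.

## 7. Known limitations

* The published headline results (the 342-patient descriptive table,
  univariable/multivariable coefficient tables, AUC 0.77 vs comparators)
  are not reproducible without the undeposited dataset; only the printed
  worked examples and property-level behaviour are asserted.
* Lomb–Scargle band power at an effective sampling near 1/mean-interval
  limits the HF band for slow heart rates at large $n$; short combined
  sequences routinely flag spectral and entropy parameters missing — by
  design, not silently.
* The stepwise procedure inherits the known instability of p-value-driven
  selection; it is implemented because it is the procedure under study, not
  as a recommendation.
* SOFA and APACHE II are not computed (laboratory inputs out of scope);
  precomputed columns can be evaluated as score entrants.
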