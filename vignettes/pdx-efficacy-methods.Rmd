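---
title: "Methods: PDX efficacy metrics, response classification and qPCR quantification"
author: "pdxefficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDX efficacy metrics, response classification and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxefficacy)
```

## The setting

Patient-derived xenograft (PDX) drug trials follow small cohorts of mice
(typically 4–7 per arm) engrafted with fragments of the same patient tumor.
Mice enter the study when their tumor reaches a volume of 60–150 mm³, are
randomized to a control or treatment arm, are measured weekly with calipers,
and are sacrificed individually once the tumor reaches about 500 mm³. With
groups this small, efficacy analysis leans on medians, rank tests and exact
conditional tests rather than on means and normal theory. `pdxefficacy`
implements that analysis end to end, together with a synthetic cohort
generator that reproduces the design so every stage can be exercised and
calibrated without animal data.

## Efficacy metrics

**Volume.** Two perpendicular caliper diameters `a >= b` (mm) are converted
to a volume. The default convention is `V = (a*b)^2 / 2`, kept as stated in
the protocol this package follows; the standard ellipsoid approximation
`V = a*b^2 / 2` is available as `"conventional"`. The printed form is
dimensionally anomalous (mm⁴), but since every downstream quantity —
RTV, TGI, RTVV — is a ratio of same-mouse or same-day volumes, the choice
cancels entirely as long as one convention is used throughout a study. We
therefore expose it as a config switch rather than silently "correcting"
it.

**RTV.** The relative tumor volume of a mouse on day *x* is
`RTV = V_x / V_1`, its volume normalized to the day-1 (treatment-start)
baseline. RTV is exactly 1 on day 1 by construction.

**TGI.** Tumor growth inhibition on day *d* is

```
TGI(d) = 100 − 100 · median RTV(treated, d) / median RTV(control, d)
```

and a TGI of at least 50% is flagged as a biologically meaningful effect.
The *optimal* TGI is the series maximum, reported with its day; ties break
to the earliest day. A day enters the TGI series only when both arms still
have at least two measured mice (`min_n_per_day`); medians of one remaining
mouse tell you little, and sacrifice thins the arms late in the study. With
an even number of mice, the median is the mean of the two central values.

**RTVV / ORR.** Per-mouse response is classified at "end of treatment",
which we define as the last measurement day the treated mouse's arm shares
with the control arm (mice sacrificed earlier contribute their last
recorded RTV and are flagged `carried_forward`; the alternative of dropping
them would discard exactly the fastest-progressing animals). The relative
tumor variation is `RTVV = RTV_mouse / median RTV(control)`, the overall
response rate is `ORR = RTVV − 1`, and the mouse is a **responder** iff
`ORR < −0.5` — a strict inequality, so a mouse sitting exactly at half the
control median is not a responder. Responder fractions are reported as
percentages rounded half-up to one decimal. Responder counts between two
treatments are compared with Fisher's exact test.

**Progression events.** For each mouse the package derives the time to
RTV × 2 (doubling) and RTV × 4: the event day is the *first measurement
day* with RTV at or above the fold. We deliberately do not interpolate
between the weekly measurements — the cadence is weekly and any
interpolation rule would manufacture resolution the data do not have. Mice
that never cross are censored at their last measurement day (for
sacrificed mice, the sacrifice day). Arms are compared by the Kaplan–Meier
product-limit estimate and the Mantel–Cox log-rank test (hypergeometric
variance, 1 df, no continuity correction), computed through the `survival`
package with a hand-coded oracle in the test suite.

## The exact tests

Arm sizes of 4–7 put every real comparison deep in exact-test territory, so
the two workhorse tests are implemented in full rather than approximated:

* **Mann–Whitney U** (two-tailed): `U` counts pairs `(x_i, y_j)` with
  `x_i > y_j` plus half the tied pairs. For tie-free data with combined
  `n ≤ 20` the p-value is exact, from the permutation distribution of `U`
  computed by a rank-sum subset-sum recursion; the two-sided p doubles the
  smaller tail and caps at 1. Larger or tied samples use the normal
  approximation with midranks, tie-corrected variance and continuity
  correction (tied small samples fall back with a warning — an exact
  tie-free enumeration would be silently wrong there).
* **Fisher's exact test** (two-sided) uses minimum-likelihood summation:
  all tables with the observed margins whose hypergeometric probability
  does not exceed the observed table's (relative tolerance 1e-7) contribute
  to p. This matches the most common software convention; other two-siding
  rules exist, and the choice is visible in the code rather than buried.

Both are validated in the test suite against brute-force enumeration
(all `C(m+n, m)` assignments; explicit `choose()` summation over all 2×2
tables with total ≤ 40) and against the independent base-R implementations.

## RT-qPCR quantification

Expression is quantified relative to the TATA-box binding protein (TBP)
reference transcript, assayed in both its human (tumor) and murine (stroma)
forms. The two reference Ct values are combined by their arithmetic mean —
the geometric mean of the linear quantities, the natural choice when the
protocol states both transcripts are used but not how; a single detected
reference passes through unchanged, and samples with neither are dropped
with a warning.

For a target gene, `ΔCt = Ct(TBP) − Ct(target)` and the relative
expression is `N_target = 2^ΔCt` (one cycle = one doubling). Values are
then rescaled so that a target amplifying at the basal quantification
limit `Ct = 35` scores exactly 1:
`expression = N_target / 2^(Ct_ref − 35) = 2^(35 − Ct_target)` when each
sample's own reference is used (the default; a cohort-median reference is
available for cross-sample comparability). Undetected targets (Ct ≥ 40 or
missing) are floored at the basal level 1 and flagged rather than dropped,
preserving group sizes for the rank tests. Treated-versus-control
comparisons use the two-tailed Mann–Whitney test on the normalized
expressions; the fold change is reported on the raw `N_target` medians,
where per-sample reference variation cancels exactly. No primer-efficiency
correction and no multiple-testing adjustment are applied (the analysis
reports unadjusted per-gene p-values).

## The synthetic cohort generator

`simulate_study()` emulates the study design, not any particular tumor
biology:

* latent exponential growth `V(t) = V1 · exp(g_i (1 − e)(t − 1))`, with the
  per-mouse rate `g_i` lognormal around the configured median `g`
  (median-preserving parameterization, `σ² = log(1 + CV²)`) — exponential
  rather than Gompertz because tumors are only followed to ~500 mm³, well
  below saturation;
* treatment as a constant multiplicative rate reduction `e` from day 1
  (`e = 0` null, `e = 1` full arrest); dosing holidays are not modelled;
* `V1` uniform on the enrollment window (default 60–150 mm³), weekly
  measurement, multiplicative lognormal observation noise;
* per-mouse sacrifice at the first *observed* volume ≥ 500 mm³ (the
  arm-mean sacrifice rule used in practice would censor mice informatively
  and its exact application is ambiguous, so the per-mouse rule keeps
  censoring well defined);
* one global seed, with each mouse's stream derived deterministically from
  it, so studies are reproducible to the byte.

Defaults: `n_per_arm = 6`, `growth_rate = 0.03`/day (doubling time ≈ 23
days, slow-growing xenografts reaching sacrifice volume in 2–3 months),
`growth_cv = 0.3`, `measurement_noise_cv = 0.1`, follow-up 120 days. These
are chosen for testability and plausibility; no published variance
components exist for the emulated cohorts, so the simulator demonstrates
the pipeline's statistical behaviour (type-I error, monotonicity, power
trends), not fidelity to any specific tumor's kinetics. What passing tests
on synthetic cohorts *do not* show: robustness to non-exponential growth,
correlated measurement error, informative arm-mean sacrifice, or
between-model heterogeneity in drug response.

```{r calibration-example}
# a null study: no treatment effect
study <- simulate_study(sim_config(seed = 20), effects = c(control = 0, t = 0))
suppressWarnings(optimal_tgi(study$arms$t, study$arms$control))
```

The test suite verifies that under the null the exact Mann–Whitney test on
day-22 RTVs rejects at α = 0.05 within the binomial band expected over
1000 replicate studies (the exact test is conservative by discreteness: at
6 vs 6 its attained two-sided size is ≈ 0.041, not 0.050), and that the
mean optimal TGI is monotone in the effect multiplier over
`e ∈ {0, 0.25, 0.5, 0.75, 1}`.

## Numerical and degenerate-input conventions

* Medians with even counts: mean of the two central values.
* Responder percentages: half-up rounding to 1 decimal.
* Log-rank with zero events in both groups: p = 1 with a warning rather
  than NaN.
* Mann–Whitney with all observations identical: p = 1.
* Single-measurement curves: censored at day 1 for fold events.
* Fisher probability comparisons use a 1e-7 relative tolerance so binary
  representation noise cannot flip table inclusion.
* Report CSVs render doubles with `%.17g`, making write→read lossless and
  repeated writes byte-identical; p-values are rounded to 3 significant
  figures only in the plain-text summary.

## Problem sizes used in the checks

The bundled tests run studies of 4–7 mice per arm (the design being
emulated), 1000-replicate null calibrations, 1000-curve property sweeps,
exhaustive Fisher validation to table total 40, and Mann–Whitney
enumeration to combined n = 8 — sizes at which the brute-force oracles are
exact and fast. The acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recomputes a full three-arm analysis and the null calibration from a single
seed.

## Known limitations

* TGI at a given day compares medians of the mice still measured that day;
  late days can rest on few mice even with the `min_n_per_day` guard, and
  differential sacrifice makes late TGI values survivorship-tinted. The
  optimal-TGI day should be read together with the arm sizes in the report.
* Pooled (unstratified) log-rank comparisons are the default when several
  PDX models are combined; stratification is left to the caller by running
  per-model studies.
* The RTVV evaluation day for mice sacrificed early uses last-value
  carry-forward, which is conservative for fast progressors.
* No hazard ratios, dose–response or PK modelling, and no body-weight or
  toxicity endpoints.
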