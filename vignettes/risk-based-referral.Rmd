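---
title: "Risk-based nephrology referral under competing risks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based nephrology referral under competing risks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroref)
```

## The problem

Most chronic kidney disease (CKD) is managed in primary care, and the
decision to refer a patient to a nephrologist has traditionally been made
with fixed thresholds of eGFR, albuminuria and age. Current guidance
instead recommends referral when the predicted 5-year risk of kidney
failure — kidney replacement therapy (KRT), i.e. chronic dialysis or
pre-emptive transplantation — exceeds a cutoff, computed with the
four-variable Kidney Failure Risk Equation (KFRE). `nephroref` implements
the full machinery needed to compare the two policies on longitudinal
laboratory data: KFRE scoring and local recalibration, rule-based referral
criteria, and a competing-risk evaluation and decision-analytic layer. A
seed-reproducible synthetic cohort generator stands in for registry data,
which are never shareable in this setting.

## The risk model

The four-variable KFRE is a Cox-type index on transformed covariates
$x = (\text{age}/10,\ \text{male},\ \text{eGFR}/5,\ \ln \text{ACR})$
centred at constants $c$ from the development cohort:

$$\text{risk}(t) = 1 - S_0(t)^{\exp(lp)}, \qquad
  lp = \beta^\top (x - c).$$

`kfre_published()` ships the published coefficients
$\beta = (-0.2201, 0.2467, -0.5567, 0.4510)$, centering
$c = (7.036, 0.5642, 7.222, 5.137)$ and the baseline survivals of the
original ($S_0(2) = 0.9832$, $S_0(5) = 0.8996$) and the non-North American
recalibrated variant ($S_0(2) = 0.9878$, $S_0(5) = 0.9240$). These
constants are transcribed from the original publications and flagged as
externally sourced; at the centering point the 5-year risk of the
non-North American variant is exactly $1 - 0.9240 = 0.076$, which the test
suite asserts.

eGFR comes from the revised Lund–Malmö equation (`egfr_rlm()`), the
creatinine equation reported automatically by Swedish laboratories; it is
piecewise in creatinine with a sex-specific knot and is continuous and
strictly decreasing, both tested. Albuminuria is harmonized to ACR in mg/g
(`harmonize_albuminuria()`): native ACR passes through (mg/mmol accepted
with factor 8.84), while PCR and dipstick tests map through a conversion
table keyed by sex/diabetes/hypertension strata. Published stratified
conversion coefficients are not redistributable here, so the shipped table
is a deliberately crude, clearly labelled synthetic fallback (fixed
dipstick category medians, fixed PCR factor); users should transcribe a
published table into the documented CSV schema for applied work.

## Observation records

Mirroring automatic reporting in electronic health records, one record is
built per creatinine test, paired with the nearest albuminuria test within
12 months (ties to the earlier test), indexed at the later date
(`pair_tests()`; a full cross-join mode exists for comparison). A person is
excluded when their *first* record has eGFR ≥ 60, prevalent KRT, or death
within one day; later records with eGFR ≥ 60 are kept by default, because
the entry criterion is defined at cohort inclusion only (a stricter
per-record filter is available). Follow-up runs to the first of KRT,
death, emigration, administrative end, or the horizon boundary, with
horizons converted to days as `floor(365.25 * years)` so boundaries are
leap-year stable. Refractory hypertension is defined as four or more
distinct antihypertensive classes dispensed in the half-open window
`(index - 183 d, index]`.

## Competing-risk evaluation

Death precludes KRT, so all observed event probabilities are
Aalen–Johansen cumulative incidences,
$\hat F_k(t) = \sum_{t_i \le t} \hat S(t_i^-) d_{k,i} / n_i$, with
$\hat S$ the all-cause Kaplan–Meier and events processed before censorings
at tied times (`aalen_johansen()`). The implementation is checked against
an exhaustive brute-force oracle on *every* dataset of up to six records
and against the multi-state `survival::survfit()` estimator; the identity
$\sum_k \hat F_k + \hat S = 1$ holds to $10^{-10}$ everywhere.
Group-wise confidence intervals use the Marubini–Valsecchi variance with a
log(−log) transform.

Discrimination and thresholds:

* `cd_roc()` builds a cumulative/dynamic ROC where a record is
  referral-positive at threshold $c$ when its predicted risk is ≥ c
  (the inclusive convention matches the referral-rule boundary), with
  $\text{Sens}(c,t) = P(M \ge c) F_{\ge c}(t) / F(t)$ and
  $\text{Spec}(c,t) = P(M < c)(1 - F_{< c}(t)) / (1 - F(t))$. With
  complete uncensored follow-up this reduces *exactly* to the empirical
  binary ROC. Under censoring the group-wise product-limit construction
  can wobble non-monotonically by $O(1/n)$; this is a property of the
  estimator, is bounded in the tests, and vanishes in the uncensored
  reduction.
* `youden_optimal()` maximises $J = \text{Sens} + \text{Spec} - 1$ over
  the threshold grid, breaking ties towards the higher threshold (fewer
  referrals). The default grid is every distinct risk value (exact
  optimisation); pipelines cap it at a quantile grid (`max_thresholds`,
  default 512) for large cohorts, a purely computational device.
* `c_index()` is the horizon-truncated cause-specific concordance:
  controls for a case at $T_i$ are records still observed beyond $T_i$
  *plus* records that died without KRT at or before $T_i$ — death means
  the referral was not needed, matching the false-positive accounting of
  the classification tables.
* `brier_score()` is the IPCW Brier score with Kaplan–Meier censoring
  weights (cases and deaths weighted by $1/G(T^-)$, horizon survivors by
  $1/G(t)$); on uncensored data it is the mean squared error.

Calibration (`calibration_table()`) splits records into deciles of
predicted risk (ties stay together; collapsed groups warn), compares the
group mean prediction with the group Aalen–Johansen incidence, and
attaches a re-split of the lowest 20% — the region that actually drives
referral decisions.

## Recalibration

`fit_recalibration()` refits the KFRE on local data with a Cox model on
the same centred transforms (so coefficients stay directly comparable),
Efron tie correction (registry dates are heavily tied; the fit is verified
against a brute-force Efron partial likelihood to $10^{-8}$), and death
treated as censoring — retaining the original KFRE structure, which was
also built on death-censored data. The baseline survival is the Breslow
estimator $S_0(t) = \exp(-\hat H_0(t))$ evaluated by step interpolation at
`floor(365.25 h)` days. Repeated records per person enter as independent
rows, matching a record-level main analysis; a person-clustered
robust-variance option exists because within-person correlation is a real
concern (the one-random-record-per-person sensitivity mode addresses it at
the design level).

## Decision analytics

`classification_table()` cross-tabulates referral against observed 5-year
KRT. The default `raw_counts` policy counts a record as a case only when
KRT occurred within the horizon — records censored earlier and deaths
count as non-cases, which is how integer cells over all observations are
naturally produced; a `cif_weighted` policy (expected cases
$n_\text{cell} F_\text{cell}(t)$) is provided because censored records
arguably carry partial information, and the two coincide exactly without
censoring. `nri()` implements the two-category net reclassification
improvement with cell-level Aalen–Johansen event probabilities, which is
censoring-robust and reduces exactly to the classical binary NRI on
uncensored data; the decomposition $\text{NRI} = \text{NRI}^+ +
\text{NRI}^-$ and antisymmetry under swapping rules are identities in the
implementation. `decision_curve()` computes net benefit
$NB(p_t) = \tfrac{n_+}{N} F_+(t) - \tfrac{n_+}{N}(1 - F_+(t))
\tfrac{p_t}{1-p_t}$ on a grid (default 0.005–0.30 by 0.005, covering all
referral cutoffs in practical discussion), with treat-all/treat-none
references; fixed rules enter as threshold-independent classifications
because they emit decisions, not risks.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a regional
testing registry rather than any real population:

* entry at the first creatinine test, uniform over 2006–2021; truncated
  normal age (mean 75.5, sd 9.5) and entry eGFR on (5, 60) (mean 56,
  sd 9, giving median ≈ 54 after truncation); log-normal person-level ACR
  (meanlog 3.05 ≈ 21 mg/g, sdlog 0.9 reproducing the reported IQR);
  49% male.
* test occasions per person $1 + \text{NB}(\text{size } 0.4, \mu = 3)$,
  reproducing a median of 2 with IQR 1–5; each occasion emits creatinine,
  and with probability 0.9 an albuminuria test up to ±30 days away (46%
  dipstick, 9% PCR, rest native ACR, 20% of quantitative values reported
  in mg/mmol).
* latent linear eGFR decline (−1.5 ± 1 ml/min/1.73 m²/yr) with ~8%
  multiplicative measurement noise, inverted through the exact RLM inverse
  so emitted creatinines are trajectory-consistent; observed ln ACR gets
  within-person noise (sd 0.4).
* cause-specific hazards: piecewise-constant baselines scaled by
  $\exp(\beta^\top(x_0 - c))$ on the entry covariates through the KFRE
  transforms — so a Cox refit has a recoverable truth — and drifting
  log-linearly with the latent eGFR decline
  ($g = \beta_\text{eGFR}\,\text{slope}/5$ per year), sampled by exact
  inverse-CDF inversion of the piecewise cumulative hazard. The 0–2y and
  2–5y KRT baseline pieces reproduce the published non-North American
  $S_0(2)$ and $S_0(5)$ at the centering point; the >5y piece (0.008/yr)
  and the death baseline (0.11/yr with its own coefficient vector) were
  fixed once so that observed person-level fractions land near 1.2–1.6%
  KRT and 35–44% death over the window.
* censoring by exponential emigration (0.01/yr) and the administrative
  window end; a `miscalibration_factor` multiplies the KRT baseline to
  emulate a population whose risk an imported model misestimates.

What the generator does **not** emulate: informative testing (occasions are
a homogeneous process, not sicker-patients-test-more), comorbidity-driven
hazards beyond the four KFRE covariates, assay drift, pediatric or
pregnancy physiology, or real Swedish demography. Passing tests therefore
demonstrate the *statistical machinery* — estimator correctness, recovery,
miscalibration detection, decision-analytic ordering — not clinical
performance on real data. One visible consequence: because records are
scored on noisy, dipstick-coarsened measurements while the truth runs on
latent covariates, the imported model shows a calibration slope around
0.6–0.7 and C-index around 0.7 on the default cohort — classical
regression dilution, smaller with `acr_only` subsets and zero in the
noise-free experiment configurations.

## Numerical and design choices

* Horizons in days: `floor(365.25 * years)`; half-open lookback windows
  `(index - L, index]`; ties at event times: events before censorings.
* KFRE referral cutoffs are boundary-inclusive (risk ≥ cutoff refers),
  which makes cutoff-nesting exact; a switch flips it.
* The pairing of creatinine with albuminuria is one record per creatinine
  test by default (nearest in-window partner) — the full cross-join within
  the window exists behind a flag since registry practice is ambiguous.
* Calendar-period strata default to tertiles of the study window.
* Cox fits require a configurable minimum number of KRT events
  (default 50) and fail loudly on non-convergence.
* The Swedish threshold criteria are shipped only as a clearly marked
  placeholder YAML (`inst/extdata/swedish_rules_example.yaml`); locally
  valid thresholds must be supplied for applied use. Likewise any locally
  recalibrated coefficient set can be loaded from the documented model
  JSON schema instead of being hard-coded.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  sim = sim_config(n_persons = 5000, seed = 1),
  out_dir = "nephroref_run",
  models = c("published", "recalibrated"),
  rules = list(kdigo2012 = rule_kdigo2012(),
               swedish_example = read_threshold_rule()),
  cutoffs = c(0.03, 0.05, 0.09, 0.15),
  seed = 1)
run <- run_pipeline(cfg)
run$discrimination
run$youden$published
```

The run writes per-record scored observations, ROC/Youden and calibration
tables, Table-2/3/4-style operating, classification and reclassification
reports, NRI and decision-curve CSVs, and a JSON manifest carrying the
seed and a content hash that stamps every CSV; identical config + seed
reproduces every file byte for byte.

## Problem sizes used in the tests

The test suite exercises estimator oracles exhaustively on all ≤6-record
datasets; coefficient recovery on 20 000 single-record persons at a high
event fraction (the information ceiling for the binary sex coefficient at
that n); miscalibration detection/repair on 300 000 single-record persons
(chosen by a power analysis so the lowest risk decile's under-prediction
sits near 4.5 standard errors); and the classification/net-benefit
patterns on 20 000 persons with observation-level covariate marginals.
The packaged acceptance script runs the full pipeline on 15 000 persons
(~50 000 records), which completes in well under a minute on one CPU.

## Known limitations

* The competing-risk cd-ROC is the cumulative/dynamic variant only; no
  incident/dynamic ROC, no curve smoothing.
* No bootstrap confidence intervals for NRI or net benefit; group-level
  CIs are analytic (log(−log)).
* The C-index variant is the truncated cause-specific concordance with
  deaths as controls — a documented choice among several defensible ones.
* The 8-variable KFRE, cystatin-based or CKD-EPI eGFR equations, and
  time-varying covariate Cox models are out of scope.
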