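---
title: "Quality-assured laboratory MELD diagnostics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-assured laboratory MELD diagnostics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labmeld)
```

## The score

The lab-MELD score estimates three-month mortality in end-stage liver
disease and drives liver-graft allocation. `compute_meld()` evaluates

$$\mathrm{MELD} = \mathrm{round}\big(10\,(0.957 \ln C + 0.378 \ln B
  + 1.12 \ln I + 0.643)\big)$$

with creatinine $C$ and bilirubin $B$ in mg/dL and the INR $I$
dimensionless. Laboratory inputs are SI units (µmol/L); the conversion
divisors are 88.4 for creatinine — pinned by the regulatory equivalence
353.6 µmol/L = 4.0 mg/dL — and 17.1 for bilirubin. Clamps, applied in this
order: the dialysis override (below), then each component floored at 1.0,
creatinine capped at 4.0 mg/dL, the rounded score clamped to [6, 40].
Rounding is half-up everywhere (`round_half_up()`), not R's default
round-half-to-even: a raw score of 19.5 reports as 20. All weights and
clamps live in `meld_coefficients()` so a regulatory variant is a
configuration change.

**Dialysis override.** Dialysis lowers creatinine without improving the
liver, so the regulations substitute 4.0 mg/dL when renal replacement
criteria are met: at least two intermittent dialyses, or at least 24 h of
continuous veno-venous hemodialysis (CVVHD), within the prior week. The
package evaluates this strictly as `sessions >= 2 || cvvhd_hours >= 24`;
albumin dialysis is a liver-support procedure, not a kidney replacement
method, and never qualifies (it triggers consultation instead).

**MELD-Na.** `compute_meld_na()` applies the sodium adjustment when the
initial MELD is at least 11 ("at least" is taken literally: 11 qualifies),
with sodium clamped to 125–137 mmol/L and the result capped at 40. Because
$1.32/0.033 = 40$, the adjustment is non-negative for every reportable
score, so MELD-Na never falls below MELD. Missing sodium leaves MELD-Na
unset rather than failing: sodium is an optional analyte on the request
form. The package computes both scores and reports lab-MELD as the primary
result; which of the two a transplant organisation consumes is a policy
question outside the laboratory.

## The verification algorithm

`validate_request()` runs six rule groups in a fixed order — order
integrity, preanalytics, INR resolution, dialysis plausibility,
anticoagulation, delta check — and collects machine-readable reason codes
in evaluation order. Codes are of two kinds. *Blocking* codes mean the
specimen cannot yield a valid score (a new draw is needed): material
errors, split orders, transit/entrance timeouts, underfilled or clotted
citrate, misidentification, under-age (PELD) requests, anticoagulation
influence, and an INR that cannot be resolved. *Consultation* codes mean
the numbers may be fine but a statement must be clarified with the sender:
all dialysis findings, delta-check failures, and an INR that was resolved
by policy rather than measured. The disposition follows mechanically:
any blocking code → `INVALID` (no result attached, ever); otherwise any
consultation code → `NEEDS_CONSULTATION` (a provisional score is computed
but not releasable); otherwise `VALID` with the released score. One design
point was genuinely open: an undeterminable INR that *is* resolved (manual
curve read, carried-forward INR) and a missing dialysis statement both
route to consultation here, because in both cases a human must sign off
before transmission — the blocking list is reserved for specimens that can
never be salvaged.

`apply_correction()` implements the consultation outcome for dialysis: the
confirmed status re-scores the request and yields `CORRECTED_VALID`, with
the old and new status in the corrections map and
`DIALYSIS_STATUS_CORRECTED` appended. A confirmed status that itself fails
the criteria keeps the case in consultation; a confirmed status equal to
the stated one returns the verdict unchanged. Correction is monotone:
revoking a qualifying status can only lower the score (creatinine below
the cap), confirming one can only raise it.

### Thresholds

Where no regulatory number exists, the defaults are routine-practice
choices, declared once in `verification_config()` and overridable from a
YAML/JSON file:

| parameter | default | why |
|---|---|---|
| co-draw tolerance | 30 min | "sent in at the same time" needs a number; one draw round |
| transit maximum | 4 h | citrate stability; longer transit inflates the INR |
| order-to-lab window | 24 h | an order executed a day late is a stale clinical picture |
| citrate fill minimum | 0.90 | citrate-to-blood mixing ratio distorts PT below ~90 % fill |
| MELD age minimum | 12 y | younger patients are PELD patients (routing only) |
| delta thresholds | creatinine 100 %, bilirubin 150 %, INR 75 % in 7 d | relative changes implausible for liver/kidney kinetics at the respective assay noise |
| anticoagulation impact | INR > 1.5 with stated VKA/DOAC, or > 1.2 × baseline | therapeutic VKA targets start near 2; 20 % over baseline exceeds analytic + biologic variation |
| synthesis "unchanged" | ± 20 % | albumin/fibrinogen/cholinesterase stability band for the unravelling heuristic |
| dialysis plausibility | creatinine < 100 µmol/L, or rise > 50 % in 7 d | near-normal or steeply rising creatinine contradicts effective renal replacement |
| clotting timeout | 315 s | coagulometer waiting time |
| INR policy | `last_determinable` | the advisory-committee practice; `table_max` (conversion-table maximum, default INR 9.0) and `block` selectable |

The anticoagulation *unravelling* heuristic deserves a note: a rising INR
with unchanged synthesis markers points to a drug, while a rising INR with
collapsing albumin/fibrinogen/cholinesterase is the liver failing — only
the former is flagged. When no synthesis marker is available in both the
current and baseline result, the heuristic stays silent rather than guess.
From laboratory values alone, minor anticoagulation effects remain
undetectable; the rule aims at clear discordance, not at certainty.

Timestamps are ISO-8601 and timezone-naive (single-site clock); age is
calendar age in completed years at draw time.

## The cohort simulator

`simulate_cohort()` exists so that every rule, disposition and rate is
testable without patient data. It generates:

* **Patients, not just rows.** Request counts per patient are geometric
  with mean 7,270/1,494 ≈ 4.87, matching the reference workload's
  requests-to-patients ratio; each patient carries base analyte levels,
  sex (63 % male), age (normal, mean 55, truncated to 12–84), dialysis
  status and anticoagulation class. Requests fluctuate around the
  patient's base level (± 10 % for bilirubin/creatinine, ± 7 % for INR),
  which keeps every clean repeat inside all delta and baseline bands by
  construction.
* **Marginals loosely calibrated, not estimated.** Bilirubin and
  creatinine are log-normal around medians 31.7 and 86 µmol/L, the INR is
  a shifted log-normal with median 1.3; dispersions were chosen once so
  that cohort extremes (≈ 2–1,100 µmol/L bilirubin, INR up to ~11) are
  plausible at n ≈ 7,000. Dialysis prevalence is 7.7 % of patients, who
  get elevated creatinine bases (150–600 µmol/L) as real dialysis patients
  do; anticoagulation prevalence is set so the per-request rate matches
  524/7,270 (the reference mixes patient and request denominators; rates
  here are per request throughout).
* **Calibrated error injection.** At most one error category per request,
  drawn with probabilities `default_error_rates()` = category count /
  7,270 from `calibration_counts()`; the categories sum to the headline
  193/7,270 ≈ 2.7 % flagged. `inject_error()` mutates a clean request
  minimally so the targeted rule fires, and fires first. Two mechanics
  matter: histories always hold the *clean* (pre-injection) values,
  because the laboratory compares against previously validated results — a
  corrupted value must not poison the next request of the same patient;
  and the delta-check injection quadruples *bilirubin* (not creatinine,
  whose spike would trip the earlier-evaluated dialysis-plausibility rule
  on dialysis patients), fabricating a prior validated result two days
  earlier when the patient has none within the lookback.

What the simulator does **not** emulate: sex-stratified analyte
differences, the joint distribution of analytes within a patient
(components are independent around their bases), seasonal or workload
drift, hemolysis and other continuous-quality gradations, multi-error
requests (available in principle but excluded from calibration), and any
real measurement-method effects. Passing pipeline tests on simulated
cohorts therefore demonstrates the correctness and calibration of the
*rules*, not the clinical performance of the thresholds on real
distributions.

## Numerical and degenerate-input choices

* Half-up rounding throughout, with an epsilon guard against binary
  representation of decimal inputs; percentages report to one decimal.
* All concentrations must be strictly positive; a missing INR is a typed
  state (`no_clot_within_timeout`), never a silent `NA` — scoring refuses
  it and directs the caller to `resolve_inr()`.
* `resolve_inr()` under `last_determinable` with an empty history blocks:
  inventing an INR is the one thing the pipeline must never do.
* An empty cohort summarising, a zero margin in the 2×2 test, mismatched
  verdict/request lengths, and unparseable timestamps are errors, not
  warnings.
* The 2×2 association helper is the uncorrected Pearson chi-squared
  (continuity correction selectable), delegated to `stats::chisq.test()`
  and cross-checked in the tests against the textbook formula.

## Problem sizes used in the test suite

The cohort-level checks run 20 seeded cohorts of 7,270 requests
(145,400 validations) and require the mean flagged rate to sit within
three binomial standard errors of the 2.7 % calibration headline, and each
category's recovered rate within three binomial standard errors of its
injected probability. Scoring equivalence against an independently coded
formula oracle uses 10,000 random panels; monotonicity, clamp idempotence
and correction monotonicity use a few hundred randomized cases each under
fixed seeds.

## Known limitations

* PELD is routed, not computed; match-MELD/standard-exception scoring is
  out of scope.
* The heparin-overdose mechanism (thrombin-time interference) is not
  modelled; such cases surface only through the baseline/delta heuristics.
* Consultation outcomes are explicit inputs (`apply_correction()`); the
  package does not mine clinical records.
* Delta and plausibility thresholds are declared defaults, not estimates;
  sites should tune them against their own populations via the config
  file.
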