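---
title: "Methods: decision-tree cost model and probabilistic sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost model and probabilistic sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddicost)
```

## The question the model answers

When a dermatologist examines a patient with one to three atypical
melanocytic lesions, optical dermoscopy (OD) alone often cannot distinguish
a benign naevus from a very early melanoma; without further tools, the
lesion is excised to rule out melanoma. Sequential digital dermoscopy
imaging (SDDI) stores dermoscopic images and compares them over time, so a
slightly or moderately suspicious lesion can be monitored instead of
excised, at the price of follow-up visits. Both strategies find the
melanomas; they differ in the *extra-costs* of the detection process —
excision and pathology of lesions that turn out benign, and/or the SDDI
monitoring visits. Melanoma excision and pathology themselves are excluded,
being identical in both arms.

`sddicost` models a two-arm comparison under Belgian 2012 tariffs:

* **Group 1** — OD only: every suspicious lesion is excised;
* **Group 2** — OD with selective SDDI: highly suspicious lesions are
  excised upfront, the rest monitored (with delayed excision on change).

The cost outcome is normalised per melanoma diagnosed, and the primary
quantity is the between-arm difference in extra-cost per melanoma.

## Billing pathway

Each benign-excision patient is billed a fixed pathway: a first
dermatologist consultation (plus, in Group 1, the optical dermoscopy fee),
a second consultation at which the excision is performed, the surgical fee
(54.10 for the first excision, 27.05 for each further same-day excision),
and a general practitioner visit for stitch removal. With the 2012 tariffs
this is 141.92 per patient with the OD fee and 135.53 without. Pathology
(62.02) is billed once per patient-session however many lesions were
removed, and two immunostains (2 x 25.41) are billed for as many benign
naevi as there were melanomas in the arm — capped, in the simulation, at
the number of benign-excision patients, since the stains are performed on
benign naevi. SDDI monitoring bills consultation + SDDI exam (52.10) at
inclusion, at 3 months, and at 12 months for the attending fraction.

Two accounting choices deserve emphasis, because they are the only
decomposition of the tariff table that reproduces the published simulated
means to the cent:

* the excision session carries its own dermatologist consultation (two
  consultations per excised patient), and
* each multi-excision patient contributes exactly one additional reduced
  excision fee (533 x 141.92 + 33 x 27.05 = 76,536.01).

Money is carried in full floating precision and rounded only in the report
layer (nearest euro; displayed totals are recomputed from the rounded
components so the printed columns add up).

## Parameter distributions

Observed sufficient statistics per arm (screened patients, benign-excision
patients, multi-excision patients, total benign excisions, melanomas, SDDI
registration and attendance) are turned into independent sampling
distributions:

| parameter | distribution | construction |
|---|---|---|
| patients with unnecessary excisions | Binomial(n, k/n) | screened / excised |
| proportion with >1 excision | Beta(33, 500) | successes, failures — no prior pseudo-counts |
| average excisions per patient | Gamma(570, 533) | shape = excisions, rate = patients |
| melanomas | Poisson(70), Poisson(32) | zero-truncated at sampling time |
| SDDI registrations | Poisson(124) | Group 2 only |
| 3-month attendance | fixed 1 | all registered patients attended |
| 12-month attendance | Beta(90, 34) | denominator = registered cohort (124) |

Zero-truncation of the melanoma counts keeps the per-melanoma ratio
defined; at rates of 32 and above it shifts the mean by less than
1e-12 relative, which the test suite asserts. The 12-month Beta uses the
registered cohort, not the 113 patients still monitored after the 3-month
excisions — forced by the printed hyperparameters (90 + 34 = 124).

The Gamma-distributed average number of excisions per patient is sampled
and recorded (it appears in the tornado analysis) but does not enter the
cost arithmetic: the multi-excision surcharge runs off the Beta proportion,
in expectation form (`n_patients x prop_multi x 27.05`). This is the only
reading under which the plug-in mean hits 76,536.01 exactly, and it
predicts — correctly, see the importance tests — a near-zero standardized
coefficient for that parameter.

## Monte Carlo engine and summaries

`run_psa()` draws every parameter once per iteration (iteration-major
order, all Group 1 parameters then all Group 2 parameters) from a single
Mersenne-Twister stream, so runs are bit-reproducible given a seed; 10,000
iterations take about three seconds. Percentiles use linear interpolation
between order statistics (R's default type 7) — a convention that must be
fixed for reproducibility; the two-sided 95% credibility interval is the
2.5th–97.5th percentile range, and difference outcomes additionally carry
the one-sided upper interval (5th percentile to maximum). The headline
significance statement is the proportion of iterations in which the
OD-only arm is more expensive per melanoma.

Variable importance regresses the standardized outcome on the eight
standardized parameter draws (sample-sd convention, n-1 denominator; the
regression keeps an intercept for numerical robustness, which is ~0 after
centring and excluded from the report). Coefficients are ranked by absolute
value, ties broken by parameter declaration order. The R-squared is checked
against an independent covariance-matrix oracle to 1e-8.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces patient-level records whose aggregation has
the statistical structure the analysis assumes: Bernoulli benign-excision
eligibility, Bernoulli multi-excision among the excised (with a
configurable probability of a third same-day excision), Poisson melanoma
counts disjoint from the benign-excision patients, Bernoulli SDDI
registration among the remaining patients and Bernoulli 12-month
attendance (3-month attendance is complete, as observed). Calibrated
defaults reproduce the published cohorts; two values are the package's own
calibration where the source tallies underdetermine them:

* a multi-excision patient receives a third excision with probability
  4/33 — 570 total excisions from 533 patients with 33 multi-excision
  patients forces exactly 4 triples among the 2-or-3 configurations;
* SDDI registration probability 124/1815, i.e. registered among screened
  patients who are neither benign-excised nor melanoma cases.

`exact_counts` mode emits a deterministic cohort hitting requested tallies
exactly (used for round-trip tests); stochastic mode drives a coverage
experiment in which parameter sets rebuilt from 50 replicate synthetic
cohorts yield 95% credibility intervals covering the generating truth at
least 90% of the time.

The generator does **not** emulate lesion-level dynamics, slow-growing
melanoma biology, clinical covariates (age, sex, phototype), or
between-dermatologist variation. A green end-to-end test therefore
establishes that the *pipeline* — aggregation, distribution construction,
propagation — is statistically coherent, not that the observational data
themselves were generated this way.

## Known limitations and honest gaps

Three published figures do not reproduce exactly under any single
reconstructed accounting rule, and the package does not pretend otherwise:

* the observed SDDI follow-up cost of 16,425 implies a non-integer number
  of visits at 52.10; the canonical convention here (inclusion + 3-month +
  12-month visits, registered-cohort denominators) gives 17,609.80, about
  7% higher. Consequently the simulated mean difference per melanoma sits
  near 515–520 rather than the published 548;
* the published Group 1 pathology mean (36,394) is ~220 below the tariff
  arithmetic (36,614.06); the source of the gap is not stated;
* the observed Group 1 total 112,920 versus the model's 113,150.07 (0.2%).

A further numerical note: asserting a 10,000-iteration Monte Carlo mean to
0.1% of its target is tighter than one Monte Carlo standard error of that
mean for the Group 2 excision component, so the test suite pins the
deterministic plug-in value to 0.1% and the Monte Carlo mean to 4 standard
errors.

This is a cost-minimization comparison only: no QALYs, survival modelling,
ICERs or cost-effectiveness acceptability curves, and no currency
conversion or non-Belgian tariff schedules (user-supplied tariff tables
are accepted via the JSON configuration).

## Worked defaults

```{r example, eval = FALSE}
ana <- run_analysis(load_config())        # published defaults, seed 1
summary(ana$result)
tornado_table(ana$importance)
write_report(ana$summary, ana$importance, "report", result = ana$result)
```
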