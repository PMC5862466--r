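---
title: "The SAH decision model: probabilities, thresholds, and what the simulator can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SAH decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahrisk)
```

## The problem

Subarachnoid hemorrhage is a rare, catastrophic cause of a very common
emergency department complaint. The workup hinges on two tests: a
non-contrast head CT whose sensitivity for subarachnoid blood decays as red
cells lyse in the CSF, and a lumbar puncture — invasive, failure-prone in
some patients, and frequently negative. `sahrisk` makes the implicit
decision calculus explicit: how probable is SAH before and after imaging,
and is that probability high enough to justify this patient's LP?

## The probability model

The engine is odds-form Bayes under conditional independence (Naive Bayes).
Writing $O(p) = p/(1-p)$:

$$O(\text{pre}) = O(\text{prevalence}) \times \prod_{i \in \text{findings}} LR_i,
\qquad
O(\text{post}) = O(\text{pre}) \times \prod_{j \in \text{imaging}} LR_j.$$

Clinical findings (the Ottawa SAH rule items: sudden onset, instant-peaking
pain, exertional onset, loss of consciousness, neck pain or limited flexion,
age 40+) update only the pre-test probability; imaging results update only
the post-test probability. Each finding carries an $LR^+ \ge 1 \ge LR^- > 0$
pair; an unanswered question contributes $LR = 1$, so an incomplete form
never biases the estimate. For a test with sensitivity $s$ and specificity
$c$, a positive result applies $s/(1-c)$, a negative one $(1-s)/c$, and a
test not done applies nothing.

Two independence assumptions matter. First, findings are treated as
independent given disease status; correlated findings (sudden onset and
instant peaking surely co-occur) make the pre-test probability overconfident
in both directions. Second, imaging results are treated as independent of
the findings given disease status. Neither is corrected for here; the
registry's per-item likelihood ratios are the place to absorb such
corrections when literature values are adopted.

### Time-dependent CT sensitivity

Non-contrast CT sensitivity is a function of hours $t$ from symptom onset to
scan. Two interchangeable parameterisations ship:

* **decay** (default): $s(t) = s_0 e^{-\lambda t}$ with $s_0 = 0.98$ and
  $\lambda = 0.01\,h^{-1}$;
* **stratified**: half-open bands $[0, 6)$ h at sensitivity 1.00 and
  $[6, \infty)$ at 0.89, with the pooled point value 0.94 retained as the
  test's time-free summary.

The band boundary is half-open on the left — a scan at exactly 6 h uses the
late value — because the early stratum is defined by being *within* six
hours. Under the stratified preset a negative CT before 6 h has $LR^- = 0$
and the posterior collapses to exactly zero; this is a feature of the
published stratum, not a numerical accident, and the gauge labels it "~0"
since a log axis cannot display zero.

CT angiography detects the aneurysm rather than the blood, so its
sensitivity is modelled as time-constant.

## The threshold model

Procedural risk factors carry difficulty weights: difficult body habitus 2,
anti-platelet/anticoagulant use 2 (the habitus value is the model's anchor
— "twice as difficult"; the antithrombotic weight is set at parity as a
config default, not a literature value). The summed difficulty $d$ never
touches the probability of disease; it raises the testing threshold

$$\theta(d) = \min(\theta_0 \cdot k^d,\ 0.99),$$

with base threshold $\theta_0 = 0.01$ and scale $k = 1.5$. The
multiplicative form was chosen over an additive one because the gauge and
the zone logic live on a log-probability axis, where a multiplicative bump
is a constant-width shift; the cap keeps the threshold a probability. All
three constants are config-exposed and marked as model choices in their
provenance strings.

Zones are a multiplicative band of ratio $r = 3$ around the threshold:
green iff $\text{post} \ge \theta r$, red iff $\text{post} \le \theta / r$,
yellow between. Boundary ties go to the decisive zones (green/red), so the
yellow band is open. The case worked in the README sits green at
post-test 3.7% against $\theta r = 3\%$; the same patient with a negative
CT angiogram falls to 0.08%, below $\theta / r = 0.33\%$, hence red. A
positive imaging result does not force the zone green — it sets
`terminal = TRUE`, because the tool's question ("should this negative- or
un-imaged patient get an LP?") is then moot.

Whether the yellow band should widen with difficulty — more room for
judgment when the procedure is riskier — is an open design question; it is
deliberately not implemented, and the band ratio is a single registry
constant.

## Numerical choices

* All odds arithmetic runs in log-odds (`qlogis`/`plogis` scale), so a
  product of large likelihood ratios (a positive CT at specificity 0.999 has
  $LR^+ = 940$) cannot overflow.
* Exact zeros and infinities are short-circuited before the log transform,
  in this precedence: any $LR = 0$ gives posterior 0; a prior of 0 stays 0;
  a prior of 1 or any infinite LR gives 1. A certain rule-out therefore
  dominates a certain rule-in if a config ever produces both.
* The gauge maps probability to angle affinely in $\log_{10} p$ between a
  clamp (default $10^{-4}$) and 1; probabilities below the clamp render at
  the axis start.
* Registry configs round-trip: integer-looking JSON numbers are normalised
  to double at load so that load → serialize → load is the identity.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: latent SAH status at the configured
prevalence; an onset-to-scan time (default log-normal with median 4 h,
`sdlog = 0.75` — a right-skewed arrival pattern typical of ED presentation
delays; the spread is this package's choice); each Ottawa finding from the
sensitivity/specificity pair *implied by its configured likelihood ratios*
via `lr_to_sens_spec()` (`spec = (1 - LR^+)/(LR^- - LR^+)`, rejecting pairs
not realizable as a binary test); and each performed test from the
registry's specificity and time-evaluated sensitivity at that patient's
scan time. The generator is therefore exactly the model the scorer assumes,
which is what makes the self-consistency checks meaningful:

* **calibration**: binned posteriors match observed SAH rates within ~3
  binomial standard errors on a 100,000-patient cohort;
* **parameter recovery**: empirical CT sensitivity among diseased patients
  reproduces the stratified band values (exactly 1.00 before 6 h);
* **falsifiability**: doubling the generator's prevalence against a fixed
  scoring prior produces visible under-prediction, so the calibration test
  can fail.

Passing these shows internal consistency — the Bayes arithmetic, the LR
inversion, and the time models agree with each other. It does **not**
validate the tool on real patients: real findings are correlated, real
prevalence varies by site, real scan-time distributions differ, and the
default per-item likelihood ratios are placeholders (2.0 / 0.5) pending
literature values. Tests are written so that nothing depends on those
placeholder values except the two documented case regressions, which are
re-pinned if the shipped defaults change.

Simulated patients carry no LP risk factors: habitus and medication use are
not generated by disease status and would only shift the threshold, not the
probabilities, so the strategy comparison fixes difficulty at 0.

`compare_strategies()` contrasts "LP for every negative-CT patient" with
"LP only in the green zone", reporting LPs performed, SAHs caught by LP,
and SAHs missed — the simulated analogue of the many-LPs-per-true-positive
problem the tool targets.

## Problem sizes and runtime

The unit suite uses cohorts of 10,000–50,000 (large enough for 3-SE binomial
checks on a 7.5% prevalence) and one 100,000-patient calibration cohort;
oracle-equivalence checks enumerate all $2^4$ finding patterns crossed with
three imaging states against a direct joint-probability computation. The
whole suite runs in a few seconds on one CPU.

## Known limitations

* Per-item Ottawa likelihood ratios, baseline prevalence, and CT
  specificities are config placeholders, flagged in their provenance
  strings; site deployment requires filling them from literature or local
  data.
* No expected-utility calculus: the threshold model is a calibrated
  heuristic, not a decision-theoretic derivation from outcome utilities.
* No CSF/LP result interpretation, no distinction between aneurysmal and
  peri-mesencephalic bleeds, no correlated-findings correction.
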