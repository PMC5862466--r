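# sahrisk

Bayesian risk estimation and lumbar-puncture (LP) decision support for
suspected subarachnoid hemorrhage (SAH) in emergency department headache
patients.

Aneurysmal SAH presents as sudden severe headache, a complaint it shares
with a large population of benign ED headaches. The standard workup is a
non-contrast head CT, followed by an LP to look for red cells or
xanthochromia when the CT is negative but suspicion persists. Modern CT is
nearly perfectly sensitive early after onset, so many of those LPs — an
invasive procedure with real complication rates — find nothing. `sahrisk`
is for clinicians and modellers who want the LP decision made explicit: it
turns bedside findings and imaging results into probabilities, and
probabilities into a recommendation.

## The model

**Pre-test probability** is a Naive Bayes update of the baseline prevalence
by the Ottawa SAH rule findings. With prior odds
`O(SAH) = p / (1 - p)` and conditionally independent findings,

    O(SAH | findings) = O(SAH) * prod_i LR_i

where `LR_i` is `LR+` for a finding present, `LR-` for one absent, and 1
for an unanswered question.

**Post-test probability** multiplies the pre-test odds by the likelihood
ratio of each imaging result, `LR+ = s / (1 - c)` and `LR- = (1 - s) / c`,
and converts back with Bayes' theorem. Non-contrast CT sensitivity is
time-dependent: by default the exponential decay

    s(t) = 0.98 * exp(-0.01 t),   t = hours from symptom onset,

with an alternative time-stratified preset (sensitivity 1.00 before 6 h,
0.89 from 6 h on; pooled point value 0.94). A negative CT inside the
perfectly sensitive stratum drives the posterior to exactly zero. CT
angiography is modelled with a time-stable sensitivity.

**The LP decision** compares the post-test probability with a testing
threshold. Procedural risk factors (difficult body habitus, anti-platelet or
anticoagulant use) carry difficulty weights — habitus weighs 2 — whose sum
never changes the probability of disease but raises the threshold
multiplicatively (`threshold = base * scale^difficulty`). The result is a
three-zone call: **green** (LP indicated), **red** (not indicated), and a
**yellow** band around the threshold where patient preference and physician
judgment decide. The three probabilities are drawn on an SVG gauge with a
logarithmic probability axis.

All parameters — prevalence, test characteristics, per-item likelihood
ratios, weights, thresholds — live in a provenance-annotated JSON registry
(`inst/extdata/registry-default.json`; format in `registry.schema.json`),
never in code.

## Worked example

A patient presents one hour after a thunderclap headache that peaked
instantly, began during exertion, with a syncopal episode; the non-contrast
CT is negative:

```r
library(sahrisk)
pat <- patient_presentation(
  hours_since_onset = 1,
  ottawa_findings = c(sudden_onset = "present", instant_peak = "present",
                      exertion = "present", loc = "present"),
  imaging_results = c(noncontrast_ct = "negative")
)
sah_assess(pat, default_registry())
#> SAH probability estimate
#>   pre-test:  56.5%
#>   post-test: 3.72%
#>   LP threshold: 1% (difficulty 0)
#>   applied LRs:
#>     noncontrast_ct negative: LR 0.02978
#> LP recommendation: zone GREEN
#>   Pre-test probability 56.5%; applied: noncontrast_ct negative (LR 0.02978);
#>   post-test probability 3.72%. LP difficulty 0 raises the testing threshold
#>   to 1%. Zone GREEN: lumbar puncture indicated.
```

The four positive rule findings push the prior (7.5%) to a 56.5% pre-test
probability; the negative CT at one hour (LR 0.0298) pulls it down to 3.7%,
still above the green boundary (threshold 1% x band ratio 3), so LP is
indicated. Adding a negative CT angiogram drops the posterior to ~0.08% and
the zone to red.

The same scoring is available from a shell via `exec/sahrisk`:

```sh
Rscript exec/sahrisk score --hours 1 --finding sudden_onset --finding loc \
    --ct negative --svg gauge.svg
Rscript exec/sahrisk simulate --n 50000 --prevalence 0.075 --seed 7 --out cohort.csv
Rscript exec/sahrisk validate --registry my-registry.json
```

`simulate` generates a ground-truth cohort (findings and CT results drawn
from exactly the registry's parameters), prints a posterior-bin calibration
table, and compares LP strategies: LP for every negative-CT patient versus
LP only in the green zone.

## Not in scope

CSF laboratory interpretation (cell counts, xanthochromia), the
peri-mesencephalic versus aneurysmal bleed distinction, external-cohort
validation, and any EHR/web front end.
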