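---
title: "Detecting DRG up-coding with a continuous-response Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DRG up-coding with a continuous-response Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschDRG)
```

## The problem

Under diagnosis-related-group (DRG) reimbursement, inpatient cases with
similar clinical characteristics and resource consumption are bundled and
paid at a common rate. A hospital can *up-code*: claim fee items, or fee
amounts, beyond what the case's true resource use warrants. The insurer
audits claims and *deducts* unjustified items; predicting which items an
audit would deduct — before submission — is the task this package addresses,
for hospital billing and audit teams.

The premise is psychometric. Within one DRG, claims share a fee structure:
a case of a given overall expensiveness should spend predictably across the
fee items. Treating fee items as test items and cases as examinees, a
one-parameter (Rasch) item-response model calibrated on a *norm group* of
clean, undeducted claims defines that expectation, and an item whose claimed
fee sits far above its expectation — a large standardized residual — is a
probable deduction.

## The model

Each raw fee for case $n$ on item $i$ is first min–max normalised onto the
unit interval using bounds taken from the norm group of the same DRG:
$O_{ni} = (\mathrm{fee} - \min_i)/(\max_i - \min_i)$, clamped to
$[\varepsilon, 1-\varepsilon]$. A fee of zero (or an absent row) means the
item was not claimed and is treated as missing: it never enters bounds,
calibration, or residuals.

The expected normalised fee follows the logistic form
$$E_{ni} = \frac{e^{\theta_n - \delta_i}}{1 + e^{\theta_n - \delta_i}},$$
where $\theta_n$ is the case's overall fee level (*ability*, logits) and
$\delta_i$ the item's *difficulty* — high $\delta$ marks an item that is
systematically small or rare within the DRG. Cell variance takes the
Bernoulli form $Var_{ni} = E_{ni}(1 - E_{ni})$, and the standardized
residual is
$$Z_{ni} = \frac{O_{ni} - E_{ni}}{\sqrt{E_{ni}(1-E_{ni})}}.$$
An item with $Z > 2$ (roughly the two-sided 5% normal criterion, rounded up
for small samples) is flagged as a probable deduction; the per-case outfit
mean-square, $\frac1k\sum_i Z_{ni}^2$, summarises overall aberrance but is
reported only, never used for flagging. Observations are continuous in
$(0,1)$ rather than binary; the score and variance equations above are taken
literally, which amounts to a quasi-binomial reading of the dichotomous
Rasch form.

### Estimation

*Calibration* (per DRG, on the norm group) is joint maximum likelihood:
alternate (a) Newton–Raphson ability updates
$\theta \leftarrow \theta + \sum_i(O_i - E_i)/\sum_i Var_i$ for every case,
(b) one mirrored Newton step per item,
$\delta_i \leftarrow \delta_i - \sum_n (O_{ni}-E_{ni})/\sum_n Var_{ni}$,
and (c) re-centring $\delta$ to mean zero — the identifiability constraint,
since only $\theta - \delta$ is determined. Sweeps stop when the largest
parameter change falls below `tol`. Standard errors are the usual
information-based $1/\sqrt{\sum Var}$.

*Scoring* a new case estimates $\theta$ from the case's observed items only,
ignoring missing (zero-fee) items — no adaptive item selection, just
estimation on the available responses. The multi-item Newton step sums
numerator and denominator over observed items; with a single item it reduces
to the single-cell update, whose fixed point is the closed form
$\theta = \delta + \mathrm{logit}(O)$. Ability is estimated from *all*
observed items, including a potentially up-coded one: the contamination this
induces is mild (one item among many shifts $\theta$ only slightly) and
matches how the method is used in practice, where the up-coded item is
unknown.

### Numerical choices

* **Clamp $\varepsilon = 0.005$.** The raw min–max map attains exactly 0
  and 1 at the norm extremes, where the logistic likelihood degenerates (a
  single boundary item would push $\theta$ to $\pm\infty$). A symmetric
  clamp — the standard extreme-score adjustment in Rasch practice — keeps
  every estimate finite. Configurable.
* **Step cap of 1 logit per Newton iteration, start at 0.** The logistic
  score function is flat in the tails; uncapped steps can overshoot from
  poor starts. The cap trades a few extra iterations for global stability.
* **Convergence `tol = 1e-4`, `max_iter = 100`**, both recorded in the
  model object. Non-convergence warns and returns the last state with a
  report, rather than failing.
* **Bounds from the norm group only.** The norm group is the reference
  standard; experimental fees outside its range are clamped. (Pooling both
  groups for bounds is defensible but would let the cases under scrutiny
  move their own yardstick.)
* **Degenerate items** (all norm fees equal) and never-observed items are
  excluded at the bounds stage with an explicit record, so calibration never
  sees a zero-variance column; a disconnected item–case pattern is an error
  naming the item.
* **Strict inequality at the flag threshold** ($Z > 2$, not $\ge$): ties
  are measure-zero but the convention is fixed. Flagging defaults to the
  upper side — the up-coding direction — with a two-sided option for
  dashboard reporting of items *below* expectation.

## The synthetic-data generator

Real claims with audit labels cannot be shipped, so every stage is exercised
on generated data with known truth. The generator emulates the structure of
the study conditions the method was built for: per DRG, a norm group of 300
clean cases and an experimental group of 194 audited cases on a 17-item fee
schema, about 10% missing cells, and each audited case carrying at least one
up-coded item.

Difficulties and abilities are drawn from standard normals (SD 1 logit, a
typical calibrated spread). Each cell's normalised fee is drawn from a Beta
distribution with mean $E(\theta_n, \delta_i)$ and precision $m = 9$
(variance $E(1-E)/(1+m)$), then mapped linearly to currency. The Beta family
respects the $(0,1)$ support the normalisation imposes; note its variance is
*smaller* than the model's nominal $E(1-E)$ by the factor $1+m$. This
mismatch is intentional and matters for interpretation: standardized
residuals on such data are under-dispersed, so under the null the $Z > 2$
flag rate sits far below the nominal 2.5% — tests assert conservative
bounds, not nominal calibration. Up-coding is injected on the normalised
scale, $x' = \min(1-\varepsilon,\ x + \Delta)$ with $\Delta = 0.4$ on one
item per case by default, keeping the effect size comparable across items;
the injected cells are exported as the `deducted` audit labels. Four
independent RNG substreams (parameters, noise, missingness, injection)
derive from the master seed, so toggling injection leaves the base data
byte-identical.

What the generator does **not** imitate: real fee distributions (heavy
tails, spikes at tariff prices), DRG case-mix, correlated missingness, or
auditors' behaviour (labels here are exactly the injected cells; real
deductions are noisy and partly driven by documentation, not fees). Passing
tests on this data shows the estimator and detector are correct and powerful
under the model's own assumptions — not that the 0.82 field accuracy would
reproduce at another hospital.

## Evaluation

Flags are compared with audit labels two ways, selectable in `accuracyTable()`:
**matched** (correct iff a genuinely deducted item was flagged — the stricter
reading) and **any** (correct iff the case was flagged at all). Matched-mode
cases without any deducted item are "not evaluable" and are excluded with a
count. Category tables score agreement of *any flag* vs *any deduction*
within drug, material and examination fees. Chi-square homogeneity tests
across years use the uncorrected Pearson statistic: on the benchmark audit
counts the uncorrected form reproduces the published p = 0.19, while the
Yates-corrected form gives ≈ 0.24, which pins the choice. ROC analysis uses
the Mann–Whitney AUC (case-level per category: max $Z$ over the category's
items vs any deduction in the category; or item-level over all cells), with
the Hanley–McNeil standard error for the test against the chance value 0.5 —
no DeLong machinery, since no two AUCs are compared.

One benchmark discrepancy is documented rather than chased: the published
examination-category p-value prints 0.50 where the uncorrected statistic on
the printed counts gives 0.494; we assert the computed 0.49 and treat the
difference as rounding.

## Problem sizes used in the shipped checks

The test suite calibrates 300 × 17 matrices (the default study size) for
difficulty recovery across 5 seeds, verifies ability estimation against a
bisection oracle on 200+ randomized instances, and runs the
detection-power sweep at shifts $\Delta \in \{0.1, 0.25, 0.4\}$ over 5
replicates; unit tests use smaller 60 × 8 sets. These sizes give stable
stochastic checks (recovery correlations ≥ 0.95, item-level detection AUC ≈
0.96 at the default shift) while keeping the full suite around a minute.

## Known limitations

* JMLE difficulty estimates carry the usual small-sample bias; with 300
  cases and 17 items it is negligible against the SE, and no bias correction
  is applied.
* One model per DRG: no partial pooling across DRGs, no covariates.
* The detector sees only fee amounts. Up-coding that preserves an item's
  normalised fee profile (e.g. inflating all items proportionally) moves
  $\theta$, not the residuals, and is invisible by design.
* Binary flags ignore magnitude above threshold; the dashboard payload
  exposes raw $Z$ for human judgement.
* No infit statistic, inter-item residual correlations, DIF analysis, or
  two/three-parameter and polytomous IRT models.
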