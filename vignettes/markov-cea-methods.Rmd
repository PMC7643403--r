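---
title: "Methods: a BPV-driven Markov cost-utility model for hypertension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a BPV-driven Markov cost-utility model for hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpvcea)
```

## The decision problem

Hypertension control is increasingly judged not only by mean blood pressure
but by blood-pressure *variability* (BPV): the visit-to-visit and ambulatory
scatter of systolic pressure, summarized by its standard deviation (SD, mmHg)
and coefficient of variation (CV). Higher nocturnal BPV predicts stroke and
myocardial infarction (MI) beyond mean pressure. `bpvcea` implements a
cost-utility model that translates a treatment's effect on nocturnal BPV into
long-run stroke/MI risk, costs and quality-adjusted life years (QALYs), and
compares two strategies for primary hypertension: nifedipine sustained-release
tablets alone versus nifedipine combined with compound Apocynum tablets, a
traditional Chinese medicine with a documented additional BPV reduction.

## Model structure

The model is a six-state Markov cohort chain with annual cycles:

* `well` — alive without stroke or MI (every patient starts here);
* `stroke` / `mi` — the acute event year; recurrence (`stroke -> stroke`,
  `mi -> mi`) re-incurs the acute state and its cost;
* `post_stroke` / `post_mi` — chronic sequelae after the acute year;
* `dead` — absorbing, with utility 0 and cost 0.

Transitions cross between the stroke and MI families only through `well` or
`dead`; structurally impossible moves are exactly zero and every row of the
transition matrix is closed by its residual (`well -> well`,
`stroke -> post_stroke`, `mi -> post_mi`, post-state self-loops). The base
case runs 20 cycles at a 5% annual discount rate, and there is no background
(non-event) mortality: death is reached only through the stroke and MI
pathways, which the structure of the source estimates dictates. Baseline age
(67.5 years) is recorded with the parameters but enters no equation, since
no transition is age-dependent.

## From event rates to transition probabilities

Estimates reported over a horizon of $T$ years are converted to a per-cycle
probability of cycle length $t$ by the constant-risk relation

$$ tP = 1 - (1 - P)^{t/T}, $$

implemented in `annualize_probability()`. Composing the per-cycle probability
back over $T$ cycles recovers $P$ exactly, which the test suite checks to
$10^{-12}$.

The well-state incidences are where BPV enters. For each arm the annual
incidence of stroke (and analogously MI) is the annualized baseline incidence
minus the achieved BPV reduction times the incidence increment per unit of
the index:

$$ p_{\text{arm}} = \max\!\big(0,\; p_{\text{base}} -
   \Delta_{\text{index}} \times \text{increment}\big). $$

The stroke pathway uses the reduction in the SD of nocturnal systolic
pressure (mmHg; 1.87 for nifedipine, 2.99 for the combination) with an
increment of 0.0032 per mmHg applied to a 5.5-year baseline stroke rate of
5.69%; the MI pathway uses the reduction in CV (0 and 0.01) against a
5.5-year baseline of 1.09%. An absolute-additive reading of this derivation
— subtraction on the annualized probability scale, baseline annualized
*before* subtracting — is the only one that reproduces the per-arm stroke
incidences to their reported precision (0.461% vs 0.460% for nifedipine;
0.103% vs 0.102% for the combination, both within one unit of the last
digit), even though BPV–risk relationships are usually described as relative
risks; the package follows the arithmetic that the fixture values embody.
One caveat is documented rather than hidden: the combined arm's MI incidence
in the fixture (0.193% per year) is not exactly the additive derivation's
0.191%, because the reported increment per unit CV cannot be reconciled with
any stated formula. The default (`sample_mode = "direct"`) therefore treats
the four per-arm incidences as primary inputs; `mode = "derived"` re-derives
them from the BPV effects when that chain of logic is wanted explicitly.

## Rewards, discounting and cycle conventions

Cycle $k$ rewards are discounted by $(1+r)^{-(k-1)}$ — the first cycle is
undiscounted. Cycle cost is the occupancy-weighted sum of annual state costs
plus the annual drug cost over the alive mass; cycle QALYs are the
occupancy-weighted utilities. Two conventions are genuinely open in any
cohort model and are explicit switches here:

* **Reward timing** (`reward_timing`): which occupancy a cycle's rewards are
  credited to. The default is `"start"` — the state occupied at the
  beginning of the cycle, the convention of the decision-tree software this
  class of model is usually built in, under which the engine reproduces its
  reference base case within about 1% on costs and 0.1% on QALYs. `"end"`
  and `"half"` (half-cycle correction) are provided; with the default
  parameters they move the nifedipine arm's 20-year cost from \$1085 to
  \$1132 and \$1178 respectively, so the choice is material and worth
  stating in any report.
* **Drug-cost accrual** (`drug_cost_states`): antihypertensive cost accrues
  in all alive states by default (patients stay on treatment after events);
  `"well_only"` restricts it to the event-free state.

No other half-cycle or continuity corrections are applied.

## Parameters and uncertainty

All parameters live in one flat table (name, base, low, high, family,
horizon) shipped as `inst/extdata/hypertension_bpv_params.yaml` and
reproducible from code via `paper_default_bundle()`; YAML, JSON and CSV
readers share one validator that rejects unknown names and bound violations.
Ranges are base ±10% unless the source reports otherwise (the well-state
utility is capped at 1; the stroke increment and the MI-family incidences
carry their own reported intervals; the discount rate is varied over 1–8%
in one-way analysis only). The post-MI annual cost is stored as 2041.84
USD: its reported range 1837.66–2246.03 back-solves to exactly that base
under ±10%, identifying the printed five-digit figure as a typo. The model
computes in USD; RMB outputs use a fixed conversion constant (6.62 RMB/USD,
back-solved from the paired cost figures in the source material, and
configurable).

For probabilistic sensitivity analysis each range is treated as a 95%
interval, $\sigma = (\text{high}-\text{low})/(2 \times 1.96)$ — the standard
convention when only ranges are reported — and distributions are fitted by
the method of moments with the mean pinned at the base value: Gamma for
costs ($k = \mu^2/\sigma^2$, $\theta = \sigma^2/\mu$), Beta for utilities
and probabilities ($\nu = \mu(1-\mu)/\sigma^2 - 1$, $\alpha = \mu\nu$,
$\beta = (1-\mu)\nu$). Probabilities are sampled on their native multi-year
scale and annualized inside the model. Parameters are drawn independently —
no correlation structure is asserted because none is reported — and each
draw re-closes the matrix rows by residual; draws implying state exits above
1 are rejected, redrawn and counted (none occur under the default ranges).
This range-to-sd rule is the single knob controlling PSA spread. Under it
the incremental net monetary benefit at the WTP threshold of \$9764.95 has a
mean near \$1200 and a standard deviation near \$230, so the acceptability
probability at the threshold is essentially 1: the ±10% ranges are simply
too narrow for meaningful decision uncertainty at that threshold. A smaller
reported probability would imply substantially wider parameter uncertainty
than the recorded ranges; reproducing such a figure would require an
undocumented parameterization, which the package deliberately does not
invent.

The one-way analysis perturbs each cost, utility and transition probability
by ±10% of its base (clamping utilities and probabilities at their legal
bounds and flagging the clamp), reruns the full two-arm model at each bound,
and sorts parameters by ICER spread. The discount rate is varied over its
own 1–8% range. With default inputs the dominant parameters are the
nifedipine arm's stroke incidence, the combination's drug cost, the
well-state utility and the two MI incidences.

## Validation design

Two independent routes compute the same quantities:

* the **cohort engine** (`run_cohort()`) propagates occupancy fractions
  exactly;
* the **microsimulation oracle** (`microsimulate()`) simulates individual
  patient trajectories and accrues per-patient discounted rewards under the
  same public conventions, sharing no implementation with the engine.

The suite requires engine totals within 3 Monte-Carlo standard errors of the
oracle at 200,000 patients across 20 randomly generated models (plus the
default model in the validation script), empirical occupancy converging to
the cohort trace, exact agreement on deterministic (0/1) chains, mass
conservation and monotone absorption on over 100 random models, and the
analytic limits: a no-event cohort accrues the closed-form discounted
annuity $u \sum_k (1+r)^{-k}$, and $r = 0$ reproduces plain undiscounted
sums. The synthetic-model generator (`generate_random_model()`) draws
row-stochastic matrices with one absorbing state, strictly positive death
reachability, and configurable sparsity; it exists for these property tests,
and deliberately does not emulate features of real cohorts (age dependence,
correlated parameters, semi-Markov sojourn times), so passing them
demonstrates engine correctness, not clinical realism.

## Problem sizes

The shipped analyses use the model's natural sizes: 20 annual cycles, 5000
PSA iterations (binomial SE below 0.7 percentage points on the acceptability
probability), 200,000 microsimulated patients for the engine check, and
50,000 draws for distribution-fit recovery. All are set in the analysis
scripts and can be raised freely.

## Known limitations

* No background mortality, age dependence, or tunnel states; the 20-year
  horizon partially masks the former's absence but survivors at 20 years are
  certainly overstated.
* The BPV-to-risk derivation is linear and additive with effects assumed
  constant over 20 years from a 4-week trial — the strongest assumption in
  the model.
* Kidney damage, a documented BPV target-organ relationship, is excluded for
  lack of quantitative estimates.
* Two-strategy comparison only; no efficiency frontier, EVPI, or correlated
  sampling.
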