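# bpvcea

Markov cohort cost-utility analysis of antihypertensive therapy driven by
blood-pressure variability (BPV).

## What it is for

Antihypertensive drugs differ not only in how far they lower blood pressure
but in how much they stabilize it. The standard deviation (SD) and
coefficient of variation (CV) of nocturnal systolic blood pressure predict
stroke and myocardial infarction (MI), so a treatment's BPV effect can be
translated into long-run event risk — and from there into costs and
quality-adjusted life years (QALYs). `bpvcea` is for health-economics
analysts who want that translation as a tested, scriptable model rather
than a spreadsheet: it compares nifedipine sustained-release tablets alone
against nifedipine combined with compound Apocynum tablets (a traditional
Chinese medicine with an additional BPV effect) for primary hypertension,
and exposes every piece — parameter handling, the cohort engine, CEA
metrics, sensitivity analysis, and an independent microsimulation check —
as reusable functions.

## The model

Six health states — alive without stroke/MI, stroke, post-stroke, MI,
post-MI, dead (absorbing, utility and cost 0) — with annual cycles over a
20-year horizon and 5% annual discounting of both costs and QALYs.
Multi-year event rates are converted to per-cycle probabilities by

    tP = 1 − (1 − P)^(t/T)

and each arm's annual well→stroke and well→MI incidences follow from its
BPV effect:

    p_arm = max(0, p_baseline_annual − Δindex × increment_per_unit)

with Δ SD (mmHg) driving stroke and Δ CV driving MI. Strategies are
compared by incremental cost-effectiveness ratio ICER = ΔC/ΔE against a
willingness-to-pay (WTP) threshold of one GDP per capita ($9764.95/QALY),
and by net monetary benefit NMB = WTP × ΔE − ΔC. Probabilistic sensitivity
analysis draws costs from Gamma and utilities/probabilities from Beta
distributions fitted by method of moments from the base values and ranges
(ranges treated as 95% intervals), yielding a cost-effectiveness
acceptability curve (CEAC). See the methods vignette
(`vignettes/markov-cea-methods.Rmd`) for conventions and assumptions.

## Worked example

```r
library(bpvcea)

bundle <- paper_default_bundle()          # or load_parameters("params.yaml")
base_case_table(bundle)[, 1:6]
#>     strategy cost_usd  cost_rmb    qalys       cer    icer
#> 1   combined 1758.438 11640.859 12.68408 138.63343 3507.81
#> 2 nifedipine 1085.271  7184.495 12.49218  86.87606      NA
```

Over 20 years the combination costs $1758.44 per patient and yields
12.684 QALYs versus $1085.27 and 12.492 for nifedipine alone: $673.17 more
buys 0.192 extra QALYs, an ICER of $3508 per QALY — well under the $9765
threshold, so the combination is cost-effective. One-way sensitivity:

```r
head(one_way_sensitivity(bundle), 3)[, c("parameter", "spread")]
#>                  parameter   spread
#> 1            discount_rate 1493.896
#> 2 p_well_stroke_nifedipine 1470.186
#> 3       drug_cost_combined 1387.619
```

and the PSA:

```r
run_psa(bundle, n_iterations = 5000, seed = 20201105)
#> <psa_result> 5000 iterations (seed 20201105, mode direct, 0 rejected draws)
#>   mean dC 673.47 USD, mean dE 0.1919 QALYs
#>   P(cost-effective at WTP 9764.95) = 1.000 (95% CI 0.999-1.000)
```

The ready-made analyses live in `analysis/01_base_case.R` …
`analysis/04_validation.R`; each prints what it finds and writes its tables
under `results/`.

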