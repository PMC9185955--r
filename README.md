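# nhecon

Health-economic evaluation of nurse-led care models in nursing homes, from
the nursing-home perspective.

## The problem

Long-term care facilities that introduce a nurse-led care model to reduce
resident hospitalisations face three economic questions that routine
accounting does not answer:

1. **What did the implementation cost?** Meetings, training, phone coaching,
   internal coordination, travel and material — priced by time-driven
   activity-based costing (TDABC): each action costs
   `frequency × duration × participants × wage` plus non-personnel
   resources, aggregated per licensed bed so homes of different size are
   comparable.
2. **What does the intervention itself cost?** The expanded-role nurse is
   the only element with a marginal price: the yearly salary cost per bed,
   with nurse density (headcount and FTE per 100 beds) and mean employment
   fraction as the staffing descriptives.
3. **Is it worth it?** With usual care as the zero-cost comparator and a 0%
   discount, the incremental cost-effectiveness ratio is

   ```
   ICER = mean salary rate / (pre rate − intervention rate)
   ```

   where both rates are per nursing-home per month, normalised per 1'000
   nursing days: the hospitalisation rate
   `hospitalisations / nursing days × 1000` and the salary rate
   `nurse salary cost / nursing days × 1000`. The result is CHF per avoided
   hospitalisation, classified on the cost-effectiveness plane
   (more-costly-but-more-effective, dominant, dominated, ...).

The package also quantifies what a hospitalisation costs the home itself:
during a resident's absence (arrival and departure days excluded) the home
loses nursing-tariff revenue — valued at the simple mean of the 12 Swiss
case-mix levels — and, depending on its billing regime, part of the hotel
revenue. Three regimes are modelled: (A) everything lost but a reservation
fee levied, (B) hotel revenue continues, (C) the resident's nursing share
continues for the first four absence days, after which a daily refund is
returned. Cost savings during absences are held at zero (all service costs
fixed), matching survey evidence.

Robustness is assessed by one-way deterministic sensitivity analysis:
nursing days and hospitalisation counts varied ±20%, salary and
hospitalisation rates over their sample ranges, rendered as an
ISPOR-style tornado diagram with the widest bar on top and a vertical line
at the base-case ICER.

Because facility ledgers of this kind are confidential, the package ships a
seeded generator ([`generate_ledger()`]) that stages the whole world — a
stepped-wedge rollout (1–2 homes starting per month), Poisson
hospitalisation counts falling from 1.27 to 1.14 per 1'000 nursing days,
salaries, process maps and price schedules — so every stage of the pipeline
is testable end to end.

## Worked example

```r
library(nhecon)

led <- generate_ledger(generator_config(seed = 42))
led
#> <nh_ledger>
#>   units:       7 (beds 71-118)
#>   census:      266 unit-months
#>   process map: 84 entries
#>   salaries:    10 spells
#>   prices:      28 schedules
#>   episodes:    884

run_cea(led)$result
#> Cost-effectiveness against usual care (zero comparator cost)
#>   incremental cost:      2965.85 CHF per 1'000 nursing days
#>   incremental effect:     0.2235 avoided hospitalisations per 1'000 nursing days
#>   ICER: 13268.5 CHF per avoided hospitalisation
#>   plane quadrant: more_costly_more_effective
```

The intervention added about 2'966 CHF of nurse-salary cost per 1'000
nursing days while the hospitalisation rate fell by 0.22 per 1'000 nursing
days in this simulated draw, i.e. roughly 13'300 CHF per avoided
hospitalisation. (A single simulated trial is noisy: the generator's
long-run effect is 1.27 − 1.14 = 0.13, giving an expected ICER near
22'600 CHF.) The deterministic check on the published summary inputs:

```r
icer(2937, 1.27, 1.14)$icer
#> [1] 22592.31
```

One-way sensitivity, widest bar first — the hospitalisation-rate and salary
parameters drive the uncertainty while a uniform nursing-day change cancels
out exactly:

```r
run_sensitivity(led)$rows[, c("parameter", "icer_low", "icer_high", "bar_length")]
#>            parameter icer_low icer_high bar_length
#> 3        salary_rate  7131.13  22413.84   15282.71
#> 2 n_hospitalisations 16585.62  11057.08    5528.54
#> 4           pre_rate -2771.67   1169.27    3940.95
#> 5          post_rate  2292.74  -1577.57    3870.31
#> 1       nursing_days 13268.50  13268.50       0.00
```

Negative ICER ends mark dominated scenarios (the rate reduction reverses).
`render_tornado(rows, base_icer, "tornado.svg")` draws the diagram.

A file-based workflow is available through the CLI
(`inst/cli/nhecon`): `simulate`, `validate`, `cost-implementation`,
`cost-intervention`, `revenue-loss`, `cea`, `sensitivity`, `report`.

## Vignette

`vignettes/nursing-home-cea.Rmd` documents the model and its assumptions,
the generator's calibration (including why salaries are rescaled to match
the published cost intensity), numerical conventions and known limitations.
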