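---
title: "Methods: costing and cost-effectiveness of a nurse-led care model in nursing homes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing and cost-effectiveness of a nurse-led care model in nursing homes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhecon)
```

# The evaluation model

`nhecon` evaluates, from the nursing-home (NH) perspective, the economics of
introducing a nurse-led care model intended to reduce resident
hospitalisations. Four quantities are computed, each by its own module, all
from one tabular "ledger" of the study:

1. **Implementation cost and time per bed** by time-driven activity-based
   costing (TDABC). Every implementation action — preparatory leadership
   meetings, an all-homes meeting, recurring leadership meetings, the nurse
   training curriculum, coaching phone calls, internal training,
   administration, internal coordination, travel, material — is one
   process-map entry priced as
   $\text{frequency} \times \text{duration} \times \text{participants}
   \times \text{wage} + \text{non-personnel cost}$,
   and timed as the same product without the wage. Entries flagged
   `per_participant = FALSE` (fixed-length offered sessions) skip the
   participant multiplier. Material rows carry cost but no time (flagged not
   applicable). Aggregation divides category sums by licensed beds; totals
   equal the category sums exactly — this conservation is tested against a
   published seven-home reference table shipped in
   `inst/extdata/reference_costing_7nh.csv`. Research-team expenditures are
   excluded by construction: the ledger only ever contains NH-side entries.

2. **Intervention cost** — the expanded-role nurse's salary, the one core
   element with a marginal price. `annual_gross` is defined as the full
   yearly amount *including* the 13th monthly payment, so a month costs
   `annual_gross × employment_fraction / 12` and a full year costs exactly
   the annual amount. Bonuses and mid-spell raises are excluded; a pay
   change closes one spell and opens another. The per-bed-year figure
   divides by *licensed* beds (occupied-bed denominators would entangle the
   occupancy assumption); densities are reported as headcount and FTE per
   100 beds, with a warning below the study staffing minimum of 0.6 FTE per
   80 beds.

3. **Revenue loss per hospitalisation.** During a resident's absence
   (arrival and departure days excluded) the home loses the nursing-tariff
   revenue, valued at the simple mean of the 12 case-mix levels (each level
   adds 20 min of daily care; resident-specific case mix is deliberately
   not used), and — depending on the billing regime — some hotel revenue:

   | regime | retained (fixed) on a given absence day |
   |---|---|
   | A | reservation fee only |
   | B | hotel revenue |
   | C, days 1–4 | hotel + resident's nursing share |
   | C, day ≥ 5 | hotel − daily refund |

   On every day and regime `variable_loss + fixed_revenue` equals the full
   daily revenue (hotel + mean nursing) — an exact conservation identity in
   the code and tests. Savings are identically zero (all service costs are
   treated as fixed), following the survey evidence of negligible savings.
   Two conventions were genuinely open and are fixed here: regime C's "first
   four days" counts *absence* days, not hospital-stay days; and from day 5
   the resident's nursing share stops *and* the refund is paid (its
   alternative reading — share continues — contradicts the day-4 boundary
   arithmetic the model must reproduce). Episodes are priced with the
   admission year's schedule and attributed to the admission month.

4. **Cost-effectiveness.** Rates are formed per NH per month:
   hospitalisations (overnight stays only) and nurse salary cost, each per
   1'000 nursing days. The comparator is usual care at zero cost, so the
   incremental cost is the mean salary rate over intervention NH-months and
   the incremental effect is the fall in the mean hospitalisation rate from
   the pre window (every census month before the unit's transition month,
   including the pre-study routine months) to the intervention window. The
   transition month is excluded from both windows by default
   (`include_transition` pools it into the intervention). Summaries are
   unweighted over NH-month rows; a nursing-day-weighted mode exists but is
   not the default, because the rate definitions are already indexed per NH
   per month. Discounting is fixed at 0% (`cea_discount_rate()`), costs and
   effects falling in the same year. A non-positive effect with positive
   cost is flagged (dominated quadrant, negative ICER carried through; an
   exactly-zero effect raises the explicit infinite-ICER flag) rather than
   silently returned.

# Sensitivity analysis

The one-way analysis perturbs one base-case variable at a time: nursing
days and hospitalisation counts by ±20% (the pragmatic convention where a
sample range is not suitable), the salary rate and the pre/post
hospitalisation rates over the observed per-NH-month sample range of the
ledger (their population endpoints are not otherwise available). Results
are tornado rows ordered by descending bar length, ties broken
alphabetically; dominated ends are plotted at their negative values, not
truncated.

A numerical point worth documenting: a common factor $f$ on *all* nursing
days multiplies both rates and the salary rate by $1/f$, which cancels from
the ICER — algebraically the bar is exactly null. Recomputing the scaled
panel in floating point would leave ~$10^{-12}$ residues, so `one_way()`
propagates relative perturbations of nursing days and hospitalisation
counts through the ICER *symbolically* (the factor is cancelled before
evaluation; counts scale the effect, so the ICER becomes `base / f`
exactly). This is exact arithmetic, not tuning, and it is why the
nursing-days bar has length 0 by construction. Range-mode perturbations
replace the summary value with the endpoint and re-evaluate `icer()`
numerically.

# The synthetic world

`generate_ledger()` stages the study the analysis assumes, so that every
pipeline stage is testable without confidential facility data:

* **Rollout.** Seven analytic units (a jointly managed multi-site group is
  one unit with pooled beds) of 60–120 beds start sequentially, 1–2 per
  month from September 2018; each has a 2-month preparatory period, exactly
  3 baseline months, a 1-month transition and an intervention running to a
  common trial end (February 2020), giving 12–17 intervention months.
  Census data start in January 2017 — at least 17 routine months before
  baseline — and form the comparator window.
* **Counts.** Monthly nursing days are `beds × days-in-month × occupancy`
  (occupancy 0.95, constant per unit — the source is silent, and Swiss
  long-term-care occupancy is high). Hospitalisation counts are Poisson
  with mean `rate × days / 1000`: the minimal distribution consistent with
  a rate per 1'000 nursing days. The transition month already draws at the
  intervention rate (implementation has begun there); this is configurable.
  A negative-binomial dispersion hook and a between-unit rate jitter exist
  but are off by default. The published rate SDs (±1.07, ±0.93) conflate
  between-unit and between-month variation; the generator does not claim to
  match them — with the default Poisson world the per-month SD is ≈ 0.7.
* **Episodes.** Each counted hospitalisation gets an admission day uniform
  in its month and a length of stay of `1 + Poisson(6)` nights (mean 7, a
  realistic acute-stay length for this population); only the derived
  absence days matter economically.
* **Salaries and the calibration.** Per unit, a headcount is drawn from the
  density range (0.8–2.0 per 100 beds), employment fractions from 40–100%
  and raw salaries uniformly from the published starting range
  (68'738–97'500 CHF). These stated descriptives are, however, mutually
  inconsistent with the published mean cost intensity of 2'937 CHF per
  1'000 nursing days under 95% occupancy (they imply ≈ 2'400–2'600). Since
  the build contract prescribes calibrating the salary side to the cost
  intensity, the generator rescales all drawn annual salaries by one global
  factor so that the ledger-wide expected salary rate equals
  `salary_rate_target` (default 2'937; set `NULL` to disable). The
  consequence — individual ledger salaries can exceed the printed starting
  range — is accepted and documented rather than hidden. `draw_salary()`
  itself always samples the printed range.
* **Prices.** Hotel tariffs 150–200 CHF/day, nursing level tariffs linear
  in the 12 case-mix levels (base 30–50, slope 14–18 CHF/level, mean ≈ 144
  CHF/day) with a small yearly increase; regimes assigned A : B : C with
  probabilities 1 : 4 : 2 so that on average one unit in seven loses hotel
  revenue, reproducing the reported ≈ 11% mean hotel-revenue loss and a
  pooled daily loss near 160 CHF (≈ 50% of daily revenue). These pooled
  magnitudes are checked as broad brackets, not point targets.
* **Determinism.** One integer seed drives *named substreams* (schedule,
  census, episodes, salaries, process map, prices), so adding or resizing
  one table never perturbs the draws of another; two calls with the same
  configuration are `identical()`.

What a green test does — and does not — establish: the generator recovers
its own rates within Monte-Carlo error and reproduces the published
base-case ICER within the stochastic tolerance, which validates the
pipeline's arithmetic end to end. It does not validate the world against
real facilities: there is no seasonality, no resident-level case mix, no
correlation between staffing and effect, and the between-unit variance
components are stylised.

# Numerical conventions

* Months are the atomic time unit (ISO `"YYYY-MM"`, integer serial
  arithmetic underneath); dates matter only inside episode bookkeeping.
* CHF amounts are held unrounded; presentation rounding is two decimals,
  half away from zero (`round_half_up()`), applied only in reports. The
  published per-bed table is compared at its printed 2-decimal precision.
* Ledger files serialise doubles at `%.17g`, so a write–read cycle is
  exactly lossless; column types are normalised in the constructor so a
  ledger assembled in code and one read from disk compare `identical()`.
* Degenerate inputs fail loudly where a statistic would be meaningless
  (zero nursing days in a rate, zero beds, an empty summary window, a
  zero-total category share) and return flagged values where the quantity
  is well-defined but extreme (infinite ICER, dominated ends, `NA` loss
  shares for units without absence days).

# Known limitations

* The published headline means (685 CHF and 9.35 h per bed, the 78%/73%
  category shares, 939 CHF per bed-year, the 52% pooled loss, the 31'300
  CHF upper salary-rate ICER) rest on unpublished weightings or inputs and
  are therefore *not* asserted anywhere; the corresponding machinery is
  covered by exact conservation and property tests instead.
* No probabilistic sensitivity analysis, no QALYs or willingness-to-pay
  threshold, no budget-impact analysis, no outpatient/short-visit effects
  (overnight stays only), and no payer-perspective hospital costs: all are
  outside the NH-perspective scope of this package.
* The five-site group is one pooled unit; per-site disaggregation is not
  representable.
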