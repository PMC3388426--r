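---
title: "Valuing premature mortality by the human-capital method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing premature mortality by the human-capital method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humcap)
```

## The model

The human-capital method values a premature death as the present discounted
value of the income the deceased would have earned until retirement. With a
constant annual income $S$, discount rate $r$, and $t$ years between death
and retirement, the loss is the ordinary annuity

$$\mathrm{PV}(S, r, t) \;=\; S\,\frac{1}{r}\left[1 - \frac{1}{(1+r)^t}\right]
\;=\; \sum_{k=1}^{t} \frac{S}{(1+r)^k},$$

with payments at the end of each year and no mid-year correction. The model
assumes the individual's income stays constant over the remaining working
period (no growth term), and uses per-capita national income as the proxy
for $S$ because individual earnings are not recorded on death certificates.
Only market output is counted: unpaid work, caring, and production past the
statutory retirement age are outside the model, so national totals are
conservative.

The pipeline is: read individual mortality records → keep deaths inside the
working-age window → compute years to retirement → bin into cohorts → value
each cohort per person → aggregate to national totals, currency conversion,
cohort shares and budget-share ratios.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `annual_income` | 5131.50 | F$ / yr | per-capita national income of the reference year |
| `discount_rate` | 0.08 | fraction / yr | the rate used in the reference costing |
| `retirement_age` | 55 | yr | statutory retirement age in Fiji |
| `working_age_min`, `working_age_max` | 15, 55 | yr | inclusive window defining "young" working-age mortality |
| `exchange_rate` | 0.6 | US$ per F$ | the ratio implied by every published F$/US$ pair (3,078.90 / 5,131.50); the rate itself is a config input |
| `bin_width` | 5 | yr | cohort width of the published table |

Both window bounds are inclusive ("aged 15–55"): an age-55 death passes the
filter but has $t = 0$ remaining working years and contributes zero loss,
so it is excluded from the cohort bins. The maximum cohort $t = 40 = 55-15$
confirms the inclusive lower bound.

## Design choices where the method is genuinely open

**Cohort binning.** Published costings report 5-year years-to-retirement
cohorts without stating how individual ages were grouped. This package
rounds each death's $t$ *up* to the nearest positive multiple of the bin
width ($t \in (0,5] \to 5$, $(5,10] \to 10$, …): every death is granted an
annuity horizon at least as long as its true remaining working life and at
most `bin_width - 1` years longer. Ages are completed integer years as
recorded on death certificates; no fractional-age interpolation.

**Two per-person modes.** In `formula` mode per-person values come from
$\mathrm{PV}(S,r,t)$. In `table` mode they are supplied as data, carried in
thousands exactly as published. The two are both needed because published
per-person columns are not always derivable from the published $S$ and $r$:
in the Fiji costing the annuity gives ≈20.5 thousand at $t=5$ and ≈61.2 at
$t=40$, while the published column shows 24.2 and 140.4 — a discrepancy the
source does not explain (an unstated income-growth assumption would be one
candidate, but guessing a reconciliation would be worse than exposing the
gap). The pipeline therefore always computes the formula total as a
cross-check and raises a `humcap_mode_divergence` warning whenever supplied
values and the formula disagree by more than 5%. Reproductions of the
published table run in table mode; the discrepancy is surfaced, never
silently absorbed.

**$r = 0$.** Valued as the analytic limit $S \cdot t$ rather than an error,
so sensitivity sweeps may include an undiscounted cell; the annuity is
continuous in $r$ at zero.

**Friction-cost comparator.** The friction-cost method is described
qualitatively in the costing literature without a formula, so the
comparator here is deliberately minimal and explicit:
`S × friction_period`, undiscounted (friction periods are months, so
within-period discounting is negligible and a discounting flag is
deliberately omitted). The unemployment rate (7.6% in the reference year)
is carried as context metadata only.

**Retirement-age sweeps.** Cohorts are keyed by years to retirement under
the base retirement age; raising the retirement age by $d$ years lengthens
every horizon by $d$ — the same people retiring later. Each sweep cell
re-runs the full valuation, so the base cell reproduces the base total
exactly.

**Half-up rounding.** Published tables round money and percentages half
away from zero (0.98752 prints as 1% at zero decimals), while R's `round()`
rounds half to even; rendering therefore uses a half-up rule. Money is
carried at full precision internally and rounded only at rendering. The
secondary-currency total is the converted primary total (sum first, convert
after): the published grand total equals the converted F$ total rather than
the sum of the per-row conversions, which differ in the last decimal.

## Numerical notes

The annuity is evaluated as $S\,(1/r)\,(-\mathrm{expm1}(-t\,\mathrm{log1p}(r)))$,
which is algebraically identical to the closed form but avoids the
catastrophic cancellation of $1-(1+r)^{-t}$ as $r \to 0$; the implementation
matches the explicit discounted sum to $10^{-9}$ relative over
$t = 0..45$ and approaches $S \cdot t$ smoothly for $r$ down to $10^{-12}$.
Degenerate inputs are contracts, not surprises: empty record sets filter
and aggregate to zero-total reports, a zero grand total makes cohort shares
a domain error, and malformed CSV rows are reported with their line numbers
and skipped (or fatal under `strict = TRUE`).

## What the synthetic generator emulates — and what it does not

`generate_records()` emulates the *structure* of a national one-year
mortality extract: a configured total number of deaths, a configured number
outside the working-age window, and (in table mode) exact per-cohort
counts. Published costings report cohort counts, not raw ages, so table
mode draws each age uniformly from the integer ages consistent with its
cohort bin — any consistent choice reproduces the downstream analysis
exactly, and uniform is the least-assuming. Out-of-window ages are drawn
from elders (56–90) and children (1–14) in 9:1 proportion; they never
affect loss totals, only filter counts. The default configuration is the
study structure itself: 273 deaths, 147 in-window, cohort counts
3, 2, 9, 13, 16, 30, 34, 40 for $t = 40$ down to 5.

The generator is deterministic per seed down to the written file, and in
table mode every seed yields identical cohort counts — which is why the
pipeline's reported totals are seed-invariant.

What it does *not* emulate: a realistic stroke-incidence age profile,
sex or ethnicity structure, cause-of-death miscoding, or year-to-year
variation. Passing tests therefore demonstrate that the valuation
arithmetic, filtering, binning and reporting are correct given records with
the assumed structure — not that the package would validate a country's
raw death-certificate data.

## Problem sizes used in the test suite

Unit and property tests run on the 273-record study structure, parameter
grids of $S \in \{1, 5131.5\}$, $r \in \{0.01, \dots, 0.2\}$,
$t \in 0..45$, 100 randomized generator round-trips, and one 10,000-record
parametric draw for the in-window-fraction check; the whole suite completes
in a few seconds.

## Known limitations

- No income-growth term: the annuity assumes constant income, so losses for
  long horizons are conservative relative to growth-adjusted variants.
- The friction-cost comparator is a single multiplication by design; it is
  a point of comparison, not a full friction-cost implementation with
  vacancy-chain adjustments.
- Morbidity, carer and treatment costs are out of scope: the package values
  mortality only, one component of a full economic burden.
- Budget shares compare a loss (a flow valued today) with one year's budget
  figures; the ratio is a communication device, not a fiscal quantity.
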