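---
title: "Composite estimation of the burden of mental disorders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite estimation of the burden of mental disorders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhburden)
library(dplyr)
```

## The estimation problem

Burden-of-disease studies organize morbidity and mortality into a
mutually exclusive cause hierarchy. Where mental disorders sit in that
hierarchy is contested: the conventional allocation counts only the core
mental-disorder causes; critics point out that neurological disorders,
substance-use disorders, much of the chronic-pain burden filed under
musculoskeletal disease, suicide and self-harm, and the excess mortality
of people living with mental disorders are thereby excluded. `mhburden`
makes the competing accounting schemes explicit, configurable and
comparable, and attaches an economic valuation and a sensitivity
analysis to each.

Three approaches are implemented side by side. The *original* approach is
the hierarchical allocation itself. The *reallocation* approach transfers
whole causes (and one configurable fraction): substance-use and
neurological disorders in full, a fraction $f$ of the musculoskeletal-pain
causes, and self-harm in full, for every measure. The *composite*
approach keeps the reallocated morbidity (YLDs) but replaces whole-cause
mortality transfers with risk-based attribution: the excess mortality of
people with mental disorders is captured through a population
attributable fraction, applied separately to natural and unnatural
causes of death.

## The mortality model

For a country with prevalence $p$ of any mental disorder and a relative
risk $RR$ of death for people with versus without mental disorders,
Levin's formula gives the attributable fraction

$$\mathrm{PAF} = \frac{p\,(RR-1)}{1 + p\,(RR-1)}.$$

For $RR \ge 1$ this lies in $[0, 1)$ and is strictly increasing in both
arguments; a protective $RR < 1$ would produce negative attribution and
is refused with an error rather than silently subtracted, since the
scheme is designed for excess-risk attribution only.

Two choices here deserve emphasis.

**The exposure is "any mental disorder", not a sum over disorders.** The
pooled relative risk contrasts people with any disorder against people
with none, so the matching exposure prevalence is the aggregate
mental-disorders prevalence, read verbatim (`any_disorder` mode).
Summing per-disorder PAFs would double-count comorbid individuals. A
`complement_product` mode ($1 - \prod_d (1 - p_d)$) is provided for data
sets that only carry per-disorder prevalence, and is documented as
assuming independence of disorders.

**One pooled RR may stand in for two.** Stratum-specific relative risks
(natural vs unnatural death) are the right inputs, and `rr_config()`
accepts them with no silent default. When only the pooled all-cause
estimate (2.2, 95% CI 2.1–2.3) is available, it is applied to both
strata and the configuration is flagged `approximation = TRUE`, so runs
carry their provenance.

## Mortality bases and the double-counting guard

The natural-cause PAF is applied to the YLLs (and deaths) of
non-communicable diseases; the unnatural-cause PAF to those of injuries,
which contain self-harm. Because NCDs *contain* the causes the composite
approach already attributes directly (mental, substance-use,
neurological, fractional musculoskeletal), those direct YLLs are
subtracted from the NCD base before the PAF is applied. Without this
guard a schizophrenia YLL could be counted once directly and once
through the PAF. The subtraction can only go negative if the input
hierarchy is inconsistent (children exceeding their parent); in that
case the base is clamped to zero and a warning names the problem.

Two further composition rules, both deliberately conservative where the
choice was open:

* self-harm YLDs are *excluded* from the composite approach's morbidity
  (its mortality is covered by the unnatural PAF); the
  `composite_self_harm_yld` flag restores them for users who want the
  more inclusive reading;
* no maternal, neonatal or infectious mortality is ever attributed — the
  natural base is NCDs only.

Attributable DALYs are composed as attributable YLLs plus attributable
YLDs — an identity the code maintains to the bit by constructing the
DALY rows from the YLL and YLD component rows rather than re-deriving
them from DALY records.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `msk_fraction` | 1/3 | fraction of musculoskeletal-pain burden | the conventional share for pain without anatomical correlate |
| `msk_fraction_bounds` | 1/6, 1/2 | sensitivity bounds | halving / augmenting-by-half the point share |
| RR (both strata) | 2.2 (2.1–2.3) | relative risk | pooled all-cause mortality estimate for any mental disorder |
| `include_substance` | original: no; others: yes | — | substance-use disorders were classified under mental disorders before being split out; the original preset mirrors the current hierarchy |
| analysis year | 2019 | calendar year | a configuration value, never inferred from data |

The musculoskeletal-pain cause list itself (low back pain, neck pain,
other musculoskeletal disorders) is a judgement call: no authoritative
enumeration of "musculoskeletal disorders without anatomical correlate"
exists. It is prominently configurable (`default_config(causes = ...)`)
and users with a different reading should override it. Similarly,
personality disorders are sometimes named among the exclusions that
motivate reallocation, but no such cause exists in the 2019 hierarchy,
so none is modelled.

## Sensitivity analysis

Uncertainty is propagated by *concordant extremes*, not Monte Carlo: one
run at all-lower settings (lower burden uncertainty intervals, lower
prevalence, lower RR, $f = 1/6$), one at the point, one at all-upper.
This matches how the source tables present a single lower/upper pair per
cell and makes no independence or correlation claims across the three
sources — a deliberate simplification, documented rather than modelled.
Burden uncertainty intervals across causes are treated as co-monotone
when summed, for the same reason.

The sandwich `lower <= point <= upper` is asserted for every
location–measure cell. A subtlety: the musculoskeletal fraction makes
individual *components* non-monotone — lowering $f$ shrinks the direct
component but enlarges the natural-cause PAF base (less is subtracted
from the NCD total) — yet totals remain ordered because the PAF is
strictly below 1. The assertion therefore applies to attributable
totals; a violation beyond floating-point round-off (tolerated at 1e-9
relative, then clamped) aborts the run, since it signals a
configuration under which the pipeline is not monotone in its inputs.

## Valuation

Attributable DALYs are valued at a multiple of GDP per capita (1× base
case, 3×), at fixed $1,000 / $5,000 per DALY, or at PPP-adjusted GDP per
capita (reported in international dollars, clearly unit-tagged).
Per-capita GDP is computed with the same population table as the
epidemiological inputs, not the economic source's own population. The
outputs are framed as the economic value of welfare losses — they are
not losses of GDP. Group percent-of-GDP uses the sum of member-country
GDPs as its denominator (not an external regional aggregate), a choice
the output tables inherit. Countries without an income classification
enter regional and global totals but no income-group total, so income
rows need not sum to the global row.

A numerical design point: every value is stored as
`multiplier × base`, with the base (DALYs × GDP per capita) summed
*inside* and the multiplier applied *outside* every aggregation. This
makes the 3× scheme bitwise three times the 1× scheme at the country,
regional and global levels — the proportionality the result tables rely
on — instead of merely equal to within round-off. Likewise the global
aggregate is computed by summing the regional aggregates, so regional
conservation holds exactly rather than approximately.

## The synthetic world generator

`generate_world()` emulates the statistical structure of the real
inputs: a cause hierarchy whose aggregates are exact sums of their
children; per-cause DALYs drawn from gamma distributions (CV 10%) around
configured cause-mix shares; group-specific morbidity fractions
splitting DALYs into YLDs and YLLs (self-harm and injuries almost pure
mortality, musculoskeletal pain almost pure morbidity); deaths derived
from YLLs; multiplicative uncertainty intervals `val × (1 ± h)`;
prevalence of any disorder uniform on [0.08, 0.18], with per-disorder
prevalences constructed as $1-(1-p)^{w_d}$ so their complement product
reproduces the aggregate exactly; GDP per capita rising steeply across
income tiers; and a planted income gradient that scales the
mental-related cause-mix shares so the attributable *share* of burden
(not the absolute burden) is about twice as large in the top tier as in
the bottom, echoing the income gradient observed in real estimates. The
mental-related share scaling is linear in the cause mix, so the planted
gradient is recovered most directly by the reallocation approach;
`income_gradient_check()` uses it by default.

Defaults are fixed study conditions, not tuning knobs: 50 countries in 5
regions, four income tiers assigned round-robin after a seeded shuffle
plus one unclassified country, 20% interval halfwidth, RR truth 2.2 with
CI 2.1–2.3, NCDs carrying 59% of DALYs (mental 5%), communicable causes
20%, injuries 10%. All randomness flows from a single seed; the same
seed yields byte-identical files.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no age or sex structure (the pipeline analyses
all-ages, both-sexes extracts), no correlation between prevalence and
income or conflict, no country-specific cause idiosyncrasies, no
asymmetric or draw-based uncertainty, and no attempt to match real
per-country magnitudes. Realism is structural (hierarchy, formats,
gradients), not numerical. Recovery tests demonstrate internal
consistency of the arithmetic, not epidemiological validity of the
inputs.

## Numerical choices and degenerate inputs

* Counts are the canonical metric; rates per 100,000 are derived views
  (converted with the population table) because fraction-times-burden
  arithmetic is only valid on counts.
* Interval-violating rows (`lower > val`, `val > upper`), negative
  values, and out-of-range proportions are hard errors naming row
  indices; stratified rows outside all-ages/both-sexes are rejected with
  a message and accounted for (`rows_in = rows_kept + rows_rejected`).
* An unmapped burden location is a hard error listing the locations; an
  unmapped economic location (e.g. a "World" aggregate) is dropped with
  a warning. Name variants resolve through an editable ISO3 alias table.
* With collapsed uncertainty (equal bounds everywhere, degenerate RR CI,
  fixed fraction) the three sensitivity runs are the same computation
  and return identical results.
* Rounding (one decimal for DALY millions and percents, two for
  trillions) happens only in `make_report()`; all stored values keep
  full precision.

## Problem sizes

The shipped tests run worlds of 1–50 countries; the acceptance script
uses the 50-country default world, a 1,000-point grid for the
attributable-fraction check, and a one-country reference fixture for the
hand-checked mortality arithmetic. The full suite completes in well
under a minute on a single CPU.

## Known limitations

The attributable-fraction machinery assumes the relative risk is
unconfounded and homogeneous across countries and strata; adjusted risk
ratios can make the attribution anticonservative if crude ratios are
lower. No age-specific PAFs are computed. The concordant-extremes bounds
are not probability intervals. And the composite totals depend on
judgement calls documented above (the musculoskeletal cause list and
fraction, the self-harm YLD exclusion), all of which are configurable
precisely because they are judgement calls.
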