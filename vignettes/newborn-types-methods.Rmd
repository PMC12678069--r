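---
title: "Methods: newborn-type classification, registry quality and trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: newborn-type classification, registry quality and trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newborntypes)
```

This vignette is the package's account of its methods: the classification
model and its boundary conventions, the data-quality and exclusion rules,
the aggregation and trend procedures, the design choices made where the
problem was genuinely open, and what the synthetic generator does and does
not emulate.

## 1. The classification model

A live birth is classified on three axes. Gestational age is carried
internally in **days** since the last menstrual period
(`ga_days = 7·weeks + days`); every threshold is expressed in days, which
removes all week/day ambiguity at boundaries. Preterm (PT) is
`ga_days ≤ 258` (36 weeks⁺⁶) and term (T) is `ga_days ≥ 259`
(37 weeks⁺⁰). Registries that record only completed weeks are normalized
with `days = 0` and flagged as week-resolution; week-based thresholds then
reduce to completed-week comparisons, which is consistent with "up to
36⁺⁶" meaning completed weeks ≤ 36.

Size for gestational age compares birthweight with the 10th and 90th
centiles of a sex- and gestational-age-specific standard: SGA strictly
below the 10th, LGA strictly above the 90th, AGA otherwise — **both
centile boundaries classify as AGA**, reading "10th–90th" as an inclusive
band. Birthweight class is LBW strictly below 2500 g; exactly 2500 g is
nonLBW ("nonLBW ≥ 2500 g" taken literally).

The six types are the cross PT/T × SGA/AGA/LGA. The *small* composite is
any type involving PT and/or SGA (PT+SGA, PT+AGA, PT+LGA, T+SGA); *large*
is T+LGA; T+AGA is the reference. The ten-type classification splits each
of the six by LBW/nonLBW. Two of the twelve formal combinations —
PT+SGA+nonLBW and T+LGA+LBW — are absent from the conventional ten-type
list; whether such births were suppressed or simply unobserved in earlier
tabulations is not documented, so this package assigns them explicit
`unexpected_*` labels and counts them. Hiding them would silently break
the conservation identity between the ten- and six-type tables.

## 2. The centile standard

The classification engine consumes *any* standard honouring the file
contract (`sex`, `ga_days` or `ga_weeks`, `p10_g`, `p90_g`); published
international newborn size standards are used in production, supplied by
the analyst, while this repository ships only synthetic standards (clearly
labelled so in file names and provenance strings). The published
coefficients are deliberately not reproduced here: the package's job is
the classification, not the standard's derivation.

Between weekly knots the centiles are interpolated **linearly at day
resolution**, independently for the 10th and the 90th centile; since the
10th lies strictly below the 90th at every knot, linearity preserves the
ordering everywhere. Sub-week handling is not specified in the field's
method descriptions, so the interpolation rule is explicit and recorded.

Standards covering a narrower window than the plausible analysis range
(154–314 days) must be extended before use, and the extension is a named,
recorded choice: `linear_extrapolate` (default) continues the slope of
the two outermost knots per sex per centile; `clamp` holds boundary
values constant. Extensions producing non-positive weights or crossing
centiles are hard errors. Neither method claims to replicate any
collaboration's own (undocumented) extrapolation of a published standard;
the method used is written into the table's provenance and the run
manifest.

## 3. Data quality and the exclusion cascade

Missingness is measured **before** exclusion, on all records received
per country-year; tail proportions (< 500 g, < 1000 g, ≤ 202 days) and
the heaping index use the **post-exclusion** analysis set. Both
denominators are emitted. The heaping index is
`n(bw = 2500) / n(bw ∈ [2250, 2499] ∪ [2501, 2750])`; an empty flank
denominator yields an undefined (missing) index, not zero. Coverage of
the reference birth population and the facility-birth share are accepted
as metadata inputs (they come from external reference estimates), feeding
the 80% inclusion criteria; the > 20% missingness rule flags country-years
(strict inequality) for the sensitivity re-analysis.

The exclusion cascade runs in a fixed order with single-count
attribution: missing gestational age (birthweight present), missing
birthweight, missing both, missing sex, implausible birthweight
(< 250 g or ≥ 6500 g — the boundary excluded from the plausible range),
implausible gestational age (< 154 or > 314 days), and implausible
birthweight/gestational-age combinations. The missing-reason precedence
(GA before BW before both before sex) mirrors the order in which these
are conventionally reported; a record missing gestational age *and* sex
counts once, under missing gestational age. Malformed rows (unparseable
values, a day-of-week field outside 0–6) are rejected at parse time and
reported separately, because the exclusion cascade is defined over
*values*, not over file defects.

The combination rule excludes birthweights beyond mean ± 5 SD of the
birthweights at the same completed gestational week. The reference
population for that envelope is not externally specified, so the envelope
is **self-referential**: computed per run from the records surviving the
earlier cascade steps, pooled over sexes and countries, using the sample
(n − 1) SD. Weeks with fewer than 10 records (configurable) define no
bounds and produce no combination exclusions — extreme-week cells are too
sparse for a stable SD. Multiplier, cell minimum and the envelope itself
are exposed so stratified or externally supplied envelopes can be
substituted. Because the envelope depends on the survivor set, re-running
the cascade on its own output with the envelope held fixed excludes
nothing further; the *included set* is invariant to permutations of the
pure filter rules, only the reason attribution depends on their order.

The flow identity `n_input = n_included + Σ exclusions` holds exactly, as
integers, for every run; percentages of input are reported at one decimal
while unrounded values stay available upstream.

## 4. Prevalence aggregation

Country-year prevalences are counts over the country-year's analysis
records. The **national** prevalence pools counts across a country's
years (count-weighted), not a mean of yearly proportions — with multi-year
periods of very different sizes the pooled figure is the one a single
national tabulation would produce. A year-median variant is available
behind a flag for sensitivity. Cross-country summaries (overall and per
region) are medians with interquartile ranges across national values,
each national data set weighted equally; quartiles use linear
interpolation between order statistics (`stats::quantile` type 7, the
default convention in mainstream statistical environments), and the rule
is recorded in the output metadata. Devolved nations supplying separate
registries are treated as separate national data sets.

## 5. Trends

Smoothed trends are centred 3-year moving averages of the annual small-
and large-composite percentages, defined only where all three consecutive
calendar years are present (endpoints and gap-adjacent years are
undefined rather than computed from partial windows). Countries with
fewer than four country-years of data are excluded from trend estimation.
A change flag is raised where the smoothed value moves by strictly more
than 0.5 **percentage points** between consecutive years — the threshold
is read on the prevalence-point scale, matching the scale of all quoted
trend values, not as a relative 0.5%. Net changes over the two decades
2000–2009 and 2010–2021 are last-defined minus first-defined smoothed
value within the period, with the years used recorded; fewer than two
defined values leave the period summary undefined.

Uncertainty bands on the annual percentages are binomial standard errors
under the normal approximation, `100·√(p(1−p)/n)`. This is a labelled
convention of this package: the construction of uncertainty bounds in the
field's published trend figures is not specified, and no claim of
replication is made. No changepoint or local-regression model is fitted;
the moving average *is* the computed artifact.

## 6. The synthetic registry generator

The generator exists so every stage has testable ground truth. Per
country it draws sex (default male share 0.515), gestational age from a
two-part law — a term Gaussian (default mean 280 d, SD 8 d, truncated to
259–314) plus a preterm tail (258 − Gamma(shape 2, scale 10) days,
bounded to 154–258) whose weight is the preterm rate — and birthweight
from a Gaussian family with piecewise-linear mean (500 g at 154 d to
3300 g at 280 d, then +10 g/day) and linearly widening SD (110 g at
154 d to 430 g at 314 d), males offset +100 g. These values are chosen
once as a realistic caricature of fetal growth at the resolution the
pipeline cares about; both mean pieces break only at day 280, a weekly
knot, so the weekly-knot toy standard interpolates the family *exactly*
at day resolution.

Target SGA and LGA rates are hit in closed form: the birthweight z-score
(relative to the toy standard's family) is drawn from N(m, c²) with
`c = (z₉₀ − z₁₀) / (Φ⁻¹(1 − lga) − Φ⁻¹(sga))` and
`m = z₁₀ − c·Φ⁻¹(sga)`, so that P(z < z₁₀) = sga and P(z > z₉₀) = lga at
every gestational age. Targets with sga + lga ≥ 1 are rejected before
sampling. Because the z-score is independent of gestational age, preterm
and SGA rates tune independently, and the small composite equals
`pt + (1 − pt)·sga`, the large composite `(1 − pt)·lga`.

Ground-truth type labels are computed **against the same toy standard the
pipeline uses**, on the uncorrupted values, so truth-vs-pipeline
agreement is exact at zero corruption and tests isolate pipeline defects
rather than family-vs-standard mismatch. Corruption is applied after
truth labelling, in a fixed order: heaping (a fraction of records with
weight in 2250–2750 g relocated to exactly 2500 g — directly the
heaping-index window), rounding to 100 g, missingness (independent MCAR
per variable), and implausible-record injection (out-of-limit weights and
gestational ages; in-window weights placed ~10 family SDs above the
weekly mean for the combination rule). Every corruption is tagged
per record. The same seed reproduces the output exactly.

The packaged 23-country scenario gives each country a target small
composite spanning 7.6–26% (median 11.7%) paired inversely with a large
composite (median 18.1%), 45% of the small target allocated to preterm;
20 countries contribute 10 years and three fewer than four years (so
exactly 20 enter trend estimation); corruption is mild (1–2% missingness,
5% heaping fraction, 2% rounding, 0.2% implausible injections per
category), keeping all countries above the 80% completeness bar. Targets
are generator inputs for demonstrations and integration tests — not
claims of replicating any real country.

What the generator does **not** emulate: non-random (differential)
missingness, gestational-age digit preference or last-menstrual-period
dating error, secular trends within a country (raw annual prevalences are
exchangeable draws), multiple-birth physiology (plurality is a
pass-through tag), and any real joint (ga, bw) distribution. Passing
tests therefore demonstrate the pipeline's *arithmetic and contracts*,
not robustness to informative data defects.

## 7. Numerical choices and degenerate inputs

* Proportion identities are checked to 1e-9; counts are exact integers.
* The prevalence of an empty country-year is omitted with a notice, not
  emitted as 0/0.
* An empty heaping denominator and an empty tail denominator are
  undefined (`NA`), never zero.
* Envelope SD uses n − 1; a zero or undefined SD defines no bounds.
* Interpolation queries outside a standard's range are errors, pushing
  the extension decision to the caller rather than extrapolating
  silently.
* The classification monotonicity (increasing weight never moves a record
  toward SGA) follows from the strict-inequality boundary rules and is
  property-tested.

## 8. Problem sizes used in the test-suite and demonstration runs

Unit and property tests run on constructed micro-fixtures and registries
of 2,000–50,000 records; the end-to-end scenario used by the integration
checks and the acceptance script generates 23 countries × ~50,000 births
(≈1.15 million records), a size at which binomial sampling error (3 SE)
on national composite prevalences is ±0.4 percentage points or less and
the full pipeline completes in seconds on one CPU. These sizes are the
package's own choice of demonstration scale.

## 9. Known limitations

* The exclusion envelope is self-referential and pooled by default;
  registries with strongly sex- or country-specific weight distributions
  may prefer a stratified envelope (supported via the `envelope`
  argument).
* Week-resolution registries are classified at `days = 0`; day-resolution
  centile interpolation then uses the week's first day, a conservative
  convention flagged per record.
* No imputation anywhere: records that cannot be classified are excluded
  and accounted, never filled in.
* Aggregate outputs only by default; per-record outputs and small-cell
  suppression (< 5) are explicit opt-ins for disclosure control.
* Preterm sub-strata (extremely/very/late preterm) and spontaneous vs.
  clinician-initiated distinctions are out of scope.
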