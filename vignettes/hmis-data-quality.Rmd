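---
title: "Assessing routine HMIS data quality along the data journey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing routine HMIS data quality along the data journey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmisdq)
library(dplyr)
```

## The problem

In most facility-based health information systems a single service event is
recorded several times before it becomes a national statistic. A client is
written into a **register**, ticked on a daily **tally sheet**, the monthly
totals are compiled into a **report form** whose copy is submitted to the
**district office**, and a district clerk finally keys the value into
**DHIS2**. Every hand-off can lose, inflate or silently revise the count:
events are never registered, tally sheets are over-marked or skipped
entirely, reports are compiled by guesswork, submitted copies go missing in
district filing, and values are "corrected" at entry without documentation.

`hmisdq` treats this five-source *data journey* as the unit of analysis. It
quantifies quality along three axes — tool **availability**, recording
**completeness** and numerical **accuracy** — and pairs the metrics with a
generative simulator of the journey, so every metric can be validated by
parameter recovery on synthetic data without access to any confidential
facility dataset.

## The data-journey model

For facility $f$, indicator $i$ and month $t$, a true event count
$N_{fit} \sim \mathrm{Poisson}(\mu_{s(i),\ell(f)})$ is drawn with a mean per
(service area, facility level). The five sources derive from it:

* register recount $R = \mathrm{Bin}(N,\,1-p_{\text{reg miss}})$;
* tally count $T = \mathrm{Bin}(N,\,1-p_{\text{tally miss}}) +
  \mathrm{Pois}(\lambda_{\text{overmark}} N)$;
* facility report $F$: per service-area-month one compile mode is drawn —
  a copy of the tally total, a register recount, or an *inflated guess*
  ($R \times$ inflation factor, rounded half away from zero);
* district copy $D = F$ unless the report is lost in transmission;
* DHIS2 value $Z = D$, revised by a correction factor with probability
  $p_{\text{corr}}$ (an *undocumented* revision) and perturbed by a
  keystroke error (±1 in a random decimal place, floored at zero) with
  probability $p_{\text{entry}}$.

Each tool can additionally be *unlocatable at review time* (per
service-area-month absence probabilities). Absence is an audit phenomenon,
not a generation one: the monthly report is compiled from the latent tally
or register counts even if the auditors later fail to find the register, so
the simulator can reproduce the real-world finding of reports that exist
without locatable register support. Structurally, however, a missing
facility report implies missing district and DHIS2 values, because those
sources are physical copies of it.

Poisson truth was chosen for simplicity; configurable over-dispersion is a
non-goal. Counts are kept integer everywhere; the only roundings (inflated
guesses, corrections) use a fixed half-away-from-zero rule so runs are
bit-reproducible across platforms.

### Reproducibility and sub-streams

A single global seed is expanded with a deterministic string hash into one
sub-stream per facility and stage (`truth`, `journey`, `register_rows`).
Adding facilities to a roster therefore never reshuffles the draws of
existing facilities — a property the test suite asserts directly.

## Availability

A tool-month counts as *observed* when at least one record for that tool,
facility, service area and month exists. The availability rate is
$100 \times \text{observed}/\text{expected}$ tool-months over an inclusive
month window; the same arithmetic applied to district copies of facility
reports is the district's *reporting completeness*. Facility-level rates
are always computed first and then summarised across facilities with the
median, 25th and 75th percentiles, and their spread (p75 − p25). Quantiles
use linear interpolation between closest order statistics (type 7), the
default convention in major statistical environments; the convention is an
argument of `summarize_distribution()`.

Rates are categorised into four bands: `very_high` (75, 100],
`high` [50, 75], `average` [25, 50) and `low` [0, 25). The printed
conventions for such bands typically overlap at the cut points; we resolve
them so the four intervals partition [0, 100], with 75 in `high` because
`very_high` is strictly "above 75".

## Completeness

The register audit is rule-based: each field has a `field_rule()` — coded
(allowed code set, case-sensitive after whitespace trimming), numeric
(range) or free text, plus a required flag. A blank required field counts
as a blank violation; a present value outside its code set or range counts
as invalid; a row is adherent iff it has no violations. One conditional
rule ships by default: severity is required only when a diagnosis is
recorded. Case sensitivity matters here because the canonical coding
violation is language confusion — `Y`/`Yes` used where the instructed codes
are `N` (*Ndiyo*, yes) and `H` (*Hapana*, no) — and `N` is valid in both
conventions, so only exact tokens carry the signal.

## Accuracy: six difference ratios

The difference ratio of two sources is the ratio of their **pooled sums**
over facility-months where both are present:

$$\mathrm{DR} = \frac{\sum_{\text{both present}} x_{\text{later}}}
                     {\sum_{\text{both present}} x_{\text{earlier}}}.$$

Pooling sums (rather than averaging per-row ratios) is robust to zero-count
months and matches how recounted totals are compared in practice. Absence
is never imputed as zero; 0/0 is flagged `undefined_0_over_0` and excluded
from category tallies but kept in an audit column, positive/0 is flagged
`infinite_over` and categorised `extremely_over`.

```{r indices}
diff_index_table()
```

Diff1–2 form the *health-facility phase* (recording to compilation),
Diff3–5 the *transmission phase* (Diff3 captures documented revisions of
the submitted copy, Diff4 undocumented revisions at DHIS2 entry, Diff5
their composition), and Diff6 the *robust phase* comparing the two extreme
ends of the journey. DRs are categorised on seven levels from
`highly_under` (< 0.5) through `matched` (±5 %) to `extremely_over` (> 2).
The printed threshold conventions leave 0.5 and 0.75 unassigned between
neighbouring bands; both default into `moderately_under` so the categories
partition $[0,\infty)$, and the 0.5 closure is configurable
(`half_rule = "highly_under"`).

Note a pooled identity the implementation asserts against a brute-force
re-summation oracle: Diff6 always equals (total DHIS2)/(total register)
over its pairwise-complete set — but Diff6 = Diff2 × Diff3 × Diff4 only
when per-row ratios are constant, so narrative comparisons across indices
computed on different pairwise-complete sets need care.

## A worked example

```{r example}
params <- journey_params(p_register_miss = 0.2, seed = 42)  # else lossless
roster <- simulate_roster(seed = 42)[1:10, ]
truth  <- simulate_true_events(roster, indicator_catalogue(),
                               "2016-01", "2016-12", params)
counts <- propagate_journey(truth, params)
compute_diff_indices(counts)
```

With 20 % of events never registered and an otherwise lossless journey,
Diff1 and Diff2 estimate $1/(1-0.2) = 1.25$ and the transmission indices
stay at exactly 1 — the parameter-recovery property the acceptance suite
checks within three Monte-Carlo standard errors.

## Default study conditions

The default roster mirrors a published census of 115 primary-care
facilities: 67 dispensaries, 36 health centres, 12 hospitals across 11
named districts (5 urban, 6 rural), with per-service-area offer rates
taken from that census (e.g. OPD in 114/115 facilities, IPD in 43/115),
34 indicators over 7 service areas, a 45-month window (January 2014 –
September 2017) and a 12-month detailed-review subset used for the
accuracy tables and register audit. `default_journey_params()` is a single
illustrative error preset — tally under-use, a fifth of reports compiled
by ~3× inflated guesswork, 35 % transmission loss, occasional undocumented
corrections — chosen once to reproduce the reported error *phenomena*
qualitatively; no field dataset exists from which to calibrate the rates,
and they are not presented as estimates for any country.

What the simulator does **not** emulate: patient identity across visits,
clinically coherent diagnoses, seasonality or trends in volumes, spatial
correlation between neighbouring facilities, and improvement over time.
Passing recovery tests therefore show the *metrics* are correct and the
*pipeline* is faithful to its generative assumptions — not that any
particular real HMIS has these error rates.

## Numerical and design choices

* Problem sizes in the test and acceptance runs are kept modest (tens of
  facilities, one to four years, ≥ 1 000 facility-month pairs for
  Monte-Carlo recovery at 3-standard-error tolerance), which keeps the
  whole suite under a minute while leaving Monte-Carlo error well below
  the tested tolerances.
* Months are `YYYY-MM` strings; all windows are inclusive on both ends,
  and window additivity is property-tested.
* Display rounding (rates to one decimal, DRs to two, ranges to whole
  percents) happens only at CSV/HTML export; computation is unrounded.
* The colour legend for match categories is a fixed colour-blind-safe
  palette shipped in `match_palette()`.
* The statistical comparison of strata (t tests, proportion tests) is
  deliberately out of scope; the package produces the stratified
  descriptive tables such tests would consume.
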