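---
title: "The case/non-case method: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The case/non-case method: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicase)
```

## The problem

Spontaneous adverse drug reaction (ADR) reporting systems collect voluntary
notifications of suspected drug harms. They have no denominator — nobody
knows how many patients took each drug — so incidence cannot be estimated.
What can be estimated is *disproportionality*: whether an event of interest
is reported more often in combination with a given drug than the rest of
the database would suggest. `vigicase` implements the case/non-case flavour
of this analysis for behavioural events (hostility, aggression,
interpersonal violence), together with the descriptive epidemiology that
usually accompanies it and a synthetic report generator for validating the
whole pipeline.

## Case selection

Reactions are coded to a PT → HLT → SOC hierarchy (preferred term, high
level term, system organ class). An event of interest is captured as a
named SMQ-style term set with two scopes: a *narrow* scope of specific
terms and a *broad* scope that adds sensitive terms (narrow ⊆ broad). A
report is a **case** when at least one of its reactions is coded to a PT in
the scoped set, however many match; every other report in the database is a
**non-case**. The partition is exhaustive and disjoint by construction, and
the test suite checks `select_cases()` against a brute-force scan of every
(report, reaction) pair.

Only the primary HLT/SOC path of each PT is modelled. Real medical
terminologies are multi-axial and licensed; the bundled dictionary
(`mock_dictionary_path()`) is a mock sufficient for the pipeline: it
carries the hostility/aggression narrow terms, the sensitive terms as the
broad extension, and a set of background PTs. PT matching is by code after
case-insensitive name normalization.

## The statistics

With cases defined, each drug yields a 2×2 table over reports:

|            | event (case) | no event |
|------------|:---:|:---:|
| drug       | a | b |
| no drug    | c | d |

A report counts as exposed when the drug appears among its suspected drugs
(role `suspect`, and by default also `interaction`; concomitant medication
does not count). Three statistics quantify disproportionate reporting:

* **ROR** (reporting odds ratio) $= ad/bc$, with the Wald interval
  $\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$;
* **PRR** (proportional reporting ratio)
  $= \frac{a/(a+b)}{c/(c+d)}$, with interval
  $\exp(\ln \mathrm{PRR} \pm z\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})$;
* **Yates-corrected χ²**
  $= N(|ad-bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]$ with $N = a+b+c+d$,
  clamped to 0 when the correction exceeds $|ad-bc|$, so a proportional
  table scores exactly 0.

A drug is flagged as a **signal of disproportionate reporting** when all
four conventional criteria hold, with strict inequalities: at least 3 case
reports, lower ROR confidence bound above 1, PRR above 2 and χ² above 4
(`signal_thresholds()`). A signal warrants causality assessment; it is not
proof of causation.

Algebraically ROR ≥ PRR whenever ROR > 1 (they coincide at the null), and
the Wald intervals shrink as all cells scale up; both properties are
enforced as tests over random tables, and the χ² implementation is checked
against `stats::chisq.test(correct = TRUE)` as an independent
implementation on 1000 random tables.

### Numerical choices

* $z$ is fixed at 1.96 rather than recomputed from a distribution
  function, for bit-stable intervals.
* Zero cells: the default policy adds 0.5 to every cell (Haldane) and
  flags the result; with the policy set to `none` a zero cell yields an
  explicit `NA`, never a silent infinity. Screened drugs must have a ≥ 3,
  so the correction never triggers on the headline analyses.
* Percentages in frequency tables are rounded **half-up** (commercial
  rounding) at 1 decimal (2 where the source tables print 2), because
  that convention — not R's round-half-to-even — reproduces every printed
  percentage of the source tabulations from their printed counts.
* Screening output is ordered by ATC code, then descending ROR, then drug
  name, so results are deterministic under ties.

## Completing published 2×2 tables

Published disproportionality tables typically print, per drug, the case
count $a$ and the estimates — not the exposure totals $a+b$. Given the
database total $N$, the case total $C$ and the printed ROR, the missing
cell has the closed form

$$b = \frac{a\,(N - C)}{\mathrm{ROR}\,(C - a) + a},\qquad c = C - a,\qquad
d = N - C - b.$$

`complete_table()` applies this inversion (the result is marked *derived*;
cells are generally non-integer and are used for verification only). On
the published interpersonal-violence analysis whose scale the package emulates (533 cases among 353,165 reports), the
recomputed PRRs for montelukast, levetiracetam, donepezil and memantine
agree with the printed values to all printed digits, and the recomputed
ROR confidence bounds agree to within one unit of the final printed digit
— the residual wobble is inherited from the printed ROR itself being
rounded to 2 decimals. The printed χ² values are *not* recoverable from
completed tables (the back-derived montelukast value is ≈ 492 against a
printed 478.66, a discrepancy no completion can remove because the
completed table already fixes every cell); the χ² implementation is
therefore validated against the formula and an independent implementation
rather than against the published column.

The report, not the reaction, is the unit of analysis: the study's 533
case reports carry 554 violence reactions, and the printed ROR→PRR pairs
are mutually consistent only with a case total of 533. Reaction-level
tables (PT and outcome distributions) use the 554 denominator; every
frequency table carries its denominator and kind (`reports`, `reactions`,
`drug_entries`) as attributes so the two cannot be silently mixed.

## Descriptive conventions

Age groups are infant [0, 2), child [2, 12), adolescent [12, 18), adult
[18, 65] and elderly (65, ∞), lower-inclusive, with absent ages in an
explicit `unknown` group. (The source material prints "adult (8–65)" once;
we read that as a typo for 18–65 since the adolescent bin ends at 17.)
Suspected-drug tables count drug entries — 671 suspected entries across
the 533 cases, of which 49 are interactions — and interaction entries are
included as suspected by default (configurable). The published ATC
level-1 and level-2 percentage columns are internally inconsistent with
the 671 denominator (e.g. 25/671 printed as 3.2, 84/671 printed as 12.8)
while the substance-level table is consistent with it; the package emits
all ATC tables against the explicit denominator 671 and makes no attempt
to guess the original denominators. Causality is summarized purely as
categorical frequency tables over the five qualitative dimensions (time
sequence, prior knowledge, dechallenge, rechallenge, alternative cause);
no causality score is computed, because the source tabulations report
none.

## The synthetic generator

Real pharmacovigilance databases are proprietary, so the package ships a
seeded generator (`generate_reports()`) whose preset
(`fedra_like_preset()`) emulates the marginal structure of a national
database: 353,165 reports, a violence case fraction of 0.15%, multi-drug
reports, and the case series' demographic, outcome, seriousness and
causality profiles.

**Caseness model.** Each drug $j$ is drawn independently per report with
baseline probability $e_j$ (rows are redrawn until at least one drug is
present), and the report is a case with probability
$\operatorname{logit}^{-1}\!\big(\operatorname{logit}(p_0) + \sum_{j
\text{ exposed}} \beta_j\big)$. This is the simplest mechanism with a
controllable marginal association: for a rare background rate $p_0$ the
realized ROR of drug $j$ is approximately $e^{\beta_j}$, and recovery
tests compare against the realized, counted table rather than only the
asymptotic value.

**Preset parameters.** The catalogue holds the 16 most-reported suspected
substances with $\beta_j$ set at their screened RORs, plus 20 null
background drugs whose exposure probabilities make reports average about
two drug mentions (so the ≥ 1-drug redraw is rare, about 8% of rows, and
the conditioning distortion small). Per-drug exposure baselines are
back-derived with `complete_table()` from each drug's case count and ROR
— plausible magnitudes standing in for unpublished exposure totals, and
labelled as derived. Lorazepam, frequently reported but without
disproportionality, gets a modest $\beta = \ln 1.5$, below every
threshold. The background rate $p_0$ is solved in closed form so the
expected case fraction equals the target exactly under the rare-event
expectation conditioned on the redraw
(`expected_case_count()` documents the formula); at full scale the
expectation is 533 cases. Case reports carry 1–3 distinct violence PTs
(mean ≈ 1.04, matching 554 reactions per 533 cases) weighted by the
published PT distribution (86.6% aggression); outcomes, seriousness
criteria and causality categories follow the published case-series
frequencies, with a fatal outcome tied to the fatal seriousness
criterion. Demographics draw an age group from the case-series weights
and then an age uniformly within the bin — matching how grouped ages are
reported without inventing a population pyramid. Where the source gives
only a partial breakdown (nurse/consumer split of reporters, the
adolescent and infant group sizes, the splits of incompletely reported
causality categories), the preset fixes a single realistic allocation and
keeps it.

**Determinism.** The seed is part of the configuration; a config
reproduces its database bit-for-bit (tested down to the serialized CSV
bytes), and the manifest records the seed, a config hash, a generator
version tag and the realized marginals. A single global random stream
with a documented draw order means that adding fields preserves earlier
reproducibility only at the same config version.

**What it does not emulate.** Reporting trends over calendar years (years
are uniform), duplicate and follow-up reports, correlated co-prescription,
dose or narrative text. Passing recovery and calibration tests therefore
demonstrates that the estimators and thresholds behave correctly under a
known generative model — not that they would behave identically on real
reporting data, whose biases (under-reporting, notoriety effects,
channelling) the generator deliberately leaves out.

## Problem sizes used in the checks

The validation suite runs the deterministic table-completion checks at the
full database scale (they are closed-form), parameter-recovery and null
calibration at 50,000 reports with 20 replicates for the coverage check
(the montelukast-scale effect then yields only a handful of exposed cases
per replicate, which is exactly the sparse regime the method must handle),
and one full-scale generation-plus-screening run at 353,165 reports. The
package's own choice of these sizes keeps the whole suite to around a
minute of compute while exercising every code path at realistic
magnitudes.

## Known limitations

* Wald intervals are asymptotic; with very small cells they are rough,
  which is why the minimum-report rule exists.
* No Bayesian disproportionality (IC/BCPNN, EBGM/MGPS) and no
  multiple-comparison control — matching standard practice in these screens, which
  applies none.
* The mock terminology is not MedDRA; real analyses must license and load
  the real dictionary in the same TSV layout.
* `complete_table()` inverts printed estimates; its output inherits the
  printed rounding and must never be treated as observed data.
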