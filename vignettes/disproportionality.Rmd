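---
title: "Case/non-case disproportionality analysis of FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality analysis of FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect reports of suspected adverse drug
reactions without denominators: there is no count of everyone exposed, only
of those for whom something was reported. Risk can therefore not be
estimated as incidence; instead one asks whether an event is reported
*disproportionately* often with an exposure of interest, relative to a
comparator exposure within the same database. `faersror` implements this
case/non-case design for drug–drug interaction screening: does adding a
second drug to a target drug increase the reporting of an event beyond the
target drug alone?

The motivating application is visual hallucination (MedDRA preferred term
10047570) under the antifungal voriconazole, alone and combined with a
dopaminergic drug (levodopa) or dopamine antagonists (risperidone,
chlorpromazine). The package is, however, generic over the target drug,
the comparator list, the event preferred term and the synonym dictionary.

## The statistic

For each index exposure group, reports are cross-classified as case
(the event preferred term is among the report's reactions) or non-case
(any other report), giving the 2×2 table

|              | cases | non-cases |
|--------------|-------|-----------|
| index group  | a     | b         |
| reference    | c     | d         |

The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},$$

with the Woolf (log-normal) confidence interval

$$\exp\!\left(\log \mathrm{ROR} \pm z_{1-\alpha/2}\,
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

and a two-sided Wald p-value $2\,(1 - \Phi(|\log \mathrm{ROR}|/SE))$ on the
same standard error. The reference group is shared by all index groups, so
every table reuses the same $(c, d)$ margin. A group is flagged as a
*signal* when the lower confidence bound exceeds 1 **and** at least
`min_cases` (default 3) cases were reported; the case-count clause guards
against the instability of disproportionality estimates at very small
counts. Because the interval and the test derive from the same z statistic,
`ci_low > 1` holds exactly when `p < 1 - ci_level` for an ROR above one —
a property the test suite checks exactly.

Assumptions worth keeping in mind: reports are treated as independent
after deduplication; reporting behaviour is assumed comparable between
index and reference groups (no adjustment for confounding, stimulated
reporting, or channeling); and a disproportionality signal is a screening
result, not a causal or incidence estimate.

### Numerical choices

* No continuity correction: a zero cell makes ROR, CI and p undefined, and
  they are rendered as dashes. Correction constants change small-count
  estimates materially and are not universally used; undefined is honest.
* The z quantile is `qnorm(1 - (1 - level)/2)` (≈ 1.959964 at 95%), not the
  literal 1.96.
* Display rounding is half-up to 3 decimals for ROR and CI bounds and to
  3 decimals for p-values, with values below 0.0005 shown as `<0.001`
  (`round_half_up()` is exported because R's `round()` rounds half-even).
* The occurrence percentage is computed as $100\,a/b$ — cases per hundred
  **non-cases**, not per hundred reports. This matches the reporting
  convention of the published analyses this package reproduces (3 cases
  against 17 non-cases is shown as 17.6%); it is an idiosyncrasy of that
  convention and is documented on `occurrence_pct()`.

## The data flow

`run_faers_pipeline()` executes the full flow; each stage is also an
exported function.

1. **Ingestion** (`read_faers_quarter()`): the four `$`-delimited quarterly
   tables (DEMO, DRUG, REAC, THER; post-2012 column set) are joined into
   one report per distinct `primaryid`. Partial dates (`YYYY`, `YYYYMM`)
   are padded to the first day/month for comparison and flagged; unparsable
   dates become missing and are counted, never fatal. Ages are normalized
   to years, weights to kilograms. Orphan rows are dropped and counted.
2. **Normalization** (`normalize_drugs()`): each drug entry gets a
   canonical ingredient from a synonym dictionary, trying the
   active-ingredient field before the verbatim name, case-insensitively on
   whole semicolon-separated components. Unmapped drugs never drop a
   report.
3. **Deduplication** (`deduplicate()`): one report per case number — the
   greatest receipt date wins, ties broken by the greatest zero-padded
   `primaryid`. A missing receipt date sorts before any present date.
4. **Post-event exclusion** (`exclude_post_event()`): a report is removed
   iff it contains the ingredient, both the ingredient's earliest therapy
   start and the report's event date are known, and the start is
   *strictly* after the event ("administered after the occurrence" is read
   as strictly after; a same-day start is kept). Missing dates never
   trigger exclusion — conservative retention. The pipeline applies this
   per study drug.
5. **Group assignment** (`assign_groups()`): with S the set of study drugs
   in a report, S = {target} is the reference; one comparator alone is that
   comparator's group; target plus one comparator is the combination
   group; any other multi-study-drug set is excluded (groups must be
   disjoint, and "other drugs were administered" exclusions are read this
   way — one reading among several possible, documented rather than
   asserted); an empty S is outside the analysis. Non-study drugs never
   affect assignment, and drug role codes are deliberately not filtered
   (suspect and concomitant both count as exposure).
6. **Statistics** (`disprop_ror()`): the fitting function, returning a
   classed object with `print`, `summary`, `coef`, `confint` and
   `as.data.frame` methods.

Every filter logs `(n_in, n_removed, n_out)` with
`n_in = n_removed + n_out`, and the pipeline asserts that every input
report lands in exactly one terminal category (analyzed group,
excluded-duplicate, excluded-post-event, excluded-other-drug,
not-in-analysis), so the data-collection flowchart can be regenerated
mechanically from the provenance log.

### Open design points, decided and fixed

* **"Most recent" duplicate**: keyed on the FAERS receipt date (`fda_dt`);
  the tie rule (greatest `primaryid`) is ours, since none is standard.
* **Event date**: the report-level `event_dt` operationalizes event onset;
  reaction-level onset dates are not in the supported column set.
* **Fixed-dose combinations**: the default dictionary counts
  carbidopa/levodopa and benserazide/levodopa products as levodopa
  exposure. This is an assumption; override the dictionary to change it.
* **Per-drug index groups**: comparators are analyzed per drug, not pooled,
  matching how such results are tabulated.
* **IQR percentiles** in `demographics_table()` use linear interpolation
  between order statistics (R quantile type 7); percentages are per group
  total, unlike the occurrence percentage above — each table keeps its own
  convention.

## The synthetic generator

Real FAERS extracts are large, external downloads; `simulate_faers()`
generates report sets with known ground truth so that every stage is
testable offline. It emulates exactly the structure the pipeline
exercises:

* case-level exposures to the study drugs (independent Bernoulli draws per
  drug, plus optional pairwise joint excess), an extra non-study drug to
  exercise the assignment rules, and at least one drug per report;
* a case-level event indicator whose odds in group $g$ are
  $\theta_g \cdot p_0/(1-p_0)$, with $p_0$ the baseline event probability
  and $\theta_g$ a configurable true reporting-odds multiplier — applied at
  the case level and copied to duplicates, so deduplication cannot bias
  event frequency;
* duplicate report versions (a duplicated case gets `1 + Geometric(0.5)`
  extra versions, capped at five reports) sharing the case id with
  strictly increasing receipt dates; the last-received version is the
  canonical one in the ground truth;
* therapy starts at or before event onset, except a configured fraction of
  target exposures that strictly postdate it (the post-event exclusion
  path);
* demographic missingness, country weights, and partial-information
  patterns (missing event dates, missing therapy starts).

Defaults follow the published data-collection flow where it pins them
down: `duplicate_rate = 0.17` reproduces the roughly 24% duplicate share
of retrieved voriconazole reports (75,180 of 314,328),
`post_event_rate = 0.03` the roughly 3% post-event share of the
deduplicated remainder (7,262 of 239,148), and
`baseline_event_prob = 0.014` the reference-group event rate
(323 of 22,839). Marginal exposure prevalences cannot be recovered from a
published analysis (they depend on the whole database); the defaults
(0.10/0.08/0.09/0.02 for the four study drugs) are chosen once to give
reference and single-drug groups in the hundreds-to-thousands and
combination groups in the tens at the simulation sizes used, mimicking the
rare-combination regime of the real analysis.

`realized_tables()` is the brute-force oracle: it enumerates canonical,
non-post-event reports from the ground truth and tallies the 2×2 counts
directly, with no pipeline code involved. The test suite requires the
pipeline's tables to equal this enumeration exactly on 50 generated
datasets of 2,000 cases, checks 95% CI coverage of an injected
combination-group multiplier of 12 over 200 replicates of 50,000 cases
(within three binomial standard errors of 0.95), and bounds the per-group
signal-flag rate under the null (all multipliers 1) over 500 replicates of
2,000 cases by the nominal one-sided 2.5% plus three Monte-Carlo standard
errors. These sizes keep the full suite within a few minutes on one core
while leaving the Monte-Carlo checks well powered.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic marginal distributions of drugs and
reactions, correlated co-medication patterns, reporting-quality drift over
quarters, probabilistic (non-exact) duplicates with differing case
numbers, country- or reporter-specific reporting behaviour, and any
confounding structure linking exposure to event risk. Agreement with the
oracle demonstrates that the pipeline computes the intended quantities,
not that the ROR is unbiased for a causal effect in FAERS.

## A worked example

```{r example}
cfg <- simulation_config(
  n_cases = 50000,
  odds_multiplier = c("voriconazole+levodopa" = 12))
sim <- simulate_faers(cfg, seed = 7)
res <- run_faers_pipeline(reports = sim$reports)
res$fit
```

```{r published}
# The published 2x2 counts can be fed to the estimator directly:
tabs <- data.frame(
  group = c("levodopa", "voriconazole+levodopa"),
  a = c(1582, 3), b = c(89228, 17), c = 323, d = 22516)
disprop_ror(tabs)
```

## Limitations

* Only the post-2012 FAERS ASCII column set is supported; historical
  schema revisions are out of scope.
* Duplicate detection is exact on the case number; probabilistic record
  linkage across differing case ids is not attempted.
* No Bayesian disproportionality measures (BCPNN/EBGM), no
  interaction-specific statistics beyond the case/non-case ROR design, and
  no multiple-testing adjustment — matching the design this package
  implements, whose published counterpart applies none.
* The published absolute flow counts and demographics of the real FAERS
  extract are not reproducible without the database itself; the package
  verifies its statistics against the published 2×2 tables and its
  machinery against synthetic ground truth.
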