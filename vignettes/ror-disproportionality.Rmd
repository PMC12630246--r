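---
title: "Case/non-case ROR disproportionality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case ROR disproportionality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvror)
```

## The design and its estimand

In a spontaneous-reporting database the denominator of true drug
exposure is unknown, so absolute risks cannot be estimated. The
case/non-case design instead compares *reporting composition*: among
reports of the event of interest (cases) versus all other reports
(non-cases), is a drug mentioned as suspect disproportionately often?
The measure is the reporting odds ratio (ROR) on a 2×2 table of
suspected-drug **mentions** — a report naming two suspected drugs
contributes two mentions to its stratum, but a drug is counted at most
once per report. The ROR is an association between *reporting* of a drug
and *reporting* of the event; it is a hypothesis-generating quantity,
not a risk ratio, and it says nothing about causality.

The pipeline stages are:

1. **Classification.** A report is a case iff at least one of its
   reaction Preferred Terms is in the SMQ term list. Matching is exact
   on normalized strings (trimmed, case-folded) — never substring or
   fuzzy, because the SMQ is a curated list and approximate matching
   would silently change case counts. The narrow/broad scope attribute
   is provenance only; it selects which file the analyst loads.
2. **Non-case sampling.** Four non-cases per case, drawn uniformly
   without replacement with a user-supplied seed (R's Mersenne-Twister
   stream). The design is unmatched; no stratification variables are
   used. The full pool size is retained so the headline case proportion
   of the whole database stays computable after sampling.
3. **Mention expansion.** Reports unroll to (report, drug) pairs.
   Fixed combinations used as single products in practice (e.g.
   sulfamethoxazole + trimethoprim) are collapsed to one mention via a
   rules file matching component names or ATC5 codes; otherwise each
   active substance counts individually. Mentions whose ATC5 code is
   missing cannot be placed in the hierarchy: they are kept, flagged,
   excluded from entity/sibling cells, and reported in the run log so
   the (typically 4–7%) data loss is auditable rather than silent.
4. **Eligibility.** Only entities suspected in at least `min_cases = 5`
   case reports are tested, at the level being tested (a class analysis
   counts class mentions).
5. **Estimation.** For an entity with cells (a, b) the comparator is
   either its within-class siblings (`siblings_within_parent`: c, d are
   the parent-class totals minus the entity) or everything else
   (`all_other`: c, d are the stratum totals minus the entity). If any
   cell is zero, the Haldane correction adds 0.5 to *all four* cells —
   the conservative variant, which keeps zero-cell estimates finite and
   reproduces published zero-cell results exactly; correcting only the
   zero cells would not. Then ROR = (a·d)/(b·c) with the Woolf (log)
   interval `exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`, z = 1.96.
6. **Flagging.** Signal iff ROR ≥ 2 and lower CI bound > 1 (strict) and
   pre-correction case mentions ≥ 5. All comparisons use full precision;
   rounding (half-up, two decimals for ROR/CI) is presentation only.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| sampling ratio | 4 non-cases per case | the classical case/non-case compromise between precision and extraction cost |
| `min_cases` | 5 | below ~5 case mentions the ROR is dominated by single reports |
| z | 1.96 | 95% two-sided Woolf interval; configurable for sensitivity analyses |
| Haldane increment | 0.5 on all four cells | finite estimates with zero cells; conservative (shrinks extreme RORs) |
| comparator, ATC5 | `siblings_within_parent` | contrasts a substance against its own therapeutic class, isolating substance effects from class effects |
| comparator, ATC2 | `all_other` | the common convention for class-level screening; the sibling option (other classes under the same anatomical group) is also available and the choice is recorded in the manifest |

Class-level results are sensitive to the comparator convention;
published class RORs are often not recoverable without knowing it, so
`run_analysis()` writes the choice into the manifest and the results
table rather than leaving it implicit.

## The synthetic generator: what it emulates and what it does not

`generate_database()` produces databases with the structure that makes
this pipeline hard to test on real data: rare cases among many reports,
multi-drug reports with a heavy single-drug mode, multi-label
seriousness outcomes, and substantial missingness that *differs between
strata*. The preset ("sampled" scale: 1,760 reports with exactly 352
cases; "full" scale: 53,505 reports) mirrors a published national AKI
cohort: female share 46.1% / 60.9% (case / non-case), age
59.56 ± 21.6 vs 50.00 ± 22.1 years with 42.6% / 22.7% missing, sex
missing 8.8% / 3.9%, outcome classification absent in 4.8% / 30.5%, and
single-drug reports 67.6% / 82.5%. Where the emulated cohort reports a
single number per stratum, that number is the default; remaining
choices (drug catalogue weights, background reaction vocabulary,
reporter type 96.6% / 90% healthcare professionals, a Poisson(0.4) tail
on 5+ drug reports, Poisson(0.7) background reaction counts) were fixed
once at values typical of national databases and are not tuned.

Planted associations act multiplicatively on a drug's mention odds
conditional on case status. Concretely, a drug's per-slot sampling
weight w becomes m·w in case reports, and multi-drug reports are drawn
by systematic probability-proportional-to-size sampling, so a drug's
inclusion probability in a k-drug report is exactly k × its weight
share. Because the other drugs' weights are unchanged, the population
mention-odds ratio of a singly-planted drug equals m *exactly* at every
report size — this is what makes parameter-recovery tests well-defined.
Two caveats follow from the same arithmetic: (i) when several strong
associations are planted at once they share the case-mention budget and
each measured ROR is attenuated below its multiplier (visible in the
preset, where multipliers 3.2 / 3.8 / 9 yield RORs near 4.6 / 3.6 / 8 —
finite-composition behaviour that real mention data exhibits too); and
(ii) inclusion probabilities are capped at 1 for very heavy drugs in
large reports, a negligible regime under the defaults.

The generator does **not** model drug co-prescription correlation,
temporal reporting trends (the Weber effect), duplicate reports, or
reaction-term miscoding. A green end-to-end test therefore establishes
that the pipeline's logic and statistics are correct under the stated
generative model — not that the method is robust to those real-world
phenomena.

Cases are tagged with one SMQ term from a five-term synthetic renal
list (not licensed MedDRA content); non-cases draw only from a disjoint
background vocabulary, so classification recovers the generated status
exactly and the generator's ground truth is usable as an oracle.

## Numerical and degenerate-input choices

- Ties round half away from zero (`round_half_up()`), matching how
  published tables are typically rounded; base R's round-half-even would
  disagree on exact .5 ties. An epsilon of 1e-9 absorbs binary
  representation error.
- `pearson_chi2()` applies no continuity correction (published cohort
  tables verify against this choice) and refuses tables with a zero
  margin; the cohort summary reports such variables as "not estimable"
  instead of aborting.
- The equal-variance t-test is computed from summary statistics
  (mean, SD, n per group) because that is the form available when
  checking published cohorts; it equals `t.test(..., var.equal = TRUE)`
  on raw data.
- An entity that constitutes its entire parent class has an empty
  sibling comparator; `build_table()` errors with guidance to use
  `all_other`, and `ror_table()` records the message in the `note`
  column rather than failing the whole run.
- An empty outcome *set* means the outcome classification is missing —
  distinct from "no serious outcome". Percentages use per-variable
  complete-case denominators (outcome percentages use outcome-present
  reports), never listwise deletion.
- Sampling, generation and the pipeline never disturb the caller's RNG
  state; every stochastic step takes an explicit seed, and the run
  manifest (seed, thresholds, comparators, input checksums) makes a run
  replayable bit-for-bit.

## Open design decisions taken

- **Mentions, not reports, are the counting unit** for contingency
  tables. This is the only reading under which a published cohort's
  drug-table column totals are consistent with its drugs-per-report
  distribution, and it matches field practice.
- **Combination handling matches components.** A rules file lists the
  component substances (or codes) of clinically fixed combinations;
  within a report, any matching mentions collapse to one mention under
  the combined label, optionally carrying the combination product's own
  ATC5 so it participates in class aggregation.
- **Per-status generator parameters.** Demographics and missingness are
  (case, non-case) pairs rather than single values because the cohort
  structure being emulated differs by stratum; a scalar is accepted and
  recycled where the distinction does not matter.
- **Exact versus Bernoulli case counts.** Report status is i.i.d.
  Bernoulli by default (the natural sampling model); presets fix the
  case count exactly so downstream totals are pinned for testing. Both
  keep the case marginal at `case_fraction` in expectation.

## Known limitations

- Exact Preferred-Term matching only; no MedDRA hierarchy navigation,
  so a term list must be supplied at the PT level.
- No adjustment for multiple testing (matching field practice for
  screening); the results table carries the number of entities tested
  so users can adjust post hoc.
- The Woolf interval is asymptotic: with a corrected zero cell the CI is
  extremely wide and its coverage is only approximate; the package
  reports such rows with `corrected = TRUE` so they can be weighed
  accordingly.
- One published cohort statistic (an age-comparison value printed as
  31.776) is not recoverable as the equal-variance t statistic from the
  printed summaries (which give ≈ 5.67); the package implements the
  stated test and does not attempt to reproduce that number.
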