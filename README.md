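# pvror

Case/non-case disproportionality analysis for spontaneous-reporting
(pharmacovigilance) databases, with a synthetic report generator so the
entire pipeline is testable without access to any real
individual-case-safety-report (ICSR) data.

## The problem and who this is for

Spontaneous reporting systems collect ICSRs: one report names the
suspected drug(s) and the reaction term(s), plus demographics and
seriousness outcomes. A standard way to screen such databases for safety
signals is the **case/non-case design**: reports with the event of
interest (here: acute kidney injury, identified via a Standardised
MedDRA Query term list) are the cases, all other reports are non-cases,
and a drug's reporting disproportionality is measured by the **reporting
odds ratio** on a 2×2 table of drug-mention counts

|            | case | non-case |
|------------|------|----------|
| drug       | a    | b        |
| comparator | c    | d        |

    ROR = (a·d) / (b·c)
    95% CI = exp( ln ROR ± 1.96 · √(1/a + 1/b + 1/c + 1/d) )   (Woolf)

with the conservative **Haldane correction** (add 0.5 to *all four*
cells) whenever a cell is zero. A drug is flagged as a signal when, a
priori, ROR ≥ 2 **and** the lower 95% bound > 1 **and** it is suspected
in ≥ 5 cases. The package is aimed at pharmacoepidemiologists and
pharmacovigilance analysts who want this pipeline as reusable, tested
code rather than ad-hoc scripts.

What it provides, module by module:

- **ICSR store** — a validated one-row-per-report container with
  lossless CSV round-trip (`read_reports()` / `write_reports()`), and
  ATC-hierarchy helpers (`atc_ancestor()`).
- **Case classifier** — exact, normalized Preferred-Term matching
  against an SMQ term list (`load_smq()`, `classify_all()`).
- **Non-case sampler** — seeded 4:1 random extraction without
  replacement (`sample_noncases()`).
- **Contingency builder** — drug-mention expansion with
  fixed-combination collapsing, the ≥ 5-case eligibility filter, and 2×2
  tables at the ATC2 (class) or ATC5 (substance) level under a
  `siblings_within_parent` or `all_other` comparator (`build_table()`).
- **ROR statistics** — `haldane_adjust()`, `compute_ror()`,
  `evaluate_signal()`, plus the cohort tests: Pearson χ² without
  continuity correction and the equal-variance two-sample *t* from
  summary statistics.
- **Synthetic data** — `generate_database()` draws databases with
  planted drug–event associations whose population mention-odds ratio
  equals the configured multiplier, enabling calibration, power and
  type-I-error studies (`evaluate_operating_characteristics()`).
- **Pipeline** — `run_analysis()` orchestrates classify → sample →
  build → estimate → flag with a reproducibility manifest; `pv_cli()` /
  `exec/pvror` expose `simulate` and `analyze` subcommands.

## Worked example

The package ships the drug-mention counts of a published national
case/non-case AKI analysis (352 cases, 1,408 sampled non-cases) as a
plain-text fixture. Replaying them through the full pipeline:

```r
library(pvror)
m   <- counts_to_mentions(example_aki_counts())
res <- ror_table(m, level = 5, comparator = "siblings_within_parent")
res[res$signal, ]
```

prints the eleven flagged substances (estimates rounded half-up to two
decimals):

```
  entity                label    a    b    c     d corrected    ror ci_low  ci_high
 B01AE07 dabigatran etexilate 20.0 19.0 14.0  43.0     FALSE   3.23   1.35     7.72
 C10AA01          simvastatin  7.0  4.0  4.0  20.0     FALSE   8.75   1.71    44.72
 H02AB06         prednisolone  9.0 13.0  1.0  16.0     FALSE  11.08   1.24    99.15
 J01XA01           vancomycin  9.0  5.0 27.0 135.0     FALSE   9.00   2.80    28.96
 J05AF07 tenofovir disoproxil 38.0 19.0 83.0 159.0     FALSE   3.83   2.08     7.06
 J05AF09        emtricitabine 24.0 13.0 97.0 165.0     FALSE   3.14   1.53     6.45
 L01EG02           everolimus  9.5  0.5 83.5 196.5      TRUE  44.71   2.57   777.14
 L04AA06    mycophenolic acid  9.0  8.0 43.0 170.0     FALSE   4.45   1.62    12.20
 L04AD01          ciclosporin 15.0  3.0 37.0 175.0     FALSE  23.65   6.51    85.85
 L04AD02           tacrolimus  5.0  5.0 47.0 173.0     FALSE   3.68   1.02    13.25
 V03AC03          deferasirox  9.5  0.5  0.5   3.5      TRUE 133.00   2.19  8082.55
```

Reading one row: dabigatran etexilate was suspected in a = 20 case and
b = 19 non-case mentions; its within-class comparator (the other
antithrombotic agents, B01) contributes c = 14 and d = 43, giving
ROR 3.23 with 95% CI [1.35, 7.72] — reported disproportionately often
with AKI relative to its class. The two `corrected = TRUE` rows had a
zero cell, so 0.5 was added to all four cells before estimation.

A fully synthetic end-to-end run with planted ground truth:

```r
db  <- generate_database(preset_config("sampled", seed = 42))
run <- run_analysis(db$reports,
                    smq_definition(synthetic_smq_terms(), name = "ARF (synthetic)"),
                    seed = 42)
run
#> Case/non-case run: 1760 reports, 352 cases (20.0% of database), 1408 non-cases sampled from 1408
#> 33 entities tested; 3 signal(s)
#>   dabigatran etexilate         level 5  ROR   4.64 [ 2.69-    8.00]  a=76
#>   vancomycin                   level 5  ROR   8.01 [ 4.68-   13.73]  a=55
#>   tenofovir disoproxil         level 5  ROR   3.57 [ 2.27-    5.59]  a=78
```

The three flagged drugs are exactly the three associations the preset
plants (odds multipliers 3.2, 3.8 and 9).

## Command line

```sh
Rscript exec/pvror simulate --preset sampled --seed 1 --out db.csv --truth-out truth.json
Rscript exec/pvror analyze --reports db.csv \
    --smq inst/extdata/smq_acute_renal_failure_synthetic.txt \
    --seed 1 --out-dir results/
```

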