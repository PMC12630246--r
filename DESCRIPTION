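Package: pvror
Title: Case/Non-Case Disproportionality Analysis for Spontaneous Reporting
    Databases
Version: 0.1.0
Authors@R:
    person("pvror", "maintainers", email = "pvror@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection with the
    case/non-case design: classify individual case safety reports (ICSRs)
    as cases via a Standardised MedDRA Query (SMQ) term list, draw a seeded
    fixed-ratio sample of non-cases without replacement, expand reports
    into drug mentions with fixed-combination handling, aggregate over the
    ATC hierarchy, and estimate Haldane-corrected reporting odds ratios
    (ROR) with Woolf 95% confidence intervals and a-priori signal criteria.
    Includes cohort descriptive statistics (Pearson chi-square,
    equal-variance t-test) and a synthetic ICSR generator with planted
    drug-event associations so the full pipeline is testable without any
    real pharmacovigilance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
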