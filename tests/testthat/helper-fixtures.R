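# Shared fixture builders: everything is constructed in code at test time.

fixture_smq <- function() {
  smq_definition(synthetic_smq_terms(), name = "ARF (synthetic)",
                 scope = "narrow")
}

smq_fixture_path <- function() {
  system.file("extdata", "smq_acute_renal_failure_synthetic.txt",
              package = "pvror")
}

rules_fixture_path <- function() {
  system.file("extdata", "combination_rules.csv", package = "pvror")
}

# A handwritten three-report table exercising every field, including
# characters that need escaping in list cells.
tiny_reports <- function() {
  icsr_reports(
    report_id = c("R1", "R2", "R3"),
    report_date = as.Date(c("2012-03-01", NA, "2019-11-30")),
    reporter_hcp = c(TRUE, NA, FALSE),
    sex = c("F", NA, "M"),
    age_years = c(71.5, NA, 34),
    outcomes = list(c("hospitalization", "death"), character(0),
                    "clinically_important"),
    drugs = list(
      data.frame(atc5 = "B01AE07", inn = "dabigatran etexilate",
                 stringsAsFactors = FALSE),
      data.frame(atc5 = c("J05AF07", "J05AF09"),
                 inn = c("tenofovir disoproxil", "emtricitabine"),
                 stringsAsFactors = FALSE),
      data.frame(atc5 = NA_character_, inn = "herbal mix | unspecified",
                 stringsAsFactors = FALSE)),
    reactions = list(c("Acute kidney injury", "Nausea"),
                     "Headache",
                     c("Rash", "Back\\slash term")))
}

# Minimal pool of n non-case-like reports (one drug, one reaction each).
id_pool <- function(n, prefix = "P") {
  icsr_reports(
    report_id = sprintf("%s%05d", prefix, seq_len(n)),
    drugs = rep(list(data.frame(atc5 = "N02BE01", inn = "paracetamol",
                                stringsAsFactors = FALSE)), n),
    reactions = rep(list("Nausea"), n))
}
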