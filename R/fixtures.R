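# Bundled example data: drug-mention counts from a published national
# pharmacovigilance case/non-case analysis of acute kidney injury, and a
# replay helper that rebuilds a mention table from such counts so the
# whole disproportionality path can be exercised on known numbers.

#' Example drug-mention counts from an AKI case/non-case analysis
#'
#' Case and non-case suspected-drug mention counts at the ATC2 class and
#' ATC5 substance level, as published by a national spontaneous-reporting
#' AKI disproportionality study (352 cases, 1,408 sampled non-cases).
#' Rows with an empty `atc5` carry the class totals; the remaining rows
#' are the individually reported substances of that class.
#'
#' @return data.frame with columns `atc2`, `class_name`, `atc5`, `inn`,
#'   `cases`, `noncases`.
#' @export
example_aki_counts <- function() {
  path <- system.file("extdata", "aki_drug_counts.csv", package = "pvror")
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), fileEncoding = "UTF-8")
  df$cases <- as.integer(df$cases)
  df$noncases <- as.integer(df$noncases)
  df
}

#' Rebuild a mention table from class/substance count data
#'
#' Expands a count table shaped like [example_aki_counts()] into one
#' mention row per counted drug mention. Each class's unlisted remainder
#' (class total minus the listed substances) becomes a synthetic sibling
#' entity `<ATC2>ZZ99` labelled "other <class>", so sibling-comparator
#' tables built from the result reproduce `c = class total - a`,
#' `d = class total - b` exactly.
#'
#' @param counts data.frame with columns `atc2`, `class_name`, `atc5`,
#'   `inn`, `cases`, `noncases`; empty `atc5` rows are class totals.
#' @return a `mention_table` (one synthetic report per mention).
#' @export
counts_to_mentions <- function(counts = example_aki_counts()) {
  is_total <- !nzchar(counts$atc5)
  drugs <- counts[!is_total, , drop = FALSE]
  totals <- counts[is_total, , drop = FALSE]
  if (anyDuplicated(totals$atc2)) {
    stop_pvror("duplicate class-total row for '%s'",
               totals$atc2[duplicated(totals$atc2)][1L])
  }
  listed_cases <- tapply(drugs$cases, drugs$atc2, sum)
  listed_noncases <- tapply(drugs$noncases, drugs$atc2, sum)
  rem_cases <- totals$cases - ifelse(is.na(listed_cases[totals$atc2]), 0L,
                                     listed_cases[totals$atc2])
  rem_noncases <- totals$noncases -
    ifelse(is.na(listed_noncases[totals$atc2]), 0L,
           listed_noncases[totals$atc2])
  if (any(rem_cases < 0) || any(rem_noncases < 0)) {
    stop_pvror("listed substance counts exceed the class total for '%s'",
               totals$atc2[which(rem_cases < 0 | rem_noncases < 0)][1L])
  }
  ent <- data.frame(
    atc5 = c(drugs$atc5, paste0(totals$atc2, "ZZ99")),
    label = c(drugs$inn, paste("other", totals$class_name)),
    cases = c(drugs$cases, as.integer(rem_cases)),
    noncases = c(drugs$noncases, as.integer(rem_noncases)),
    stringsAsFactors = FALSE)
  n_case <- sum(ent$cases)
  n_noncase <- sum(ent$noncases)
  m <- data.frame(
    report_id = c(sprintf("C%05d", seq_len(n_case)),
                  sprintf("N%05d", seq_len(n_noncase))),
    case_status = rep(c("case", "noncase"), c(n_case, n_noncase)),
    atc5 = c(rep(ent$atc5, ent$cases), rep(ent$atc5, ent$noncases)),
    label = c(rep(ent$label, ent$cases), rep(ent$label, ent$noncases)),
    stringsAsFactors = FALSE)
  m$combined <- FALSE
  m$unclassified <- FALSE
  class(m) <- c("mention_table", "data.frame")
  attr(m, "totals") <- mention_totals(m)
  m
}
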