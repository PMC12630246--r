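# Drug-mention expansion, fixed-combination collapsing, the minimum-case
# eligibility filter, and 2x2 contingency tables over the ATC hierarchy.
#
# The unit of counting is the drug MENTION, not the report: a report
# naming two suspected drugs contributes two mentions to its stratum.
# Mentions whose ATC5 code is missing cannot be placed in the hierarchy;
# they are kept in the mention table flagged `unclassified`, excluded from
# entity and sibling-comparator cells, and reported separately so the data
# loss is auditable.

#' Read fixed-combination rules
#'
#' Some products are fixed combinations used as a single entity in
#' clinical practice (e.g. sulfamethoxazole + trimethoprim); their
#' components are collapsed to one mention rather than counted as separate
#' substances. The rules file is a CSV with columns `combined_label`,
#' `member_match` (an ATC5 code, or a case-insensitive glob matched
#' against the substance name), and optionally `combined_atc5` (the ATC5
#' of the combination product, letting it participate in class-level
#' aggregation). One member per row; member sets must be disjoint across
#' rules.
#'
#' @param path CSV file path.
#' @return list of rules: each a list(combined_label, members, combined_atc5).
#' @export
read_combination_rules <- function(path) {
  if (!file.exists(path)) stop_pvror("combination rules file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), fileEncoding = "UTF-8")
  if (!all(c("combined_label", "member_match") %in% names(df))) {
    stop_pvror("rules file needs columns combined_label, member_match")
  }
  if (!"combined_atc5" %in% names(df)) df$combined_atc5 <- ""
  rules <- lapply(split(df, df$combined_label), function(g) {
    atc <- unique(g$combined_atc5[nzchar(g$combined_atc5)])
    if (length(atc) > 1L) {
      stop_pvror("rule '%s' has conflicting combined_atc5 values",
                 g$combined_label[1L])
    }
    list(combined_label = g$combined_label[1L],
         members = unique(g$member_match),
         combined_atc5 = if (length(atc)) atc else NA_character_)
  })
  names(rules) <- NULL
  all_members <- unlist(lapply(rules, `[[`, "members"))
  if (anyDuplicated(all_members)) {
    stop_pvror("combination rule member '%s' appears in more than one rule",
               all_members[duplicated(all_members)][1L])
  }
  rules
}

# Which rule does a mention belong to? Vectorized over mentions; returns
# integer rule index or NA.
match_rule <- function(atc5, inn, rules) {
  out <- rep(NA_integer_, length(atc5))
  for (ri in seq_along(rules)) {
    hit <- rep(FALSE, length(atc5))
    for (m in rules[[ri]]$members) {
      if (grepl(ATC5_PATTERN, m)) {
        hit <- hit | (!is.na(atc5) & atc5 == m)
      } else {
        hit <- hit | grepl(utils::glob2rx(m), inn, ignore.case = TRUE)
      }
    }
    out[is.na(out) & hit] <- ri
  }
  out
}

#' Expand classified reports into a drug-mention table
#'
#' One row per distinct (report, drug entity) pair. Components matched by
#' a fixed-combination rule are collapsed to a single mention carrying the
#' rule's label (and its `combined_atc5`, when given). Mentions with a
#' missing ATC5 are kept but flagged `unclassified`.
#'
#' @param cases,noncases `icsr_df` strata from [classify_all()] (the
#'   non-cases typically already sampled by [sample_noncases()]).
#' @param rules optional list from [read_combination_rules()].
#' @return a data.frame of class `mention_table` with columns `report_id`,
#'   `case_status` ("case"/"noncase"), `atc5`, `label` (substance name or
#'   combined label), `unclassified`; attribute `totals` holds the
#'   case/non-case mention totals (unclassified included) and the
#'   unclassified counts per stratum.
#' @export
expand_mentions <- function(cases, noncases, rules = NULL) {
  unroll <- function(reports, status) {
    if (nrow(reports) == 0L) {
      return(data.frame(report_id = character(0), case_status = character(0),
                        atc5 = character(0), label = character(0),
                        stringsAsFactors = FALSE))
    }
    k <- vapply(reports$drugs, nrow, integer(1))
    data.frame(
      report_id = rep(reports$report_id, k),
      case_status = status,
      atc5 = unlist(lapply(reports$drugs, `[[`, "atc5"), use.names = FALSE),
      label = unlist(lapply(reports$drugs, `[[`, "inn"), use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  m <- rbind(unroll(cases, "case"), unroll(noncases, "noncase"))
  m$combined <- FALSE
  if (!is.null(rules) && length(rules)) {
    ri <- match_rule(m$atc5, m$label, rules)
    hit <- !is.na(ri)
    m$label[hit] <- vapply(rules, `[[`, character(1), "combined_label")[ri[hit]]
    m$atc5[hit] <- vapply(rules, `[[`, character(1), "combined_atc5")[ri[hit]]
    m$combined[hit] <- TRUE
  }
  # dedupe: one mention per (report, entity) — collapsing a combination's
  # components, or the same drug listed twice (two dose forms), to one row
  key <- paste(m$report_id, ifelse(is.na(m$atc5), "", m$atc5), m$label,
               sep = "\r")
  # a combination rule can merge rows that then share (report, atc5, label)
  dup <- duplicated(key)
  # rows with same report+atc5 but different label remain distinct drugs;
  # rows collapsed by a rule share the label too, so the key above suffices
  m <- m[!dup, , drop = FALSE]
  # a fixed combination without its own ATC5 is still a well-defined
  # level-5 entity (keyed by label); only code-less ordinary mentions are
  # hierarchically unplaceable
  m$unclassified <- is.na(m$atc5) & !m$combined
  rownames(m) <- NULL
  class(m) <- c("mention_table", "data.frame")
  attr(m, "totals") <- mention_totals(m)
  m
}

#' Mention totals of a mention table
#'
#' @param mentions a `mention_table`.
#' @return list with `n_case_mentions`, `n_noncase_mentions` (all mentions,
#'   unclassified included) and `n_case_unclassified`,
#'   `n_noncase_unclassified`.
#' @export
mention_totals <- function(mentions) {
  is_case <- mentions$case_status == "case"
  list(n_case_mentions = sum(is_case),
       n_noncase_mentions = sum(!is_case),
       n_case_unclassified = sum(is_case & mentions$unclassified),
       n_noncase_unclassified = sum(!is_case & mentions$unclassified))
}

# Entity key of each mention at a chosen ATC level. Level 5: the ATC5 code
# when present, else the bare label for combination entities without a
# code; level 2 (or 1): the ATC prefix, with code-less mentions NA.
entity_key <- function(mentions, level) {
  combined <- mentions$combined %||% rep(FALSE, nrow(mentions))
  if (level == 5) {
    key <- ifelse(is.na(mentions$atc5), NA_character_, mentions$atc5)
    key[is.na(key) & combined] <- mentions$label[is.na(key) & combined]
    key
  } else {
    len <- ATC_LEVEL_NCHAR[level]
    ifelse(is.na(mentions$atc5), NA_character_,
           substr(mentions$atc5, 1L, len))
  }
}

#' Entities meeting the minimum-case filter
#'
#' Only entities suspected in at least `min_cases` case reports are
#' analysed (the a-priori eligibility rule). The filter applies at the
#' level being tested: class-level analyses count class case mentions.
#'
#' @param mentions a `mention_table`.
#' @param level ATC level of the entities: 2 (therapeutic subgroup) or 5
#'   (substance).
#' @param min_cases minimum case-mention count (default 5).
#' @return data.frame with columns `entity`, `label` (a representative
#'   substance name; the ATC code itself at level 2), `n_case_mentions`,
#'   `n_noncase_mentions`, restricted to eligible entities and sorted by
#'   entity.
#' @export
filter_min_cases <- function(mentions, level = 5, min_cases = 5) {
  if (!level %in% c(1, 2, 5)) stop_pvror("level must be 1, 2 or 5")
  if (min_cases < 1) stop_pvror("min_cases must be >= 1")
  key <- entity_key(mentions, level)
  keep <- !is.na(key)
  key <- key[keep]
  status <- mentions$case_status[keep]
  lab <- mentions$label[keep]
  if (!length(key)) {
    return(data.frame(entity = character(0), label = character(0),
                      n_case_mentions = integer(0),
                      n_noncase_mentions = integer(0)))
  }
  a <- tapply(status == "case", key, sum)
  b <- tapply(status == "noncase", key, sum)
  labels <- tapply(lab, key, function(x) x[1L])
  out <- data.frame(entity = names(a),
                    label = if (level == 5) unname(labels) else names(a),
                    n_case_mentions = as.integer(a),
                    n_noncase_mentions = as.integer(b),
                    stringsAsFactors = FALSE)
  out <- out[out$n_case_mentions >= min_cases, , drop = FALSE]
  out <- out[order(out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a 2x2 contingency table directly from cells
#'
#' Cell layout of the case/non-case design: `a` = case mentions of the
#' entity, `b` = non-case mentions of the entity, `c` = case mentions of
#' the comparator set, `d` = non-case mentions of the comparator set.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param entity entity identifier (ATC code or combined label).
#' @param level ATC level (2 or 5), or NA.
#' @param comparator comparator strategy string.
#' @param label human-readable name.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, entity = NA_character_,
                              level = NA_integer_,
                              comparator = NA_character_, label = entity) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop_pvror("cells must be finite and non-negative")
  }
  if (all(cells == 0)) stop_pvror("all four cells are zero")
  structure(list(entity = entity, label = label, level = level,
                 comparator = comparator,
                 a = a, b = b, c = c, d = d,
                 n_case_mentions = as.integer(round(a)),
                 corrected = FALSE),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table for %s (level %s, comparator %s)%s\n",
              x$label, format(x$level), format(x$comparator),
              if (x$corrected) " [Haldane-corrected]" else ""))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("entity", "comparator"),
                              c("case", "noncase")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table for one entity from a mention table
#'
#' `a` and `b` are the entity's case/non-case mention counts. The
#' comparator cells depend on the strategy:
#' \describe{
#'   \item{`siblings_within_parent`}{`c`, `d` are the mention totals of the
#'     entity's parent class (ATC2 for a level-5 entity, ATC1 for a
#'     level-2 entity) minus the entity's own cells — i.e. the entity's
#'     siblings. Unclassified mentions never enter these cells.}
#'   \item{`all_other`}{`c`, `d` are the database-wide mention totals
#'     (unclassified mentions included — they are real "other drug"
#'     exposure) minus the entity's cells, so `a + c` and `b + d` equal
#'     the stratum mention totals.}
#' }
#'
#' @param mentions a `mention_table`.
#' @param entity ATC code at `level`, or a combined label (then only
#'   `all_other` is available).
#' @param level 2 or 5.
#' @param comparator `"siblings_within_parent"` or `"all_other"`.
#' @param label optional human-readable name.
#' @return a `contingency_table` (uncorrected counts).
#' @export
build_table <- function(mentions, entity, level = 5,
                        comparator = c("siblings_within_parent", "all_other"),
                        label = NULL) {
  comparator <- match.arg(comparator)
  is_code <- grepl("^[A-Z]", entity) && nchar(entity) %in% ATC_LEVEL_NCHAR &&
    grepl("^[A-Z][0-9A-Z]*$", entity)
  key <- if (is_code) entity_key(mentions, level) else mentions$label
  in_entity <- !is.na(key) & key == entity
  if (!any(in_entity)) stop_pvror("entity '%s' has no mentions", entity)
  is_case <- mentions$case_status == "case"
  a <- sum(in_entity & is_case)
  b <- sum(in_entity & !is_case)
  if (is.null(label)) {
    label <- if (is_code && level == 5) mentions$label[in_entity][1L] else entity
  }
  if (comparator == "siblings_within_parent") {
    if (!is_code) {
      stop_pvror(paste0("entity '%s' has no ATC code, so it has no parent ",
                        "class; use comparator = 'all_other'"), entity)
    }
    parent_level <- if (level == 5) 2L else 1L
    parent <- atc_ancestor(entity, parent_level)
    pkey <- entity_key(mentions, parent_level)
    in_parent <- !is.na(pkey) & pkey == parent
    cc <- sum(in_parent & is_case) - a
    dd <- sum(in_parent & !is_case) - b
    if (cc == 0 && dd == 0) {
      stop_pvror(paste0("entity '%s' is its entire parent class '%s': the ",
                        "sibling comparator is empty; use comparator = ",
                        "'all_other'"), entity, parent)
    }
  } else {
    tot <- mention_totals(mentions)
    cc <- tot$n_case_mentions - a
    dd <- tot$n_noncase_mentions - b
    if (cc == 0 && dd == 0) {
      stop_pvror("entity '%s' is the whole database: empty comparator", entity)
    }
  }
  contingency_table(a, b, cc, dd, entity = entity, level = level,
                    comparator = comparator, label = label)
}
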