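# Data model for individual case safety reports (ICSRs) and tabular I/O.
#
# Reports are held in a plain data.frame (class "icsr_df") with one row per
# report and list-columns for the multi-valued fields:
#   report_id    character, unique
#   report_date  Date (NA allowed)
#   reporter_hcp logical, NA = unknown reporter type
#   sex          character "F"/"M", NA = missing ("U" on input is normalized
#                to missing)
#   age_years    numeric in [0, 120], NA = missing
#   outcomes     list of character subsets of outcome_levels(); an EMPTY set
#                means the outcome classification is missing, it is not an
#                assertion that nothing happened
#   drugs        list of data.frames with columns atc5 (7-char ATC level-5
#                code or NA) and inn (substance name); deduplicated
#   reactions    list of non-empty character vectors of MedDRA Preferred
#                Terms

ATC5_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

ICSR_COLUMNS <- c("report_id", "report_date", "reporter_hcp", "sex",
                  "age_years", "outcomes", "drug_atc5_list", "drug_inn_list",
                  "reaction_pt_list")

#' Seriousness outcome vocabulary
#'
#' The fixed set of seriousness outcomes a report may carry (a report can
#' have several; an empty set marks the outcome classification as missing).
#'
#' @return character vector of the six outcome labels, in canonical order.
#' @export
outcome_levels <- function() {
  c("death", "hospitalization", "clinically_important",
    "life_threatening", "disability", "congenital_anomaly")
}

#' Construct a validated ICSR table
#'
#' Builds the canonical report container from parallel vectors/lists and
#' validates every invariant (unique ids, ATC pattern, age range, non-empty
#' drug and reaction lists). Drugs are deduplicated on (atc5, inn) within a
#' report; outcome sets are deduplicated and put in canonical order.
#'
#' @param report_id character vector of unique report identifiers.
#' @param drugs list of data.frames with columns `atc5`, `inn` (one per
#'   report), or a single data.frame recycled is NOT allowed.
#' @param reactions list of character vectors of reaction Preferred Terms.
#' @param report_date Date vector (or coercible), NA allowed.
#' @param reporter_hcp logical vector, NA = unknown.
#' @param sex character vector "F"/"M"/NA ("U" normalized to NA).
#' @param age_years numeric vector in \[0, 120\], NA = missing.
#' @param outcomes list of character vectors drawn from [outcome_levels()];
#'   empty = outcome missing.
#' @return a data.frame of class `icsr_df`.
#' @export
icsr_reports <- function(report_id, drugs, reactions,
                         report_date = as.Date(NA),
                         reporter_hcp = NA, sex = NA_character_,
                         age_years = NA_real_, outcomes = list(character(0))) {
  n <- length(report_id)
  recycle <- function(x) {
    if (length(x) == 1L && n > 1L) rep(x, n) else x
  }
  recycle_list <- function(x) {
    if (!is.list(x)) stop_pvror("expected a list")
    if (length(x) == 1L && n > 1L) rep(x, n) else x
  }
  df <- data.frame(report_id = as.character(report_id),
                   stringsAsFactors = FALSE)
  df$report_date <- as.Date(recycle(report_date))
  df$reporter_hcp <- as.logical(recycle(reporter_hcp))
  df$sex <- as.character(recycle(sex))
  df$age_years <- as.numeric(recycle(age_years))
  df$outcomes <- recycle_list(outcomes)
  df$drugs <- recycle_list(drugs)
  df$reactions <- recycle_list(reactions)
  canonicalize_reports(df)
}

# Normalize then validate; shared by the constructor and the CSV reader.
canonicalize_reports <- function(df) {
  df$sex[!is.na(df$sex) & df$sex == "U"] <- NA_character_
  df$sex[!is.na(df$sex) & df$sex == ""] <- NA_character_
  lev <- outcome_levels()
  df$outcomes <- lapply(df$outcomes, function(o) {
    o <- unique(as.character(o))
    o[order(match(o, lev))]
  })
  df$drugs <- lapply(df$drugs, function(d) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    d$atc5 <- as.character(d$atc5)
    d$atc5[!is.na(d$atc5) & d$atc5 == ""] <- NA_character_
    d$inn <- as.character(d$inn)
    d <- d[!duplicated(paste(ifelse(is.na(d$atc5), "", d$atc5), d$inn,
                             sep = "\r")), , drop = FALSE]
    rownames(d) <- NULL
    d[, c("atc5", "inn")]
  })
  df$reactions <- lapply(df$reactions, function(r) unique(as.character(r)))
  rownames(df) <- NULL
  validate_reports(df)
  class(df) <- c("icsr_df", "data.frame")
  df
}

#' Validate an ICSR table
#'
#' Checks every model invariant and raises an error naming the offending
#' row and value on the first violation.
#'
#' @param df a data.frame shaped like the output of [icsr_reports()].
#' @return the input, invisibly, if valid.
#' @export
validate_reports <- function(df) {
  dup <- duplicated(df$report_id)
  if (any(dup)) {
    stop_pvror("duplicate report_id '%s' (row %d)",
               df$report_id[dup][1L], which(dup)[1L])
  }
  if (any(!nzchar(df$report_id))) {
    stop_pvror("empty report_id (row %d)", which(!nzchar(df$report_id))[1L])
  }
  bad_sex <- !is.na(df$sex) & !df$sex %in% c("F", "M")
  if (any(bad_sex)) {
    stop_pvror("invalid sex '%s' (row %d)", df$sex[bad_sex][1L],
               which(bad_sex)[1L])
  }
  bad_age <- !is.na(df$age_years) &
    (df$age_years < 0 | df$age_years > 120)
  if (any(bad_age)) {
    stop_pvror("age_years %s out of [0, 120] (row %d)",
               format(df$age_years[bad_age][1L]), which(bad_age)[1L])
  }
  lev <- outcome_levels()
  for (i in seq_len(nrow(df))) {
    o <- df$outcomes[[i]]
    bad <- setdiff(o, lev)
    if (length(bad)) {
      stop_pvror("unknown outcome '%s' (row %d, report %s)", bad[1L], i,
                 df$report_id[i])
    }
    d <- df$drugs[[i]]
    if (is.null(d) || nrow(d) == 0L) {
      stop_pvror("empty drug list (row %d, report %s)", i, df$report_id[i])
    }
    bad_atc <- !is.na(d$atc5) & !grepl(ATC5_PATTERN, d$atc5)
    if (any(bad_atc)) {
      stop_pvror("malformed ATC5 code '%s' (row %d, report %s)",
                 d$atc5[bad_atc][1L], i, df$report_id[i])
    }
    r <- df$reactions[[i]]
    if (length(r) == 0L || all(!nzchar(r))) {
      stop_pvror("empty reaction list (row %d, report %s)", i,
                 df$report_id[i])
    }
  }
  invisible(df)
}

#' Read ICSRs from CSV
#'
#' Reads the flat one-row-per-report CSV format: columns `report_id`,
#' `report_date` (ISO-8601), `reporter_hcp` (true/false/empty), `sex`
#' (F/M/U/empty), `age_years`, `outcomes`, `drug_atc5_list`,
#' `drug_inn_list`, `reaction_pt_list`. Multi-valued cells are
#' "|"-separated with backslash escaping; empty cells are the missing
#' markers. `drug_atc5_list` and `drug_inn_list` must be element-wise
#' parallel (an empty element means the ATC5 code is missing for that
#' drug).
#'
#' @param path file path of the CSV.
#' @param date_from,date_to optional ISO dates; when given, reports are
#'   restricted to the inclusive window (reports with a missing date are
#'   dropped by the filter).
#' @return a validated `icsr_df`.
#' @export
read_reports <- function(path, date_from = NULL, date_to = NULL) {
  if (!file.exists(path)) stop_pvror("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(ICSR_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_pvror("missing required column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  parse_lgl <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "1", "t", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "0", "f", "no")] <- FALSE
    out
  }
  df <- data.frame(report_id = raw$report_id, stringsAsFactors = FALSE)
  df$report_date <- as.Date(ifelse(nzchar(raw$report_date),
                                   raw$report_date, NA))
  df$reporter_hcp <- parse_lgl(raw$reporter_hcp)
  df$sex <- ifelse(nzchar(raw$sex), raw$sex, NA_character_)
  df$age_years <- suppressWarnings(
    as.numeric(ifelse(nzchar(raw$age_years), raw$age_years, NA)))
  bad_age <- nzchar(raw$age_years) & is.na(df$age_years)
  if (any(bad_age)) {
    stop_pvror("non-numeric age_years '%s' (row %d)",
               raw$age_years[bad_age][1L], which(bad_age)[1L])
  }
  df$outcomes <- lapply(raw$outcomes, split_listcell)
  atc <- lapply(raw$drug_atc5_list, split_listcell)
  inn <- lapply(raw$drug_inn_list, split_listcell)
  df$drugs <- vector("list", n)
  for (i in seq_len(n)) {
    a <- atc[[i]]
    s <- inn[[i]]
    if (length(a) == 0L && length(s) > 0L) a <- rep("", length(s))
    if (length(a) != length(s)) {
      stop_pvror(paste0("drug_atc5_list and drug_inn_list lengths differ ",
                        "(%d vs %d) in row %d"), length(a), length(s), i)
    }
    df$drugs[[i]] <- data.frame(atc5 = ifelse(nzchar(a), a, NA_character_),
                                inn = s, stringsAsFactors = FALSE)
  }
  df$reactions <- lapply(raw$reaction_pt_list, split_listcell)
  df <- canonicalize_reports(df)
  if (!is.null(date_from) || !is.null(date_to)) {
    keep <- !is.na(df$report_date)
    if (!is.null(date_from)) keep <- keep & df$report_date >= as.Date(date_from)
    if (!is.null(date_to)) keep <- keep & df$report_date <= as.Date(date_to)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("icsr_df", "data.frame")
  }
  df
}

#' Write ICSRs to CSV
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(x, p))` equals
#' `x` (value equality; float formatting aside).
#'
#' @param reports an `icsr_df`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  fmt_num <- function(x) ifelse(is.na(x), "",
                                formatC(x, format = "g", digits = 15))
  out <- data.frame(
    report_id = reports$report_id,
    report_date = ifelse(is.na(reports$report_date), "",
                         format(reports$report_date, "%Y-%m-%d")),
    reporter_hcp = ifelse(is.na(reports$reporter_hcp), "",
                          ifelse(reports$reporter_hcp, "true", "false")),
    sex = ifelse(is.na(reports$sex), "", reports$sex),
    age_years = fmt_num(reports$age_years),
    outcomes = vapply(reports$outcomes, join_listcell, character(1)),
    drug_atc5_list = vapply(reports$drugs,
                            function(d) join_listcell(d$atc5), character(1)),
    drug_inn_list = vapply(reports$drugs,
                           function(d) join_listcell(d$inn), character(1)),
    reaction_pt_list = vapply(reports$reactions, join_listcell, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- ATC hierarchy ---------------------------------------------------------

ATC_LEVEL_NCHAR <- c(1L, 3L, 4L, 5L, 7L)  # level 1..5 code lengths

#' ATC level of a code
#'
#' The Anatomical Therapeutic Chemical classification encodes its five
#' levels by code length: 1 char (anatomical group), 3 (therapeutic
#' subgroup), 4, 5, and 7 (chemical substance).
#'
#' @param code character vector of ATC codes.
#' @return integer vector of levels 1..5.
#' @export
atc_level <- function(code) {
  lv <- match(nchar(code), ATC_LEVEL_NCHAR)
  bad <- is.na(lv) & !is.na(code)
  if (any(bad)) {
    stop_pvror("invalid ATC code length: '%s'", code[bad][1L])
  }
  lv
}

#' Ancestor of an ATC code at a chosen level
#'
#' Ancestor extraction is prefix truncation: the ATC2 (therapeutic
#' subgroup) of "B01AE07" is "B01", its ATC1 is "B". Requesting a level
#' deeper than the code itself is an error; requesting the code's own
#' level is the identity.
#'
#' @param code character vector of ATC codes.
#' @param level target level, integer in 1..5.
#' @return character vector of ancestor codes.
#' @export
atc_ancestor <- function(code, level) {
  if (!level %in% 1:5) stop_pvror("level must be in 1..5, got %s", level)
  lv <- atc_level(code)
  if (any(lv < level, na.rm = TRUE)) {
    bad <- code[!is.na(lv) & lv < level][1L]
    stop_pvror("cannot take the level-%d ancestor of '%s' (level %d)",
               level, bad, atc_level(bad))
  }
  substr(code, 1L, ATC_LEVEL_NCHAR[level])
}
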