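# Case/non-case classification against an SMQ Preferred-Term list.
#
# A report is a case iff at least one of its reaction Preferred Terms is a
# member of the SMQ term set. Matching is exact on normalized strings
# (trimmed, case-folded) — never substring or fuzzy: the SMQ is a curated
# list and approximate matching would silently change case counts.

normalize_pt <- function(x) tolower(trimws(x))

#' Load an SMQ term list
#'
#' Reads a plain-text Standardised MedDRA Query definition: one Preferred
#' Term per line, UTF-8, `#`-prefixed comments and blank lines ignored.
#' Terms are normalized (trimmed, case-folded) and deduplicated.
#'
#' @param path file path.
#' @param name SMQ name carried for provenance (e.g. "Acute renal failure").
#' @param scope "narrow" or "broad"; carried as metadata only — it selects
#'   which term file the analyst loads, it does not change matching.
#' @return an object of class `smq`: list with `name`, `scope`, `terms`
#'   (normalized match keys) and `raw_terms` (as read, deduplicated).
#' @export
load_smq <- function(path, name = basename(path),
                     scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  if (!file.exists(path)) stop_pvror("SMQ file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  smq_definition(lines, name = name, scope = scope)
}

#' Build an SMQ definition from a character vector of terms
#'
#' @param terms character vector of Preferred Terms.
#' @inheritParams load_smq
#' @return an `smq` object.
#' @export
smq_definition <- function(terms, name = "custom", scope = "narrow") {
  raw <- unique(trimws(as.character(terms)))
  raw <- raw[nzchar(raw)]
  keys <- unique(normalize_pt(raw))
  if (length(keys) == 0L) {
    stop_pvror("SMQ '%s' has no terms after normalization", name)
  }
  structure(list(name = name, scope = scope, terms = keys, raw_terms = raw),
            class = "smq")
}

#' @export
print.smq <- function(x, ...) {
  cat(sprintf("SMQ '%s' (%s scope): %d preferred terms\n",
              x$name, x$scope, length(x$terms)))
  invisible(x)
}

#' Classify reports as case / non-case
#'
#' @param reports an `icsr_df`.
#' @param smq an `smq` object.
#' @return logical vector: TRUE where the report is a case (at least one
#'   reaction PT in the SMQ term set).
#' @export
classify_reports <- function(reports, smq) {
  stopifnot(inherits(smq, "smq"))
  vapply(reports$reactions,
         function(r) any(normalize_pt(r) %in% smq$terms),
         logical(1))
}

#' Partition reports into cases and non-cases
#'
#' Splits the database into the two disjoint strata of the case/non-case
#' design; row order within each stratum is preserved, and
#' `nrow(cases) + nrow(noncases) == nrow(reports)` always.
#'
#' @inheritParams classify_reports
#' @return list with elements `cases` and `noncases`, both `icsr_df`.
#' @export
classify_all <- function(reports, smq) {
  is_case <- classify_reports(reports, smq)
  split_df <- function(keep) {
    out <- reports[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("icsr_df", "data.frame")
    out
  }
  list(cases = split_df(is_case), noncases = split_df(!is_case))
}
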