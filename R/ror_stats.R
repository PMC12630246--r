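# Statistical core: Haldane zero-cell correction, reporting odds ratio
# with Woolf (log-method) confidence interval, a-priori signal criteria,
# and the cohort descriptive tests.

#' Haldane zero-cell correction
#'
#' If any cell of the 2x2 table is zero, 0.5 is added to ALL FOUR cells
#' (the conservative variant, not zero-cells-only) and the table is marked
#' corrected; otherwise the table is returned unchanged. The
#' pre-correction case-mention count is preserved for the signal
#' criterion.
#'
#' @param table a `contingency_table`.
#' @return the (possibly corrected) `contingency_table`.
#' @export
haldane_adjust <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    table$a <- table$a + 0.5
    table$b <- table$b + 0.5
    table$c <- table$c + 0.5
    table$d <- table$d + 0.5
    table$corrected <- TRUE
  }
  table
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a d) / (b c); the CI is the Woolf / log method,
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. All cells must be
#' strictly positive — apply [haldane_adjust()] first when a cell can be
#' zero. Full precision is kept internally; rounding (half-up, 2 decimals)
#' happens only in [format()]/printing.
#'
#' @param table a `contingency_table` with all cells > 0.
#' @param z normal quantile for the CI (default 1.96, the 95% level).
#' @return object of class `ror_result`: entity metadata, the (possibly
#'   corrected) cells, `ror`, `ci_low`, `ci_high`, `se_log`, `z`,
#'   `corrected`, and `n_case_mentions` (the pre-correction `a`).
#' @export
compute_ror <- function(table, z = 1.96) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells <= 0)) {
    stop_pvror(paste0("cell(s) <= 0 in table for '%s'; apply haldane_adjust()",
                      " before compute_ror()"), format(table$entity))
  }
  ror <- (table$a * table$d) / (table$b * table$c)
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  structure(list(entity = table$entity, label = table$label,
                 level = table$level, comparator = table$comparator,
                 a = table$a, b = table$b, c = table$c, d = table$d,
                 ror = ror,
                 ci_low = exp(log(ror) - z * se),
                 ci_high = exp(log(ror) + z * se),
                 se_log = se, z = z,
                 corrected = table$corrected,
                 n_case_mentions = table$n_case_mentions),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("%s (level %s, %s): ROR %.2f [%.2f-%.2f]%s, %d case mentions\n",
              x$label, format(x$level), format(x$comparator),
              round_half_up(x$ror, 2), round_half_up(x$ci_low, 2),
              round_half_up(x$ci_high, 2),
              if (x$corrected) " (Haldane-corrected)" else "",
              x$n_case_mentions))
  invisible(x)
}

#' A-priori signal criteria
#'
#' The default thresholds flag an entity when ROR >= 2, the lower 95% CI
#' bound is strictly above 1, and the entity was suspected in at least 5
#' cases.
#'
#' @param min_ror minimum ROR (inclusive).
#' @param min_ci_low the lower CI bound must exceed this (strict).
#' @param min_cases minimum pre-correction case-mention count (inclusive).
#' @return list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_ror = 2, min_ci_low = 1, min_cases = 5) {
  if (min_ror <= 0 || min_ci_low <= 0 || min_cases <= 0) {
    stop_pvror("signal criteria thresholds must be positive")
  }
  structure(list(min_ror = min_ror, min_ci_low = min_ci_low,
                 min_cases = as.integer(min_cases)),
            class = "signal_criteria")
}

#' Evaluate the signal criteria on a ROR result
#'
#' Comparisons use the unrounded estimates and the PRE-correction case
#' count. All three conditions are independently binding.
#'
#' @param result a `ror_result`.
#' @param criteria a [signal_criteria()] object.
#' @return TRUE iff the result is a signal.
#' @export
evaluate_signal <- function(result, criteria = signal_criteria()) {
  stopifnot(inherits(result, "ror_result"))
  result$ror >= criteria$min_ror &&
    result$ci_low > criteria$min_ci_low &&
    result$n_case_mentions >= criteria$min_cases
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic on an r x k table of counts — no continuity
#' correction, expected counts from the row/column margins, df =
#' (r-1)(k-1). The p-value comes from the chi-square reference
#' distribution.
#'
#' @param table numeric matrix of non-negative counts.
#' @return list(statistic, df, p).
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop_pvror("counts must be finite and non-negative")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop_pvror("zero row or column margin: statistic undefined")
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sample t-test with equal variances, from summary statistics
#'
#' Pooled-variance t statistic computed from means, SDs and group sizes
#' (the form needed when only published summaries are available);
#' df = n1 + n2 - 2, two-sided p.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list(t, df, p).
#' @export
two_sample_t_equal_var <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_pvror("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_pvror("standard deviations must be > 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Percentage, rounded half-up to one decimal
#'
#' @param numerator,denominator non-negative integers,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator` rounded half-up to 1 decimal.
#' @export
proportion_pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_pvror("denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop_pvror("numerator must be in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Disproportionality results for every eligible entity
#'
#' Convenience wrapper running the eligibility filter, table construction,
#' Haldane correction, ROR estimation and signal evaluation over a mention
#' table at one ATC level.
#'
#' @param mentions a `mention_table`.
#' @param level 2 or 5.
#' @param comparator comparator strategy passed to [build_table()].
#' @param min_cases eligibility threshold (also the default case-count
#'   signal criterion).
#' @param z CI quantile.
#' @param criteria [signal_criteria()] used for flagging.
#' @return data.frame: entity, label, level, comparator, a, b, c, d
#'   (post-correction), corrected, ror, ci_low, ci_high,
#'   n_case_mentions, signal, note (non-empty when a table could not be
#'   built, e.g. an empty sibling comparator; its estimates are NA).
#' @export
ror_table <- function(mentions, level = 5,
                      comparator = c("siblings_within_parent", "all_other"),
                      min_cases = 5, z = 1.96,
                      criteria = signal_criteria(min_cases = min_cases)) {
  comparator <- match.arg(comparator)
  eligible <- filter_min_cases(mentions, level = level, min_cases = min_cases)
  rows <- lapply(seq_len(nrow(eligible)), function(i) {
    ent <- eligible$entity[i]
    res <- tryCatch({
      ct <- build_table(mentions, ent, level = level, comparator = comparator)
      compute_ror(haldane_adjust(ct), z = z)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(entity = ent, label = eligible$label[i], level = level,
                 comparator = comparator, a = NA_real_, b = NA_real_,
                 c = NA_real_, d = NA_real_, corrected = NA,
                 ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 n_case_mentions = eligible$n_case_mentions[i],
                 signal = FALSE, note = res, stringsAsFactors = FALSE)
    } else {
      data.frame(entity = ent, label = res$label, level = level,
                 comparator = comparator, a = res$a, b = res$b, c = res$c,
                 d = res$d, corrected = res$corrected, ror = res$ror,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 n_case_mentions = res$n_case_mentions,
                 signal = evaluate_signal(res, criteria), note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(entity = character(0), label = character(0),
                      level = integer(0), comparator = character(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      d = numeric(0), corrected = logical(0),
                      ror = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), n_case_mentions = integer(0),
                      signal = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}
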