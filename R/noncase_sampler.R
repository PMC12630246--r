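# Seeded random sampling of non-cases at a fixed ratio per case, without
# replacement. The design is unmatched simple random sampling: no
# stratification or matching variables.

#' Sample non-cases at a fixed ratio per case
#'
#' Draws exactly `ratio * n_cases` distinct non-case reports uniformly at
#' random without replacement. The draw is fully determined by
#' `(input order, seed)` — R's default Mersenne-Twister stream seeded with
#' `seed` — so a published run is replayable; the result is sorted by
#' `report_id` for stable downstream output. The caller's RNG state is
#' left untouched.
#'
#' @param noncases an `icsr_df` (or any data.frame with a `report_id`
#'   column) holding the full non-case pool.
#' @param n_cases number of cases the sample is matched to in size.
#' @param ratio non-cases drawn per case (default 4).
#' @param seed integer RNG seed; required for reproducibility.
#' @return the sampled rows of `noncases`, sorted by `report_id`, with
#'   attributes `sampling_plan` (ratio, seed, pool_size, n_cases).
#' @export
sample_noncases <- function(noncases, n_cases, ratio = 4, seed) {
  if (missing(seed)) stop_pvror("a seed is required for non-case sampling")
  if (ratio < 1 || ratio != as.integer(ratio)) {
    stop_pvror("ratio must be a positive integer, got %s", format(ratio))
  }
  size <- as.integer(ratio) * as.integer(n_cases)
  pool <- nrow(noncases)
  if (size > pool) {
    stop_pvror("non-case pool too small: need %d (= %d cases x ratio %d) but only %d available",
               size, n_cases, ratio, pool)
  }
  idx <- with_seed(seed, sample.int(pool, size))
  out <- noncases[idx, , drop = FALSE]
  out <- out[order(out$report_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(noncases)
  attr(out, "sampling_plan") <- list(ratio = as.integer(ratio),
                                     seed = as.integer(seed),
                                     pool_size = pool,
                                     n_cases = as.integer(n_cases))
  out
}
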