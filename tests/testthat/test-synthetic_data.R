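test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- synthetic_config(n_reports = 300, seed = 13)
  set.seed(1)
  before <- .Random.seed
  a <- generate_database(cfg)
  expect_identical(.Random.seed, before)
  b <- generate_database(cfg)
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth, b$truth)
  c <- generate_database(synthetic_config(n_reports = 300, seed = 14))
  expect_false(identical(a$reports, c$reports))
  # byte-identical on disk
  p1 <- tempfile(); p2 <- tempfile()
  write_reports(a$reports, p1); write_reports(b$reports, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("case counts follow the configured fraction", {
  # Bernoulli status: within central 99% binomial bounds
  cfg <- synthetic_config(n_reports = 1760, case_fraction = 0.2, seed = 21)
  db <- generate_database(cfg)
  n_cases <- sum(db$truth$case_status)
  bounds <- stats::qbinom(c(0.005, 0.995), 1760, 0.2)
  expect_gte(n_cases, bounds[1])
  expect_lte(n_cases, bounds[2])
  # exact mode pins the count
  db2 <- generate_database(preset_config("sampled", seed = 21))
  expect_identical(sum(db2$truth$case_status), 352L)
})

test_that("reports satisfy every model invariant by construction", {
  db <- generate_database(preset_config("sampled", seed = 3))
  expect_silent(validate_reports(db$reports))
  expect_identical(nrow(db$reports), 1760L)
  # cases carry an SMQ term, non-cases never do
  is_case <- classify_reports(db$reports, fixture_smq())
  expect_identical(unname(is_case), unname(db$truth$case_status))
  # dates inside the window
  expect_true(all(db$reports$report_date >= as.Date("2009-01-01") &
                    db$reports$report_date <= as.Date("2020-12-31")))
})

test_that("drugs-per-report marginals match the configured distribution", {
  dist <- c(0.70, 0.15, 0.08, 0.04, 0.03)
  p_gof <- vapply(1:4, function(seed) {
    cfg <- synthetic_config(n_reports = 1500, drugs_per_report_dist = dist,
                            seed = seed)
    db <- generate_database(cfg)
    k <- pmin(vapply(db$reports$drugs, nrow, integer(1)), 5L)
    obs <- vapply(1:5, function(j) sum(k == j), integer(1))
    stats::chisq.test(obs, p = dist)$p.value
  }, numeric(1))
  expect_true(all(p_gof > 0.001))
})

test_that("demographics and missingness track the per-stratum parameters", {
  cfg <- preset_config("sampled", seed = 8)
  db <- generate_database(cfg)
  case <- db$reports[db$truth$case_status, ]
  noncase <- db$reports[!db$truth$case_status, ]
  # missing age ~ 42.6% in cases vs 22.7% in non-cases
  expect_equal(mean(is.na(case$age_years)), 0.426, tolerance = 0.12)
  expect_equal(mean(is.na(noncase$age_years)), 0.227, tolerance = 0.12)
  # age means separated in the planted direction
  expect_gt(mean(case$age_years, na.rm = TRUE),
            mean(noncase$age_years, na.rm = TRUE))
  # female share lower among cases
  expect_lt(mean(case$sex == "F", na.rm = TRUE),
            mean(noncase$sex == "F", na.rm = TRUE))
  # outcome classification mostly present in cases, often absent otherwise
  expect_gt(mean(lengths(noncase$outcomes) == 0),
            mean(lengths(case$outcomes) == 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(case_fraction = 0), "case_fraction")
  expect_error(synthetic_config(planted = c(ZZZ9999 = 2)), "not in the catalog")
  expect_error(synthetic_config(planted = c(B01AE07 = -1)), "must be > 0")
  expect_error(synthetic_config(p_female = c(1.2, 0.5)), "probabilities")
  small_cat <- default_drug_catalog()[1:4, ]
  expect_error(synthetic_config(drug_catalog = small_cat), "catalog too small")
  expect_error(synthetic_config(noise_pts = c("Anuria", "Rash")), "disjoint")
})

test_that("truth sidecar round-trips through JSON", {
  db <- generate_database(synthetic_config(n_reports = 50, seed = 2,
                                           planted = c(B01AE07 = 4)))
  path <- tempfile(fileext = ".json")
  write_truth(db$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$planted$B01AE07, 4)
  expect_identical(length(back$case_status), 50L)
  expect_equal(unlist(back$case_status[["R000001"]]),
               unname(db$truth$case_status["R000001"]))
})

test_that("a strong planted association is detected with high power", {
  # multiplier 10 with ~20+ expected case mentions: the three-part
  # criterion should flag in essentially every replicate
  cfg <- synthetic_config(n_reports = 600, case_fraction = 1 / 6,
                          exact_case_count = TRUE,
                          planted = c(J01XA01 = 10), seed = 17)
  oc <- evaluate_operating_characteristics(cfg, n_reps = 10, seed = 1700)
  expect_gt(oc$power$power, 0.9)
})

test_that("with no planted effect the estimated log-ROR centers on zero", {
  lr <- vapply(1:30, function(rep) {
    cfg <- synthetic_config(n_reports = 2000, case_fraction = 1 / 6,
                            exact_case_count = TRUE, seed = 4000 + rep)
    db <- generate_database(cfg)
    parts <- classify_all(db$reports, fixture_smq())
    sampled <- sample_noncases(parts$noncases, nrow(parts$cases), 4,
                               seed = 4100 + rep)
    m <- expand_mentions(parts$cases, sampled)
    # paracetamol: the catalogue's most-mentioned null drug
    log(compute_ror(haldane_adjust(
      build_table(m, "N02BE01", 5, "all_other")))$ror)
  }, numeric(1))
  se <- stats::sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr)), 3 * se)
})

test_that("operating characteristics degenerate correctly at n_reps = 1", {
  cfg <- synthetic_config(n_reports = 600, case_fraction = 1 / 6,
                          exact_case_count = TRUE,
                          planted = c(J01XA01 = 9), seed = 5)
  oc <- evaluate_operating_characteristics(cfg, n_reps = 1)
  expect_true(oc$power$power %in% c(0, 1))
  expect_true(is.na(oc$type1_rate) ||
                (oc$type1_rate >= 0 && oc$type1_rate <= 1))
  expect_identical(oc$power$multiplier, 9)
})
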