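# Synthetic ICSR generator with known ground truth.
#
# The generator emulates the structure of a national spontaneous-reporting
# extract: rare cases among many reports, multi-drug reports with a heavy
# single-drug mode, multi-label seriousness outcomes, and substantial
# sex/age/outcome missingness that differs between cases and non-cases.
# Planted drug-event associations act multiplicatively on a drug's
# mention odds conditional on case status, so the implied population ROR
# equals the configured multiplier and parameter-recovery tests are
# well-defined.

#' Synthetic SMQ term list used by the generator
#'
#' A small synthetic stand-in for a narrow acute-renal-failure SMQ; it is
#' NOT licensed MedDRA content, just five plausible renal Preferred
#' Terms used to tag generated case reports.
#'
#' @return character vector of 5 terms.
#' @export
synthetic_smq_terms <- function() {
  c("Acute kidney injury", "Renal failure", "Anuria", "Oliguria",
    "Renal impairment")
}

# Background reaction vocabulary for non-case (and extra case) PTs;
# disjoint from the synthetic SMQ by construction.
default_noise_pts <- function() {
  c("Nausea", "Headache", "Rash", "Dizziness", "Pruritus", "Vomiting",
    "Diarrhoea", "Pyrexia", "Fatigue", "Urticaria", "Dyspnoea", "Cough",
    "Myalgia", "Arthralgia", "Somnolence", "Insomnia", "Anaemia",
    "Hypotension", "Hypertension", "Abdominal pain", "Constipation",
    "Oedema peripheral", "Tremor", "Palpitations")
}

#' Default synthetic drug catalogue
#'
#' Twenty-five substances spanning the ATC classes typically seen in
#' renal-safety analyses, with relative baseline mention weights shaped
#' like a real reporting database (a few very common drugs, a long tail).
#'
#' @return data.frame with columns `atc5`, `inn`, `baseline_prob`
#'   (relative sampling weight of the drug among suspected-drug slots).
#' @export
default_drug_catalog <- function() {
  data.frame(
    atc5 = c("A10BA02", "A10BH01", "B01AC06", "B01AE07", "C03CA01",
             "C09CA03", "C10AA01", "H02AB06", "J01CA04", "J01XA01",
             "J02AA01", "J05AF07", "J05AF09", "J05AG03", "J05AP08",
             "L01EB02", "L01EG02", "L01EX01", "L04AA06", "L04AB04",
             "L04AD01", "L04AD02", "M01AE01", "N02BE01", "V03AC03"),
    inn = c("metformin", "sitagliptin", "acetylsalicylic acid",
            "dabigatran etexilate", "furosemide", "valsartan",
            "simvastatin", "prednisolone", "amoxicillin", "vancomycin",
            "amphotericin B", "tenofovir disoproxil", "emtricitabine",
            "efavirenz", "sofosbuvir", "erlotinib", "everolimus",
            "sunitinib", "mycophenolic acid", "adalimumab", "ciclosporin",
            "tacrolimus", "ibuprofen", "paracetamol", "deferasirox"),
    baseline_prob = c(20, 5, 25, 19, 6, 8, 10, 12, 40, 6, 4, 20, 14, 10,
                      12, 6, 5, 4, 8, 25, 5, 6, 30, 35, 3),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Parameters of the synthetic ICSR database. Per-status parameters are
#' length-2 vectors `(case, noncase)`. Defaults describe a sampled-cohort
#' scale database (1,760 reports, 20% cases) whose demographic and
#' missingness structure mirrors a published national AKI case/non-case
#' cohort: female share 46.1%/60.9%, age 59.56+-21.6 vs 50.00+-22.1 with
#' 42.6%/22.7% missing age, 8.8%/3.9% missing sex, outcome classification
#' missing in 4.8%/30.5%, and a drugs-per-report distribution with
#' 67.6%/82.5% single-drug reports.
#'
#' @param n_reports total reports to generate.
#' @param case_fraction expected case share.
#' @param exact_case_count if TRUE the case count is exactly
#'   `round(n_reports * case_fraction)` (which reports are cases is still
#'   random); if FALSE case status is i.i.d. Bernoulli.
#' @param drug_catalog data.frame as [default_drug_catalog()].
#' @param planted named numeric vector of true odds multipliers by ATC5;
#'   drugs not named have multiplier 1 (null).
#' @param drugs_per_report_dist probabilities over 1..5+ suspected drugs:
#'   a length-5 vector, or a 2 x 5 matrix with rows (case, noncase).
#' @param p_female,p_hcp per-status probabilities.
#' @param age_mean_case,age_mean_noncase,age_sd age model (years); `age_sd`
#'   may be length 2.
#' @param missing_age_rate,missing_sex_rate,missing_outcome_rate per-status
#'   missingness rates.
#' @param outcome_probs 6 x 2 matrix of per-outcome probabilities
#'   (rows = [outcome_levels()], columns = case, noncase), conditional on
#'   the outcome classification being present.
#' @param smq_terms Preferred Terms marking generated cases.
#' @param noise_pts background reaction vocabulary (disjoint from
#'   `smq_terms`).
#' @param date_range length-2 character ISO dates of the reporting window.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 1760,
                             case_fraction = 0.2,
                             exact_case_count = FALSE,
                             drug_catalog = default_drug_catalog(),
                             planted = numeric(0),
                             drugs_per_report_dist = rbind(
                               case = c(0.676, 0.185, 0.091, 0.023, 0.025),
                               noncase = c(0.825, 0.121, 0.031, 0.011, 0.012)),
                             p_female = c(0.461, 0.609),
                             p_hcp = c(0.966, 0.90),
                             age_mean_case = 59.56,
                             age_mean_noncase = 50.00,
                             age_sd = c(21.6, 22.1),
                             missing_age_rate = c(0.426, 0.227),
                             missing_sex_rate = c(0.088, 0.039),
                             missing_outcome_rate = c(0.048, 0.305),
                             outcome_probs = cbind(
                               case = c(0.096, 0.508, 0.642, 0.078, 0.030,
                                        0.003),
                               noncase = c(0.071, 0.267, 0.653, 0.084, 0.087,
                                           0.001)),
                             smq_terms = synthetic_smq_terms(),
                             noise_pts = default_noise_pts(),
                             date_range = c("2009-01-01", "2020-12-31"),
                             seed = 1L) {
  two <- function(x) if (length(x) == 1L) c(x, x) else x
  if (is.null(dim(drugs_per_report_dist))) {
    drugs_per_report_dist <- rbind(case = drugs_per_report_dist,
                                   noncase = drugs_per_report_dist)
  }
  drugs_per_report_dist <- drugs_per_report_dist /
    rowSums(drugs_per_report_dist)
  cfg <- list(n_reports = as.integer(n_reports),
              case_fraction = case_fraction,
              exact_case_count = isTRUE(exact_case_count),
              drug_catalog = drug_catalog,
              planted = planted,
              drugs_per_report_dist = drugs_per_report_dist,
              p_female = two(p_female), p_hcp = two(p_hcp),
              age_mean_case = age_mean_case,
              age_mean_noncase = age_mean_noncase,
              age_sd = two(age_sd),
              missing_age_rate = two(missing_age_rate),
              missing_sex_rate = two(missing_sex_rate),
              missing_outcome_rate = two(missing_outcome_rate),
              outcome_probs = outcome_probs,
              smq_terms = smq_terms, noise_pts = noise_pts,
              date_range = as.Date(date_range),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_reports < 1) stop_pvror("n_reports must be >= 1")
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1) {
    stop_pvror("case_fraction must be in (0, 1)")
  }
  if (!all(c("atc5", "inn", "baseline_prob") %in% names(cfg$drug_catalog))) {
    stop_pvror("drug_catalog needs columns atc5, inn, baseline_prob")
  }
  if (any(cfg$drug_catalog$baseline_prob <= 0)) {
    stop_pvror("baseline_prob weights must be > 0")
  }
  if (length(cfg$planted)) {
    missing_drug <- setdiff(names(cfg$planted), cfg$drug_catalog$atc5)
    if (length(missing_drug)) {
      stop_pvror("planted drug '%s' is not in the catalog", missing_drug[1L])
    }
    if (any(cfg$planted <= 0)) stop_pvror("planted multipliers must be > 0")
  }
  probs <- c(cfg$p_female, cfg$p_hcp, cfg$missing_age_rate,
             cfg$missing_sex_rate, cfg$missing_outcome_rate,
             cfg$outcome_probs)
  if (any(probs < 0) || any(probs > 1)) {
    stop_pvror("all probabilities must be in [0, 1]")
  }
  if (nrow(cfg$outcome_probs) != length(outcome_levels())) {
    stop_pvror("outcome_probs needs one row per outcome level")
  }
  # drugs-per-report support cannot exceed the catalogue
  if (nrow(cfg$drug_catalog) < 8L) {
    stop_pvror("catalog too small: multi-drug reports can need up to 8 drugs")
  }
  if (length(cfg$smq_terms) == 0L) stop_pvror("smq_terms must be non-empty")
  if (any(normalize_pt(cfg$noise_pts) %in% normalize_pt(cfg$smq_terms))) {
    stop_pvror("noise_pts must be disjoint from smq_terms")
  }
  invisible(cfg)
}

#' Preset generator configurations
#'
#' `"sampled"` is the post-sampling cohort scale (1,760 reports, exactly
#' 352 cases); `"full"` is the full database scale (53,505 reports,
#' exactly 352 cases). Both plant three associations — dabigatran
#' etexilate (odds multiplier 3.2), tenofovir disoproxil (3.8) and
#' vancomycin (9) — spanning the moderate-to-strong range reported for
#' drug-induced AKI.
#'
#' @param scale `"sampled"` or `"full"`.
#' @param seed RNG seed.
#' @return a [synthetic_config()].
#' @export
preset_config <- function(scale = c("sampled", "full"), seed = 1L) {
  scale <- match.arg(scale)
  planted <- c(B01AE07 = 3.2, J05AF07 = 3.8, J01XA01 = 9)
  if (scale == "sampled") {
    synthetic_config(n_reports = 1760, case_fraction = 352 / 1760,
                     exact_case_count = TRUE, planted = planted, seed = seed)
  } else {
    synthetic_config(n_reports = 53505, case_fraction = 352 / 53505,
                     exact_case_count = TRUE, planted = planted, seed = seed)
  }
}

# Systematic probability-proportional-to-size draw of k distinct items:
# inclusion probability of item j is exactly min(1, k * share_j) (after
# redistributing the capped excess), so a drug's expected mention count is
# k * share_j and the population mention-odds ratio of a planted drug
# equals its configured multiplier at every report size.
pps_draw <- function(shares, k) {
  m <- length(shares)
  if (k >= m) return(seq_len(m))
  pi <- k * shares
  for (iter in 1:10) {
    over <- pi >= 1
    if (!any(pi > 1)) break
    pi[over] <- 1
    rest <- k - sum(over)
    pi[!over] <- rest * shares[!over] / sum(shares[!over])
  }
  cum <- cumsum(pi)
  points <- stats::runif(1) + 0:(k - 1L)
  findInterval(points, cum, left.open = TRUE) + 1L
}

#' Generate a synthetic ICSR database
#'
#' Fully reproducible from `config$seed` (the caller's RNG state is
#' preserved). Case reports carry one SMQ term plus optional background
#' terms; non-cases carry background terms only, so an SMQ built from
#' `config$smq_terms` recovers the generated case status exactly. Each
#' report's suspected drugs are drawn without replacement from the
#' catalogue with weights `baseline_prob`, multiplied by the planted odds
#' multiplier for case reports.
#'
#' @param config a [synthetic_config()].
#' @return list with `reports` (an `icsr_df`) and `truth`: list with
#'   `planted` (named multipliers for the full catalogue) and
#'   `case_status` (named logical by report id).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cat_df <- config$drug_catalog
  m <- nrow(cat_df)
  mult <- rep(1, m)
  names(mult) <- cat_df$atc5
  if (length(config$planted)) mult[names(config$planted)] <- config$planted
  w_base <- cat_df$baseline_prob
  w_case <- w_base * mult

  with_seed(config$seed, {
    n <- config$n_reports
    if (config$exact_case_count) {
      n_case <- round(n * config$case_fraction)
      is_case <- rep(FALSE, n)
      is_case[sample.int(n, n_case)] <- TRUE
    } else {
      is_case <- stats::runif(n) < config$case_fraction
    }
    st <- ifelse(is_case, 1L, 2L)  # column index: 1 = case, 2 = noncase

    # drugs per report: categorical over 1..5+, 5+ = 5 plus a Poisson tail
    k <- integer(n)
    for (s in 1:2) {
      idx <- which(st == s)
      k[idx] <- sample.int(5L, length(idx), replace = TRUE,
                           prob = config$drugs_per_report_dist[s, ])
    }
    five_plus <- which(k == 5L)
    k[five_plus] <- pmin(5L + stats::rpois(length(five_plus), 0.4), 8L)

    # suspected drug draws, weighted without replacement within a report
    didx <- integer(sum(k))
    pos <- c(0L, cumsum(k))
    singles <- which(k == 1L)
    for (s in 1:2) {
      idx <- singles[st[singles] == s]
      if (length(idx)) {
        didx[pos[idx] + 1L] <- sample.int(
          m, length(idx), replace = TRUE,
          prob = if (s == 1L) w_case else w_base)
      }
    }
    multi <- which(k > 1L)
    share_case <- w_case / sum(w_case)
    share_base <- w_base / sum(w_base)
    for (i in multi) {
      didx[(pos[i] + 1L):pos[i + 1L]] <- pps_draw(
        if (st[i] == 1L) share_case else share_base, k[i])
    }
    drug_rows <- data.frame(atc5 = cat_df$atc5[didx],
                            inn = cat_df$inn[didx],
                            stringsAsFactors = FALSE)
    drugs <- split(drug_rows, factor(rep(seq_len(n), k),
                                     levels = seq_len(n)))
    names(drugs) <- NULL

    # reactions: cases get one SMQ term; everyone gets background noise
    n_noise <- stats::rpois(n, 0.7) + ifelse(is_case, 0L, 1L)
    noise_draws <- sample(config$noise_pts, sum(n_noise), replace = TRUE)
    noise_split <- split(noise_draws,
                         factor(rep(seq_len(n), n_noise), levels = seq_len(n)))
    smq_draw <- sample(config$smq_terms, n, replace = TRUE)
    reactions <- vector("list", n)
    for (i in seq_len(n)) {
      r <- unique(noise_split[[i]])
      if (is_case[i]) r <- c(smq_draw[i], r)
      reactions[[i]] <- r
    }

    sex <- ifelse(stats::runif(n) < config$p_female[st], "F", "M")
    sex[stats::runif(n) < config$missing_sex_rate[st]] <- NA_character_

    age_mean <- ifelse(is_case, config$age_mean_case, config$age_mean_noncase)
    age <- stats::rnorm(n, age_mean, config$age_sd[st])
    age <- round(pmin(pmax(age, 0), 120), 1)
    age[stats::runif(n) < config$missing_age_rate[st]] <- NA_real_

    hcp <- stats::runif(n) < config$p_hcp[st]

    outcomes <- rep(list(character(0)), n)
    present <- stats::runif(n) >= config$missing_outcome_rate[st]
    lev <- outcome_levels()
    todo <- which(present)
    tries <- 0L
    while (length(todo) && tries < 50L) {
      pm <- matrix(stats::runif(length(todo) * length(lev)),
                   nrow = length(todo))
      thr <- t(config$outcome_probs)[st[todo], , drop = FALSE]
      hitm <- pm < thr
      drawn <- lapply(seq_along(todo), function(j) lev[hitm[j, ]])
      got <- lengths(drawn) > 0L
      outcomes[todo[got]] <- drawn[got]
      todo <- todo[!got]
      tries <- tries + 1L
    }
    # astronomically unlikely fallback: keep the classification present
    outcomes[todo] <- list("clinically_important")

    days <- as.integer(config$date_range[2] - config$date_range[1])
    report_date <- config$date_range[1] +
      sample.int(days + 1L, n, replace = TRUE) - 1L

    report_id <- sprintf("R%06d", seq_len(n))
    reports <- data.frame(report_id = report_id, stringsAsFactors = FALSE)
    reports$report_date <- report_date
    reports$reporter_hcp <- hcp
    reports$sex <- sex
    reports$age_years <- age
    reports$outcomes <- outcomes
    reports$drugs <- drugs
    reports$reactions <- reactions
    reports <- canonicalize_reports(reports)

    truth <- list(planted = mult,
                  case_status = stats::setNames(is_case, report_id))
    list(reports = reports, truth = truth)
  })
}

#' Write the ground-truth sidecar file
#'
#' @param truth the `truth` element of [generate_database()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(planted = as.list(truth$planted),
                            case_status = as.list(truth$case_status)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Operating characteristics of the signal criteria
#'
#' Monte-Carlo estimate of the per-drug type-I error (fraction of
#' null-drug tests flagged) and per-planted-drug power of the three-part
#' signal criterion, under repeated generation, classification, 4:1
#' non-case sampling and drug-level disproportionality analysis.
#'
#' @param config a [synthetic_config()]; drugs with multiplier 1 are the
#'   null set.
#' @param criteria [signal_criteria()].
#' @param n_reps number of replicates.
#' @param ratio non-case sampling ratio.
#' @param comparator comparator for the drug-level tables; `all_other`
#'   (default) is the regime in which the planted multiplier equals the
#'   population ROR.
#' @param seed base seed; replicate r uses `seed + r` for generation and
#'   an offset stream for sampling.
#' @return list with `type1_rate`, `type1_se`, `n_null_tests`, and
#'   `power`: data.frame(atc5, multiplier, n_reps, power, se).
#' @export
evaluate_operating_characteristics <- function(config,
                                               criteria = signal_criteria(),
                                               n_reps = 50,
                                               ratio = 4,
                                               comparator = "all_other",
                                               seed = config$seed) {
  stopifnot(n_reps >= 1)
  smq <- smq_definition(config$smq_terms, name = "synthetic", scope = "narrow")
  planted_atc <- names(config$planted)[config$planted != 1]
  null_flags <- 0L
  null_tests <- 0L
  power_hits <- stats::setNames(numeric(length(planted_atc)), planted_atc)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    db <- generate_database(cfg)
    parts <- classify_all(db$reports, smq)
    sampled <- sample_noncases(parts$noncases, nrow(parts$cases),
                               ratio = ratio, seed = seed + 500000L + r)
    mentions <- expand_mentions(parts$cases, sampled)
    res <- ror_table(mentions, level = 5, comparator = comparator,
                     min_cases = criteria$min_cases, criteria = criteria)
    is_null <- !res$entity %in% planted_atc
    null_flags <- null_flags + sum(res$signal[is_null])
    null_tests <- null_tests + sum(is_null)
    hit <- planted_atc %in% res$entity[res$signal]
    power_hits[planted_atc[hit]] <- power_hits[planted_atc[hit]] + 1
  }
  type1 <- if (null_tests > 0) null_flags / null_tests else NA_real_
  pw <- power_hits / n_reps
  power <- data.frame(atc5 = character(0), multiplier = numeric(0),
                      n_reps = integer(0), power = numeric(0),
                      se = numeric(0), stringsAsFactors = FALSE)
  if (length(planted_atc)) {
    power <- data.frame(
      atc5 = planted_atc,
      multiplier = as.numeric(config$planted[planted_atc]),
      n_reps = as.integer(n_reps),
      power = as.numeric(pw),
      se = sqrt(pw * (1 - pw) / n_reps),
      stringsAsFactors = FALSE)
  }
  list(type1_rate = type1,
       type1_se = if (null_tests > 0)
         sqrt(type1 * (1 - type1) / null_tests) else NA_real_,
       n_null_tests = null_tests,
       power = power)
}
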