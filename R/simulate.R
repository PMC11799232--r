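# Synthetic spontaneous-reporting-system extracts with known ground truth.
#
# Generative model, per report (case):
#   * one PS drug drawn from the drug catalog weights; extra concomitant
#     drugs (roles SS/C/I) drawn independently;
#   * one guaranteed "index" event drawn from the event catalog
#     probabilities q (Zipf-shaped, mimicking the heavy tail of event
#     frequencies in spontaneous reports), plus independent per-PT
#     Bernoulli extras with probabilities p = (mean_events - 1) * q, so
#     every report carries at least one event and the marginal inclusion
#     probability of PT j is B_j = 1 - (1 - q_j)(1 - p_j);
#   * demographics (sex, age with missing mass, country, date) drawn
#     independently of drugs and events;
#   * a fraction of cases is emitted twice with an incremented version,
#     exercising the deduplication step.
#
# Planting a (drug g, pt j, rho) association replaces, for reports whose
# PS drug is g, the Bernoulli probability of j by p' chosen so the
# marginal inclusion becomes B' with odds(B') = rho * odds(B_j). Because
# only the target drug's arm is modified, the expected 2x2 table has
# ROR exactly rho (the comparator arm is untouched); PRR converges to rho
# for rare events. Infeasible targets (implied probability outside [0,1])
# are rejected at scenario construction.

#' Default drug catalog for the simulator
#'
#' Three triazole antifungals plus a background of drugs commonly
#' co-reported in immunocompromised populations, with PS-probability
#' weights summing to 1.
#'
#' @return Named numeric vector of PS-assignment weights.
#' @export
default_drug_catalog <- function() {
  c(
    voriconazole = 0.15, posaconazole = 0.04, isavuconazole = 0.02,
    fluconazole = 0.12, itraconazole = 0.05, `amphotericin b` = 0.07,
    caspofungin = 0.06, micafungin = 0.05, cyclosporine = 0.08,
    tacrolimus = 0.10, prednisone = 0.10, methotrexate = 0.06,
    rituximab = 0.05, `piperacillin-tazobactam` = 0.05
  )
}

#' Default event catalog for the simulator
#'
#' The distinct preferred terms of the published top-20 signal tables,
#' padded with synthetic filler terms to 150 entries; baseline
#' probabilities are assigned by Zipf rank in [sim_scenario()].
#'
#' @return Character vector of preferred terms.
#' @export
default_event_catalog <- function() {
  real <- unique(c(
    "death", "drug interaction", "hallucination", "condition aggravated",
    "photosensitivity reaction", "visual impairment", "drug level increased",
    "disease progression", "vision blurred", "drug resistance",
    "hallucination visual", "respiratory failure", "hepatic function abnormal",
    "drug level decreased", "hepatotoxicity", "treatment failure",
    "drug-induced liver injury", "delirium", "actinic keratosis",
    "neurotoxicity", "product use issue", "hypokalaemia",
    "drug level below therapeutic", "antibiotic level below therapeutic",
    "pseudoaldosteronism", "electrocardiogram qt prolonged",
    "febrile neutropenia", "liver function test abnormal",
    "hepatocellular injury", "pancytopenia", "cardiac arrest",
    "neuropathy peripheral", "cholestasis", "hepatic enzyme increased",
    "off label use", "thrombocytopenia", "neutropenia",
    "therapy non-responder", "multiple organ dysfunction syndrome",
    "nervous system disorder", "blood creatinine increased",
    "general physical health deterioration", "underdose", "eosinophilia"
  ))
  c(real, sprintf("event_%03d", seq_len(150 - length(real))))
}

#' Define a simulation scenario
#'
#' Collects and validates all generative parameters; every random choice
#' in [generate_reports()] is driven by `seed` alone. Defaults emulate a
#' mid-sized FAERS extract: heavy-tailed event frequencies, about half
#' male reports, roughly 30% missing ages, US-dominated reporting
#' countries, and a 5% case-duplication rate.
#'
#' @param seed Integer seed; mandatory, there is no hidden global
#'   randomness.
#' @param n_reports Number of distinct cases to generate.
#' @param drugs Named numeric vector of PS-assignment weights (normalized
#'   internally).
#' @param events Character vector of preferred terms.
#' @param zipf_exponent Zipf exponent for baseline event probabilities
#'   (`q_j` proportional to `rank^-s`); ignored when `event_probs` given.
#' @param event_probs Optional explicit baseline event probabilities.
#' @param mean_events Expected events per report (1 guaranteed index event
#'   plus Bernoulli extras).
#' @param planted Data frame with columns `drug`, `pt`, `ror`: planted
#'   associations and their target reporting odds ratios.
#' @param sex_probs Named probabilities for female/male/unknown.
#' @param age_missing Probability that age is missing.
#' @param age_bin_probs Probabilities of the four known age bins.
#' @param country_probs Named country weights; the `unknown` entry is the
#'   missing-country mass.
#' @param concomitant_mean Mean number of extra (non-PS) drugs per report
#'   (Poisson, capped at 3).
#' @param role_probs Role probabilities for extra drugs (SS/C/I).
#' @param duplicate_case_rate Fraction of cases emitted twice with
#'   incremented report version.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(seed,
                         n_reports = 20000,
                         drugs = default_drug_catalog(),
                         events = default_event_catalog(),
                         zipf_exponent = 1.5,
                         event_probs = NULL,
                         mean_events = 3,
                         planted = NULL,
                         sex_probs = c(female = 0.32, male = 0.50,
                                       unknown = 0.18),
                         age_missing = 0.30,
                         age_bin_probs = c(`<18` = 0.09, `18-44` = 0.16,
                                           `45-64` = 0.33, `>=65` = 0.42),
                         country_probs = c(US = 0.40, JP = 0.10, FR = 0.07,
                                           CN = 0.06, GB = 0.04, DE = 0.03,
                                           ES = 0.03, IT = 0.02, CA = 0.02,
                                           AU = 0.02, unknown = 0.21),
                         concomitant_mean = 0.8,
                         role_probs = c(SS = 0.50, C = 0.35, I = 0.15),
                         duplicate_case_rate = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1, !is.na(seed))
  stopifnot(n_reports >= 1)

  drug_names <- normalize_term(names(drugs))
  if (anyDuplicated(drug_names)) stop("duplicate drug names in catalog")
  w <- as.numeric(drugs) / sum(drugs)

  events <- normalize_term(events)
  if (anyDuplicated(events)) stop("duplicate event names in catalog")
  m <- length(events)
  q <- if (is.null(event_probs)) {
    seq_len(m)^(-zipf_exponent)
  } else {
    stopifnot(length(event_probs) == m, all(event_probs > 0))
    as.numeric(event_probs)
  }
  q <- q / sum(q)

  stopifnot(mean_events >= 1)
  p_extra <- (mean_events - 1) * q
  if (any(p_extra > 0.9)) {
    stop("baseline extra-event probability exceeds 0.9; ",
         "reduce mean_events or flatten the event distribution")
  }
  b_base <- 1 - (1 - q) * (1 - p_extra)

  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("drug", "pt", "ror") %in% names(planted)))
    planted$drug <- normalize_term(planted$drug)
    planted$pt <- normalize_term(planted$pt)
    planted$g <- match(planted$drug, drug_names)
    planted$j <- match(planted$pt, events)
    if (anyNA(planted$g)) stop("planted drug not in catalog")
    if (anyNA(planted$j)) stop("planted pt not in catalog")
    if (any(planted$ror <= 0)) stop("planted target ror must be positive")
    if (anyDuplicated(planted[, c("g", "j")])) {
      stop("duplicate planted (drug, pt) pair")
    }
    bj <- b_base[planted$j]
    odds <- planted$ror * bj / (1 - bj)
    planted$b_target <- odds / (1 + odds)
    planted$p_prime <- 1 - (1 - planted$b_target) / (1 - q[planted$j])
    bad <- planted$p_prime < 0 | planted$p_prime > 0.999
    if (any(bad)) {
      stop(sprintf(
        paste0("planted association (%s, %s, ror = %g) is infeasible: ",
               "implied event probability %.4f outside [0, 1); choose a ",
               "smaller target ror or a rarer baseline event"),
        planted$drug[bad][1], planted$pt[bad][1], planted$ror[bad][1],
        planted$b_target[bad][1]
      ))
    }
  }

  stopifnot(abs(sum(sex_probs) - 1) < 1e-6,
            abs(sum(age_bin_probs) - 1) < 1e-6,
            abs(sum(country_probs) - 1) < 1e-6,
            abs(sum(role_probs) - 1) < 1e-6,
            age_missing >= 0, age_missing <= 1,
            duplicate_case_rate >= 0, duplicate_case_rate < 1,
            concomitant_mean >= 0)

  structure(list(
    seed = seed, n_reports = as.integer(n_reports),
    drug_names = drug_names, drug_weights = w,
    events = events, q = q, p_extra = p_extra, b_base = b_base,
    mean_events = mean_events, planted = planted,
    sex_probs = sex_probs, age_missing = age_missing,
    age_bin_probs = age_bin_probs, country_probs = country_probs,
    concomitant_mean = concomitant_mean, role_probs = role_probs,
    duplicate_case_rate = duplicate_case_rate
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: %d reports, %d drugs, %d events, seed %d\n",
    x$n_reports, length(x$drug_names), length(x$events), x$seed
  ))
  if (!is.null(x$planted) && nrow(x$planted) > 0) {
    cat(sprintf("  planted: %s\n", paste(
      sprintf("(%s, %s, ror %g)", x$planted$drug, x$planted$pt,
              x$planted$ror), collapse = ", "
    )))
  }
  invisible(x)
}

# Marginal event-inclusion probability of event j for a report whose PS
# drug is g (index form), honouring planted overrides.
inclusion_prob <- function(scenario, g, j) {
  b <- scenario$b_base[j]
  pl <- scenario$planted
  if (!is.null(pl)) {
    hit <- pl$g == g & pl$j == j
    if (any(hit)) b <- pl$b_target[hit][1]
  }
  b
}

#' Generate a synthetic report extract
#'
#' Draws a full report-level extract (one row per report x drug x event)
#' from a [sim_scenario()]. Deterministic given the scenario seed; the
#' caller's RNG state is left untouched.
#'
#' @param scenario A `sim_scenario`.
#' @return Tibble of report records in the [read_reports()] layout, with
#'   the scenario attached as attribute `"scenario"`.
#' @export
generate_reports <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(scenario$seed)

  n <- scenario$n_reports
  k <- length(scenario$drug_names)
  m <- length(scenario$events)
  q <- scenario$q
  p_extra <- scenario$p_extra
  pl <- scenario$planted

  ps <- sample.int(k, n, replace = TRUE, prob = scenario$drug_weights)

  # events: one guaranteed index draw per report ...
  idx_event <- sample.int(m, n, replace = TRUE, prob = q)
  ecase <- vector("list", m + 1L)
  ept <- vector("list", m + 1L)
  ecase[[1]] <- seq_len(n)
  ept[[1]] <- idx_event
  # ... plus independent Bernoulli extras, planted pairs overriding the
  # probability within the target drug's PS arm.
  planted_pts <- if (is.null(pl)) integer() else unique(pl$j)
  for (j in seq_len(m)) {
    if (j %in% planted_pts) {
      rows <- pl[pl$j == j, , drop = FALSE]
      pool <- which(!(ps %in% rows$g))
      kk <- rbinom(1L, length(pool), p_extra[j])
      sel <- if (kk > 0) pool[sample.int(length(pool), kk)] else integer()
      for (r in seq_len(nrow(rows))) {
        arm <- which(ps == rows$g[r])
        sel <- c(sel, arm[runif(length(arm)) < rows$p_prime[r]])
      }
    } else {
      kk <- rbinom(1L, n, p_extra[j])
      sel <- if (kk > 0) sample.int(n, kk) else integer()
    }
    ecase[[j + 1L]] <- sel
    ept[[j + 1L]] <- rep.int(j, length(sel))
  }
  ecase <- unlist(ecase)
  ept <- unlist(ept)
  keep <- !duplicated((ecase - 1) * m + ept)
  ecase <- ecase[keep]
  ept <- ept[keep]

  # concomitant drugs
  n_extra <- pmin(rpois(n, scenario$concomitant_mean), 3L)
  xtot <- sum(n_extra)
  xcase <- rep.int(seq_len(n), n_extra)
  xdrug <- sample.int(k, xtot, replace = TRUE, prob = scenario$drug_weights)
  xrole <- sample(names(scenario$role_probs), xtot, replace = TRUE,
                  prob = scenario$role_probs)
  dcase <- c(seq_len(n), xcase)
  ddrug <- c(ps, xdrug)
  drole <- c(rep("PS", n), xrole)
  keepd <- !duplicated((dcase - 1) * k + ddrug) # PS rows first, so they win
  dcase <- dcase[keepd]; ddrug <- ddrug[keepd]; drole <- drole[keepd]

  # demographics, one draw per case
  sex <- sample(names(scenario$sex_probs), n, replace = TRUE,
                prob = scenario$sex_probs)
  bin <- sample.int(4L, n, replace = TRUE, prob = scenario$age_bin_probs)
  lo <- c(1, 18, 45, 65)[bin]
  hi <- c(18, 45, 65, 90)[bin]
  age <- floor(lo + runif(n) * (hi - lo))
  age[runif(n) < scenario$age_missing] <- NA_real_
  country <- sample(names(scenario$country_probs), n, replace = TRUE,
                    prob = scenario$country_probs)
  country[country == "unknown"] <- NA_character_
  date0 <- as.Date("2015-01-01")
  date <- date0 + (sample.int(3195L, n, replace = TRUE) - 1L)

  rows <- dplyr::inner_join(
    tibble::tibble(case = dcase,
                   drug_name = scenario$drug_names[ddrug],
                   role = drole),
    tibble::tibble(case = ecase, pt = scenario$events[ept]),
    by = "case", relationship = "many-to-many"
  )

  dup <- runif(n) < scenario$duplicate_case_rate
  rows$report_version <- 1L
  rows2 <- rows[dup[rows$case], , drop = FALSE]
  rows2$report_version <- 2L
  all_rows <- dplyr::bind_rows(rows, rows2)
  all_rows <- all_rows[order(all_rows$case, all_rows$report_version), ,
                       drop = FALSE]

  records <- tibble::tibble(
    case_id = sprintf("C%06d", all_rows$case),
    report_version = all_rows$report_version,
    drug_name = all_rows$drug_name,
    role = all_rows$role,
    pt = all_rows$pt,
    sex = sex[all_rows$case],
    age_years = age[all_rows$case],
    country = country[all_rows$case],
    received_date = date[all_rows$case]
  )
  attr(records, "scenario") <- scenario
  records
}

#' Expected contingency table under the generative model
#'
#' Closed-form expected cells (real-valued) of the deduplicated 2x2 table
#' for a (drug, pt) pair, from the scenario's marginal probabilities. For
#' a pair planted with target odds ratio `rho` whose event is planted for
#' no other drug, the odds ratio of the expected table is exactly `rho`;
#' for an unplanted pair it is exactly 1.
#'
#' @param scenario A `sim_scenario`.
#' @param drug,pt Catalog members identifying the pair.
#' @return A real-valued `contingency_table` with cells summing to
#'   `n_reports`.
#' @export
expected_table <- function(scenario, drug, pt) {
  stopifnot(inherits(scenario, "sim_scenario"))
  g <- match(normalize_term(drug), scenario$drug_names)
  j <- match(normalize_term(pt), scenario$events)
  if (is.na(g)) stop("drug not in catalog: ", drug)
  if (is.na(j)) stop("pt not in catalog: ", pt)

  n <- scenario$n_reports
  w <- scenario$drug_weights
  b_g <- inclusion_prob(scenario, g, j)
  others <- setdiff(seq_along(w), g)
  b_other <- vapply(others, function(h) inclusion_prob(scenario, h, j),
                    numeric(1))

  a <- n * w[g] * b_g
  b <- n * w[g] * (1 - b_g)
  cc <- n * sum(w[others] * b_other)
  dd <- n * (1 - w[g]) - cc
  new_contingency(scenario$drug_names[g], scenario$events[j], a, b, cc, dd)
}
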