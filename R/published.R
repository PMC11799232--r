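# Bundled published-summary inputs.
#
# Two small delimited tables transcribed from the published
# triazole-antifungal study are shipped as package data: per-drug
# demographic marginals (counts and printed percentages) and the top-20
# signal rows (report count, PRR, chi-squared, ROR, 95% CI). They serve
# as worked inputs for the arithmetic checks and the summary-inversion
# tool. A synthetic PT-to-SOC map covering the same preferred terms is
# also included; it is a stand-in written for this package, not licensed
# MedDRA content.

#' Published per-drug demographic marginals
#'
#' @return Tibble with columns `drug`, `section` (sex/age/country),
#'   `level`, `count`, `percent` (the printed percentage).
#' @export
published_demographics <- function() {
  readr::read_csv(
    system.file("extdata", "published_demographics.csv", package = "pvmine"),
    col_types = "cccid", progress = FALSE
  )
}

#' Published top-20 signal rows per drug
#'
#' @return Tibble with columns `drug`, `pt`, `a`, `prr`, `chi2`, `ror`,
#'   `ror_ci_low`, `ror_ci_high` as printed (3-decimal rounding).
#' @export
published_signals <- function() {
  out <- readr::read_csv(
    system.file("extdata", "published_signals.csv", package = "pvmine"),
    col_types = "cciddddd", progress = FALSE
  )
  out
}

#' Bundled synthetic PT-to-SOC map
#'
#' A hand-written stand-in mapping covering the preferred terms of the
#' published signal tables; SOC labels follow the standard top-level
#' organ-class names.
#'
#' @return A `soc_map` tibble (see [load_soc_map()]).
#' @export
synthetic_soc_map <- function() {
  load_soc_map(
    system.file("extdata", "soc_map_synthetic.csv", package = "pvmine")
  )
}

#' Expand demographic marginal counts into report records
#'
#' Builds a minimal report-record tibble whose per-drug sex, age-bin and
#' country marginals equal the supplied counts, so that summary
#' percentages can be recomputed through the same code path as for a real
#' extract. Sex, age and country are assigned independently (only the
#' marginals are meaningful). Cases beyond the listed countries are given
#' a missing country.
#'
#' @param counts Tibble in the [published_demographics()] layout,
#'   restricted to one drug.
#' @return Tibble of report records (one row per case, role PS).
#' @export
records_from_marginals <- function(counts) {
  drug <- unique(counts$drug)
  stopifnot(length(drug) == 1)
  sex_rows <- counts[counts$section == "sex", , drop = FALSE]
  age_rows <- counts[counts$section == "age", , drop = FALSE]
  ctry_rows <- counts[counts$section == "country", , drop = FALSE]
  total <- sum(sex_rows$count)
  stopifnot(total == sum(age_rows$count), total >= sum(ctry_rows$count))

  sex <- rep(sex_rows$level, sex_rows$count)
  age_rep <- c(`<18` = 10, `18-44` = 30, `45-64` = 50, `>=65` = 70,
               unknown = NA_real_)
  age <- rep(unname(age_rep[age_rows$level]), age_rows$count)
  country <- c(rep(ctry_rows$level, ctry_rows$count),
               rep(NA_character_, total - sum(ctry_rows$count)))

  tibble::tibble(
    case_id = sprintf("%s-%06d", substr(drug, 1, 4), seq_len(total)),
    report_version = 1L,
    drug_name = normalize_term(drug),
    role = "PS",
    pt = "adverse event",
    sex = sex,
    age_years = age,
    country = country,
    received_date = as.Date(NA)
  )
}
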