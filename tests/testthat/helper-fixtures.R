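# Fixture builders and independent brute-force oracles used across tests.

make_records <- function(case_id, drug, role = "PS", pt,
                         sex = "unknown", age = NA_real_,
                         country = NA_character_, version = 1L,
                         date = as.Date(NA)) {
  tibble::tibble(
    case_id = as.character(case_id),
    report_version = as.integer(version),
    drug_name = pvmine:::normalize_term(drug),
    role = role,
    pt = pvmine:::normalize_term(pt),
    sex = sex,
    age_years = as.numeric(age),
    country = country,
    received_date = date
  )
}

# Random report extract with a handful of drugs and PTs; the first drug of
# each case is PS, others get random roles. Some cases carry two versions.
random_extract <- function(n_cases, seed, n_drugs = 5, n_pts = 8,
                           p_dup = 0.15) {
  set.seed(seed)
  drugs <- paste0("drug", seq_len(n_drugs))
  pts <- paste0("pt", seq_len(n_pts))
  rows <- list()
  for (i in seq_len(n_cases)) {
    nd <- sample(1:3, 1)
    ne <- sample(1:3, 1)
    d <- sample(drugs, nd)
    e <- sample(pts, ne)
    roles <- c("PS", sample(c("SS", "C", "I"), nd - 1, replace = TRUE))
    combo <- expand.grid(k = seq_len(nd), pt = e,
                         stringsAsFactors = FALSE)
    n_versions <- if (runif(1) < p_dup) 2L else 1L
    for (v in seq_len(n_versions)) {
      rows[[length(rows) + 1L]] <- make_records(
        case_id = sprintf("case%04d", i),
        drug = d[combo$k], role = roles[combo$k], pt = combo$pt,
        sex = sample(c("female", "male", "unknown"), 1),
        age = if (runif(1) < 0.3) NA_real_ else sample(1:90, 1),
        country = sample(c("US", "JP", "FR", NA), 1),
        version = v
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Independent double-loop counter over cases: the oracle for
# build_contingency. `pts` may be several preferred terms (SOC events).
brute_force_table <- function(records, drug, pts) {
  drug <- pvmine:::normalize_term(drug)
  pts <- pvmine:::normalize_term(pts)
  ids <- unique(records$case_id)
  a <- b <- cc <- d <- 0L
  for (cid in ids) {
    sub <- records[records$case_id == cid, , drop = FALSE]
    has_drug <- any(sub$drug_name == drug & sub$role == "PS")
    has_event <- any(sub$pt %in% pts)
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Random strictly positive 2x2 table.
random_positive_table <- function() sample.int(500, 4, replace = TRUE)

# Exact summary statistics of a table, computed by direct arithmetic
# (independent of the package's vectorized code paths).
direct_summary <- function(a, b, cc, d) {
  ror <- a * d / (b * cc)
  se_r <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  prr <- (a / (a + b)) / (cc / (cc + d))
  list(
    a = a, prr = prr, ror = ror,
    ror_ci_low = exp(log(ror) - 1.96 * se_r),
    ror_ci_high = exp(log(ror) + 1.96 * se_r)
  )
}

write_extract_file <- function(records, path = tempfile(fileext = ".csv")) {
  write_reports(records, path)
  path
}
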