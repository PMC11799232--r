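# 2x2 contingency tables for (drug, event) pairs.
#
# Counting is case-level: a report (one deduplicated case) contributes to
# cell a when the target drug appears with role PS in that case AND the
# target event appears at least once, regardless of row multiplicity. The
# comparator (cells c and d) is every case of the supplied extract where
# the target drug is not PS; a drug occurring only as SS/C/I counts as
# comparator.

new_contingency <- function(drug, event, a, b, c, d) {
  structure(
    list(drug = drug, event = event,
         a = a, b = b, c = c, d = d, n = a + b + c + d),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 contingency table: drug '%s' vs event '%s'\n",
              x$drug, x$event))
  cat(sprintf("              event   other\n"))
  cat(sprintf("  drug (PS) %7s %7s\n", format(x$a), format(x$b)))
  cat(sprintf("  other     %7s %7s   (N = %s)\n",
              format(x$c), format(x$d), format(x$n)))
  invisible(x)
}

# Accepts a contingency_table, a list with fields a..d, or a numeric
# vector of length 4 in (a, b, c, d) order.
table_cells <- function(table) {
  if (inherits(table, "contingency_table") ||
      (is.list(table) && all(c("a", "b", "c", "d") %in% names(table)))) {
    return(as.numeric(c(table$a, table$b, table$c, table$d)))
  }
  if (is.numeric(table) && length(table) == 4) return(as.numeric(table))
  stop("expected a contingency table or a numeric vector (a, b, c, d)")
}

#' Build the 2x2 contingency table for one (drug, event) pair
#'
#' `a` counts cases where `drug` has role PS and the event is present;
#' `b` those PS cases without the event; `c` comparator cases with the
#' event; `d` the remainder. `a + b + c + d` equals the number of cases in
#' the extract. Records should already be deduplicated.
#'
#' For SOC-level tables, pass the member preferred terms via `pts`; the
#' event is then "the case carries at least one PT in the set".
#'
#' @param records Tibble of (deduplicated) report records.
#' @param drug Target drug name.
#' @param event Event label (a preferred term, or a SOC label when `pts`
#'   is supplied).
#' @param pts Preferred term(s) defining the event; defaults to `event`.
#' @return A `contingency_table` object.
#' @export
build_contingency <- function(records, drug, event, pts = event) {
  if (nrow(records) == 0) stop("extract contains zero reports")
  d <- normalize_term(drug)
  pts <- normalize_term(pts)

  all_cases <- unique(records$case_id)
  n_total <- length(all_cases)
  ps_cases <- unique(records$case_id[records$drug_name == d &
                                       records$role == "PS"])
  ev_cases <- unique(records$case_id[records$pt %in% pts])

  a <- sum(ev_cases %in% ps_cases)
  b <- length(ps_cases) - a
  cc <- length(ev_cases) - a
  dd <- n_total - a - b - cc
  new_contingency(d, if (length(event) == 1) normalize_term(event) else d,
                  a, b, cc, dd)
}

#' Enumerate contingency tables for all observed (drug, PT) pairs
#'
#' Produces exactly one table per (drug, preferred term) pair with
#' `a >= 1`, for each drug in `drugs`, in deterministic (drug, PT)
#' lexicographic order.
#'
#' @param records Tibble of (deduplicated) report records.
#' @param drugs Character vector of target drugs (non-empty).
#' @return Tibble with columns `drug`, `event`, `a`, `b`, `c`, `d`.
#' @export
enumerate_pairs <- function(records, drugs) {
  if (length(drugs) == 0) stop("drugs must be non-empty")
  if (nrow(records) == 0) stop("extract contains zero reports")
  drugs <- sort(unique(normalize_term(drugs)))

  case_pt <- dplyr::distinct(
    tibble::tibble(case_id = records$case_id, pt = records$pt)
  )
  n_total <- length(unique(records$case_id))
  pt_tot <- dplyr::count(case_pt, .data$pt, name = "n_pt")

  blocks <- lapply(drugs, function(d) {
    ps <- unique(records$case_id[records$drug_name == d &
                                   records$role == "PS"])
    n_ps <- length(ps)
    sub <- case_pt[case_pt$case_id %in% ps, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(drug = character(), event = character(),
                            a = integer(), b = integer(),
                            c = integer(), d = integer()))
    }
    acount <- dplyr::count(sub, .data$pt, name = "a")
    m <- dplyr::left_join(acount, pt_tot, by = "pt")
    tibble::tibble(
      drug = d,
      event = m$pt,
      a = as.integer(m$a),
      b = as.integer(n_ps - m$a),
      c = as.integer(m$n_pt - m$a),
      d = as.integer(n_total - n_ps - (m$n_pt - m$a))
    )
  })
  out <- dplyr::bind_rows(blocks)
  out[order(out$drug, out$event), , drop = FALSE]
}
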