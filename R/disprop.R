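# Disproportionality statistics on 2x2 tables.
#
# For the table
#               event   other
#   drug (PS)     a       b
#   other         c       d
#
# ROR = ad / bc, with 95% CI exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))
# PRR = [a/(a+b)] / [c/(c+d)], with 95% CI
#       exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))
# The multiplier 1.96 is used verbatim (not the exact normal quantile), as
# is conventional in signal-mining tables.

Z95 <- 1.96

ror_point_ci <- function(a, b, c, d, z = Z95) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(est = est, low = est * exp(-z * se), high = est * exp(z * se))
}

prr_point_ci <- function(a, b, c, d, z = Z95) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(est = est, low = est * exp(-z * se), high = est * exp(z * se))
}

chi2_value <- function(a, b, c, d, variant = "pearson") {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- if (variant == "yates") {
    n * pmax(abs(a * d - b * c) - n / 2, 0)^2
  } else {
    n * (a * d - b * c)^2
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Haldane-Anscombe correction: +0.5 on every cell, applied only to tables
# that contain a zero cell so that well-populated tables are untouched.
haldane_cells <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  list(a = a + 0.5 * zero, b = b + 0.5 * zero,
       c = c + 0.5 * zero, d = d + 0.5 * zero)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/(bc)`; the CI is lognormal with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. A table with any zero cell yields an
#' undefined result (`NA` values, `undefined = TRUE`) unless
#' `haldane = TRUE`, which adds 0.5 to every cell of zero-containing
#' tables before computing.
#'
#' @param table A `contingency_table`, a list with fields `a`..`d`, or a
#'   numeric vector `(a, b, c, d)`.
#' @param haldane Apply the Haldane +0.5 correction to zero-cell tables.
#' @return List with `ror`, `ci_low`, `ci_high`, `undefined`.
#' @export
compute_ror <- function(table, haldane = FALSE) {
  x <- table_cells(table)
  if (any(x == 0)) {
    if (!haldane) {
      return(list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  undefined = TRUE))
    }
    h <- haldane_cells(x[1], x[2], x[3], x[4])
    x <- c(h$a, h$b, h$c, h$d)
  }
  r <- ror_point_ci(x[1], x[2], x[3], x[4])
  list(ror = r$est, ci_low = r$low, ci_high = r$high, undefined = FALSE)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the CI is lognormal with standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Undefined when `a` or `c` is
#' zero, unless `haldane = TRUE` (0.5 added to every cell of zero-cell
#' tables).
#'
#' @inheritParams compute_ror
#' @return List with `prr`, `ci_low`, `ci_high`, `undefined`.
#' @export
compute_prr <- function(table, haldane = FALSE) {
  x <- table_cells(table)
  if (any(x == 0)) {
    if (!haldane && (x[1] == 0 || x[3] == 0)) {
      return(list(prr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  undefined = TRUE))
    }
    if (haldane) {
      h <- haldane_cells(x[1], x[2], x[3], x[4])
      x <- c(h$a, h$b, h$c, h$d)
    }
  }
  p <- prr_point_ci(x[1], x[2], x[3], x[4])
  list(prr = p$est, ci_low = p$low, ci_high = p$high, undefined = FALSE)
}

#' Chi-squared statistic of a 2x2 table
#'
#' Pearson: `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. Yates: the same with
#' numerator `N(|ad - bc| - N/2)^2`, floored at zero. Returns `NA` when
#' any margin is zero.
#'
#' @inheritParams compute_ror
#' @param variant `"pearson"` (default, no continuity correction) or
#'   `"yates"`.
#' @return The chi-squared value (scalar), `NA` if undefined.
#' @export
chi_square <- function(table, variant = c("pearson", "yates")) {
  variant <- match.arg(variant)
  x <- table_cells(table)
  if ((x[1] + x[2]) == 0 || (x[3] + x[4]) == 0 ||
      (x[1] + x[3]) == 0 || (x[2] + x[4]) == 0) {
    return(NA_real_)
  }
  chi2_value(x[1], x[2], x[3], x[4], variant)
}

#' Apply the joint signal criteria
#'
#' A (drug, event) pair is a signal when, simultaneously, the report count
#' `a >= a_min` (default 3), the lower 95% CI bound of the ROR strictly
#' exceeds `ror_ci_low_min` (default 1), and the PRR strictly exceeds
#' `prr_min` (default 2). Pairs with undefined statistics are never
#' signals.
#'
#' @param stats Data frame with columns `a`, `ror_ci_low`, `prr` and
#'   optionally `defined` (logical).
#' @param a_min Minimum report count (inclusive).
#' @param ror_ci_low_min Strict lower threshold on the ROR CI lower bound.
#' @param prr_min Strict lower threshold on the PRR.
#' @return Logical vector, one element per row of `stats`.
#' @export
apply_signal_criteria <- function(stats, a_min = 3, ror_ci_low_min = 1,
                                  prr_min = 2) {
  defined <- if ("defined" %in% names(stats)) {
    stats$defined
  } else {
    !is.na(stats$ror_ci_low) & !is.na(stats$prr)
  }
  defined & !is.na(stats$ror_ci_low) & !is.na(stats$prr) &
    stats$a >= a_min &
    stats$ror_ci_low > ror_ci_low_min &
    stats$prr > prr_min
}

#' Disproportionality statistics for a set of contingency tables
#'
#' Vectorized ROR/PRR/chi-squared computation plus the joint signal
#' criteria for a table of (drug, event) pair counts such as produced by
#' [enumerate_pairs()]. Pairs with a zero cell are flagged undefined and
#' excluded from signals (no silent correction); `haldane = TRUE` corrects
#' zero-cell tables by +0.5 on every cell instead.
#'
#' @param pairs Data frame with columns `a`, `b`, `c`, `d` and optionally
#'   `drug`, `event`.
#' @param chi2_variant `"pearson"` or `"yates"`.
#' @param haldane Apply the Haldane correction to zero-cell tables.
#' @inheritParams apply_signal_criteria
#' @return Tibble with the pair counts plus `ror`, `ror_ci_low`,
#'   `ror_ci_high`, `prr`, `prr_ci_low`, `prr_ci_high`, `chi2`, `defined`,
#'   `is_signal` and `reason` (why a pair is not a signal; `NA` for
#'   signals).
#' @export
signal_stats <- function(pairs, chi2_variant = c("pearson", "yates"),
                         haldane = FALSE, a_min = 3, ror_ci_low_min = 1,
                         prr_min = 2) {
  chi2_variant <- match.arg(chi2_variant)
  a0 <- as.numeric(pairs$a); b0 <- as.numeric(pairs$b)
  c0 <- as.numeric(pairs$c); d0 <- as.numeric(pairs$d)

  zero <- a0 == 0 | b0 == 0 | c0 == 0 | d0 == 0
  if (haldane) {
    h <- haldane_cells(a0, b0, c0, d0)
    a <- h$a; b <- h$b; cc <- h$c; dd <- h$d
    defined <- rep(TRUE, length(a0))
  } else {
    a <- a0; b <- b0; cc <- c0; dd <- d0
    defined <- !zero
  }

  r <- ror_point_ci(a, b, cc, dd)
  p <- prr_point_ci(a, b, cc, dd)
  chi <- chi2_value(a, b, cc, dd, chi2_variant)
  blank <- function(x) ifelse(defined, x, NA_real_)

  out <- tibble::tibble(
    drug = if ("drug" %in% names(pairs)) pairs$drug else NA_character_,
    event = if ("event" %in% names(pairs)) pairs$event else NA_character_,
    a = as.integer(a0), b = as.integer(b0),
    c = as.integer(c0), d = as.integer(d0),
    ror = blank(r$est), ror_ci_low = blank(r$low), ror_ci_high = blank(r$high),
    prr = blank(p$est), prr_ci_low = blank(p$low), prr_ci_high = blank(p$high),
    chi2 = blank(chi),
    defined = defined
  )
  out$is_signal <- apply_signal_criteria(out, a_min = a_min,
                                         ror_ci_low_min = ror_ci_low_min,
                                         prr_min = prr_min)
  reason <- rep(NA_character_, nrow(out))
  reason[!out$defined] <- "undefined"
  reason[is.na(reason) & out$a < a_min] <- "a_below_min"
  reason[is.na(reason) & !(out$ror_ci_low > ror_ci_low_min)] <- "ror_ci_low"
  reason[is.na(reason) & !(out$prr > prr_min)] <- "prr"
  out$reason <- reason
  out
}

#' Frequency-ranked signal table
#'
#' Keeps only signals (`is_signal`), sorts by report count `a` descending,
#' breaking ties by ROR descending and then event name, and truncates to
#' the top `n`.
#'
#' @param stats Output of [signal_stats()].
#' @param n Number of rows to keep (default 20).
#' @return The ranked, truncated tibble.
#' @export
rank_signals <- function(stats, n = 20) {
  sig <- stats[stats$is_signal %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  ord <- order(-sig$a, -sig$ror, sig$event)
  utils::head(sig[ord, , drop = FALSE], n)
}

#' Write a signal-statistics table to disk
#'
#' Delimited output uses the column order drug, pt, a, prr, chi2, ror,
#' ror_ci_low, ror_ci_high, is_signal; statistics are rounded to 3
#' decimals for display. `format = "json"` writes the same rows as a JSON
#' array.
#'
#' @param stats Output of [signal_stats()] or [rank_signals()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits Display rounding for the statistic columns.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(stats, path, format = c("csv", "json"),
                               digits = 3) {
  format <- match.arg(format)
  cols <- c("drug", "event", "a", "prr", "chi2", "ror", "ror_ci_low",
            "ror_ci_high", "is_signal")
  out <- stats[, intersect(cols, names(stats)), drop = FALSE]
  names(out)[names(out) == "event"] <- "pt"
  for (col in c("prr", "chi2", "ror", "ror_ci_low", "ror_ci_high")) {
    if (col %in% names(out)) out[[col]] <- round(out[[col]], digits)
  }
  if (format == "csv") {
    readr::write_csv(out, path, na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         digits = NA)
  }
  invisible(path)
}
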