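# Inversion of published disproportionality summaries.
#
# A published signal row reports (a, PRR, ROR, ROR 95% CI) but not the
# underlying cells b, c, d. For an all-positive table those four numbers
# pin the cells down exactly:
#
#   p := a/(a+b)  satisfies  PRR = p/q and ROR = [p/(1-p)]/[q/(1-q)],
#   which combine to  p = (ROR - PRR)/(ROR - 1)   (ROR != 1),
#   q  = p / PRR,
#   and the CI half-width gives S2 := [ln(hi/lo)/(2*1.96)]^2
#        = 1/a + 1/b + 1/c + 1/d,
#   so with R := S2 - 1/a - 1/b:  c = 1/(R(1-q)),  d = 1/(Rq).
#
# The same algebra exposes impossible rows: a positive table with ROR > 1
# forces 1 < PRR < ROR (and symmetrically ROR < PRR < 1 when ROR < 1), and
# the CI width must leave room for positive c and d.

#' Invert a published summary row to its contingency table
#'
#' Recovers the continuous cells `(b, c, d)` of the 2x2 table that
#' reproduces a published report count `a`, PRR, ROR and ROR 95% CI
#' exactly, using the closed-form solution of the three defining
#' equations. Inputs that no positive table can produce raise an
#' "inconsistent summary" error naming the violated relation.
#'
#' @param a Report count (cell a), positive.
#' @param prr Published PRR, positive.
#' @param ror Published ROR, positive, different from 1.
#' @param ror_ci_low,ror_ci_high Published 95% CI bounds of the ROR.
#' @param gm_tol Maximum relative disagreement tolerated between
#'   `sqrt(ror_ci_low * ror_ci_high)` and `ror` (default 0.005); a CI
#'   built as `exp(ln ROR +/- 1.96 se)` has geometric mean equal to the
#'   point estimate up to print rounding.
#' @return An object of class `inverted_table`: list with `table`
#'   (continuous cells), `table_rounded` (nearest-integer cells),
#'   `residuals` (tibble comparing the recomputed statistics of the
#'   continuous solution with the inputs), and `max_rel_error`.
#' @export
invert_summary <- function(a, prr, ror, ror_ci_low, ror_ci_high,
                           gm_tol = 0.005) {
  vals <- c(a = a, prr = prr, ror = ror,
            ror_ci_low = ror_ci_low, ror_ci_high = ror_ci_high)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("inconsistent summary: all of a, prr, ror and the CI bounds ",
         "must be positive numbers")
  }
  gm <- sqrt(ror_ci_low * ror_ci_high)
  if (abs(gm / ror - 1) >= gm_tol) {
    stop(sprintf(
      paste0("inconsistent summary: geometric mean of the CI bounds ",
             "(%.4f) disagrees with the ROR (%.4f) beyond the rounding ",
             "tolerance; the CI is not of the form exp(ln ROR +/- 1.96 se)"),
      gm, ror
    ))
  }
  if (abs(ror - 1) < 1e-9) {
    stop("inconsistent summary: ROR = 1 leaves the table underdetermined")
  }

  p <- (ror - prr) / (ror - 1)
  if (p <= 0 || p >= 1) {
    stop(sprintf(
      paste0("inconsistent summary: PRR/ROR ordering violated - a ",
             "positive table requires 1 < PRR < ROR when ROR > 1 (or ",
             "ROR < PRR < 1 when ROR < 1), got PRR = %g, ROR = %g"),
      prr, ror
    ))
  }
  q <- p / prr
  if (q <= 0 || q >= 1) {
    stop(sprintf(
      "inconsistent summary: implied comparator proportion q = %g is not in (0, 1)",
      q
    ))
  }
  b <- a * (1 - p) / p
  s2 <- (log(ror_ci_high / ror_ci_low) / (2 * Z95))^2
  r_rem <- s2 - 1 / a - 1 / b
  if (r_rem <= 0) {
    stop(sprintf(
      paste0("inconsistent summary: CI width gives 1/a+1/b+1/c+1/d = %g ",
             "but 1/a + 1/b alone is %g, leaving no room for positive c, d"),
      s2, 1 / a + 1 / b
    ))
  }
  cc <- 1 / (r_rem * (1 - q))
  dd <- 1 / (r_rem * q)

  rr <- ror_point_ci(a, b, cc, dd)
  pp <- prr_point_ci(a, b, cc, dd)
  residuals <- tibble::tibble(
    stat = c("prr", "ror", "ror_ci_low", "ror_ci_high"),
    input = c(prr, ror, ror_ci_low, ror_ci_high),
    recomputed = c(pp$est, rr$est, rr$low, rr$high)
  )
  residuals$rel_error <- abs(residuals$recomputed / residuals$input - 1)

  structure(list(
    table = new_contingency("(inverted)", "(inverted)", a, b, cc, dd),
    table_rounded = new_contingency("(inverted)", "(inverted)",
                                    round(a), round(b), round(cc), round(dd)),
    residuals = residuals,
    max_rel_error = max(residuals$rel_error)
  ), class = "inverted_table")
}

#' @export
print.inverted_table <- function(x, ...) {
  cat("Inverted summary -> continuous 2x2 table\n")
  cat(sprintf("  a = %.6g  b = %.6g  c = %.6g  d = %.6g  (N = %.6g)\n",
              x$table$a, x$table$b, x$table$c, x$table$d, x$table$n))
  cat(sprintf("  max relative residual of recomputed statistics: %.3g\n",
              x$max_rel_error))
  invisible(x)
}

#' Invert a table of published summary rows
#'
#' Applies [invert_summary()] to each row of a data frame with columns
#' `a`, `prr`, `ror`, `ror_ci_low`, `ror_ci_high` (extra label columns
#' such as `drug`, `pt` are carried through). Rows that fail the
#' consistency checks are kept with `status` describing the violation.
#'
#' @param rows Data frame of published rows.
#' @inheritParams invert_summary
#' @return Tibble with the label columns, continuous and rounded cells,
#'   `max_rel_error`, and `status` (`"ok"` or the error message).
#' @export
invert_summary_table <- function(rows, gm_tol = 0.005) {
  need <- c("a", "prr", "ror", "ror_ci_low", "ror_ci_high")
  absent <- setdiff(need, names(rows))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  labels <- setdiff(names(rows), need)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, , drop = FALSE]
    res <- tryCatch(
      invert_summary(row$a, row$prr, row$ror, row$ror_ci_low,
                     row$ror_ci_high, gm_tol = gm_tol),
      error = function(e) conditionMessage(e)
    )
    base <- row[, labels, drop = FALSE]
    base$a <- row$a
    if (is.character(res)) {
      base$b <- NA_real_; base$c <- NA_real_; base$d <- NA_real_
      base$b_int <- NA_real_; base$c_int <- NA_real_; base$d_int <- NA_real_
      base$max_rel_error <- NA_real_
      base$status <- res
    } else {
      base$b <- res$table$b; base$c <- res$table$c; base$d <- res$table$d
      base$b_int <- res$table_rounded$b
      base$c_int <- res$table_rounded$c
      base$d_int <- res$table_rounded$d
      base$max_rel_error <- res$max_rel_error
      base$status <- "ok"
    }
    tibble::as_tibble(base)
  })
  dplyr::bind_rows(out)
}
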