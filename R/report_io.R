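# Report-level extract input/output, deduplication and demographics.

#' Read a report-level adverse event extract
#'
#' Parses a delimited extract with one row per report x drug x event, using
#' the column layout of common FAERS front-end exports: `caseid`,
#' `reportid` (case version), `drugname`, `role_cod`, `pt`, and optionally
#' `sex`, `age`, `age_cod`, `occr_country`, `receipt_date`. Any further
#' columns are carried through untouched.
#'
#' Drug names and preferred terms are trimmed and case-folded. Rows with an
#' unusable key field (empty case id, non-positive version, unknown role
#' code, empty drug or event name) are rejected with a line-numbered
#' diagnostic, retrievable via `attr(x, "rejected")`. Unparseable ages or
#' dates only blank the affected field (with a warning), never the row.
#' Ages in non-year units are converted to years using the `age_cod`
#' column (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`); an unknown unit or an
#' age outside `[0, 150)` becomes missing.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param quiet Suppress rejection/parsing warnings.
#' @return A tibble of report records with columns `case_id`,
#'   `report_version`, `drug_name`, `role`, `pt`, `sex`, `age_years`,
#'   `country`, `received_date`, plus any passthrough columns. Rejected
#'   rows are attached as attribute `"rejected"`.
#' @seealso [write_reports()], [deduplicate_reports()]
#' @export
read_reports <- function(path, delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
  required <- c("caseid", "reportid", "drugname", "role_cod", "pt")
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }

  n <- nrow(raw)
  line <- seq_len(n) + 1L # header occupies line 1

  case_id <- trimws(raw$caseid)
  version <- suppressWarnings(as.integer(raw$reportid))
  drug_name <- normalize_term(raw$drugname)
  role <- toupper(trimws(raw$role_cod))
  pt <- normalize_term(raw$pt)

  reason <- rep(NA_character_, n)
  flag <- function(bad, msg, value) {
    hit <- bad & is.na(reason)
    reason[hit] <<- sprintf("%s (value: '%s')", msg, value[hit])
  }
  flag(case_id == "", "empty case id", raw$caseid)
  flag(is.na(version) | version < 1L, "report version not a positive integer",
       raw$reportid)
  flag(!(role %in% ROLE_CODES), "unknown role code", raw$role_cod)
  flag(drug_name == "", "empty drug name", raw$drugname)
  flag(pt == "", "empty event term", raw$pt)

  keep <- is.na(reason)
  rejected <- tibble::tibble(line = line[!keep], reason = reason[!keep])
  if (nrow(rejected) > 0 && !quiet) {
    warning(sprintf(
      "rejected %d row(s); first: line %d, %s",
      nrow(rejected), rejected$line[1], rejected$reason[1]
    ), call. = FALSE)
  }

  sex <- parse_sex(if ("sex" %in% names(raw)) raw$sex else rep("", n))
  age <- parse_age(
    if ("age" %in% names(raw)) raw$age else rep("", n),
    if ("age_cod" %in% names(raw)) raw$age_cod else rep("", n),
    quiet = quiet
  )
  country <- if ("occr_country" %in% names(raw)) {
    out <- toupper(trimws(raw$occr_country))
    out[out == ""] <- NA_character_
    out
  } else {
    rep(NA_character_, n)
  }
  date <- parse_receipt_date(
    if ("receipt_date" %in% names(raw)) raw$receipt_date else rep("", n),
    quiet = quiet
  )

  records <- tibble::tibble(
    case_id = case_id,
    report_version = version,
    drug_name = drug_name,
    role = role,
    pt = pt,
    sex = sex,
    age_years = age,
    country = country,
    received_date = date
  )
  passthrough <- setdiff(names(raw), c(
    required, "sex", "age", "age_cod", "occr_country", "receipt_date"
  ))
  for (col in passthrough) records[[col]] <- raw[[col]]

  records <- records[keep, , drop = FALSE]
  attr(records, "rejected") <- rejected
  records
}

parse_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  out
}

# Conversion factors from age_cod units to years. FAERS-style codes;
# DEC = decades.
AGE_UNIT_YEARS <- c(
  YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
  DY = 1 / 365.25, HR = 1 / 8760
)

parse_age <- function(age, age_cod, quiet = FALSE) {
  age <- trimws(age)
  cod <- toupper(trimws(age_cod))
  cod[cod == ""] <- "YR"
  num <- suppressWarnings(as.numeric(age))
  fac <- AGE_UNIT_YEARS[cod]
  years <- num * as.numeric(fac)
  bad <- (age != "" & is.na(num)) |
    (!is.na(num) & is.na(fac)) |
    (!is.na(years) & (years < 0 | years >= 150))
  years[bad] <- NA_real_
  years[age == ""] <- NA_real_
  if (any(bad) && !quiet) {
    warning(sprintf("%d unparseable age value(s) set to missing", sum(bad)),
            call. = FALSE)
  }
  years
}

parse_receipt_date <- function(x, quiet = FALSE) {
  x <- trimws(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  retry <- is.na(d) & x != ""
  d[retry] <- as.Date(x[retry], format = "%Y%m%d")
  bad <- is.na(d) & x != ""
  if (any(bad) && !quiet) {
    warning(sprintf("%d unparseable date(s) set to missing", sum(bad)),
            call. = FALSE)
  }
  d
}

#' Write report records in the extract layout
#'
#' Inverse of [read_reports()]: writes the standard column layout
#' (`caseid`, `reportid`, `drugname`, `role_cod`, `pt`, `sex`, `age`,
#' `age_cod`, `occr_country`, `receipt_date`) so that a written file read
#' back yields the same records. Ages are written in years.
#'
#' @param records Tibble of report records.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_reports <- function(records, path, delim = ",") {
  sex_out <- c(female = "F", male = "M", unknown = "")[records$sex]
  out <- tibble::tibble(
    caseid = records$case_id,
    reportid = records$report_version,
    drugname = records$drug_name,
    role_cod = records$role,
    pt = records$pt,
    sex = unname(sex_out),
    age = ifelse(is.na(records$age_years), "",
                 format(records$age_years, trim = TRUE, scientific = FALSE,
                        digits = 15)),
    age_cod = ifelse(is.na(records$age_years), "", "YR"),
    occr_country = ifelse(is.na(records$country), "", records$country),
    receipt_date = ifelse(is.na(records$received_date), "",
                          format(records$received_date, "%Y-%m-%d"))
  )
  std <- c("case_id", "report_version", "drug_name", "role", "pt", "sex",
           "age_years", "country", "received_date")
  for (col in setdiff(names(records), std)) out[[col]] <- records[[col]]
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Keep only the latest version of each case
#'
#' Spontaneous-reporting databases store successive versions of the same
#' case under one case id; analyses count each case once. This keeps, for
#' every `case_id`, only the rows carrying its highest `report_version`,
#' preserving the original row order otherwise.
#'
#' @param records Tibble of report records.
#' @return The deduplicated tibble.
#' @export
deduplicate_reports <- function(records) {
  if (nrow(records) == 0) return(records)
  max_v <- tapply(records$report_version, records$case_id, max)
  keep <- records$report_version == unname(max_v[records$case_id])
  records[keep, , drop = FALSE]
}

age_bin <- function(age) {
  b <- rep("unknown", length(age))
  ok <- !is.na(age)
  b[ok & age < 18] <- "<18"
  b[ok & age >= 18 & age < 45] <- "18-44"
  b[ok & age >= 45 & age < 65] <- "45-64"
  b[ok & age >= 65] <- ">=65"
  factor(b, levels = AGE_BINS)
}

pct_of <- function(count, total) {
  if (total <= 0) return(rep(0, length(count)))
  round(100 * count / total, 2)
}

#' Demographics summary for one drug
#'
#' Counts the distinct cases in which `drug` appears with role PS, broken
#' down by sex, age bin and reporting country. Records should already be
#' deduplicated; demographics are taken from the first row of each case.
#' The country ranking covers reports with a known country (ties broken
#' alphabetically); cases without a country are reported separately in
#' `country_unknown`.
#'
#' @param records Tibble of (deduplicated) report records.
#' @param drug Drug name (matched case-insensitively).
#' @param top_n Number of countries to rank (default 5).
#' @return An object of class `demographics_summary`: a list with
#'   `drug`, `total_reports`, `sex_counts`, `sex_percent`,
#'   `age_bin_counts`, `age_bin_percent`, `top_countries` (tibble with
#'   `country`, `n`, `pct`), and `country_unknown`.
#' @export
demographics_summary <- function(records, drug, top_n = 5) {
  d <- normalize_term(drug)
  sub <- records[records$drug_name == d & records$role == "PS", , drop = FALSE]
  cases <- sub[!duplicated(sub$case_id), , drop = FALSE]
  total <- nrow(cases)

  sex_counts <- table(factor(cases$sex, levels = SEX_LEVELS))
  age_counts <- table(age_bin(cases$age_years))

  known <- cases$country[!is.na(cases$country)]
  tb <- table(known)
  if (length(tb) > 0) {
    ord <- order(-as.integer(tb), names(tb))
    tb <- tb[ord]
  }
  top <- utils::head(tibble::tibble(
    country = names(tb),
    n = as.integer(tb),
    pct = pct_of(as.integer(tb), total)
  ), top_n)

  structure(list(
    drug = d,
    total_reports = total,
    sex_counts = stats::setNames(as.integer(sex_counts), names(sex_counts)),
    sex_percent = stats::setNames(pct_of(as.integer(sex_counts), total),
                                  names(sex_counts)),
    age_bin_counts = stats::setNames(as.integer(age_counts), names(age_counts)),
    age_bin_percent = stats::setNames(pct_of(as.integer(age_counts), total),
                                      names(age_counts)),
    top_countries = top,
    country_unknown = sum(is.na(cases$country))
  ), class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Demographics for %s (%d reports, PS role, distinct cases)\n",
              x$drug, x$total_reports))
  cat("Sex:\n")
  for (s in names(x$sex_counts)) {
    cat(sprintf("  %-8s %6d  %6.2f%%\n", s, x$sex_counts[[s]],
                x$sex_percent[[s]]))
  }
  cat("Age (years):\n")
  for (s in names(x$age_bin_counts)) {
    cat(sprintf("  %-8s %6d  %6.2f%%\n", s, x$age_bin_counts[[s]],
                x$age_bin_percent[[s]]))
  }
  cat("Top reporting countries:\n")
  for (i in seq_len(nrow(x$top_countries))) {
    cat(sprintf("  %-8s %6d  %6.2f%%\n", x$top_countries$country[i],
                x$top_countries$n[i], x$top_countries$pct[i]))
  }
  invisible(x)
}

#' Long-format demographics table for several drugs
#'
#' One row per (drug, section, level) with a count and a percentage of
#' that drug's distinct PS cases, mirroring the layout of published
#' demographics tables.
#'
#' @inheritParams demographics_summary
#' @param drugs Character vector of drug names.
#' @return Tibble with columns `drug`, `section` (sex/age/country),
#'   `level`, `n`, `pct`.
#' @export
demographics_table <- function(records, drugs, top_n = 5) {
  blocks <- lapply(drugs, function(dr) {
    s <- demographics_summary(records, dr, top_n = top_n)
    dplyr::bind_rows(
      tibble::tibble(drug = s$drug, section = "sex",
                     level = names(s$sex_counts),
                     n = unname(s$sex_counts), pct = unname(s$sex_percent)),
      tibble::tibble(drug = s$drug, section = "age",
                     level = names(s$age_bin_counts),
                     n = unname(s$age_bin_counts),
                     pct = unname(s$age_bin_percent)),
      tibble::tibble(drug = s$drug, section = "country",
                     level = s$top_countries$country,
                     n = s$top_countries$n, pct = s$top_countries$pct)
    )
  })
  dplyr::bind_rows(blocks)
}
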