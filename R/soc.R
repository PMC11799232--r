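# Preferred-term to system-organ-class mapping and SOC-level analyses.
#
# MedDRA itself is licensed; the mapping arrives as a plain delimited file
# (pt, soc[, is_primary]). Each PT has exactly one primary SOC; counting
# is primary-SOC-only so that per-drug percentages sum to 100.

#' Load a PT to SOC mapping table
#'
#' Reads a delimited file with columns `pt`, `soc` and optionally
#' `is_primary` (assumed `TRUE` when absent). PT keys are normalized
#' (trimmed, case-folded); exact duplicate rows are dropped silently;
#' two primary rows mapping one PT to different SOCs are a fatal error
#' citing both file lines.
#'
#' @param path Path to the mapping file.
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma.
#' @return A tibble of class `soc_map` with columns `pt`, `soc`,
#'   `is_primary`.
#' @export
load_soc_map <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("soc map file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  if (!all(c("pt", "soc") %in% names(raw))) {
    stop("soc map must have columns 'pt' and 'soc'")
  }
  map <- tibble::tibble(
    pt = normalize_term(raw$pt),
    soc = trimws(gsub("[[:space:]]+", " ", raw$soc)),
    is_primary = if ("is_primary" %in% names(raw)) {
      tolower(trimws(raw$is_primary)) %in% c("true", "t", "1", "yes", "y")
    } else {
      rep(TRUE, nrow(raw))
    },
    line = seq_len(nrow(raw)) + 1L
  )
  dup <- duplicated(map[, c("pt", "soc", "is_primary")])
  map <- map[!dup, , drop = FALSE]

  prim <- map[map$is_primary, , drop = FALSE]
  conflict <- prim$pt[duplicated(prim$pt)]
  if (length(conflict) > 0) {
    ptc <- conflict[1]
    lines <- prim$line[prim$pt == ptc]
    stop(sprintf(
      "conflicting primary SOC for PT '%s' (file lines %s)",
      ptc, paste(lines, collapse = ", ")
    ))
  }
  map$line <- NULL
  class(map) <- c("soc_map", class(map))
  map
}

# Named vector: normalized PT -> primary SOC label.
soc_primary_lookup <- function(soc_map) {
  prim <- soc_map[soc_map$is_primary, , drop = FALSE]
  stats::setNames(prim$soc, prim$pt)
}

#' Aggregate one drug's signals by system organ class
#'
#' Counts each signal once under its preferred term's primary SOC and
#' expresses counts as percentages of the drug's total signal count.
#' Signals whose PT is absent from the map fall into an `"Unmapped"`
#' bucket with a warning.
#'
#' @param signals Tibble of signal rows for one drug (rows where
#'   `is_signal` is true are used when that column is present), with the
#'   preferred term in column `event` or `pt`.
#' @param soc_map A `soc_map` from [load_soc_map()].
#' @return Tibble with columns `drug`, `soc`, `n_signals`, `percent`,
#'   sorted by count descending (ties by SOC name).
#' @export
soc_aggregate <- function(signals, soc_map) {
  if ("is_signal" %in% names(signals)) {
    signals <- signals[signals$is_signal %in% TRUE, , drop = FALSE]
  }
  drug <- if ("drug" %in% names(signals) && nrow(signals) > 0) {
    signals$drug[1]
  } else {
    NA_character_
  }
  if (nrow(signals) == 0) {
    return(tibble::tibble(drug = character(), soc = character(),
                          n_signals = integer(), percent = numeric()))
  }
  pt <- if ("event" %in% names(signals)) signals$event else signals$pt
  lookup <- soc_primary_lookup(soc_map)
  soc <- unname(lookup[normalize_term(pt)])
  n_unmapped <- sum(is.na(soc))
  if (n_unmapped > 0) {
    warning(sprintf("%d signal PT(s) not in the SOC map, counted as 'Unmapped'",
                    n_unmapped), call. = FALSE)
    soc[is.na(soc)] <- "Unmapped"
  }
  tb <- table(soc)
  ord <- order(-as.integer(tb), names(tb))
  tb <- tb[ord]
  tibble::tibble(
    drug = drug,
    soc = names(tb),
    n_signals = as.integer(tb),
    percent = 100 * as.integer(tb) / nrow(signals)
  )
}

#' SOC-level disproportionality for one drug
#'
#' Builds the (drug, SOC) contingency table in which the event is "the
#' case carries at least one preferred term whose primary SOC is `soc`",
#' then computes the full disproportionality statistics.
#'
#' @param records Tibble of (deduplicated) report records.
#' @param drug Target drug name.
#' @param soc SOC label, matched case-insensitively against the map.
#' @param soc_map A `soc_map` from [load_soc_map()].
#' @param chi2_variant,haldane Passed to [signal_stats()].
#' @return One-row tibble in the [signal_stats()] layout, with the SOC
#'   label in `event`.
#' @export
soc_level_ror <- function(records, drug, soc, soc_map,
                          chi2_variant = "pearson", haldane = FALSE) {
  prim <- soc_map[soc_map$is_primary, , drop = FALSE]
  members <- prim$pt[tolower(prim$soc) == tolower(trimws(soc))]
  if (length(members) == 0) stop("SOC not present in map: ", soc)
  ct <- build_contingency(records, drug, event = soc, pts = members)
  pair <- tibble::tibble(drug = normalize_term(drug), event = trimws(soc),
                         a = ct$a, b = ct$b, c = ct$c, d = ct$d)
  signal_stats(pair, chi2_variant = chi2_variant, haldane = haldane)
}
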