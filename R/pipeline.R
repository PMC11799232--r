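# Pipeline orchestration: configuration and file-producing commands.
#
# A single configuration drives all commands; every output is a UTF-8
# delimited table with a header, written deterministically (fixed config
# and seed give byte-identical outputs). Each filtering step logs
# before/after counts via message().

#' Build a run configuration
#'
#' @param ... Named settings overriding the defaults: `input` (extract
#'   path or vector of paths), `drugs` (character vector), `soc_map`
#'   (mapping file path), `out_dir`, `a_min`, `prr_min`,
#'   `ror_ci_low_min`, `chi2_variant` ("pearson"/"yates"), `dedup`
#'   (logical), `haldane` (logical), `top_n`, `socs` (SOC labels for the
#'   SOC-level ROR command), `seed` (for simulation), `scenario` (list of
#'   [sim_scenario()] arguments), `invert_input` (file of published rows),
#'   `delim`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    input = NULL, drugs = character(), soc_map = NULL, out_dir = ".",
    delim = ",", a_min = 3, prr_min = 2, ror_ci_low_min = 1,
    chi2_variant = "pearson", dedup = TRUE, haldane = FALSE, top_n = 20,
    socs = NULL, seed = NULL, scenario = list(), invert_input = NULL
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all configuration settings must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration setting(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$a_min > 0, cfg$prr_min > 0, cfg$ror_ci_low_min > 0,
            cfg$top_n > 0, cfg$chi2_variant %in% c("pearson", "yates"))
  cfg$drugs <- normalize_term(cfg$drugs)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Settings in `...` override the file (mirroring command-line flags
#' overriding the config file).
#'
#' @param path Path to a YAML configuration file.
#' @param ... Overrides, as in [run_config()].
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  from_file <- yaml::read_yaml(path) %||% list()
  if (!is.null(from_file$drugs)) {
    from_file$drugs <- unlist(from_file$drugs)
  }
  if (!is.null(from_file$scenario) && !is.null(from_file$scenario$planted)) {
    pl <- from_file$scenario$planted
    if (!is.data.frame(pl)) {
      from_file$scenario$planted <- dplyr::bind_rows(
        lapply(pl, tibble::as_tibble)
      )
    }
  }
  do.call(run_config, utils::modifyList(from_file, list(...)))
}

pv_log <- function(fmt, ...) message(sprintf(paste0("[pvmine] ", fmt), ...))

slug <- function(x) gsub("(^_)|(_$)", "", gsub("[^a-z0-9]+", "_", x))

# Read (possibly several) extract files, log, and optionally deduplicate.
load_extract <- function(config) {
  if (is.null(config$input)) stop("config$input is required")
  parts <- lapply(config$input, read_reports, quiet = TRUE)
  records <- dplyr::bind_rows(parts)
  pv_log("extract: %d rows, %d cases", nrow(records),
         length(unique(records$case_id)))
  if (isTRUE(config$dedup)) {
    records <- deduplicate_reports(records)
    pv_log("after dedup: %d rows, %d cases", nrow(records),
           length(unique(records$case_id)))
  }
  records
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

# Shared by cmd_signals and cmd_soc.
compute_signal_stats <- function(config, records) {
  pairs <- enumerate_pairs(records, config$drugs)
  pv_log("pairs with a >= 1: %d", nrow(pairs))
  signal_stats(pairs, chi2_variant = config$chi2_variant,
               haldane = config$haldane, a_min = config$a_min,
               ror_ci_low_min = config$ror_ci_low_min,
               prr_min = config$prr_min)
}

#' Run the signal-mining command
#'
#' Computes disproportionality statistics for every observed (drug, PT)
#' pair of the configured drugs and writes, per drug, the full statistics
#' table, the signal-only table, and the frequency-ranked top-N table.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the statistics tibble and the written
#'   file paths.
#' @export
cmd_signals <- function(config) {
  records <- load_extract(config)
  stats <- compute_signal_stats(config, records)
  out <- ensure_out_dir(config)
  files <- character()
  for (d in config$drugs) {
    sd <- stats[stats$drug == d, , drop = FALSE]
    ps_n <- if (nrow(sd) > 0) sd$a[1] + sd$b[1] else 0L
    sig <- sd[sd$is_signal, , drop = FALSE]
    pv_log("%s: %d PS reports, %d pairs, %d signals", d, ps_n, nrow(sd),
           nrow(sig))
    f_all <- file.path(out, paste0(slug(d), "_stats.csv"))
    f_sig <- file.path(out, paste0(slug(d), "_signals.csv"))
    f_top <- file.path(out, paste0(slug(d), "_top.csv"))
    write_signal_table(sd, f_all)
    write_signal_table(sig, f_sig)
    write_signal_table(rank_signals(sd, n = config$top_n), f_top)
    files <- c(files, f_all, f_sig, f_top)
  }
  invisible(list(stats = stats, files = files))
}

#' Run the demographics command
#'
#' Writes one long-format demographics block per configured drug (count
#' and percentage per sex, age bin and top reporting country).
#'
#' @param config A `run_config`.
#' @return Invisibly, the output file path.
#' @export
cmd_demographics <- function(config) {
  records <- load_extract(config)
  tab <- demographics_table(records, config$drugs)
  out <- file.path(ensure_out_dir(config), "demographics.csv")
  readr::write_csv(tab, out, na = "")
  invisible(out)
}

#' Run the SOC-distribution command
#'
#' Mines signals as in [cmd_signals()] and aggregates each drug's signals
#' by primary system organ class.
#'
#' @param config A `run_config` with `soc_map` set.
#' @return Invisibly, the output file path.
#' @export
cmd_soc <- function(config) {
  if (is.null(config$soc_map)) stop("config$soc_map is required")
  records <- load_extract(config)
  stats <- compute_signal_stats(config, records)
  map <- load_soc_map(config$soc_map)
  blocks <- lapply(config$drugs, function(d) {
    soc_aggregate(stats[stats$drug == d, , drop = FALSE], map)
  })
  tab <- dplyr::bind_rows(blocks)
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(drug = character(), soc = character(),
                          n_signals = integer(), percent = numeric())
  }
  tab$percent <- round(tab$percent, 2)
  out <- file.path(ensure_out_dir(config), "soc_distribution.csv")
  readr::write_csv(tab, out, na = "")
  invisible(out)
}

#' Run the SOC-level ROR command
#'
#' Computes the SOC-level disproportionality statistics for every
#' configured (drug, SOC) combination.
#'
#' @param config A `run_config` with `soc_map` and `socs` set.
#' @return Invisibly, the output file path.
#' @export
cmd_soc_ror <- function(config) {
  if (is.null(config$soc_map)) stop("config$soc_map is required")
  if (is.null(config$socs)) stop("config$socs is required")
  records <- load_extract(config)
  map <- load_soc_map(config$soc_map)
  rows <- list()
  for (d in config$drugs) {
    for (s in config$socs) {
      rows[[length(rows) + 1L]] <- soc_level_ror(
        records, d, s, map,
        chi2_variant = config$chi2_variant, haldane = config$haldane
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  keep <- c("drug", "event", "a", "ror", "ror_ci_low", "ror_ci_high")
  tab <- tab[, keep, drop = FALSE]
  names(tab)[names(tab) == "event"] <- "soc"
  for (col in c("ror", "ror_ci_low", "ror_ci_high")) {
    tab[[col]] <- round(tab[[col]], 3)
  }
  out <- file.path(ensure_out_dir(config), "soc_ror.csv")
  readr::write_csv(tab, out, na = "")
  invisible(out)
}

#' Run the simulation command
#'
#' Generates a synthetic extract from `config$scenario` (with
#' `config$seed`) and writes it in the standard extract layout together
#' with a ground-truth sidecar of expected cells for every planted pair.
#'
#' @param config A `run_config` with `seed` set.
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required for simulation")
  scenario <- do.call(sim_scenario,
                      c(list(seed = config$seed), config$scenario))
  records <- generate_reports(scenario)
  pv_log("simulated %d rows, %d cases", nrow(records),
         length(unique(records$case_id)))
  out <- ensure_out_dir(config)
  f_rep <- file.path(out, "simulated_reports.csv")
  write_reports(records, f_rep, delim = config$delim)

  pl <- scenario$planted
  gt <- if (is.null(pl) || nrow(pl) == 0) {
    tibble::tibble(drug = character(), pt = character(),
                   target_ror = numeric(), a = numeric(), b = numeric(),
                   c = numeric(), d = numeric())
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(pl)), function(i) {
      et <- expected_table(scenario, pl$drug[i], pl$pt[i])
      tibble::tibble(drug = pl$drug[i], pt = pl$pt[i],
                     target_ror = pl$ror[i],
                     a = et$a, b = et$b, c = et$c, d = et$d)
    }))
  }
  f_gt <- file.path(out, "ground_truth.csv")
  readr::write_csv(gt, f_gt, na = "")
  invisible(c(f_rep, f_gt))
}

#' Run the summary-inversion command
#'
#' Reads a delimited file of published rows (`a`, `prr`, `ror`,
#' `ror_ci_low`, `ror_ci_high`, plus optional label columns) and writes
#' the recovered tables with residuals; inconsistent rows are kept with
#' their diagnosis in `status`.
#'
#' @param config A `run_config` with `invert_input` set.
#' @return Invisibly, a list with the result tibble, the output path, and
#'   the number of inconsistent rows.
#' @export
cmd_invert <- function(config) {
  if (is.null(config$invert_input)) stop("config$invert_input is required")
  rows <- readr::read_csv(config$invert_input,
                          show_col_types = FALSE, progress = FALSE)
  res <- invert_summary_table(rows)
  n_bad <- sum(res$status != "ok")
  pv_log("inverted %d row(s), %d inconsistent", nrow(res), n_bad)
  out <- file.path(ensure_out_dir(config), "inverted.csv")
  res_out <- res
  for (col in c("b", "c", "d", "max_rel_error")) {
    res_out[[col]] <- signif(res_out[[col]], 10)
  }
  readr::write_csv(res_out, out, na = "")
  invisible(list(result = res, path = out, n_inconsistent = n_bad))
}
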