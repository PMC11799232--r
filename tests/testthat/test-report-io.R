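# Extract parsing, deduplication and demographics.

test_that("a small extract round-trips through write and read", {
  rec <- make_records(
    case_id = c("A", "A", "B", "C", "D", "E"),
    drug = c("Voriconazole ", "voriconazole", "Posaconazole", "drugX",
             "drugY", "drugX"),
    role = c("PS", "PS", "PS", "SS", "C", "I"),
    pt = c("Hepatotoxicity", "death", "Death", "rash", "rash", "nausea"),
    sex = c("female", "female", "male", "unknown", "male", "female"),
    age = c(34, 34, NA, 17.5, 70, 2),
    country = c("US", "US", "JP", NA, "FR", "US"),
    date = as.Date(c("2020-01-02", "2020-01-02", NA, "2019-12-31",
                     "2021-06-15", NA))
  )
  path <- write_extract_file(rec)
  back <- read_reports(path)
  strip <- function(x) {
    attr(x, "rejected") <- NULL
    as.data.frame(x)
  }
  expect_equal(nrow(back), 6)
  expect_equal(back$drug_name[1], "voriconazole")
  expect_equal(back$pt[3], "death")
  # identity on valid records (modulo attributes)
  expect_equal(strip(back), strip(rec))
  # read -> write -> read is the identity
  path2 <- write_extract_file(back)
  again <- read_reports(path2)
  expect_equal(strip(again), strip(back))
})

test_that("rows with invalid key fields are rejected with line diagnostics", {
  txt <- paste(
    "caseid,reportid,drugname,role_cod,pt,sex,age,age_cod,occr_country,receipt_date",
    "A,1,drugx,PS,rash,F,30,YR,US,2020-01-01",
    "B,1,drugx,XX,rash,M,40,YR,US,2020-01-01",
    "C,1,drugx,PS,,M,40,YR,US,2020-01-01",
    sep = "\n"
  )
  path <- tempfile(fileext = ".csv")
  writeLines(txt, path)
  expect_warning(rec <- read_reports(path), "rejected 2 row")
  expect_equal(nrow(rec), 1)
  rej <- attr(rec, "rejected")
  expect_equal(rej$line, c(3L, 4L))
  expect_match(rej$reason[1], "unknown role code")
  expect_match(rej$reason[1], "XX")
})

test_that("a missing required column is fatal", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("caseid,reportid,drugname,pt", "A,1,x,y"), path)
  expect_error(read_reports(path), "role_cod")
})

test_that("ages are converted to years and bad values blanked", {
  txt <- paste(
    "caseid,reportid,drugname,role_cod,pt,age,age_cod",
    "A,1,x,PS,e,24,MON",
    "B,1,x,PS,e,7,DEC",
    "C,1,x,PS,e,abc,YR",
    "D,1,x,PS,e,200,YR",
    "E,1,x,PS,e,35,",
    sep = "\n"
  )
  path <- tempfile(fileext = ".csv")
  writeLines(txt, path)
  expect_warning(rec <- read_reports(path), "age")
  expect_equal(rec$age_years, c(2, 70, NA, NA, 35))
})

test_that("tab-delimited input is auto-detected", {
  txt <- paste(
    "caseid\treportid\tdrugname\trole_cod\tpt",
    "A\t1\tdrugx\tPS\trash",
    sep = "\n"
  )
  path <- tempfile(fileext = ".tsv")
  writeLines(txt, path)
  rec <- read_reports(path)
  expect_equal(rec$drug_name, "drugx")
})

test_that("deduplication keeps only the highest version per case", {
  rec <- make_records(
    case_id = c("A", "A", "A", "B", "C"),
    drug = c("x", "x", "x", "y", "z"),
    pt = c("p1", "p1", "p2", "p1", "p3"),
    version = c(1L, 2L, 2L, 1L, 1L)
  )
  out <- deduplicate_reports(rec)
  expect_equal(out$case_id, c("A", "A", "B", "C"))
  expect_true(all(out$report_version[out$case_id == "A"] == 2L))
  # identity when all cases are distinct
  distinct <- make_records(case_id = letters[1:4], drug = "x", pt = "p")
  expect_equal(deduplicate_reports(distinct), distinct)
})

test_that("deduplication agrees with brute-force per-case grouping", {
  rec <- random_extract(10, seed = 71, p_dup = 0.4)
  out <- deduplicate_reports(rec)
  expect_equal(length(unique(out$case_id)), 10)
  for (cid in unique(rec$case_id)) {
    expected_v <- max(rec$report_version[rec$case_id == cid])
    expect_true(all(out$report_version[out$case_id == cid] == expected_v))
  }
})

test_that("demographics counts distinct PS cases with the printed age bins", {
  rec <- make_records(
    case_id = c("A", "A", "B", "C", "D", "E", "F"),
    drug = c("x", "x", "x", "x", "x", "x", "y"),
    role = c("PS", "PS", "PS", "PS", "PS", "SS", "PS"),
    pt = "p",
    sex = c("female", "female", "male", "male", "unknown", "male", "male"),
    age = c(17.9, 17.9, 18, 44.99, 65, 30, 50),
    country = c("US", "US", "US", "JP", NA, "FR", "FR")
  )
  s <- demographics_summary(rec, "x")
  expect_equal(s$total_reports, 4) # E is SS only, F is another drug
  expect_equal(unname(s$sex_counts), c(1L, 2L, 1L))
  expect_equal(s$age_bin_counts[["<18"]], 1L)
  expect_equal(s$age_bin_counts[["18-44"]], 2L)
  expect_equal(s$age_bin_counts[[">=65"]], 1L)
  expect_equal(s$top_countries$country, c("US", "JP"))
  expect_equal(s$country_unknown, 1)
  # absent drug: empty summary
  empty <- demographics_summary(rec, "nosuchdrug")
  expect_equal(empty$total_reports, 0)
  expect_equal(sum(empty$sex_counts), 0)
})

test_that("demographic percentages sum to 100 and ignore row order", {
  rec <- random_extract(120, seed = 5)
  rec <- deduplicate_reports(rec)
  s <- demographics_summary(rec, "drug1")
  expect_gt(s$total_reports, 0)
  expect_lt(abs(sum(s$sex_percent) - 100), 0.02)
  expect_lt(abs(sum(s$age_bin_percent) - 100), 0.02)
  perm <- rec[sample(nrow(rec)), , drop = FALSE]
  s2 <- demographics_summary(perm, "drug1")
  expect_equal(s2$sex_counts, s$sex_counts)
  expect_equal(s2$age_bin_counts, s$age_bin_counts)
  expect_equal(s2$top_countries, s$top_countries)
})

test_that("published marginal counts reproduce the printed shares", {
  demo <- published_demographics()
  vori <- records_from_marginals(demo[demo$drug == "voriconazole", ])
  s <- demographics_summary(vori, "voriconazole")
  expect_equal(s$total_reports, 8898)
  expect_equal(s$sex_percent[["male"]], 50.31)
  expect_equal(s$sex_percent[["female"]], 32.11)
  over45 <- s$age_bin_counts[["45-64"]] + s$age_bin_counts[[">=65"]]
  expect_equal(round(100 * over45 / s$total_reports, 2), 52.72)
})
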