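# PT -> SOC mapping, aggregation and SOC-level disproportionality.

write_map <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("pt,soc,is_primary", lines), path)
  path
}

test_that("the SOC map loads, deduplicates and rejects conflicts", {
  map <- load_soc_map(write_map(c(
    "Rash,Skin disorders,TRUE",
    "nausea,Gastrointestinal disorders,TRUE",
    "headache,Nervous system disorders,TRUE"
  )))
  expect_equal(nrow(map), 3)
  expect_equal(map$pt[1], "rash")

  dup <- load_soc_map(write_map(c(
    "rash,Skin disorders,TRUE",
    "rash,Skin disorders,TRUE"
  )))
  expect_equal(nrow(dup), 1)

  expect_error(
    load_soc_map(write_map(c(
      "rash,Skin disorders,TRUE",
      "rash,Immune system disorders,TRUE"
    ))),
    "conflicting primary SOC for PT 'rash'.*lines 2, 3"
  )
})

test_that("signals aggregate to primary SOCs with percentages of the signal count", {
  map <- load_soc_map(write_map(c(
    "p1,SOC A,TRUE",
    "p2,SOC A,TRUE",
    "p3,SOC B,TRUE",
    "p4,SOC B,TRUE"
  )))
  sig <- tibble::tibble(drug = "x", event = c("p1", "p2", "p3", "p4"),
                        is_signal = TRUE)
  agg <- soc_aggregate(sig, map)
  expect_equal(sort(agg$soc), c("SOC A", "SOC B"))
  expect_equal(agg$percent, c(50, 50))
  expect_equal(sum(agg$n_signals), nrow(sig))

  # one unmapped PT falls in the Unmapped bucket with a warning
  sig2 <- tibble::tibble(drug = "x", event = c("p1", "p2", "p3", "mystery"),
                         is_signal = TRUE)
  expect_warning(agg2 <- soc_aggregate(sig2, map), "Unmapped")
  expect_equal(agg2$n_signals[agg2$soc == "Unmapped"], 1L)
  expect_equal(agg2$percent[agg2$soc == "Unmapped"], 25)
  expect_equal(sum(agg2$n_signals), 4L)
  expect_lt(abs(sum(agg2$percent) - 100), 0.05)

  # permutation invariance and empty input
  perm <- sig[c(3, 1, 4, 2), ]
  expect_equal(soc_aggregate(perm, map), agg)
  expect_equal(nrow(soc_aggregate(sig[0, ], map)), 0)
})

test_that("a single-PT SOC reduces to the PT-level ROR", {
  rec <- deduplicate_reports(random_extract(100, seed = 9))
  map <- load_soc_map(write_map(c("pt1,Solo SOC,TRUE")))
  soc_row <- soc_level_ror(rec, "drug1", "Solo SOC", map)
  ct <- build_contingency(rec, "drug1", "pt1")
  pt_row <- signal_stats(tibble::tibble(drug = "drug1", event = "pt1",
                                        a = ct$a, b = ct$b, c = ct$c,
                                        d = ct$d))
  expect_equal(soc_row$ror, pt_row$ror)
  expect_equal(soc_row$a, pt_row$a)
})

test_that("a two-PT SOC counts the union of cases, checked by brute force", {
  rec <- deduplicate_reports(random_extract(100, seed = 10))
  map <- load_soc_map(write_map(c("pt1,Pair SOC,TRUE", "pt2,Pair SOC,TRUE")))
  soc_row <- soc_level_ror(rec, "drug1", "Pair SOC", map)
  bf <- brute_force_table(rec, "drug1", c("pt1", "pt2"))
  expect_equal(soc_row$a, unname(bf["a"]))
  expect_equal(soc_row$c, unname(bf["c"]))
  # union bound: SOC-level a never exceeds the sum of member PT-level a
  a1 <- build_contingency(rec, "drug1", "pt1")$a
  a2 <- build_contingency(rec, "drug1", "pt2")$a
  expect_lte(soc_row$a, a1 + a2)
})

test_that("an unknown SOC or an empty extract raises an error", {
  rec <- deduplicate_reports(random_extract(20, seed = 11))
  map <- load_soc_map(write_map(c("pt1,Solo SOC,TRUE")))
  expect_error(soc_level_ror(rec, "drug1", "No Such SOC", map),
               "not present in map")
  empty <- rec[0, ]
  expect_error(soc_level_ror(empty, "drug1", "Solo SOC", map),
               "zero reports")
})

test_that("the bundled synthetic map covers every published signal PT", {
  map <- synthetic_soc_map()
  pub <- published_signals()
  lookup <- map$soc[match(unique(pub$pt), map$pt)]
  expect_false(anyNA(lookup))
  # aggregation over published voriconazole signals involves several SOCs
  vori <- tibble::tibble(drug = "voriconazole",
                         event = pub$pt[pub$drug == "voriconazole"],
                         is_signal = TRUE)
  agg <- soc_aggregate(vori, map)
  expect_equal(sum(agg$n_signals), 20L)
  expect_lt(abs(sum(agg$percent) - 100), 0.05)
})
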