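# ROR / PRR / chi-squared point values, CIs, criteria and ranking.

test_that("worked tables reproduce direct-arithmetic values", {
  # balanced table: ROR 1, chi2 0
  r <- compute_ror(c(10, 10, 10, 10))
  expect_equal(r$ror, 1)
  se <- sqrt(4 / 10)
  expect_equal(r$ci_low, exp(-1.96 * se))
  expect_equal(r$ci_high, exp(1.96 * se))
  expect_equal(round(r$ci_low, 4), 0.2895)
  expect_equal(round(r$ci_high, 4), 3.4543)
  expect_equal(chi_square(c(10, 10, 10, 10)), 0)

  # unbalanced table, all statistics against the direct formulas
  a <- 5; b <- 95; cc <- 100; d <- 9900
  r <- compute_ror(c(a, b, cc, d))
  expect_equal(r$ror, a * d / (b * cc))
  expect_equal(round(r$ror, 4), 5.2105)
  expect_equal(round(r$ci_low, 4), 2.0752)
  expect_equal(round(r$ci_high, 3), 13.083)
  p <- compute_prr(c(a, b, cc, d))
  expect_equal(p$prr, 5)
  n <- a + b + cc + d
  chi_direct <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(chi_square(c(a, b, cc, d)), chi_direct)
  expect_equal(round(chi_direct, 3), 15.398)
  yates_direct <- n * (abs(a * d - b * cc) - n / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(chi_square(c(a, b, cc, d), "yates"), yates_direct)
  expect_equal(round(yates_direct, 3), 11.756)
})

test_that("chi-squared agrees with stats::chisq.test in both variants", {
  for (i in 1:20) {
    x <- random_positive_table()
    m <- matrix(x, nrow = 2, byrow = TRUE)
    expect_equal(chi_square(x, "pearson"),
                 unname(stats::chisq.test(m, correct = FALSE)$statistic))
    expect_equal(chi_square(x, "yates"),
                 unname(stats::chisq.test(m, correct = TRUE)$statistic))
  }
})

test_that("a proportion-balanced table has PRR exactly 1", {
  # a/(a+b) = c/(c+d) = 0.2
  p <- compute_prr(c(20, 80, 40, 160))
  expect_equal(p$prr, 1)
})

test_that("zero cells flag the statistics undefined unless Haldane is on", {
  r <- compute_ror(c(0, 10, 5, 100))
  expect_true(r$undefined)
  expect_true(is.na(r$ror))
  rh <- compute_ror(c(0, 10, 5, 100), haldane = TRUE)
  expect_false(rh$undefined)
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 5.5))
  # a non-zero table is untouched by the haldane flag
  expect_equal(compute_ror(c(5, 5, 5, 5), haldane = TRUE)$ror,
               compute_ror(c(5, 5, 5, 5))$ror)
  expect_true(compute_prr(c(5, 5, 0, 5))$undefined)
  expect_true(is.na(chi_square(c(0, 0, 5, 5))))
})

test_that("the joint signal criteria read thresholds strictly", {
  mk <- function(a, lo, prr) {
    tibble::tibble(a = a, ror_ci_low = lo, prr = prr, defined = TRUE)
  }
  expect_false(apply_signal_criteria(mk(2, 5, 10)))
  expect_true(apply_signal_criteria(mk(3, 1.001, 2.001)))
  expect_false(apply_signal_criteria(mk(100, 1, 10)))   # CI low must exceed 1
  expect_false(apply_signal_criteria(mk(100, 5, 2)))    # PRR strictly > 2
  und <- tibble::tibble(a = 50, ror_ci_low = NA_real_, prr = NA_real_,
                        defined = FALSE)
  expect_false(apply_signal_criteria(und))
})

test_that("signal_stats flags pairs and reports the failed criterion", {
  pairs <- tibble::tibble(
    drug = "x",
    event = c("strong", "rare", "weak", "zero"),
    a = c(30, 2, 30, 0),
    b = c(70, 98, 370, 100),
    c = c(50, 50, 700, 50),
    d = c(9850, 9850, 8900, 9850)
  )
  st <- signal_stats(pairs)
  expect_true(st$is_signal[st$event == "strong"])
  expect_equal(st$reason[st$event == "rare"], "a_below_min")
  expect_equal(st$reason[st$event == "weak"], "ror_ci_low")
  expect_equal(st$reason[st$event == "zero"], "undefined")
  expect_true(is.na(st$reason[st$event == "strong"]))
  expect_false(any(st$is_signal[st$event != "strong"]))
})

test_that("rank_signals orders by count, then ROR, then event name", {
  st <- tibble::tibble(
    drug = "x",
    event = c("e1", "e2", "e3", "e4"),
    a = c(5, 9, 9, 9),
    ror = c(50, 3, 2, 3),
    is_signal = c(TRUE, TRUE, TRUE, TRUE)
  )
  top <- rank_signals(st, n = 3)
  expect_equal(top$event, c("e2", "e4", "e3"))
  expect_equal(nrow(rank_signals(st[0, ], 5)), 0)
})

test_that("published ranking starts with death then drug interaction", {
  pub <- published_signals()
  vori <- pub[pub$drug == "voriconazole", ]
  st <- tibble::tibble(drug = vori$drug, event = vori$pt, a = vori$a,
                       ror = vori$ror, is_signal = TRUE)
  top <- rank_signals(st, n = 20)
  expect_equal(top$event[1:2], c("death", "drug interaction"))
  expect_equal(top$a[1:2], c(734L, 513L))
})

test_that("ROR exceeds PRR exactly when ROR exceeds 1, and CIs are geometric", {
  set.seed(424)
  for (i in 1:300) {
    x <- random_positive_table()
    st <- signal_stats(tibble::tibble(a = x[1], b = x[2], c = x[3],
                                      d = x[4]))
    if (st$ror > 1) expect_gt(st$ror, st$prr)
    if (st$ror < 1) expect_lt(st$ror, st$prr)
    if (st$ror == 1) expect_equal(st$prr, 1)
    expect_lt(abs(sqrt(st$ror_ci_low * st$ror_ci_high) / st$ror - 1), 1e-9)
    expect_lt(abs(sqrt(st$prr_ci_low * st$prr_ci_high) / st$prr - 1), 1e-9)
  }
})

test_that("chi-squared is invariant under simultaneous row and column swap", {
  set.seed(77)
  for (i in 1:25) {
    x <- random_positive_table()
    swapped <- c(x[4], x[3], x[2], x[1])
    expect_equal(chi_square(x), chi_square(swapped))
    expect_equal(chi_square(x, "yates"), chi_square(swapped, "yates"))
  }
})

test_that("increasing a with the other cells fixed increases ROR and PRR", {
  set.seed(88)
  for (i in 1:25) {
    x <- random_positive_table()
    r0 <- compute_ror(x)$ror; r1 <- compute_ror(x + c(5, 0, 0, 0))$ror
    p0 <- compute_prr(x)$prr; p1 <- compute_prr(x + c(5, 0, 0, 0))$prr
    expect_gt(r1, r0)
    expect_gt(p1, p0)
  }
})

test_that("the published death row is consistent with the ROR > PRR identity", {
  pub <- published_signals()
  death <- pub[pub$drug == "voriconazole" & pub$pt == "death", ]
  expect_gt(death$ror, 1)
  expect_gt(death$ror, death$prr)
})
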