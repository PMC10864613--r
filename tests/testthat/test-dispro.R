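# one case per event so the X-term table is exactly (a, b, c, d)
events_from_counts <- function(a, b, c, d) {
  ids <- sprintf("id%05d", seq_len(a + b + c + d))
  target <- ids[seq_len(a + b)]
  ev <- tibble::tibble(
    primaryid = ids,
    pt = c(rep("X", a), rep("Y", b), rep("X", c), rep("Y", d)),
    soc = "S"
  )
  list(events = ev, target = target)
}

test_that("a hand-enumerated background yields the full 2x2 partition", {
  ev <- tibble::tibble(primaryid = c("1", "2", "3", "4"),
                       pt = c("ptP", "ptQ", "ptP", "ptQ"), soc = "s")
  t <- build_contingency(ev, target_ids = c("1", "2"), term = "ptP", level = "pt")
  expect_equal(unlist(t[c("a", "b", "c", "d")], use.names = FALSE), c(1L, 1L, 1L, 1L))
  # target term absent for the target drug
  t0 <- build_contingency(ev, target_ids = c("1", "2"), term = "ptZ", level = "pt")
  expect_equal(t0$a, 0L)
  expect_equal(t0$b, 2L)
})

test_that("the reporting odds ratio and its Woolf interval match hand values", {
  r <- ror_ci(1, 1, 1, 1)
  expect_equal(r$ror, 1)
  expect_equal(r$ror_low, exp(-1.96 * 2), tolerance = 1e-4)
  expect_equal(r$ror_high, exp(1.96 * 2), tolerance = 1e-4)
  expect_equal(ror_ci(10, 90, 100, 9900)$ror, 11)
  # zero cell without correction is undefined, never an error
  expect_true(is.na(ror_ci(0, 10, 10, 100)$ror))
  expect_false(is.na(ror_ci(0, 10, 10, 100, correction = "haldane")$ror))
})

test_that("PRR and the plain Pearson chi-squared match hand values and the oracle", {
  p <- prr_chisq(1, 1, 1, 1)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(prr_chisq(10, 90, 100, 9900)$prr, 10)
  oracle <- function(a, b, c, d) {
    unname(suppressWarnings(
      stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE), correct = FALSE)$statistic
    ))
  }
  expect_equal(prr_chisq(10, 90, 100, 9900)$chi2, oracle(10, 90, 100, 9900),
               tolerance = 1e-12)
  tabs <- random_tables(200, seed = 7)
  got <- prr_chisq(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  want <- purrr::pmap_dbl(tabs, oracle)
  expect_lt(max(abs(got - want)), 1e-9)
  # Yates variant agrees with the corrected oracle on a 2x2
  expect_equal(prr_chisq(10, 90, 100, 9900, yates = TRUE)$chi2,
               unname(suppressWarnings(
                 stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                                   correct = TRUE)$statistic
               )),
               tolerance = 1e-9)
})

test_that("the raw information component matches its printed formula", {
  for (k in c(1, 2, 5, 100)) {
    expect_equal(bcpnn_ic(k, k, k, k, method = "bate")$ic, 0)
  }
  expect_equal(bcpnn_ic(10, 90, 100, 9900, method = "bate")$ic, log2(101 / 11),
               tolerance = 1e-12)
  expect_equal(log2(101 / 11), 3.198875, tolerance = 1e-4)
  expect_true(is.na(bcpnn_ic(0, 10, 10, 100, method = "bate")$ic))
})

test_that("closed-form credibility bounds track the Monte-Carlo posterior", {
  tabs <- random_tables(15, min_cell = 5, seed = 21)
  cf <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d, method = "closed_form")
  mc <- withr::with_seed(404,
    bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d, method = "monte_carlo", n_draws = 4e4))
  expect_lt(max(abs(cf$ic025 - mc$ic025)), 0.1)
  expect_lt(max(abs(cf$ic975 - mc$ic975)), 0.1)
  # interval brackets the point estimate
  expect_true(all(cf$ic025 <= cf$ic & cf$ic <= cf$ic975))
  # a = 0 still yields finite bounds through the prior
  z <- bcpnn_ic(0, 10, 10, 100)
  expect_true(is.finite(z$ic025) && is.finite(z$ic975))
  expect_lt(z$ic025, 0)
})

test_that("all three statistics are monotone in a and null at independence", {
  a <- 1:50
  r <- ror_ci(a, 100, 50, 5000)$ror
  p <- prr_chisq(a, 100, 50, 5000)$prr
  ic <- bcpnn_ic(a, 100, 50, 5000, method = "bate")$ic
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(ic) > 0))
  # chi2 = 0 and ror = 1 exactly when ad = bc
  expect_equal(prr_chisq(6, 3, 10, 5)$chi2, 0)
  expect_equal(ror_ci(6, 3, 10, 5)$ror, 1)
  expect_gt(prr_chisq(7, 3, 10, 5)$chi2, 0)
})

test_that("signal criteria require a >= 3, the thresholds, and defined statistics", {
  # huge ror but only two cases -> no ROR flag
  e <- events_from_counts(2, 1, 1, 1000)
  res <- dispro_signals(e$events, e$target)
  x <- res[res$term == "X", ]
  expect_gt(x$ror, 100)
  expect_false(x$flag_ror)
  expect_false(x$consensus)
  # the worked table satisfies the PRR criterion
  e <- events_from_counts(10, 90, 100, 9900)
  x <- dispro_signals(e$events, e$target) %>% dplyr::filter(term == "X")
  expect_true(x$flag_prr)
  expect_true(x$consensus == (x$flag_ror && x$flag_prr && x$flag_bcpnn))
  # undefined statistics can never signal: term absent from the background
  e <- events_from_counts(5, 5, 0, 10)
  e$events <- e$events[e$events$pt == "X" | e$events$primaryid %in% e$target, ]
  x <- dispro_signals(e$events, e$target) %>% dplyr::filter(term == "X")
  expect_true(is.na(x$ror))
  expect_false(x$flag_ror)
  expect_false(x$consensus)
})

test_that("consensus signals split into expected and unexpected by the label list", {
  e <- events_from_counts(30, 70, 20, 2000)
  res <- dispro_signals(e$events, e$target)
  expect_true(res$consensus[res$term == "X"])
  out <- flag_unexpected(res, label_terms = "x") # case-folded match
  expect_equal(out$expected[out$term == "X"], "expected")
  out <- flag_unexpected(res, label_terms = "something else")
  expect_equal(out$expected[out$term == "X"], "unexpected")
  expect_equal(out$expected[out$term == "Y"], "n/a")
  expect_warning(unk <- flag_unexpected(res, NULL), "label")
  expect_true(all(is.na(unk$expected)))
})

test_that("ranking sorts descending with alphabetical tie-break, stably", {
  res <- tibble::tibble(term = c("banana", "apple", "cherry"),
                        a = c(35, 58, 35), ic025 = c(1.2, 0.5, 3.0))
  by_n <- rank_signals(res, "case_number")
  expect_equal(by_n$term, c("apple", "banana", "cherry"))
  by_ic <- rank_signals(res, "ic025")
  expect_equal(by_ic$term, c("cherry", "banana", "apple"))
  expect_equal(nrow(rank_signals(res[0, ], "case_number")), 0)
})

test_that("consensus recovers planted signals on synthetic data", {
  res <- shared_pipeline()
  sim <- shared_sim()
  sig <- dplyr::inner_join(res$signals_pt, sim$truth$signals, by = c(term = "pt"))
  # the consensus set is contained in each per-algorithm positive set
  expect_true(all(sig$flag_ror[sig$consensus]))
  expect_true(all(sig$flag_prr[sig$consensus]))
  expect_true(all(sig$flag_bcpnn[sig$consensus]))
  # the strongest planted signals dominate the observed-to-expected ratio
  strong <- sig[sig$lambda == 8, ]
  expect_true(all(strong$a / (strong$a + strong$b) >
                    strong$c / (strong$c + strong$d)))
})
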