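tto_toy <- function(demo, ther) {
  drug <- tibble::tibble(PRIMARYID = unique(demo$PRIMARYID),
                         CASEID = unique(demo$CASEID), DRUG_SEQ = "1",
                         ROLE_COD = "PS", DRUGNAME = "TARGETINIB", PROD_AI = NA)
  reac <- tibble::tibble(PRIMARYID = demo$PRIMARYID, CASEID = demo$CASEID,
                         PT = "Dizziness")
  cases <- assemble_cases(toy_bundle(demo = demo, drug = drug, reac = reac, ther = ther))
  select_primary_suspect(cases, test_dict())
}

test_that("onset intervals are whole-day differences with the stated exclusions", {
  demo <- dplyr::bind_rows(
    demo_row("11", caseid = "1", event = "20200115"),
    demo_row("21", caseid = "2", event = "20191230"),
    demo_row("31", caseid = "3", event = "20200101"),
    demo_row("41", caseid = "4", event = "202001"),
    demo_row("51", caseid = "5", event = NA),
    demo_row("61", caseid = "6", event = "20200301")
  )
  ther <- tibble::tibble(
    PRIMARYID = c("11", "21", "31", "41", "51", "61"),
    CASEID = c("1", "2", "3", "4", "5", "6"),
    DSG_DRUG_SEQ = "1",
    START_DT = c("20200101", "20200101", "20200101", "20200101", "20200101", "202003"),
    END_DT = NA
  )
  tto <- compute_tto(tto_toy(demo, ther))
  rec <- tto$records
  expect_equal(rec$days[rec$caseid == "1"], 14L)
  expect_false("2" %in% rec$caseid) # onset precedes start
  expect_equal(rec$days[rec$caseid == "3"], 0L) # same-day onset retained
  expect_false("4" %in% rec$caseid) # partial event date
  expect_false("5" %in% rec$caseid) # missing event date
  expect_false("6" %in% rec$caseid) # only a partial start date
  audit <- tibble::deframe(tto$audit)
  expect_equal(unname(audit["used"]), 2L)
  expect_equal(unname(audit["onset precedes therapy start"]), 1L)
  # audit partitions the cohort
  expect_equal(sum(tto$audit$n), 6L)
})

test_that("the earliest complete start date among linked therapy rows is used", {
  demo <- demo_row("11", caseid = "1", event = "20200215")
  ther <- tibble::tibble(
    PRIMARYID = "11", CASEID = "1", DSG_DRUG_SEQ = c("1", "1", "1", "2"),
    START_DT = c("20200201", "20200101", "202001", "20190101"), END_DT = NA
  )
  # seq 2 belongs to another drug; the partial row is ignored
  rec <- compute_tto(tto_toy(demo, ther))$records
  expect_equal(rec$days, 45L) # from 2020-01-01, the earliest full linked start
})

test_that("onset summaries use linear-interpolation quantiles, order-free", {
  rec <- tibble::tibble(primaryid = as.character(1:3), caseid = as.character(1:3),
                        days = c(30, 10, 20))
  s <- summarize_tto(rec)
  expect_equal(s$median, 20)
  expect_equal(c(s$q1, s$q3), c(15, 25))
  s1 <- summarize_tto(rec[c(2, 3, 1), ])
  expect_equal(s, s1)
  single <- summarize_tto(tibble::tibble(primaryid = "1", caseid = "1", days = 5))
  expect_equal(c(single$median, single$q1, single$q3), c(5, 5, 5))
  # per-SOC summaries reuse the case's events' organ classes
  ev <- tibble::tibble(primaryid = c("1", "1", "2", "3"),
                       soc = c("A", "B", "A", "A"))
  by_soc <- summarize_tto(rec, by = "soc", events = ev)
  expect_equal(by_soc$n[by_soc$group == "A"], 3L)
  expect_equal(by_soc$n[by_soc$group == "B"], 1L)
})

test_that("period histogram uses the fixed bins with day 0 in the first", {
  rec <- tibble::tibble(days = c(0, 400))
  h <- tto_periods(rec)
  expect_equal(h$n[h$period == "0-30"], 1L)
  expect_equal(h$n[h$period == ">360"], 1L)
  expect_equal(sum(h$n), 2L)
  expect_equal(h$pct[h$period == "0-30"], 50)
  edge <- tto_periods(tibble::tibble(days = c(30, 31, 360, 361)))
  expect_equal(edge$n, c(1L, 1L, 0L, 0L, 1L, 1L))
})

test_that("maximum likelihood recovers the Weibull parameters", {
  days <- withr::with_seed(71, round(rweibull(500, 0.56, 30)))
  fit <- fit_weibull(days)
  expect_true(fit$converged)
  expect_lt(abs(fit$shape - 0.56), 0.15 * 0.56)
  expect_true(fit$shape_ci[1] <= fit$shape & fit$shape <= fit$shape_ci[2])
  expect_true(all(c(fit$shape_ci, fit$scale_ci) > 0))
  td <- tidy(fit)
  expect_equal(td$term, c("shape", "scale"))
  expect_equal(td$estimate[1], fit$shape)
  g <- glance(fit)
  expect_equal(g$n, 500L)
})

test_that("the fit agrees with an independent MLE implementation", {
  # exact-observation path vs fitdistrplus on continuous data
  days <- withr::with_seed(72, rweibull(400, 0.8, 45))
  fit <- fit_weibull(days)
  ref <- fitdistrplus::fitdist(days, "weibull")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  # interval-censored path vs fitdistrplus on whole-day data
  d <- withr::with_seed(73, round(rweibull(400, 0.7, 30)))
  fit2 <- fit_weibull(d)
  cens <- data.frame(left = ifelse(d == 0, NA, d - 0.5), right = d + 0.5)
  ref2 <- fitdistrplus::fitdistcens(cens, "weibull")
  expect_equal(fit2$shape, unname(ref2$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit2$scale, unname(ref2$estimate["scale"]), tolerance = 1e-3)
})

test_that("shape estimation is nearly unbiased at moderate size", {
  shapes <- vapply(1:50, function(i) {
    days <- withr::with_seed(1000 + i, round(rweibull(2000, 0.56, 30)))
    fit_weibull(days)$shape
  }, numeric(1))
  expect_lt(abs(mean(shapes) - 0.56), 0.05 * 0.56)
})

test_that("degenerate and undersized inputs are refused gracefully", {
  expect_error(fit_weibull(c(5, 6, 7)), "at least 10")
  fit <- fit_weibull(rep(10, 50))
  expect_false(fit$converged)
  expect_equal(fit$hazard_class, "indeterminate")
  expect_equal(classify_hazard(fit), "indeterminate")
})

test_that("hazard classification uses the whole confidence interval", {
  mk <- function(lo, hi) structure(list(converged = TRUE, shape_ci = c(lo, hi)),
                                   class = "weibull_fit")
  expect_equal(classify_hazard(mk(0.51, 0.61)), "early-failure")
  expect_equal(classify_hazard(mk(0.9, 1.1)), "random")
  expect_equal(classify_hazard(mk(1.2, 1.6)), "wear-out")
})
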