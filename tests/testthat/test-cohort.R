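test_that("drug matching normalises case and whitespace; substring mode widens", {
  dict <- drug_dictionary("larotrectinib", brand = "VITRAKVI")
  expect_true(match_drug("VITRAKVI", dict = dict))
  expect_true(match_drug("vitrakvi ", dict = dict))
  expect_true(match_drug("Larotrectinib", dict = dict))
  expect_false(match_drug("LAROTRECTINIB MESYLATE", dict = dict))
  expect_true(match_drug("LAROTRECTINIB MESYLATE", dict = dict, mode = "substring"))
  expect_false(match_drug("OXALIPLATIN", dict = dict, mode = "substring"))
  # PROD_AI can match when DRUGNAME does not
  expect_true(match_drug("BRANDED THING", prod_ai = "larotrectinib", dict = dict))
  expect_error(drug_dictionary(" "), "non-empty")
})

toy_cases <- function() {
  b <- toy_bundle(
    demo = dplyr::bind_rows(
      demo_row("1011", caseid = "101"), # target as PS
      demo_row("1021", caseid = "102"), # target as C only
      demo_row("1031", caseid = "103"), # target PS + other drugs SS
      demo_row("1041", caseid = "104")  # unrelated
    ),
    drug = dplyr::bind_rows(
      tibble::tibble(PRIMARYID = "1011", CASEID = "101", DRUG_SEQ = "1",
                     ROLE_COD = "PS", DRUGNAME = "TARGETINIB", PROD_AI = NA),
      tibble::tibble(PRIMARYID = "1021", CASEID = "102", DRUG_SEQ = "1",
                     ROLE_COD = "C", DRUGNAME = "TARGETINIB", PROD_AI = NA),
      tibble::tibble(PRIMARYID = "1031", CASEID = "103", DRUG_SEQ = c("1", "2"),
                     ROLE_COD = c("PS", "SS"), DRUGNAME = c("TARGETRA", "OTHERDRUG"),
                     PROD_AI = NA),
      tibble::tibble(PRIMARYID = "1041", CASEID = "104", DRUG_SEQ = "1",
                     ROLE_COD = "PS", DRUGNAME = "OTHERDRUG", PROD_AI = NA)
    ),
    reac = tibble::tibble(
      PRIMARYID = c("1011", "1011", "1021", "1031", "1041"),
      CASEID = c("101", "101", "102", "103", "104"),
      PT = c("Dizziness", "Ataxia", "Dizziness", "Tremor", "Dizziness")
    )
  )
  assemble_cases(b)
}

subset_cases_for_test <- function(cases, ids) faersignal:::subset_cases(cases, ids)

test_that("primary-suspect selection conditions on the target role only", {
  cases <- toy_cases()
  cohort <- select_primary_suspect(cases, test_dict())
  expect_setequal(cohort$demo$primaryid, c("1011", "1031"))
  expect_equal(cohort$matched,
               tibble::tibble(primaryid = c("1011", "1031"), drug_seq = 1L))
  # the PS cohort is a subset of dictionary matches regardless of role
  any_role <- unique(cases$drugs$primaryid[match_drug(cases$drugs$drugname,
                                                      cases$drugs$prod_ai, test_dict())])
  expect_true(all(cohort$demo$primaryid %in% any_role))
  # empty input -> empty cohort
  empty <- subset_cases_for_test(cases, character(0))
  expect_equal(nrow(select_primary_suspect(empty, test_dict())$demo), 0)
})

test_that("event explosion counts each distinct PT once per case and maps SOC", {
  b <- toy_bundle(
    demo = demo_row("1011", caseid = "101"),
    reac = tibble::tibble(PRIMARYID = "1011", CASEID = "101",
                          PT = c("dizziness", "dizziness", "ataxia"))
  )
  map <- tibble::tibble(pt = c("dizziness", "vertigo"), soc = "Nervous-like class")
  ev <- explode_events(assemble_cases(b), map)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$pt, c("dizziness", "ataxia"))
  expect_equal(ev$soc[ev$pt == "dizziness"], "Nervous-like class")
  expect_equal(ev$soc[ev$pt == "ataxia"], "UNMAPPED")
  expect_equal(attr(ev, "n_unmapped"), 1)
  # empty cohort -> no events
  none <- explode_events(subset_cases_for_test(assemble_cases(b), character(0)), map)
  expect_equal(nrow(none), 0)
})

test_that("indication-related terms are excluded by case-folded equality", {
  ev <- tibble::tibble(primaryid = c("1", "2", "3"),
                       pt = c("Thyroid cancer", "Dizziness", "THYROID CANCER"),
                       soc = "x")
  out <- exclude_indication_terms(ev, "thyroid cancer")
  expect_equal(out$pt, "Dizziness")
  expect_equal(attr(out, "n_excluded"), 2)
  # empty set is the identity
  same <- exclude_indication_terms(ev, character(0))
  expect_equal(nrow(same), 3)
  # everything indication-related -> empty output with a warning
  expect_warning(gone <- exclude_indication_terms(ev[-2, ], "thyroid cancer"), "no events")
  expect_equal(nrow(gone), 0)
})

test_that("the default indication set derives from the cohort's own INDI records", {
  b <- toy_bundle(
    demo = demo_row("1011", caseid = "101"),
    drug = tibble::tibble(PRIMARYID = "1011", CASEID = "101", DRUG_SEQ = "1",
                          ROLE_COD = "PS", DRUGNAME = "TARGETINIB", PROD_AI = NA),
    reac = tibble::tibble(PRIMARYID = "1011", CASEID = "101",
                          PT = c("Neoplasm-like term", "Dizziness")),
    indi = tibble::tibble(PRIMARYID = "1011", CASEID = "101", INDI_DRUG_SEQ = "1",
                          INDI_PT = "Neoplasm-like term")
  )
  cases <- assemble_cases(b)
  cohort <- select_primary_suspect(cases, test_dict())
  ev <- explode_events(cases, tibble::tibble(pt = character(0), soc = character(0)))
  out <- exclude_indication_terms(ev, cohort = cohort)
  expect_equal(out$pt, "Dizziness")
  expect_error(exclude_indication_terms(ev), "indication_pts")
})

test_that("event conservation holds across the organ-class partition", {
  res <- shared_pipeline()
  ev <- res$events
  counts <- contingency_counts(ev, res$cohort$demo$primaryid, level = "soc")
  expect_equal(sum(counts$a), sum(ev$primaryid %in% res$cohort$demo$primaryid))
  expect_equal(sum(counts$a + counts$c), nrow(ev))
})
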