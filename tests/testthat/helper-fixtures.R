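# shared fixtures, all built in code

test_dict <- function() drug_dictionary("targetinib", brand = "TARGETRA")

# build a faers_bundle from partial row specs; unnamed columns filled with NA
toy_bundle <- function(demo = NULL, drug = NULL, reac = NULL, ther = NULL,
                       indi = NULL, outc = NULL, quarter = "2020Q1") {
  spec <- faersignal:::faers_table_columns()
  one <- function(rows, cols) {
    if (is.null(rows)) {
      return(tibble::as_tibble(c(list(quarter = character(0)),
                                 stats::setNames(rep(list(character(0)), length(cols)), cols))))
    }
    rows <- tibble::as_tibble(rows)
    if (!"quarter" %in% names(rows)) rows$quarter <- quarter
    for (cl in cols) if (!cl %in% names(rows)) rows[[cl]] <- NA_character_
    rows[, c("quarter", cols)]
  }
  structure(
    list(demo = one(demo, spec$demo), drug = one(drug, spec$drug),
         reac = one(reac, spec$reac), ther = one(ther, spec$ther),
         indi = one(indi, spec$indi), outc = one(outc, spec$outc)),
    class = "faers_bundle"
  )
}

# a DEMO row with sensible defaults
demo_row <- function(primaryid, caseid = substr(primaryid, 1, nchar(primaryid) - 1),
                     fda = "20200301", event = "20200201", ...) {
  tibble::tibble(PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fda,
                 EVENT_DT = event, ...)
}

# medium synthetic dataset shared across tests (built once per run)
shared_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      sim <<- faers_simulate(synth_scenario(n_reports = 4000, seed = 417))
    }
    sim
  }
})

shared_pipeline <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      sim <- shared_sim()
      res <<- faers_pipeline(sim, test_dict(), sim$truth$scenario$pt_vocabulary)
    }
    res
  }
})

random_tables <- function(n, min_cell = 0, seed = 99) {
  withr::with_seed(seed, tibble::tibble(
    a = sample(max(min_cell, 1):150, n, TRUE),
    b = sample(max(min_cell, 1):800, n, TRUE),
    c = sample(max(min_cell, 1):800, n, TRUE),
    d = sample(max(min_cell, 5):30000, n, TRUE)
  ))
}
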