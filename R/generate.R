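#' Simulate a FAERS-like quarterly report stream
#'
#' Generates the six raw tables of a spontaneous-report database (DEMO, DRUG,
#' REAC, THER, INDI, OUTC) for a [synth_scenario()], together with a
#' ground-truth ledger. All table columns are character, exactly as the
#' "$"-delimited ASCII distribution carries them; typed parsing happens at
#' ingestion ([assemble_cases()]), never here.
#'
#' Structure generated per case: one DEMO row per submitted version; a
#' primary-suspect DRUG row (the target drug for a `target_share` fraction of
#' cases) plus a Poisson number of co-reported SS/C/I drugs; 1-10 distinct
#' reaction PTs drawn without replacement with weights
#' `weight * lambda(drug, pt)`; THER rows whose START_DT places the DEMO
#' EVENT_DT a Weibull-distributed whole-day interval after therapy start;
#' INDI and OUTC rows. A `duplication_rate` fraction of cases is re-submitted
#' under the same CASEID with a higher PRIMARYID and a later (or tied) FDA_DT.
#'
#' @param scenario A [synth_scenario()].
#' @return An object of class `faers_sim`: a list with `tables` (class
#'   `faers_bundle`, the six tibbles, each carrying a `quarter` column) and
#'   `truth`, a list holding `signals` (pt, lambda, is_signal), `duplicates`
#'   (caseid, kept/removed PRIMARYID, fda_tie), `cohort` (caseids whose
#'   primary suspect is the target drug), `tto` (true onset intervals) and the
#'   scenario itself.
#' @export
#' @examples
#' sim <- faers_simulate(synth_scenario(n_reports = 200, seed = 7))
#' sim$tables$demo
faers_simulate <- function(scenario) {
  scenario <- validate_scenario(scenario)
  withr::with_seed(scenario$seed, simulate_impl(scenario))
}

# weighted sampling without replacement of k[i] of P items for each of m rows,
# exponential-key trick: item j of row i wins a slot iff its key rexp(1)/w[j]
# ranks among the k[i] smallest in the row
sample_terms <- function(m, k, w) {
  P <- length(w)
  if (m == 0) return(list(case = integer(0), pt = integer(0)))
  keys <- stats::rexp(m * P) / rep(w, times = m)
  ord <- order(rep(seq_len(m), each = P), keys)
  idx <- ord[rep((seq_len(m) - 1L) * P, times = k) + sequence(k)]
  list(case = rep(seq_len(m), times = k), pt = (idx - 1L) %% P + 1L)
}

empty_tables <- function() {
  structure(purrr::imap(faers_table_columns(), function(cols, nm) {
    tibble::as_tibble(c(list(quarter = character(0)),
                        stats::setNames(rep(list(character(0)), length(cols)), cols)))
  }), class = "faers_bundle")
}

simulate_impl <- function(scn) {
  n <- scn$n_reports
  vocab <- scn$pt_vocabulary
  if (n == 0L) {
    return(structure(list(
      tables = empty_tables(),
      truth = list(
        signals = tibble::tibble(pt = vocab$pt, soc = vocab$soc,
                                 lambda = {
                                   l <- rep(1, nrow(vocab))
                                   l[match(scn$signal_spec$pt, vocab$pt)] <- scn$signal_spec$lambda
                                   l
                                 },
                                 is_signal = lambda > 1),
        duplicates = tibble::tibble(caseid = character(0), kept_primaryid = character(0),
                                    removed_primaryid = character(0), fda_tie = logical(0)),
        cohort = tibble::tibble(caseid = character(0), primaryid = character(0)),
        tto = tibble::tibble(caseid = character(0), days = integer(0), negative = logical(0)),
        scenario = scn
      )
    ), class = "faers_sim"))
  }
  P <- nrow(vocab)
  win <- list(start = quarter_bounds(scn$quarters[1])$start,
              end = quarter_bounds(scn$quarters[length(scn$quarters)])$end)
  span <- as.integer(win$end - win$start)

  lambda <- rep(1, P)
  lambda[match(scn$signal_spec$pt, vocab$pt)] <- scn$signal_spec$lambda

  caseid <- sprintf("%d", 10000000L + seq_len(n))
  pid1 <- paste0(caseid, "1")

  is_target <- stats::runif(n) < scn$target_share

  ## primary-suspect drug name
  ps_name <- character(n)
  nt <- sum(is_target)
  form <- sample(c("GEN", "BRAND", "gen"), nt, TRUE, prob = c(0.45, 0.35, 0.20))
  ps_name[is_target] <- dplyr::case_when(
    form == "GEN" ~ toupper(scn$target_drug$generic),
    form == "BRAND" ~ scn$target_drug$brand,
    TRUE ~ scn$target_drug$generic
  )
  ps_name[!is_target] <- sample(scn$background_drugs, n - nt, TRUE)
  ps_ai <- ifelse(is_target & stats::runif(n) < 0.8,
                  toupper(scn$target_drug$generic), NA_character_)

  ## reactions: distinct PTs per case, truncated-geometric count on 1..10
  kprob <- stats::dgeom(0:9, 0.5)
  k <- sample.int(10L, n, TRUE, prob = kprob / sum(kprob))
  tgt_idx <- which(is_target)
  bg_idx <- which(!is_target)
  st <- sample_terms(length(tgt_idx), k[tgt_idx], vocab$weight * lambda)
  sb <- sample_terms(length(bg_idx), k[bg_idx], vocab$weight)
  reac_case <- c(tgt_idx[st$case], bg_idx[sb$case])
  reac_pt <- c(st$pt, sb$pt)

  ## timeline: therapy start -> event (Weibull days) -> report receipt
  start <- win$start + sample.int(max(span - 60L, 1L), n, TRUE) - 1L
  tto_days <- round(stats::rweibull(n, scn$tto$shape, scn$tto$scale))
  neg <- stats::runif(n) < scn$negative_tto_rate
  event <- start + ifelse(neg, -sample.int(30L, n, TRUE), tto_days)
  fda <- event + 7L + stats::rgeom(n, 1 / 40)
  fda <- pmin(pmax(fda, win$start), win$end)
  quarter <- quarter_of_date(fda)

  ## demographics
  ms <- scn$missingness
  grp <- sample.int(3L, n, TRUE, prob = c(0.2, 0.7, 0.1))
  age_years <- c(stats::runif(n, 0.5, 17), stats::runif(n, 18, 64),
                 stats::runif(n, 65, 90))[seq_len(n) + (grp - 1L) * n]
  age_known <- stats::runif(n) >= ms$age
  unit <- sample(c("YR", "MON", "DEC", "DY", "WK"), n, TRUE,
                 prob = c(0.80, 0.05, 0.05, 0.07, 0.03))
  age_val <- dplyr::case_when(
    unit == "YR" ~ round(age_years),
    unit == "MON" ~ round(age_years * 12),
    unit == "DEC" ~ round(age_years / 10),
    unit == "DY" ~ round(age_years * 365),
    TRUE ~ round(age_years * 52)
  )
  age <- ifelse(age_known, sprintf("%d", as.integer(age_val)), NA_character_)
  age_cod <- ifelse(age_known, unit, NA_character_)
  sex <- ifelse(stats::runif(n) < ms$sex, NA_character_,
                sample(c("F", "M"), n, TRUE, prob = c(0.52, 0.48)))
  wt <- ifelse(stats::runif(n) < ms$weight, NA_character_,
               sprintf("%.1f", pmin(pmax(stats::rnorm(n, 70, 18), 4), 160)))
  country <- sample(c("US", "JP", "FR", "DE", "CA", "GB", "MX", "CH", "IL", "BR"),
                    n, TRUE, prob = c(0.50, 0.12, 0.07, 0.06, 0.05, 0.05, 0.04, 0.04, 0.03, 0.04))
  occp <- sample(c("MD", "PH", "OT", "CN", NA), n, TRUE,
                 prob = c(0.30, 0.15, 0.18, 0.34, 0.03))

  event_str <- encode_date(event, miss = ms$event_dt, partial = ms$partial_event)

  demo <- tibble::tibble(
    quarter = quarter, PRIMARYID = pid1, CASEID = caseid,
    FDA_DT = date_to_faers(fda), EVENT_DT = event_str,
    AGE = age, AGE_COD = age_cod, SEX = sex, WT = wt,
    REPORTER_COUNTRY = country, OCCP_COD = occp
  )

  ## drugs: PS row + extras; occasionally the target appears in a non-PS role
  n_extra <- pmin(stats::rpois(n, scn$extra_drug_mean), 3L)
  conc_target <- !is_target & stats::runif(n) < 0.01
  ex_case <- rep(seq_len(n), n_extra)
  ex_seq <- sequence(n_extra) + 1L
  drug <- dplyr::bind_rows(
    tibble::tibble(case = seq_len(n), DRUG_SEQ = "1", ROLE_COD = "PS",
                   DRUGNAME = ps_name, PROD_AI = ps_ai),
    tibble::tibble(case = ex_case, DRUG_SEQ = sprintf("%d", ex_seq),
                   ROLE_COD = sample(c("SS", "C", "I"), length(ex_case), TRUE,
                                     prob = c(0.40, 0.45, 0.15)),
                   DRUGNAME = sample(scn$background_drugs, length(ex_case), TRUE),
                   PROD_AI = NA_character_),
    tibble::tibble(case = which(conc_target),
                   DRUG_SEQ = sprintf("%d", n_extra[conc_target] + 2L),
                   ROLE_COD = "C", DRUGNAME = toupper(scn$target_drug$generic),
                   PROD_AI = NA_character_)
  ) %>%
    dplyr::arrange(.data$case, as.integer(.data$DRUG_SEQ))

  ## reactions; target cases sometimes also report their indication term
  indic <- ifelse(stats::runif(n) < 0.8,
                  sample(scn$indication_pts, n, TRUE), NA_character_)
  ind_as_reac <- which(is_target & !is.na(indic) &
                         stats::runif(n) < scn$indication_reaction_rate)
  reac <- dplyr::bind_rows(
    tibble::tibble(case = reac_case, PT = vocab$pt[reac_pt]),
    tibble::tibble(case = ind_as_reac, PT = indic[ind_as_reac])
  ) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$case, .data$PT)

  ## therapy rows for the PS drug (a second, later row for 10% of them) and
  ## for a fraction of co-reported drugs
  has_ther <- stats::runif(n) < 0.9
  start_str <- encode_date(start, miss = ms$start_dt, partial = ms$partial_start)
  end_dt <- start + round(stats::runif(n, 10, 300))
  end_str <- ifelse(stats::runif(n) < 0.5, date_to_faers(end_dt), NA_character_)
  second <- has_ther & stats::runif(n) < 0.1
  ex_ther <- stats::runif(length(ex_case)) < 0.4
  ther <- dplyr::bind_rows(
    tibble::tibble(case = which(has_ther), DSG_DRUG_SEQ = "1",
                   START_DT = start_str[has_ther], END_DT = end_str[has_ther]),
    tibble::tibble(case = which(second), DSG_DRUG_SEQ = "1",
                   START_DT = date_to_faers(start[second] +
                                              sample.int(200L, sum(second), TRUE) + 29L),
                   END_DT = NA_character_),
    tibble::tibble(case = ex_case[ex_ther], DSG_DRUG_SEQ = sprintf("%d", ex_seq[ex_ther]),
                   START_DT = date_to_faers(win$start +
                                              sample.int(max(span, 1L), sum(ex_ther), TRUE) - 1L),
                   END_DT = NA_character_)
  ) %>%
    dplyr::arrange(.data$case, as.integer(.data$DSG_DRUG_SEQ), .data$START_DT)

  indi <- tibble::tibble(case = which(!is.na(indic)), INDI_DRUG_SEQ = "1",
                         INDI_PT = indic[!is.na(indic)])

  outc_prob <- c(OT = 0.38, HO = 0.28, DE = 0.17, LT = 0.024, DS = 0.010)
  outc <- purrr::map_dfr(names(outc_prob), function(code) {
    tibble::tibble(case = which(stats::runif(n) < outc_prob[[code]]), OUTC_COD = code)
  }) %>% dplyr::arrange(.data$case, .data$OUTC_COD)

  ## duplicate submissions: same CASEID, higher PRIMARYID, later or tied FDA_DT
  dup <- which(stats::runif(n) < scn$duplication_rate)
  fda2 <- pmin(fda[dup] + 14L + sample.int(106L, length(dup), TRUE), win$end)
  tie <- stats::runif(length(dup)) < scn$fda_tie_rate
  fda2[tie] <- fda[dup][tie]
  pid2 <- paste0(caseid[dup], "2")

  child <- function(tab, extra_cols) {
    out <- tibble::tibble(
      quarter = quarter[tab$case], PRIMARYID = pid1[tab$case], CASEID = caseid[tab$case]
    )
    v2 <- match(tab$case, dup)
    dup_rows <- which(!is.na(v2))
    out <- dplyr::bind_cols(out, tab[extra_cols])
    if (length(dup_rows)) {
      d2 <- out[dup_rows, ]
      d2$quarter <- quarter_of_date(fda2[v2[dup_rows]])
      d2$PRIMARYID <- pid2[v2[dup_rows]]
      out <- dplyr::bind_rows(out, d2)
    }
    out
  }

  demo2 <- demo[dup, ]
  demo2$PRIMARYID <- pid2
  demo2$FDA_DT <- date_to_faers(fda2)
  demo2$quarter <- quarter_of_date(fda2)
  tables <- structure(list(
    demo = dplyr::bind_rows(demo, demo2),
    drug = child(drug, c("DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI")),
    reac = child(reac, "PT"),
    ther = child(ther, c("DSG_DRUG_SEQ", "START_DT", "END_DT")),
    indi = child(indi, c("INDI_DRUG_SEQ", "INDI_PT")),
    outc = child(outc, "OUTC_COD")
  ), class = "faers_bundle")

  truth <- list(
    signals = tibble::tibble(pt = vocab$pt, soc = vocab$soc, lambda = lambda,
                             is_signal = lambda > 1),
    duplicates = tibble::tibble(caseid = caseid[dup], kept_primaryid = pid2,
                                removed_primaryid = pid1[dup],
                                fda_tie = fda2 == fda[dup]),
    cohort = tibble::tibble(caseid = caseid[is_target],
                            primaryid = ifelse(caseid[is_target] %in% caseid[dup],
                                               paste0(caseid[is_target], "2"),
                                               pid1[is_target])),
    tto = tibble::tibble(caseid = caseid, days = ifelse(neg, NA_integer_,
                                                        as.integer(tto_days)),
                         negative = neg),
    scenario = scn
  )
  structure(list(tables = tables, truth = truth), class = "faers_sim")
}

# full dates degraded to missing / 6-digit partial at the configured rates
encode_date <- function(d, miss, partial) {
  u <- stats::runif(length(d))
  dplyr::case_when(
    u < miss ~ NA_character_,
    u < miss + partial ~ format(d, "%Y%m"),
    TRUE ~ date_to_faers(d)
  )
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim>", nrow(x$tables$demo), "DEMO rows (",
      dplyr::n_distinct(x$tables$demo$CASEID), "cases ),",
      nrow(x$tables$reac), "REAC rows,",
      sum(x$truth$signals$is_signal), "planted signals\n")
  invisible(x)
}
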