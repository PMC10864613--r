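#' Run the full signal-detection pipeline
#'
#' Convenience wrapper chaining the stages in their canonical order:
#' assemble -> deduplicate -> window -> primary-suspect cohort -> event
#' explosion -> indication exclusion -> disproportionality at PT and SOC
#' level -> time to onset -> Weibull fit -> demographics. Each stage is also
#' available as its own function; this wrapper only wires them together and
#' collects the audits.
#'
#' @param data A `faers_sim`, `faers_bundle`, or a directory of quarterly
#'   files (read via [read_faers_data()]).
#' @param dict [drug_dictionary()] of the target drug.
#' @param pt_soc_map Tibble `pt`/`soc`.
#' @param window Optional quarter range `c(from, to)` applied after
#'   deduplication.
#' @param label_terms Optional PT-level label-term list for expectedness.
#' @param indication_pts Indication terms to exclude; `NULL` derives them from
#'   the cohort's own INDI records.
#' @param method Information-component bound construction (see [bcpnn_ic()]).
#' @param min_tto Minimum records for the Weibull fit; below it the fit is
#'   skipped (`weibull = NULL`).
#' @return List: `cases`, `dedup_audit`, `cohort`, `events` (all drugs,
#'   indication-filtered), `signals_pt`, `signals_soc`, `tto` (records +
#'   audit), `weibull`, `demographics`, `annual_counts`.
#' @export
#' @examples
#' sim <- faers_simulate(synth_scenario(n_reports = 2000, seed = 3))
#' dict <- drug_dictionary("targetinib", brand = "TARGETRA")
#' res <- faers_pipeline(sim, dict, sim$truth$scenario$pt_vocabulary)
#' dplyr::filter(res$signals_pt, consensus)
faers_pipeline <- function(data, dict, pt_soc_map, window = NULL,
                           label_terms = NULL, indication_pts = NULL,
                           method = "closed_form", min_tto = 10) {
  if (is.character(data)) data <- read_faers_data(data)
  cases <- assemble_cases(data)
  dd <- dedup_cases(cases)
  cases <- dd$cases
  if (!is.null(window)) cases <- filter_window(cases, window[1], window[2])
  cohort <- select_primary_suspect(cases, dict)
  events <- explode_events(cases, pt_soc_map)
  events <- exclude_indication_terms(events, indication_pts, cohort = cohort)
  target_ids <- cohort$demo$primaryid
  sig_pt <- dispro_signals(events, target_ids, level = "pt", method = method)
  sig_soc <- dispro_signals(events, target_ids, level = "soc", method = method)
  if (!is.null(label_terms)) sig_pt <- flag_unexpected(sig_pt, label_terms)
  tto <- compute_tto(cohort)
  weibull <- if (nrow(tto$records) >= min_tto) fit_weibull(tto$records, min_n = min_tto)
  list(
    cases = cases, dedup_audit = dd$audit, cohort = cohort, events = events,
    signals_pt = sig_pt, signals_soc = sig_soc, tto = tto, weibull = weibull,
    demographics = demographics_table(cohort), annual_counts = annual_counts(cohort)
  )
}
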