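#' Deduplicate assembled case reports
#'
#' Applies the FDA-recommended rules for collapsing quarterly re-submissions:
#' among report versions sharing a CASEID, keep the one with the most recent
#' FDA_DT; if FDA_DTs tie, keep the highest PRIMARYID. A missing FDA_DT loses
#' to any present date ("most recent" cannot select an unknown date); two
#' missing dates fall through to the PRIMARYID rule. PRIMARYIDs are compared
#' numerically when all of them parse as numbers, lexicographically otherwise.
#'
#' The kept set depends only on the key fields, never on input order, and the
#' operation is idempotent.
#'
#' @param cases A `faers_cases` from [assemble_cases()].
#' @return A list with `cases` (one version per CASEID) and `audit`, a tibble
#'   listing every removed PRIMARYID with the winner that displaced it.
#' @export
#' @examples
#' sim <- faers_simulate(synth_scenario(n_reports = 300, seed = 2))
#' dd <- dedup_cases(assemble_cases(sim))
#' dd$audit
dedup_cases <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  d <- cases$demo
  fda_key <- as.numeric(d$fda_dt)
  fda_key[is.na(fda_key)] <- -Inf
  pid_key <- id_order_key(d$primaryid)
  ranked <- tibble::tibble(primaryid = d$primaryid, caseid = d$caseid,
                           fda_dt = d$fda_dt, fda_key = fda_key, pid_key = pid_key) %>%
    dplyr::arrange(.data$caseid, dplyr::desc(.data$fda_key), dplyr::desc(.data$pid_key)) %>%
    dplyr::group_by(.data$caseid) %>%
    dplyr::mutate(.rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  kept <- dplyr::filter(ranked, .data$.rank == 1L)
  removed <- dplyr::filter(ranked, .data$.rank > 1L)
  audit <- removed %>%
    dplyr::left_join(dplyr::select(kept, "caseid", kept_primaryid = "primaryid"),
                     by = "caseid") %>%
    dplyr::select("caseid", "kept_primaryid", removed_primaryid = "primaryid",
                  removed_fda_dt = "fda_dt")
  list(cases = subset_cases(cases, kept$primaryid), audit = audit)
}
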