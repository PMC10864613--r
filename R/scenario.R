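#' Synthetic organ-class hierarchy and term vocabulary
#'
#' A deliberately synthetic two-level terminology: 26 organ classes (mirroring
#' the granularity of the real dictionary's highest level) each owning five
#' preferred terms, so every term maps to exactly one organ class. Names are
#' invented, not licensed dictionary content. Term weights set the background
#' reporting propensity; they cycle through `c(2, 1.5, 1, 0.5, 0.25)` within
#' each class so the vocabulary spans common and rare terms.
#'
#' @param n_soc Number of organ classes (default 26).
#' @param terms_per_soc Terms per class (default 5).
#' @return Tibble with columns `pt`, `soc`, `weight`.
#' @export
synth_pt_vocabulary <- function(n_soc = 26, terms_per_soc = 5) {
  soc <- sprintf("Synthetic organ class %02d", seq_len(n_soc))
  tibble::tibble(
    pt = sprintf("Synthetic term %03d", seq_len(n_soc * terms_per_soc)),
    soc = rep(soc, each = terms_per_soc),
    weight = rep(c(2, 1.5, 1, 0.5, 0.25)[seq_len(terms_per_soc)], times = n_soc)
  )
}

#' Define a synthetic reporting scenario
#'
#' A scenario fixes every condition of a simulated spontaneous-report stream:
#' the number of unique cases, the quarterly window, the drug and term
#' vocabularies, planted drug-event signal strengths, duplication and
#' missingness rates, and the Weibull onset-time distribution. The generator
#' ([faers_simulate()]) is deterministic given the scenario's seed.
#'
#' Planted signals are expressed as a reporting-rate ratio `lambda >= 1` for a
#' (target drug, term) pair: within target-drug reports the term's sampling
#' weight is multiplied by `lambda`; all other terms keep `lambda = 1`.
#'
#' @param n_reports Number of unique cases (before duplication).
#' @param quarters Character vector of consecutive quarter labels.
#' @param target_drug List with `generic` and `brand` names of the drug of
#'   interest.
#' @param background_drugs Character vector of comparator drug names.
#' @param pt_vocabulary Tibble `pt`/`soc`/`weight`; see [synth_pt_vocabulary()].
#' @param signal_spec Tibble with columns `pt` and `lambda` (all `lambda >= 1`);
#'   terms absent from it have true rate ratio 1.
#' @param target_share Probability that a case's primary-suspect drug is the
#'   target drug.
#' @param duplication_rate Fraction of cases re-submitted under the same CASEID
#'   with a higher PRIMARYID and later (or, for `fda_tie_rate` of them, equal)
#'   FDA_DT.
#' @param fda_tie_rate Fraction of duplicates sharing the original FDA_DT, to
#'   exercise the PRIMARYID tie-break.
#' @param missingness Named list of per-field missing probabilities:
#'   `age`, `sex`, `weight`, `event_dt`, `start_dt`, plus `partial_event` and
#'   `partial_start`, the fractions of present dates degraded to 6-digit
#'   year-month form.
#' @param tto List with Weibull `shape` and `scale` (days) of the true
#'   onset-interval distribution.
#' @param negative_tto_rate Fraction of cases whose recorded event date
#'   precedes therapy start (data-entry-style error, exercises the exclusion
#'   rule).
#' @param indication_pts Terms recorded as the target drug's indication.
#' @param indication_reaction_rate Probability that a target-drug case also
#'   lists its indication term among its reactions.
#' @param extra_drug_mean Mean number of non-suspect co-reported drugs per case.
#' @param seed Integer random seed.
#' @return A validated object of class `synth_scenario`.
#' @export
#' @examples
#' scn <- synth_scenario(n_reports = 500, seed = 1)
#' scn$signal_spec
synth_scenario <- function(n_reports = 50000,
                           quarters = quarter_seq("2019Q3", "2023Q1"),
                           target_drug = list(generic = "targetinib", brand = "TARGETRA"),
                           background_drugs = sprintf("comparator_%03d", 1:60),
                           pt_vocabulary = synth_pt_vocabulary(),
                           signal_spec = default_signal_spec(pt_vocabulary),
                           target_share = 0.02,
                           duplication_rate = 0.08,
                           fda_tie_rate = 0.2,
                           missingness = list(age = 0.90, sex = 0.07, weight = 0.65,
                                              event_dt = 0.25, start_dt = 0.30,
                                              partial_event = 0.10, partial_start = 0.05),
                           tto = list(shape = 0.56, scale = 30),
                           negative_tto_rate = 0.02,
                           indication_pts = utils::tail(pt_vocabulary$pt, 3),
                           indication_reaction_rate = 0.02,
                           extra_drug_mean = 0.8,
                           seed = 1L) {
  scn <- structure(
    list(
      n_reports = as.integer(n_reports), quarters = quarters,
      target_drug = target_drug, background_drugs = background_drugs,
      pt_vocabulary = tibble::as_tibble(pt_vocabulary),
      signal_spec = tibble::as_tibble(signal_spec),
      target_share = target_share, duplication_rate = duplication_rate,
      fda_tie_rate = fda_tie_rate, missingness = missingness, tto = tto,
      negative_tto_rate = negative_tto_rate, indication_pts = indication_pts,
      indication_reaction_rate = indication_reaction_rate,
      extra_drug_mean = extra_drug_mean, seed = as.integer(seed)
    ),
    class = "synth_scenario"
  )
  validate_scenario(scn)
}

#' Default planted signals
#'
#' Plants six signals of graded strength (`lambda` 2, 3, 4, 4, 8, 8) on
#' half-weight terms, keeping the planted probability mass small relative to
#' the background so that null terms stay near rate ratio 1.
#'
#' @param pt_vocabulary Vocabulary tibble.
#' @return Tibble with columns `pt`, `lambda`.
#' @export
default_signal_spec <- function(pt_vocabulary = synth_pt_vocabulary()) {
  half <- pt_vocabulary$pt[pt_vocabulary$weight == 0.5]
  if (length(half) < 6) half <- utils::head(pt_vocabulary$pt, 6)
  tibble::tibble(pt = half[1:6], lambda = c(2, 3, 4, 4, 8, 8))
}

validate_scenario <- function(scn) {
  stopifnot(inherits(scn, "synth_scenario"))
  fail <- function(msg) stop("invalid scenario: ", msg, call. = FALSE)
  if (is.na(scn$n_reports) || scn$n_reports < 0) fail("n_reports must be a non-negative integer")
  if (!length(scn$quarters) || anyNA(quarter_index(scn$quarters))) fail("malformed quarter labels")
  if (!is.character(scn$background_drugs) || !length(scn$background_drugs)) {
    fail("background drug vocabulary is empty")
  }
  if (!nzchar(scn$target_drug$generic)) fail("target drug name is empty")
  v <- scn$pt_vocabulary
  if (!nrow(v)) fail("PT vocabulary is empty")
  if (anyDuplicated(v$pt)) fail("PT vocabulary has duplicated terms (PT->SOC must be unique)")
  if (any(v$weight <= 0)) fail("background weights must be positive")
  s <- scn$signal_spec
  if (nrow(s)) {
    if (any(s$lambda < 1)) fail("signal lambda must be >= 1")
    if (!all(s$pt %in% v$pt)) fail("signal_spec names terms absent from the vocabulary")
    if (anyDuplicated(s$pt)) fail("signal_spec has duplicated terms")
  }
  for (p in c("duplication_rate", "fda_tie_rate", "target_share", "negative_tto_rate",
              "indication_reaction_rate")) {
    if (scn[[p]] < 0 || scn[[p]] > 1) fail(paste(p, "must be in [0, 1]"))
  }
  if (any(unlist(scn$missingness) < 0) || any(unlist(scn$missingness) > 1)) {
    fail("missingness probabilities must be in [0, 1]")
  }
  if (scn$tto$shape <= 0 || scn$tto$scale <= 0) fail("Weibull shape and scale must be positive")
  scn
}

#' @export
print.synth_scenario <- function(x, ...) {
  cat("<synth_scenario>\n")
  cat("  cases:", x$n_reports, " quarters:", x$quarters[1], "..",
      x$quarters[length(x$quarters)], "\n")
  cat("  target drug:", x$target_drug$generic, "(", x$target_drug$brand, "), share",
      x$target_share, "\n")
  cat("  vocabulary:", nrow(x$pt_vocabulary), "PTs /",
      length(unique(x$pt_vocabulary$soc)), "SOCs;",
      nrow(x$signal_spec), "planted signals\n")
  cat("  duplication:", x$duplication_rate, " seed:", x$seed, "\n")
  invisible(x)
}
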