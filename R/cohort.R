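#' Drug dictionary for report recognition
#'
#' Collects the names under which a drug appears in spontaneous reports:
#' generic name, brand names and optional active-ingredient strings. Matching
#' is case-insensitive after trimming.
#'
#' @param generic Generic name.
#' @param brand Character vector of brand names.
#' @param active Character vector of active-ingredient strings.
#' @return An object of class `drug_dictionary`.
#' @export
#' @examples
#' dict <- drug_dictionary("larotrectinib", brand = "VITRAKVI")
#' match_drug("Vitrakvi ", dict = dict)
drug_dictionary <- function(generic, brand = character(0), active = character(0)) {
  names <- unique(c(generic, brand, active))
  names <- names[!is.na(names) & nzchar(stringr::str_trim(names))]
  if (!length(names)) stop("drug dictionary needs at least one non-empty name", call. = FALSE)
  structure(list(generic = generic, names = names,
                 normalized = tolower(stringr::str_trim(names))),
            class = "drug_dictionary")
}

#' Match a drug-entry name against a dictionary
#'
#' Default mode `"exact"` compares the whole string after trimming and
#' case-folding, so salt forms such as "LAROTRECTINIB MESYLATE" do not match;
#' mode `"substring"` additionally accepts a dictionary name appearing as a
#' whole word inside the entry. Either DRUGNAME or PROD_AI may match.
#'
#' @param drugname Character vector of DRUGNAME values.
#' @param prod_ai Optional character vector of PROD_AI values.
#' @param dict A [drug_dictionary()].
#' @param mode `"exact"` (whole string) or `"substring"` (word boundary).
#' @return Logical vector.
#' @export
match_drug <- function(drugname, prod_ai = NULL, dict, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  hit <- function(x) {
    if (is.null(x)) return(rep(FALSE, length(drugname)))
    x <- tolower(stringr::str_trim(as.character(x)))
    out <- x %in% dict$normalized
    if (mode == "substring") {
      pat <- paste0("\\b(", paste(stringr::str_escape(dict$normalized), collapse = "|"),
                    ")\\b")
      out <- out | (!is.na(x) & stringr::str_detect(x, pat))
    }
    out & !is.na(x)
  }
  hit(drugname) | hit(prod_ai)
}

#' Select reports with the target drug as primary suspect
#'
#' A report enters the cohort only if it carries at least one drug entry that
#' matches the dictionary *and* is role-coded PS. Reports where the drug
#' appears only as secondary suspect, concomitant or interacting are excluded.
#' The matched drug sequence numbers are retained (component `matched`) for
#' therapy-date linkage in time-to-onset analysis.
#'
#' @param cases A deduplicated `faers_cases`.
#' @param dict A [drug_dictionary()].
#' @param mode Matching mode passed to [match_drug()].
#' @return A `faers_cases` restricted to the cohort, with a `matched` tibble
#'   (`primaryid`, `drug_seq`).
#' @export
select_primary_suspect <- function(cases, dict, mode = c("exact", "substring")) {
  stopifnot(inherits(cases, "faers_cases"))
  mode <- match.arg(mode)
  dr <- cases$drugs
  is_match <- match_drug(dr$drugname, dr$prod_ai, dict, mode) & dr$role_code == "PS"
  matched <- dr[is_match, c("primaryid", "drug_seq")]
  out <- subset_cases(cases, unique(matched$primaryid))
  out$matched <- matched
  out
}

#' Read a PT to organ-class mapping
#'
#' @param path Two-column delimited file (tab or comma) with columns `pt` and
#'   `soc`.
#' @return Tibble `pt`/`soc`.
#' @export
read_pt_soc_map <- function(path) {
  map <- readr::read_delim(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(map) <- tolower(names(map))
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("PT->SOC mapping needs columns 'pt' and 'soc'", call. = FALSE)
  }
  dplyr::distinct(tibble::as_tibble(map[c("pt", "soc")]), .data$pt, .keep_all = TRUE)
}

#' Explode case reports to event level
#'
#' One event per distinct preferred term per report: identical PTs repeated
#' within one report count once, so the event is the drug-term pair the
#' disproportionality unit requires. Each event carries its mapped organ
#' class (`"UNMAPPED"`, counted in attribute `n_unmapped`, when the mapping
#' lacks the term) and the case-level demographics.
#'
#' @param cases A `faers_cases`.
#' @param pt_soc_map Tibble `pt`/`soc` (e.g. [read_pt_soc_map()] or the
#'   scenario's `pt_vocabulary`).
#' @return Tibble of events: `primaryid`, `pt`, `soc`, `quarter`, `fda_dt`,
#'   demographics. Attribute `n_unmapped` counts events without a mapped SOC.
#' @export
explode_events <- function(cases, pt_soc_map) {
  stopifnot(inherits(cases, "faers_cases"))
  map <- dplyr::distinct(tibble::as_tibble(pt_soc_map)[c("pt", "soc")],
                         .data$pt, .keep_all = TRUE)
  ev <- cases$reactions %>%
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) %>%
    dplyr::distinct(.data$primaryid, .data$pt) %>%
    dplyr::left_join(map, by = "pt") %>%
    dplyr::mutate(soc = dplyr::coalesce(.data$soc, "UNMAPPED")) %>%
    dplyr::left_join(
      dplyr::select(cases$demo, "primaryid", "caseid", "quarter", "fda_dt",
                    "age_years", "sex", "weight_kg", "reporter_country", "reporter_type"),
      by = "primaryid"
    )
  attr(ev, "n_unmapped") <- sum(ev$soc == "UNMAPPED")
  ev
}

#' Exclude indication-related terms from an event table
#'
#' Events whose term is among the drug's treatment indications are removed so
#' the disease being treated is not mistaken for a drug effect. Matching is
#' exact term equality after case-folding. When `indication_pts` is `NULL`
#' and a cohort is supplied, the set defaults to the union of INDI_PT values
#' recorded for the cohort's matched drug entries.
#'
#' @param events Event tibble from [explode_events()].
#' @param indication_pts Character vector of indication terms, or `NULL`.
#' @param cohort Optional `faers_cases` with a `matched` component, used to
#'   derive the default set.
#' @return Filtered event tibble; attribute `n_excluded` counts removals.
#' @export
exclude_indication_terms <- function(events, indication_pts = NULL, cohort = NULL) {
  if (is.null(indication_pts)) {
    if (is.null(cohort) || is.null(cohort$matched)) {
      stop("supply indication_pts or a cohort with matched drug entries", call. = FALSE)
    }
    ind <- dplyr::semi_join(
      cohort$indications, cohort$matched,
      by = c(primaryid = "primaryid", indi_drug_seq = "drug_seq")
    )
    indication_pts <- unique(ind$indi_pt)
  }
  key <- tolower(stringr::str_trim(indication_pts))
  drop <- tolower(stringr::str_trim(events$pt)) %in% key
  out <- events[!drop, , drop = FALSE]
  if (all(drop) && nrow(events)) {
    warning("all events were indication-related; no events remain", call. = FALSE)
  }
  attr(out, "n_unmapped") <- attr(events, "n_unmapped")
  attr(out, "n_excluded") <- sum(drop)
  out
}
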