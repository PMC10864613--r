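faers_table_columns <- function() {
  list(
    demo = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE", "AGE_COD",
             "SEX", "WT", "REPORTER_COUNTRY", "OCCP_COD"),
    drug = c("PRIMARYID", "CASEID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", "PROD_AI"),
    reac = c("PRIMARYID", "CASEID", "PT"),
    ther = c("PRIMARYID", "CASEID", "DSG_DRUG_SEQ", "START_DT", "END_DT"),
    indi = c("PRIMARYID", "CASEID", "INDI_DRUG_SEQ", "INDI_PT"),
    outc = c("PRIMARYID", "CASEID", "OUTC_COD")
  )
}

#' Write a simulated bundle as quarterly "$"-delimited ASCII files
#'
#' Lays the tables out the way the quarterly distribution does: one directory
#' per quarter holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`,
#' `INDI.txt`, `OUTC.txt`, each "$"-delimited with a header row. Missing
#' values are written as empty fields. A write -> read round trip reproduces
#' the bundle exactly.
#'
#' @param x A `faers_sim` or `faers_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the file paths written.
#' @export
write_faers_quarters <- function(x, dir) {
  if (inherits(x, "faers_sim")) x <- x$tables
  stopifnot(inherits(x, "faers_bundle") || is.list(x))
  quarters <- sort(unique(unlist(lapply(x, function(t) t$quarter))))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory ", dir, call. = FALSE)
  }
  paths <- character(0)
  for (q in quarters) {
    qdir <- file.path(dir, q)
    dir.create(qdir, showWarnings = FALSE)
    for (nm in names(faers_table_columns())) {
      tab <- x[[nm]]
      tab <- tab[tab$quarter == q, setdiff(names(tab), "quarter"), drop = FALSE]
      p <- file.path(qdir, paste0(toupper(nm), ".txt"))
      readr::write_delim(tab, p, delim = "$", na = "")
      paths <- c(paths, p)
    }
  }
  # quarters with no rows anywhere still deserve header-only files
  if (!length(quarters)) {
    qdir <- file.path(dir, "empty")
    dir.create(qdir, showWarnings = FALSE)
    for (nm in names(faers_table_columns())) {
      tab <- tibble::as_tibble(stats::setNames(
        rep(list(character(0)), length(faers_table_columns()[[nm]])),
        faers_table_columns()[[nm]]
      ))
      p <- file.path(qdir, paste0(toupper(nm), ".txt"))
      readr::write_delim(tab, p, delim = "$", na = "")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read one quarter of "$"-delimited tables
#'
#' All columns are read as character; nothing is coerced or excluded at parse
#' time. Malformed dates stay as their raw strings and are flagged only when
#' cases are assembled, so that downstream exclusion rules see them.
#'
#' @param paths Either a quarter directory containing `DEMO.txt` ... `OUTC.txt`,
#'   or a named list/vector of file paths with names `demo`, `drug`, `reac`,
#'   `ther`, `indi`, `outc`.
#' @param quarter Quarter label attached to every row; defaults to the
#'   directory name.
#' @return A `faers_bundle`: named list of tibbles, each with a `quarter`
#'   column first.
#' @export
read_faers_quarter <- function(paths, quarter = NULL) {
  spec <- faers_table_columns()
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    if (is.null(quarter)) quarter <- basename(normalizePath(paths))
    paths <- stats::setNames(
      file.path(paths, paste0(toupper(names(spec)), ".txt")), names(spec)
    )
  }
  if (is.null(quarter)) quarter <- NA_character_
  out <- purrr::imap(spec, function(cols, nm) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      warning("missing ", toupper(nm), " file for quarter ", quarter, "; treated as empty",
              call. = FALSE)
      tab <- tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      tab <- readr::read_delim(p, delim = "$", na = "",
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE)
      missing_cols <- setdiff(cols, names(tab))
      if (length(missing_cols)) {
        stop("file ", p, " lacks mandatory column(s): ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      }
    }
    dplyr::bind_cols(tibble::tibble(quarter = rep(quarter, nrow(tab))), tab)
  })
  structure(out, class = "faers_bundle")
}

#' Read every quarter under a directory
#'
#' @param dir Directory whose sub-directories are quarter labels (as written by
#'   [write_faers_quarters()]).
#' @return A single `faers_bundle` with all quarters row-bound.
#' @export
read_faers_data <- function(dir) {
  qdirs <- list.dirs(dir, recursive = FALSE)
  bundles <- lapply(sort(qdirs), read_faers_quarter)
  bind_bundles(bundles)
}

bind_bundles <- function(bundles) {
  structure(
    purrr::map(stats::setNames(nm = names(faers_table_columns())), function(nm) {
      dplyr::bind_rows(lapply(bundles, `[[`, nm))
    }),
    class = "faers_bundle"
  )
}

#' Assemble quarterly tables into case-centric records
#'
#' Joins the child tables to DEMO on PRIMARYID, parses dates (retaining
#' partial/invalid values with validity flags), normalises age to years
#' (AGE_COD: YR x1, DEC x10, MON /12, WK /52, DY /365; unknown codes give
#' missing) and maps the reporter occupation code to consumer / health
#' professional. Child rows whose PRIMARYID is absent from DEMO are orphans:
#' counted, never fatal.
#'
#' @param bundles A `faers_bundle`, a `faers_sim`, or a list of bundles across
#'   quarters.
#' @param window Optional two-element quarter range `c(from, to)`; report
#'   versions received outside it are dropped at assembly. Leave `NULL` to
#'   window after deduplication (see [filter_window()]).
#' @return An object of class `faers_cases`: list of tibbles `demo` (one row
#'   per PRIMARYID), `drugs`, `reactions`, `therapies`, `indications`,
#'   `outcomes`, plus an `orphans` count per child table.
#' @export
assemble_cases <- function(bundles, window = NULL) {
  if (inherits(bundles, "faers_sim")) bundles <- bundles$tables
  if (!inherits(bundles, "faers_bundle")) bundles <- bind_bundles(bundles)
  if (!is.null(window)) {
    keep <- quarter_seq(window[1], window[2])
    bundles <- structure(purrr::map(bundles, ~ dplyr::filter(.x, .data$quarter %in% keep)),
                         class = "faers_bundle")
  }
  d <- bundles$demo
  if (anyDuplicated(d$PRIMARYID)) {
    warning("duplicated PRIMARYID rows in DEMO; keeping first occurrence", call. = FALSE)
    d <- dplyr::distinct(d, .data$PRIMARYID, .keep_all = TRUE)
  }
  fda <- parse_faers_date(d$FDA_DT)
  evt <- parse_faers_date(d$EVENT_DT)
  demo <- tibble::tibble(
    primaryid = d$PRIMARYID, caseid = d$CASEID, quarter = d$quarter,
    fda_dt = fda$date, fda_validity = fda$validity,
    event_dt = evt$date, event_dt_raw = evt$raw, event_validity = evt$validity,
    age_years = age_to_years(d$AGE, d$AGE_COD),
    sex = dplyr::if_else(toupper(d$SEX) %in% c("F", "M"), toupper(d$SEX), NA_character_),
    weight_kg = suppressWarnings(as.numeric(d$WT)),
    reporter_country = d$REPORTER_COUNTRY,
    reporter_type = occp_to_reporter(d$OCCP_COD)
  )

  ids <- demo$primaryid
  orphans <- integer(0)
  take <- function(tab, nm) {
    ok <- tab$PRIMARYID %in% ids
    orphans[[nm]] <<- sum(!ok)
    tab[ok, , drop = FALSE]
  }
  drugs <- take(bundles$drug, "drug")
  drugs <- tibble::tibble(
    primaryid = drugs$PRIMARYID,
    drug_seq = suppressWarnings(as.integer(drugs$DRUG_SEQ)),
    role_code = toupper(stringr::str_trim(drugs$ROLE_COD)),
    drugname = drugs$DRUGNAME, prod_ai = drugs$PROD_AI
  )
  reac <- take(bundles$reac, "reac")
  reactions <- tibble::tibble(primaryid = reac$PRIMARYID, pt = reac$PT)
  th <- take(bundles$ther, "ther")
  ts <- parse_faers_date(th$START_DT)
  te <- parse_faers_date(th$END_DT)
  therapies <- tibble::tibble(
    primaryid = th$PRIMARYID,
    dsg_drug_seq = suppressWarnings(as.integer(th$DSG_DRUG_SEQ)),
    start_dt = ts$date, start_validity = ts$validity,
    end_dt = te$date, end_validity = te$validity
  )
  ind <- take(bundles$indi, "indi")
  indications <- tibble::tibble(
    primaryid = ind$PRIMARYID,
    indi_drug_seq = suppressWarnings(as.integer(ind$INDI_DRUG_SEQ)),
    indi_pt = ind$INDI_PT
  )
  ou <- take(bundles$outc, "outc")
  outcomes <- tibble::tibble(primaryid = ou$PRIMARYID,
                             outc_cod = toupper(stringr::str_trim(ou$OUTC_COD)))
  structure(
    list(demo = demo, drugs = drugs, reactions = reactions, therapies = therapies,
         indications = indications, outcomes = outcomes, orphans = orphans),
    class = "faers_cases"
  )
}

#' Restrict assembled cases to an analysis window
#'
#' Keeps report versions whose receipt quarter lies in `[from, to]`. Run after
#' [dedup_cases()] so that the kept version of each case decides membership.
#'
#' @param cases A `faers_cases`.
#' @param from,to Quarter labels.
#' @return A `faers_cases` restricted to the window.
#' @export
filter_window <- function(cases, from, to) {
  keep <- cases$demo$primaryid[cases$demo$quarter %in% quarter_seq(from, to)]
  subset_cases(cases, keep)
}

subset_cases <- function(cases, primaryids) {
  out <- cases
  for (nm in c("demo", "drugs", "reactions", "therapies", "indications", "outcomes")) {
    out[[nm]] <- dplyr::filter(cases[[nm]], .data$primaryid %in% primaryids)
  }
  if (!is.null(cases$matched)) {
    out$matched <- dplyr::filter(cases$matched, .data$primaryid %in% primaryids)
  }
  out
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases>", nrow(x$demo), "report versions,",
      dplyr::n_distinct(x$demo$caseid), "cases;",
      nrow(x$reactions), "reaction rows\n")
  if (length(x$orphans) && any(x$orphans > 0)) {
    cat("  orphan child rows:", paste(names(x$orphans), x$orphans, collapse = ", "), "\n")
  }
  invisible(x)
}
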