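#' Baseline demographics of a cohort
#'
#' Tabulates the conventional baseline blocks of a spontaneous-report cohort:
#' age bands (<18, 18-64, >64 years), sex, weight bands (<80, 80-100,
#' >100 kg), the top reporting countries, reporter type, the top treatment
#' indications, and serious-outcome codes. Percentages are rounded half-up to
#' one decimal. Closed blocks (age, sex, weight, reporter type) include an
#' Unknown category so their counts sum to the cohort size; serious-outcome
#' percentages are computed over the total number of outcome entries, since
#' one report can carry several outcome codes.
#'
#' @param cohort A `faers_cases` (deduplicated, primary-suspect filtered).
#' @param top_n How many countries/indications to list.
#' @return Tibble `block`, `category`, `n`, `pct`.
#' @export
demographics_table <- function(cohort, top_n = 5) {
  stopifnot(inherits(cohort, "faers_cases"))
  d <- cohort$demo
  n_cohort <- nrow(d)
  if (!n_cohort) {
    return(tibble::tibble(block = character(0), category = character(0),
                          n = integer(0), pct = numeric(0)))
  }
  block <- function(name, category, denom = n_cohort) {
    tibble::tibble(block = name, category = category) %>%
      dplyr::count(.data$block, .data$category, name = "n") %>%
      dplyr::mutate(pct = pct1(.data$n, denom))
  }
  age_band <- dplyr::case_when(
    is.na(d$age_years) ~ "Unknown",
    d$age_years < 18 ~ "<18",
    d$age_years <= 64 ~ "18-64",
    TRUE ~ ">64"
  )
  sex_cat <- dplyr::case_when(d$sex == "F" ~ "Female", d$sex == "M" ~ "Male",
                              TRUE ~ "Unknown")
  wt_band <- dplyr::case_when(
    is.na(d$weight_kg) ~ "Unknown",
    d$weight_kg < 80 ~ "<80",
    d$weight_kg <= 100 ~ "80-100",
    TRUE ~ ">100"
  )
  rep_cat <- dplyr::case_when(
    d$reporter_type == "consumer" ~ "Consumer",
    d$reporter_type == "health professional" ~ "Health professional",
    TRUE ~ "Unknown"
  )
  country <- block("Reported countries", dplyr::coalesce(d$reporter_country, "Unknown")) %>%
    dplyr::slice_max(.data$n, n = top_n, with_ties = FALSE)
  ind <- cohort$indications
  if (!is.null(cohort$matched)) {
    ind <- dplyr::semi_join(ind, cohort$matched,
                            by = c(primaryid = "primaryid", indi_drug_seq = "drug_seq"))
  }
  indications <- tibble::tibble(block = "Indications", category = ind$indi_pt) %>%
    dplyr::count(.data$block, .data$category, name = "n") %>%
    dplyr::mutate(pct = pct1(.data$n, n_cohort)) %>%
    dplyr::slice_max(.data$n, n = top_n, with_ties = FALSE)
  outc <- cohort$outcomes
  outcomes <- tibble::tibble(block = "Serious outcomes", category = outc$outc_cod) %>%
    dplyr::count(.data$block, .data$category, name = "n") %>%
    dplyr::mutate(pct = pct1(.data$n, nrow(outc))) %>%
    dplyr::arrange(dplyr::desc(.data$n))
  dplyr::bind_rows(
    block("Age (years)", factor(age_band, c("<18", "18-64", ">64", "Unknown"))) %>%
      dplyr::mutate(category = as.character(.data$category)),
    block("Sex", factor(sex_cat, c("Female", "Male", "Unknown"))) %>%
      dplyr::mutate(category = as.character(.data$category)),
    block("Weight (kg)", factor(wt_band, c("<80", "80-100", ">100", "Unknown"))) %>%
      dplyr::mutate(category = as.character(.data$category)),
    country, block("Reporter type", rep_cat), indications, outcomes
  )
}

#' Annual report counts
#'
#' Counts kept report versions by calendar year of FDA receipt date; versions
#' without a parseable FDA_DT are counted under `"unknown"`.
#'
#' @param cohort A `faers_cases`.
#' @return Tibble `year`, `n`.
#' @export
annual_counts <- function(cohort) {
  d <- cohort$demo
  year <- ifelse(is.na(d$fda_dt), "unknown", format(d$fda_dt, "%Y"))
  dplyr::count(tibble::tibble(year = year), .data$year, name = "n")
}

#' Chi-squared homogeneity of two organ-class profiles
#'
#' Pearson chi-squared test (no continuity correction) of whether two drugs
#' distribute their events over organ classes in the same proportions.
#' Classes with zero combined count are dropped first.
#'
#' @param events_drug1,events_drug2 Event tibbles (or any tibbles with a
#'   `soc` column).
#' @return Tibble `statistic`, `df`, `p_value`, `n_soc`.
#' @export
compare_soc_profiles <- function(events_drug1, events_drug2) {
  t1 <- table(events_drug1$soc)
  t2 <- table(events_drug2$soc)
  socs <- sort(union(names(t1), names(t2)))
  m <- rbind(as.integer(t1[socs]), as.integer(t2[socs]))
  m[is.na(m)] <- 0L
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) stop("need at least two organ classes with events", call. = FALSE)
  if (any(rowSums(m) == 0)) stop("one profile has no events", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, n_soc = ncol(m))
}

#' Recompute printed percentages from their counts
#'
#' Internal-consistency device for published summary tables: a percentage is
#' consistent when it equals `round_half_up(100 n / total, digits)` exactly.
#'
#' @param n,total,printed Vectors of counts, denominators and printed
#'   percentages.
#' @param digits Decimals the source prints.
#' @return Tibble `n`, `total`, `printed`, `recomputed`, `consistent`.
#' @export
check_percentages <- function(n, total, printed, digits = 1) {
  recomputed <- round_half_up(100 * n / total, digits)
  tibble::tibble(n = n, total = total, printed = printed, recomputed = recomputed,
                 consistent = abs(recomputed - printed) < 10^(-digits) / 2)
}

#' Bundled published summary statistics
#'
#' Reference tables transcribed from a published FAERS pharmacovigilance
#' study of the first-generation NTRK inhibitors (entrectinib, window 2019Q3
#' to 2023Q1; larotrectinib, 2018Q4 to 2023Q1), used by the test-suite's
#' internal-consistency checks:
#'
#' * `"soc_signals"` - organ-class level case counts and disproportionality
#'   statistics per drug;
#' * `"baseline"` - demographic baseline blocks with printed counts and
#'   percentages (cohort sizes 563 and 524);
#' * `"tto"` - onset-period counts, medians and Weibull shape estimates.
#'
#' @param name Which table.
#' @return Tibble.
#' @export
published_reference <- function(name = c("soc_signals", "baseline", "tto")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("ntrk_", name, ".tsv"), package = "faersignal",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Assemble a report bundle on disk
#'
#' Writes every supplied analysis output as a UTF-8 tab-delimited table under
#' `dir`, together with `manifest.json` recording row counts, the
#' configuration hash, the seed, and any sections that were requested but
#' unavailable. Identical inputs produce byte-identical bundles.
#'
#' @param outputs Named list of tibbles (e.g. `demographics`, `annual_counts`,
#'   `signals_pt`, `signals_soc`, `tto_summary`, `tto_periods`, `weibull`,
#'   `dedup_audit`, `tto_audit`). `NULL` elements are recorded as gaps.
#' @param dir Output directory.
#' @param config Arbitrary configuration list, hashed into the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, a list with `paths` and `gaps`.
#' @export
build_report <- function(outputs, dir, config = list(), seed = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create report directory ", dir, call. = FALSE)
  }
  gaps <- names(outputs)[vapply(outputs, is.null, logical(1))]
  paths <- character(0)
  rows <- list()
  for (nm in setdiff(names(outputs), gaps)) {
    tab <- outputs[[nm]]
    if (inherits(tab, "weibull_fit")) tab <- tidy(tab)
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tab), p, na = "")
    paths <- c(paths, p)
    rows[[nm]] <- nrow(tab)
  }
  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = seed,
    config_hash = rlang::hash(config),
    sections = rows,
    gaps = gaps
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(gaps)) {
    warning("report bundle has gaps: ", paste(gaps, collapse = ", "), call. = FALSE)
  }
  invisible(list(paths = c(paths, mp), gaps = gaps))
}
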