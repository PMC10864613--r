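#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; regulatory tables are conventionally
#' rounded half-up, so a percentage of 32.05 prints as 32.1. A tiny epsilon
#' guards against binary-representation error for values such as 50.75 that
#' are stored just below the half.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 32.05), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded to one decimal
#'
#' @param n Count (numerator).
#' @param total Denominator.
#' @return `n / total * 100`, rounded half-up to one decimal.
#' @export
pct1 <- function(n, total) round_half_up(100 * n / total, 1)

## ---- quarter labels ---------------------------------------------------------

#' Sequence of quarter labels
#'
#' @param from,to Quarter labels such as `"2019Q3"`.
#' @return Character vector of consecutive quarter labels, inclusive.
#' @export
#' @examples
#' quarter_seq("2019Q3", "2020Q2")
quarter_seq <- function(from, to) {
  i <- quarter_index(c(from, to))
  if (anyNA(i)) stop("malformed quarter label", call. = FALSE)
  if (i[1] > i[2]) stop("'from' quarter is after 'to'", call. = FALSE)
  idx <- i[1]:i[2]
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

# linear index of a quarter label; NA for malformed labels
quarter_index <- function(q) {
  ok <- grepl("^[0-9]{4}Q[1-4]$", q)
  out <- rep(NA_integer_, length(q))
  out[ok] <- as.integer(substr(q[ok], 1, 4)) * 4L + as.integer(substr(q[ok], 6, 6)) - 1L
  out
}

quarter_of_date <- function(d) {
  m <- as.POSIXlt(d)
  sprintf("%dQ%d", m$year + 1900L, m$mon %/% 3L + 1L)
}

quarter_bounds <- function(q) {
  y <- as.integer(substr(q, 1, 4))
  k <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", y, (k - 1L) * 3L + 1L))
  end <- as.Date(sprintf("%d-%02d-01", y + (k == 4L), ifelse(k == 4L, 1L, k * 3L + 1L))) - 1
  list(start = start, end = end)
}

## ---- FAERS dates ------------------------------------------------------------

#' Parse FAERS-style date strings
#'
#' FAERS distributes dates as digit strings: 8 digits (`YYYYMMDD`) are complete,
#' 6 (`YYYYMM`) and 4 (`YYYY`) are partial. Partial and malformed values are
#' retained with a validity flag rather than dropped, because exclusion rules
#' (for example in time-to-onset analysis) are applied downstream, not at parse
#' time.
#'
#' @param x Character vector of raw date fields.
#' @return A tibble with columns `raw`, `date` (`Date`, `NA` unless complete
#'   and calendar-valid) and `validity` (one of `"full"`, `"partial"`,
#'   `"missing"`, `"invalid"`).
#' @export
#' @examples
#' parse_faers_date(c("20200115", "202001", NA, "2020013"))
parse_faers_date <- function(x) {
  x <- as.character(x)
  raw <- x
  x <- stringr::str_trim(x)
  x[!is.na(x) & x == ""] <- NA_character_
  validity <- dplyr::case_when(
    is.na(x) ~ "missing",
    grepl("^[0-9]{8}$", x) ~ "full",
    grepl("^[0-9]{6}$", x) | grepl("^[0-9]{4}$", x) ~ "partial",
    TRUE ~ "invalid"
  )
  date <- rep(as.Date(NA), length(x))
  full <- validity == "full"
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    date[full] <- d
    # 8 digits that do not form a real calendar date (e.g. 20201340)
    validity[full][is.na(d)] <- "invalid"
  }
  tibble::tibble(raw = raw, date = date, validity = validity)
}

date_to_faers <- function(d) format(d, "%Y%m%d")

## ---- age normalisation ------------------------------------------------------

# AGE + AGE_COD -> years. DEC is decades in FAERS; unknown codes give NA.
age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365, HR = 1 / 8760)
  m <- mult[toupper(stringr::str_trim(age_cod))]
  m[is.na(age_cod) | stringr::str_trim(age_cod) == ""] <- 1 # bare AGE assumed years
  unname(v * m)
}

occp_to_reporter <- function(occp) {
  occp <- toupper(stringr::str_trim(occp))
  dplyr::case_when(
    occp %in% c("MD", "PH", "RN", "OT", "HP") ~ "health professional",
    occp %in% c("CN", "LW") ~ "consumer",
    TRUE ~ NA_character_
  )
}

# numeric comparison key for PRIMARYID-like identifiers: numeric when every
# id parses as a number, otherwise lexicographic rank
id_order_key <- function(id) {
  num <- suppressWarnings(as.numeric(id))
  if (!anyNA(num[!is.na(id)])) num else as.numeric(factor(id, levels = sort(unique(id))))
}
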