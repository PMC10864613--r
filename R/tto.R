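#' Time to onset per cohort case
#'
#' The onset interval is `EVENT_DT - START_DT` in whole days, where START_DT
#' is the earliest complete, calendar-valid start date among the therapy rows
#' linked (`DSG_DRUG_SEQ`) to the matched primary-suspect drug, and EVENT_DT
#' is the report's onset date. One record per case, not per event. Excluded,
#' with the reason tallied in the audit: missing or partial EVENT_DT, no
#' linked therapy row with a complete START_DT, and onsets preceding therapy
#' start. A 0-day interval (event on the first day of dosing) is retained.
#'
#' @param cohort A `faers_cases` from [select_primary_suspect()] (its
#'   `matched` component provides the drug linkage).
#' @return List with `records` (tibble `primaryid`, `caseid`, `days`) and
#'   `audit` (tibble `reason`, `n`). Audit reasons partition the cohort:
#'   `n_used + excluded = cohort size`.
#' @export
compute_tto <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cases"))
  if (is.null(cohort$matched)) {
    stop("cohort lacks matched drug entries; run select_primary_suspect() first",
         call. = FALSE)
  }
  starts <- cohort$therapies %>%
    dplyr::inner_join(cohort$matched,
                      by = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq")) %>%
    dplyr::filter(.data$start_validity == "full") %>%
    dplyr::group_by(.data$primaryid) %>%
    dplyr::summarise(start_dt = min(.data$start_dt), .groups = "drop")

  rec <- cohort$demo %>%
    dplyr::select("primaryid", "caseid", "event_dt", "event_validity") %>%
    dplyr::left_join(starts, by = "primaryid") %>%
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$event_validity == "missing" ~ "event date missing",
        .data$event_validity != "full" ~ "event date partial or invalid",
        is.na(.data$start_dt) ~ "no valid therapy start date",
        .data$event_dt < .data$start_dt ~ "onset precedes therapy start",
        TRUE ~ "used"
      ),
      days = as.integer(.data$event_dt - .data$start_dt)
    )
  audit <- rec %>%
    dplyr::count(.data$reason, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n))
  records <- rec %>%
    dplyr::filter(.data$reason == "used") %>%
    dplyr::select("primaryid", "caseid", "days")
  list(records = records, audit = audit)
}

#' Summarise onset intervals
#'
#' Median and interquartile range by linear-interpolation quantiles, overall
#' or per organ class. For per-class summaries each case's interval is reused
#' under every organ class among its events, so a case with events in two
#' classes contributes to both.
#'
#' @param records TTO record tibble from [compute_tto()].
#' @param by `"overall"` or `"soc"`.
#' @param events Event tibble (required for `by = "soc"`), used to attach
#'   organ classes via `primaryid`.
#' @return Tibble `group`, `n`, `median`, `q1`, `q3`.
#' @export
summarize_tto <- function(records, by = c("overall", "soc"), events = NULL) {
  by <- match.arg(by)
  if (by == "overall") {
    grouped <- dplyr::mutate(records, group = "overall")
  } else {
    if (is.null(events)) stop("per-SOC summaries need the event table", call. = FALSE)
    grouped <- records %>%
      dplyr::inner_join(dplyr::distinct(events, .data$primaryid, .data$soc),
                        by = "primaryid", relationship = "many-to-many") %>%
      dplyr::rename(group = "soc")
  }
  grouped %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$days),
      q1 = stats::quantile(.data$days, 0.25, names = FALSE),
      q3 = stats::quantile(.data$days, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Onset-period histogram
#'
#' Counts intervals in the conventional reporting periods 0-30, 31-60, 61-90,
#' 91-180, 181-360 and >360 days (0 days meaning onset on the first dosing
#' day).
#'
#' @param records TTO record tibble.
#' @return Tibble `period`, `n`, `pct` (percentage of all records, one
#'   decimal, half-up).
#' @export
tto_periods <- function(records) {
  breaks <- c(-0.5, 30, 60, 90, 180, 360, Inf)
  labels <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")
  bin <- cut(records$days, breaks = breaks, labels = labels)
  tibble::tibble(period = labels,
                 n = as.integer(table(bin)[labels])) %>%
    dplyr::mutate(pct = pct1(.data$n, sum(.data$n)))
}

#' Fit a Weibull model to onset intervals
#'
#' Maximum-likelihood shape and scale with Wald 95% intervals from the
#' observed information on the log-parameter scale (delta method). The shape
#' parameter carries the hazard trend: below 1 the event rate falls with time
#' on drug ("early failure"), near 1 it is constant, above 1 it rises
#' ("wear-out").
#'
#' Whole-day data (the usual case: onset intervals are date differences) are
#' fitted with the interval-censored likelihood, reading day `d` as the
#' interval `(d - 0.5, d + 0.5)` and day 0 as left-censored at half a day.
#' Treating rounded days as exact values - or shifting day 0 to 0.5 and
#' leaving the rest - inflates the shape estimate by several percent when the
#' shape is well below 1, because a sizeable share of onsets then falls
#' within the first half day. Non-integer inputs are taken as exact
#' observations.
#'
#' @param records TTO record tibble, or a numeric vector of days.
#' @param min_n Refuse to fit below this many records.
#' @return Object of class `weibull_fit`: shape and scale estimates with
#'   confidence bounds, `n_used`, `loglik`, `converged`, `hazard_class` (see
#'   [classify_hazard()]), and the fitting data.
#' @export
#' @examples
#' days <- round(rweibull(300, 0.7, 40))
#' fit <- fit_weibull(days)
#' tidy(fit)
fit_weibull <- function(records, min_n = 10) {
  days <- if (is.numeric(records)) records else records$days
  days <- days[!is.na(days)]
  if (length(days) < min_n) {
    stop("need at least ", min_n, " onset records to fit (", length(days), " given)",
         call. = FALSE)
  }
  whole_days <- all(abs(days - round(days)) < 1e-8)
  surv_obj <- if (whole_days) {
    lo <- ifelse(days == 0, NA_real_, days - 0.5)
    survival::Surv(lo, days + 0.5, type = "interval2")
  } else {
    y <- days
    y[y <= 0] <- 0.5
    survival::Surv(y)
  }
  fit <- tryCatch(
    suppressWarnings(survival::survreg(surv_obj ~ 1, dist = "weibull")),
    error = function(e) NULL
  )
  degenerate <- is.null(fit) || !is.finite(fit$scale) || fit$scale <= 0 ||
    stats::var(days) == 0 || anyNA(stats::vcov(fit))
  if (degenerate) {
    out <- structure(
      list(shape = NA_real_, shape_ci = c(NA_real_, NA_real_),
           scale = NA_real_, scale_ci = c(NA_real_, NA_real_),
           n_used = length(days), loglik = NA_real_, converged = FALSE,
           hazard_class = "indeterminate", days = days),
      class = "weibull_fit"
    )
    return(out)
  }
  # survreg parameterisation: log T = mu + sigma * W. Weibull shape = 1/sigma,
  # scale = exp(mu); delta-method CIs on log(shape) = -log(sigma) and mu.
  mu <- unname(stats::coef(fit)[1])
  log_sigma <- log(fit$scale)
  vc <- stats::vcov(fit) # covariance of (mu, log sigma)
  se_mu <- sqrt(vc[1, 1])
  se_ls <- sqrt(vc[2, 2])
  z <- stats::qnorm(0.975)
  shape <- exp(-log_sigma)
  out <- structure(
    list(
      shape = shape,
      shape_ci = exp(-log_sigma + c(-1, 1) * z * se_ls),
      scale = exp(mu),
      scale_ci = exp(mu + c(-1, 1) * z * se_mu),
      n_used = length(days), loglik = fit$loglik[1], converged = TRUE,
      hazard_class = NA_character_, days = days
    ),
    class = "weibull_fit"
  )
  out$hazard_class <- classify_hazard(out)
  out
}

#' Classify the hazard trend of a Weibull fit
#'
#' Uses the full confidence interval of the shape, not just the point
#' estimate: early-failure when the whole interval lies below 1, wear-out
#' when it lies above, random (constant hazard) when it contains 1,
#' indeterminate when the fit did not converge.
#'
#' @param fit A `weibull_fit`.
#' @return One of `"early-failure"`, `"random"`, `"wear-out"`,
#'   `"indeterminate"`.
#' @export
classify_hazard <- function(fit) {
  ci <- fit$shape_ci
  if (!isTRUE(fit$converged) || anyNA(ci)) return("indeterminate")
  if (ci[2] < 1) "early-failure" else if (ci[1] > 1) "wear-out" else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit> n =", x$n_used, "\n")
  if (x$converged) {
    cat(sprintf("  shape %.3f (%.3f-%.3f)  scale %.1f d (%.1f-%.1f)  hazard: %s\n",
                x$shape, x$shape_ci[1], x$shape_ci[2],
                x$scale, x$scale_ci[1], x$scale_ci[2], x$hazard_class))
  } else {
    cat("  fit did not converge (degenerate or ill-conditioned sample)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Weibull onset fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    conf.low = c(x$shape_ci[1], x$scale_ci[1]),
    conf.high = c(x$shape_ci[2], x$scale_ci[2])
  )
}

#' One-row summary of a Weibull onset fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return Tibble `n`, `logLik`, `converged`, `hazard_class`.
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(n = x$n_used, logLik = x$loglik, converged = x$converged,
                 hazard_class = x$hazard_class)
}
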