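#' Crude event rate with exact Poisson confidence interval
#'
#' Rate per 1000 person-years with the exact (Garwood) interval from
#' chi-square quantiles: lower bound `qchisq(alpha/2, 2k)/2 / T`, upper
#' bound `qchisq(1 - alpha/2, 2k + 2)/2 / T`, zero events giving a lower
#' bound of 0. Exact intervals are visibly asymmetric at small counts,
#' matching the published tables.
#'
#' @param events non-negative event count.
#' @param person_years positive person-time in years.
#' @param conf confidence level (default 0.95).
#' @return `rate_estimate`: events, person_years, rate, ci_low, ci_high
#'   (all rates per 1000 person-years).
#' @export
crude_rate <- function(events, person_years, conf = 0.95) {
  if (person_years <= 0) stop("person_years must be positive", call. = FALSE)
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  alpha <- 1 - conf
  k <- events
  lower <- if (k == 0) 0 else qchisq(alpha / 2, 2 * k) / 2 / person_years
  upper <- qchisq(1 - alpha / 2, 2 * k + 2) / 2 / person_years
  structure(list(events = k, person_years = person_years,
                 rate = 1000 * k / person_years,
                 ci_low = 1000 * lower, ci_high = 1000 * upper, conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.1f per 1000 py (%.0f%% CI %.1f-%.1f); %d events / %.1f py\n",
              x$rate, 100 * x$conf, x$ci_low, x$ci_high, x$events,
              x$person_years))
  invisible(x)
}

#' Crude rate ratio
#'
#' Ratio of two rates; when both arguments are [crude_rate()] objects with
#' positive event counts, a log-scale Wald CI using the `1/k_a + 1/k_b`
#' variance is attached. Bare numeric rates give the point ratio only.
#'
#' @param rate_a numerator: `rate_estimate` or rate per 1000 py.
#' @param rate_b denominator: `rate_estimate` or rate per 1000 py.
#' @param conf confidence level.
#' @return `rate_ratio` object: `ratio`, `ci_low`, `ci_high` (NA without
#'   event counts).
#' @export
rate_ratio <- function(rate_a, rate_b, conf = 0.95) {
  ra <- if (inherits(rate_a, "rate_estimate")) rate_a$rate else as.numeric(rate_a)
  rb <- if (inherits(rate_b, "rate_estimate")) rate_b$rate else as.numeric(rate_b)
  if (rb <= 0) stop("denominator rate must be positive", call. = FALSE)
  ratio <- ra / rb
  lo <- hi <- NA_real_
  if (inherits(rate_a, "rate_estimate") && inherits(rate_b, "rate_estimate")) {
    ka <- rate_a$events; kb <- rate_b$events
    if (ka > 0 && kb > 0) {
      se <- sqrt(1 / ka + 1 / kb)
      z <- qnorm(1 - (1 - conf) / 2)
      lo <- ratio * exp(-z * se)
      hi <- ratio * exp(z * se)
    }
  }
  structure(list(ratio = ratio, ci_low = lo, ci_high = hi, conf = conf,
                 rate_a = ra, rate_b = rb), class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  if (is.na(x$ci_low))
    cat(sprintf("rate ratio %.2f\n", x$ratio))
  else
    cat(sprintf("rate ratio %.2f (%.0f%% CI %.2f-%.2f)\n", x$ratio,
                100 * x$conf, x$ci_low, x$ci_high))
  invisible(x)
}

#' Outcome proportion in percent
#'
#' @param event_counts vector of event counts (summed).
#' @param denominator cohort size.
#' @return percentage, rounded to 1 decimal place (the tables' convention).
#' @export
outcome_proportion <- function(event_counts, denominator) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (any(event_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(event_counts) > denominator)
    stop("event counts exceed the denominator", call. = FALSE)
  round(100 * sum(event_counts) / denominator, 1)
}

#' Person-years at risk in a person-month table
#'
#' Each row is one month at risk; person-years = rows / 12.
#'
#' @param person_months person-month table.
#' @return person-years (numeric).
#' @export
person_years <- function(person_months) nrow(person_months) / 12

default_strata <- function() {
  list(
    age = list(var = "age_entry", breaks = c(-Inf, 25, 35, 45, Inf),
               labels = c("<25", "25-34", "35-44", ">=45"), right = FALSE),
    gender = list(var = "gender"),
    cd4_art_start = list(var = "cd4_art_start", breaks = c(-Inf, 50, 100, 200, Inf),
                         labels = c("<50", "50-99", "100-199", ">=200"),
                         right = FALSE),
    cd4_entry = list(var = "cd4_entry", breaks = c(-Inf, 50, 100, 200, Inf),
                     labels = c("<50", "50-99", "100-199", ">=200"),
                     right = FALSE),
    art_duration = list(var = "art_duration_entry", breaks = c(-Inf, 24, 48, Inf),
                        labels = c("<=24", "25-48", ">48"), right = TRUE),
    vl_suppressed_entry = list(var = "vl_suppressed_entry"),
    who_stage = list(var = "who_stage"))
}

#' Table-1-style stratified summary with crude rates by club status
#'
#' For each stratum of each baseline characteristic: N and percentage,
#' the median (IQR) of the underlying continuous variable where one
#' exists, and crude event rates (per 1000 py, exact Poisson CI) split by
#' club status. Person-time of patients who eventually joined a club
#' counts toward "not in club" until the month they enrolled, and to
#' "in club" thereafter; a stratum with no person-time in a state has its
#' rate suppressed (NA), never a division by zero.
#'
#' @param baseline cohort baseline table.
#' @param person_months person-month table for the outcome of interest.
#' @param strata named list of stratum definitions (default: the study's
#'   age/gender/CD4/ART-duration/suppression/WHO bands); each element is a
#'   list with `var` and optional `breaks`/`labels`/`right` for continuous
#'   variables.
#' @return `data.table` with one row per stratum level.
#' @export
table_one <- function(baseline, person_months, strata = default_strata()) {
  bl <- data.table::as.data.table(baseline)
  pm <- data.table::as.data.table(person_months)
  pm <- pm[patient_id %in% bl$patient_id]
  out <- list()
  for (nm in names(strata)) {
    sp <- strata[[nm]]
    if (!sp$var %in% names(bl))
      stop("unknown stratum variable: ", sp$var, call. = FALSE)
    lev <- if (!is.null(sp$breaks)) {
      cut(bl[[sp$var]], breaks = sp$breaks, labels = sp$labels,
          right = isTRUE(sp$right))
    } else factor(bl[[sp$var]])
    bl[, .lev := lev]
    pm[, .lev := bl$.lev[match(patient_id, bl$patient_id)]]
    med <- if (is.numeric(bl[[sp$var]]))
      sprintf("%.1f (%.1f-%.1f)", median(bl[[sp$var]]),
              quantile(bl[[sp$var]], 0.25), quantile(bl[[sp$var]], 0.75))
    else NA_character_
    for (lv in levels(lev)) {
      nlv <- sum(lev == lv, na.rm = TRUE)
      row <- data.table::data.table(
        variable = nm, level = lv, n = nlv,
        pct = round(100 * nlv / nrow(bl), 1), median_iqr = med)
      for (state in c(TRUE, FALSE)) {
        sub <- pm[.lev == lv & in_club == state]
        pre <- if (state) "club_" else "nonclub_"
        if (nrow(sub) == 0) {
          row[, (paste0(pre, c("events", "py", "rate", "ci_low", "ci_high"))) :=
                .(0L, 0, NA_real_, NA_real_, NA_real_)]
        } else {
          rr <- crude_rate(sum(sub$y), nrow(sub) / 12)
          row[, (paste0(pre, c("events", "py", "rate", "ci_low", "ci_high"))) :=
                .(rr$events, rr$person_years, rr$rate, rr$ci_low, rr$ci_high)]
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  bl[, .lev := NULL]
  pm[, .lev := NULL]
  data.table::rbindlist(out)
}
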