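#' Covariate specification for the weight models
#'
#' The denominator model conditions on everything (baseline covariates,
#' time-varying CD4/viral-load covariates, follow-up-time spline); the
#' numerator (stabilization) model conditions on the baseline covariates
#' and follow-up time only — the same baseline set the outcome MSM adjusts
#' for, following the usual stabilization convention. The numerator
#' covariate set must be a subset of the denominator's.
#'
#' @param denominator character vector of covariate blocks from
#'   `{"baseline", "timevarying"}`.
#' @param numerator character vector of covariate blocks.
#' @param time `"spline"` (restricted cubic, percentile knots) or
#'   `"linear"`.
#' @return a `weight_model_spec` object.
#' @export
weight_model_spec <- function(denominator = c("baseline", "timevarying"),
                              numerator = "baseline",
                              time = c("spline", "linear")) {
  time <- match.arg(time)
  stopifnot(all(denominator %in% c("baseline", "timevarying")),
            all(numerator %in% c("baseline", "timevarying")))
  if (!all(numerator %in% denominator))
    stop("numerator covariates must be a subset of denominator covariates (stabilization validity)",
         call. = FALSE)
  structure(list(denominator = denominator, numerator = numerator, time = time),
            class = "weight_model_spec")
}

weight_design <- function(pm, blocks, knots) {
  X <- cbind(`(Intercept)` = rep(1, nrow(pm)))
  X <- cbind(X, time_design(pm, knots))
  if ("baseline" %in% blocks) X <- cbind(X, baseline_design(pm))
  if ("timevarying" %in% blocks) X <- cbind(X, timevarying_design(pm))
  X
}

# rows at risk of *first* club entry: everything up to and including each
# patient's first in-club month; response = 1 at the initiation row
club_risk_set <- function(pm) {
  pm <- data.table::as.data.table(pm)
  first_club <- pm[, .(fc = if (any(in_club)) as.numeric(min(t[in_club])) else Inf),
                   by = patient_id]
  fc <- first_club$fc[match(pm$patient_id, first_club$patient_id)]
  keep <- pm$t <= fc
  joins <- as.integer(pm$in_club & pm$t == fc)
  list(keep = keep, joins = joins, first_club = fc)
}

#' Fit the pooled logistic club-entry (treatment) model
#'
#' Models the monthly probability of *first* adherence-club participation on
#' the sub-sample of person-months with no prior club participation
#' (pre-initiation months plus the initiation month itself). Used for the
#' IPTW denominator (full covariate set) and numerator (baseline-only)
#' models, and reports the covariate odds-ratio table.
#'
#' @param person_months person-month table from
#'   [build_person_month_table()].
#' @param blocks covariate blocks (`"baseline"`, `"timevarying"`).
#' @param knots follow-up-time spline knots; computed from the full table's
#'   `t` values when `NULL`. Pass the outcome model's knots for internal
#'   consistency.
#' @param time `"spline"` or `"linear"`.
#' @return `club_entry_fit`: coefficients, model and patient-clustered
#'   robust covariance, odds-ratio table, knots, counts.
#' @export
fit_treatment_model <- function(person_months,
                                blocks = c("baseline", "timevarying"),
                                knots = NULL, time = "spline") {
  pm <- data.table::as.data.table(person_months)
  data.table::setorder(pm, patient_id, t)
  rs <- club_risk_set(pm)
  sub <- pm[rs$keep]
  joins <- rs$joins[rs$keep]
  if (sum(joins) == 0)
    stop("no club initiations in the data: treatment model cannot be fitted",
         call. = FALSE)
  if (is.null(knots) && identical(time, "spline")) knots <- spline_knots(pm$t)
  if (identical(time, "linear")) knots <- NULL
  X <- drop_constant_cols(weight_design(sub, blocks, knots))
  fit <- logit_irls(X, joins)
  if (!fit$converged || any(abs(fit$coef) > 20))
    stop("club-entry model did not converge (possible separation); largest |coef| = ",
         sprintf("%.2f", max(abs(fit$coef))), call. = FALSE)
  vc_rob <- sandwich_variance_clustered(X, joins, fit$fitted, rep(1, nrow(X)),
                                        sub$patient_id)
  se <- sqrt(diag(vc_rob))
  or_tab <- data.table::data.table(
    term = names(fit$coef), estimate = fit$coef,
    or = exp(fit$coef),
    or_low = exp(fit$coef - qnorm(0.975) * se),
    or_high = exp(fit$coef + qnorm(0.975) * se),
    p_value = 2 * (1 - stats::pnorm(abs(fit$coef / se))))
  structure(list(coef = fit$coef, vcov = vc_rob, vcov_model = fit$vcov,
                 or_table = or_tab, blocks = blocks, knots = knots,
                 time = time, n_rows = nrow(X), n_events = sum(joins),
                 converged = fit$converged),
            class = "club_entry_fit")
}

#' @export
print.club_entry_fit <- function(x, ...) {
  cat(sprintf("Pooled logistic club-entry model: %d initiations / %d person-months at risk\n",
              x$n_events, x$n_rows))
  print(x$or_table[, .(term, or = round(or, 3), or_low = round(or_low, 3),
                       or_high = round(or_high, 3))])
  invisible(x)
}

predict_club_prob <- function(fit, pm) {
  X <- weight_design(pm, fit$blocks, fit$knots)
  X <- X[, names(fit$coef), drop = FALSE]
  drop(plogis(X %*% fit$coef))
}

#' Fit the pooled logistic LTF-censoring model
#'
#' Monthly probability of being censored by loss to follow-up, fitted on
#' the rebound-analysis person-month table. If the data contain no LTF
#' censoring, a degenerate zero-probability model is returned and all
#' censoring weights downstream are exactly 1.
#'
#' @inheritParams fit_treatment_model
#' @return `censoring_fit` object.
#' @export
fit_censoring_model <- function(person_months,
                                blocks = c("baseline", "timevarying"),
                                knots = NULL, time = "spline") {
  pm <- data.table::as.data.table(person_months)
  if (!"cens_ltf" %in% names(pm))
    stop("person_months lacks a cens_ltf column; build the table for outcome = 'rebound'",
         call. = FALSE)
  if (sum(pm$cens_ltf) == 0)
    return(structure(list(zero_events = TRUE, blocks = blocks, knots = knots,
                          time = time), class = "censoring_fit"))
  if (is.null(knots) && identical(time, "spline")) knots <- spline_knots(pm$t)
  if (identical(time, "linear")) knots <- NULL
  X <- drop_constant_cols(weight_design(pm, blocks, knots))
  fit <- logit_irls(X, as.integer(pm$cens_ltf))
  if (!fit$converged || any(abs(fit$coef) > 20))
    stop("censoring model did not converge (possible separation)", call. = FALSE)
  structure(list(zero_events = FALSE, coef = fit$coef, vcov_model = fit$vcov,
                 blocks = blocks, knots = knots, time = time,
                 n_rows = nrow(X), n_events = sum(pm$cens_ltf)),
            class = "censoring_fit")
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' For each pre-initiation person-month the monthly factor is the ratio of
#' the numerator to the denominator model's probability of the *observed*
#' club state that month (initiation vs not); the stabilized weight is the
#' cumulative product over the patient's months. From the initiation month
#' onward the monthly factor is 1: under `post_join = "freeze"` (default)
#' the cumulative weight stays at its initiation-month value; under
#' `post_join = "reset"` the total weight is set to exactly 1 from the
#' initiation month onward (the literal reading of "a weight of one once
#' they joined").
#'
#' @param person_months person-month table.
#' @param denominator_model,numerator_model [fit_treatment_model()] fits.
#' @param post_join `"freeze"` or `"reset"`.
#' @param prob_floor predicted probabilities of the observed state below
#'   this floor are clipped to it and the rows flagged (not silently).
#' @return `data.table` keyed by (`patient_id`, `t`) with `sw` and a
#'   `flagged` column; attribute `n_flagged`.
#' @export
compute_stabilized_iptw <- function(person_months, denominator_model,
                                    numerator_model,
                                    post_join = c("freeze", "reset"),
                                    prob_floor = 1e-6) {
  post_join <- match.arg(post_join)
  pm <- data.table::as.data.table(person_months)
  data.table::setorder(pm, patient_id, t)
  rs <- club_risk_set(pm)
  p_den <- p_num <- rep(NA_real_, nrow(pm))
  p_den[rs$keep] <- predict_club_prob(denominator_model, pm[rs$keep])
  p_num[rs$keep] <- predict_club_prob(numerator_model, pm[rs$keep])
  obs <- function(p) ifelse(rs$joins == 1L, p, 1 - p)
  den_obs <- obs(p_den); num_obs <- obs(p_num)
  flagged <- rs$keep & (den_obs < prob_floor | num_obs < prob_floor)
  den_obs <- pmax(den_obs, prob_floor)
  num_obs <- pmax(num_obs, prob_floor)
  factor_m <- ifelse(rs$keep, num_obs / den_obs, 1)
  w <- data.table::data.table(patient_id = pm$patient_id, t = pm$t,
                              .f = factor_m, flagged = flagged & rs$keep)
  w[, sw := cumprod(.f), by = patient_id]
  if (post_join == "reset") {
    post <- !rs$keep | rs$joins == 1L      # initiation month onward
    w[post, sw := 1]
  }
  w[, .f := NULL]
  if (any(w$flagged))
    warning(sum(w$flagged),
            " person-month(s) had observed-state probability below the floor (",
            prob_floor, "); clipped and flagged", call. = FALSE)
  data.table::setattr(w, "n_flagged", sum(w$flagged))
  data.table::setkey(w, patient_id, t)
  w[]
}

#' Stabilized inverse-probability-of-censoring weights
#'
#' Cumulative products of the numerator/denominator ratio of the
#' probability of remaining uncensored by LTF through each month, for the
#' rebound analysis. The combined weight for the outcome model is
#' `sw * swc` (see [combine_weights()]).
#'
#' @param person_months rebound-analysis person-month table (with
#'   `cens_ltf`).
#' @param censor_denominator_model,censor_numerator_model
#'   [fit_censoring_model()] fits.
#' @param prob_floor as in [compute_stabilized_iptw()].
#' @return `data.table` keyed by (`patient_id`, `t`) with `swc`.
#' @export
compute_censoring_weights <- function(person_months, censor_denominator_model,
                                      censor_numerator_model,
                                      prob_floor = 1e-6) {
  pm <- data.table::as.data.table(person_months)
  data.table::setorder(pm, patient_id, t)
  if (isTRUE(censor_denominator_model$zero_events) ||
      isTRUE(censor_numerator_model$zero_events)) {
    w <- data.table::data.table(patient_id = pm$patient_id, t = pm$t,
                                swc = 1, flagged = FALSE)
    data.table::setkey(w, patient_id, t)
    return(w[])
  }
  pred_cens <- function(fit) {
    X <- weight_design(pm, fit$blocks, fit$knots)
    drop(plogis(X[, names(fit$coef), drop = FALSE] %*% fit$coef))
  }
  pc_den <- pred_cens(censor_denominator_model)
  pc_num <- pred_cens(censor_numerator_model)
  den_unc <- 1 - pc_den
  num_unc <- 1 - pc_num
  flagged <- den_unc < prob_floor | num_unc < prob_floor
  den_unc <- pmax(den_unc, prob_floor)
  num_unc <- pmax(num_unc, prob_floor)
  w <- data.table::data.table(patient_id = pm$patient_id, t = pm$t,
                              .f = num_unc / den_unc, flagged = flagged)
  w[, swc := cumprod(.f), by = patient_id]
  w[, .f := NULL]
  data.table::setattr(w, "n_flagged", sum(w$flagged))
  data.table::setkey(w, patient_id, t)
  w[]
}

#' Combine treatment and censoring weight series
#'
#' @param sw treatment-weight table from [compute_stabilized_iptw()].
#' @param swc censoring-weight table from [compute_censoring_weights()]
#'   (or `NULL` for the primary outcome).
#' @return `data.table` keyed by (`patient_id`, `t`) with `sw`, `swc`, `w`.
#' @export
combine_weights <- function(sw, swc = NULL) {
  out <- data.table::copy(sw)[, .(patient_id, t, sw)]
  if (is.null(swc)) {
    out[, swc := 1]
  } else {
    out <- merge(out, swc[, .(patient_id, t, swc)], by = c("patient_id", "t"))
  }
  out[, w := sw * swc]
  data.table::setkey(out, patient_id, t)
  out[]
}

#' Percentile truncation of weights
#'
#' Replaces weights below the lower and above the upper percentile by the
#' percentile values themselves (type-7 sample quantiles).
#'
#' @param weights numeric weight vector.
#' @param percentile_pair `c(lower, upper)` in percent, `0 <= lower <
#'   upper <= 100`.
#' @return list: truncated `weights`, the `bounds` used, `n_truncated`,
#'   `mean_before`, `mean_after`.
#' @export
truncate_weights <- function(weights, percentile_pair) {
  if (length(percentile_pair) != 2 || !is.numeric(percentile_pair) ||
      percentile_pair[1] < 0 || percentile_pair[2] > 100 ||
      percentile_pair[1] >= percentile_pair[2])
    stop("percentile_pair must satisfy 0 <= lower < upper <= 100", call. = FALSE)
  qs <- unname(quantile(weights, percentile_pair / 100, type = 7))
  out <- pmin(pmax(weights, qs[1]), qs[2])
  list(weights = out, bounds = qs,
       n_truncated = sum(weights < qs[1] | weights > qs[2]),
       mean_before = mean(weights), mean_after = mean(out))
}

#' Descriptive diagnostics for a weight series
#'
#' @param weights numeric weight vector (e.g. the `w` column of
#'   [combine_weights()]).
#' @param t optional follow-up month per weight, for the mean-weight
#'   trajectory over follow-up time.
#' @param mean_tolerance flag if `|mean - 1|` exceeds this (stabilized
#'   weights should average about 1 under correct model specification).
#' @param n_extreme how many of the largest weights to report.
#' @return list of summaries; `mean_flag` is `TRUE` when the mean deviates
#'   from 1 beyond the tolerance.
#' @export
weight_diagnostics <- function(weights, t = NULL, mean_tolerance = 0.1,
                               n_extreme = 5L) {
  stopifnot(length(weights) > 0, all(is.finite(weights)), all(weights > 0))
  qs <- quantile(weights, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99), type = 7)
  ord <- order(weights, decreasing = TRUE)
  out <- list(n = length(weights), mean = mean(weights), sd = sd(weights),
              min = min(weights), max = max(weights), quantiles = qs,
              extreme_rows = head(ord, n_extreme),
              mean_flag = abs(mean(weights) - 1) > mean_tolerance)
  if (!is.null(t)) {
    dd <- data.table::data.table(t = t, w = weights)
    out$by_time <- dd[, .(mean_w = mean(w), sd_w = sd(w), n = .N), keyby = t]
  }
  out
}
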