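#' Simulation configuration for the synthetic ART cohort
#'
#' Assembles and validates the generative model: baseline covariate
#' distributions, monthly CD4 and viral-suppression dynamics, the
#' club-entry hazard model (log-odds scale), the death/LTF outcome hazard
#' and the virologic-rebound hazard. All event processes are discrete-time
#' Bernoulli hazards per month, matching the pooled-logistic analysis model
#' so that parameter recovery is well-posed. The death/LTF process doubles
#' as the (informative) LTF-censoring process of the rebound analysis.
#'
#' @param n_patients number of patients.
#' @param study_end length of the study window in months (entry months are
#'   staggered uniformly over `0:(study_end-1)`).
#' @param max_follow_up cap on per-patient follow-up, months.
#' @param meas_interval months between CD4/viral-load measurements
#'   (twice-yearly monitoring by default).
#' @param baseline list of baseline distribution parameters: gamma
#'   shape/scale for age above 18, CD4 at ART start, CD4 above 200 at entry
#'   and ART duration above 18 months, plus `female_prob`,
#'   `entry_suppressed_prob`, `who34_prob`.
#' @param cd4_dynamics list: monthly `drift` (cells/ul) and `sd` of the
#'   latent CD4 random walk (floored at 0), and `club_drift`, an additional
#'   drift while in a club (0 by default; nonzero only in
#'   treatment-affects-confounder stress scenarios, in which case the
#'   counterfactual oracle is unavailable).
#' @param suppression list: `persistence` (monthly probability a suppressed
#'   patient stays suppressed) and `resuppress_prob` (monthly probability an
#'   unsuppressed patient regains suppression).
#' @param club_model log-odds coefficients of the monthly club-entry hazard:
#'   `intercept`, `cd4_per100` (current measured CD4), `suppressed`
#'   (current measured suppression), `female`, `art_per12` (ART duration at
#'   entry per 12 months). Club entry is drawn from month 1 onward.
#' @param outcome_model log-odds coefficients of the monthly death/LTF
#'   hazard: `intercept`, `log_hr_club` (the true conditional club effect),
#'   `cd4_per100`, `suppressed`.
#' @param rebound_model log-odds coefficients of the monthly virologic
#'   rebound hazard (entry-suppressed patients only): `intercept`,
#'   `log_hr_club`, `cd4_per100`.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(n_patients = 2000L,
                       study_end = 40L,
                       max_follow_up = 40L,
                       meas_interval = 6L,
                       baseline = list(
                         age_shape = 4.2, age_scale = 4, female_prob = 0.71,
                         cd4_art_start_shape = 2.2, cd4_art_start_scale = 60,
                         cd4_entry_shape = 1.8, cd4_entry_scale = 110,
                         art_extra_shape = 2, art_extra_scale = 14,
                         entry_suppressed_prob = 0.88, who34_prob = 0.72),
                       cd4_dynamics = list(drift = 3, sd = 25, club_drift = 0),
                       suppression = list(persistence = 0.985,
                                          resuppress_prob = 0.10),
                       club_model = list(intercept = -8.65, cd4_per100 = 0.3,
                                         suppressed = 1.1, female = 0.3,
                                         art_per12 = 0.4),
                       outcome_model = list(intercept = -3.0,
                                            log_hr_club = log(0.43),
                                            cd4_per100 = -0.25,
                                            suppressed = -0.8),
                       rebound_model = list(intercept = -4.2,
                                            log_hr_club = log(0.33),
                                            cd4_per100 = -0.15)) {
  cfg <- list(n_patients = as.integer(n_patients), study_end = as.integer(study_end),
              max_follow_up = as.integer(max_follow_up),
              meas_interval = as.integer(meas_interval), baseline = baseline,
              cd4_dynamics = cd4_dynamics, suppression = suppression,
              club_model = club_model, outcome_model = outcome_model,
              rebound_model = rebound_model)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- character()
  chk_prob <- function(x, nm) if (!is.numeric(x) || x < 0 || x > 1) bad <<- c(bad, nm)
  if (cfg$n_patients < 1) bad <- c(bad, "n_patients (must be >= 1)")
  if (cfg$study_end < 1) bad <- c(bad, "study_end")
  if (cfg$max_follow_up < 1) bad <- c(bad, "max_follow_up")
  chk_prob(cfg$baseline$female_prob, "baseline$female_prob")
  chk_prob(cfg$baseline$entry_suppressed_prob, "baseline$entry_suppressed_prob")
  chk_prob(cfg$baseline$who34_prob, "baseline$who34_prob")
  chk_prob(cfg$suppression$persistence, "suppression$persistence")
  chk_prob(cfg$suppression$resuppress_prob, "suppression$resuppress_prob")
  # intercepts are the log-odds of the monthly hazard at zero covariates;
  # covariate effects must not push routine hazards past 0.5/month
  for (nm in c("outcome_model", "rebound_model")) {
    if (is.finite(cfg[[nm]]$intercept) && plogis(cfg[[nm]]$intercept) >= 0.5)
      bad <- c(bad, paste0(nm, "$intercept (monthly hazard >= 0.5)"))
  }
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Named simulation presets
#'
#' * `"confounded"` — the default stated world: healthier patients (higher
#'   current CD4, suppressed viral load, women, longer on ART)
#'   preferentially join clubs; true conditional club effects
#'   HR 0.43 (death/LTF) and 0.33 (rebound).
#' * `"null"` — as confounded but with zero club effect on both outcomes.
#' * `"randomized"` — zero confounder coefficients in the club-entry model
#'   (entry is an unconditional monthly coin flip), same outcome model.
#' * `"confounded_censoring"` — as confounded with a stronger CD4/viral-load
#'   dependence of the death/LTF hazard, stressing the informativeness of
#'   LTF censoring in the rebound analysis.
#'
#' @param name preset name.
#' @param n_patients cohort size override.
#' @return a [sim_config()].
#' @export
preset <- function(name = c("confounded", "null", "randomized",
                            "confounded_censoring"),
                   n_patients = 2000L) {
  name <- match.arg(name)
  cfg <- switch(name,
    confounded = sim_config(n_patients = n_patients),
    null = sim_config(n_patients = n_patients,
                      outcome_model = list(intercept = -3.0, log_hr_club = 0,
                                           cd4_per100 = -0.25, suppressed = -0.8),
                      rebound_model = list(intercept = -4.2, log_hr_club = 0,
                                           cd4_per100 = -0.15)),
    randomized = sim_config(n_patients = n_patients,
                            club_model = list(intercept = -5.1, cd4_per100 = 0,
                                              suppressed = 0, female = 0,
                                              art_per12 = 0)),
    confounded_censoring = sim_config(n_patients = n_patients,
                                      outcome_model = list(intercept = -2.2,
                                                           log_hr_club = log(0.43),
                                                           cd4_per100 = -0.45,
                                                           suppressed = -1.2)))
  attr(cfg, "preset") <- name
  cfg
}

draw_baseline <- function(cfg) {
  n <- cfg$n_patients
  b <- cfg$baseline
  data.table::data.table(
    patient_id = sprintf("p%05d", seq_len(n)),
    age_entry = round(18 + rgamma(n, b$age_shape, scale = b$age_scale), 1),
    gender = ifelse(runif(n) < b$female_prob, "female", "male"),
    cd4_art_start = round(rgamma(n, b$cd4_art_start_shape,
                                 scale = b$cd4_art_start_scale)),
    cd4_entry = round(201 + rgamma(n, b$cd4_entry_shape,
                                   scale = b$cd4_entry_scale)),
    vl_suppressed_entry = runif(n) < b$entry_suppressed_prob,
    art_duration_entry = round(18 + rgamma(n, b$art_extra_shape,
                                           scale = b$art_extra_scale)),
    who_stage = ifelse(runif(n) < b$who34_prob, "III/IV", "I/II"),
    entry_month = sample.int(cfg$study_end, n, replace = TRUE) - 1L)
}

#' Simulate a synthetic adherence-club cohort
#'
#' Generates patient records with the confounding structure of the study:
#' current (measured) CD4 and viral-load suppression drive both club entry
#' and the outcome hazards, so club members are systematically healthier.
#' Latent CD4 evolves monthly as a bounded random walk and suppression as a
#' two-state Markov chain, but all hazards read the *measured*
#' (carried-forward) values, which are recorded every `meas_interval`
#' months — hence the analysis models operating on LOCF covariates are
#' correctly specified. Club status follows intention-to-treat semantics:
#' once entered, always in.
#'
#' @param config a [sim_config()] or preset.
#' @param seed integer RNG seed; identical config + seed gives a
#'   byte-identical cohort.
#' @return list with `baseline` and `measurements` data.tables in the
#'   cohort CSV schema.
#' @export
simulate_cohort <- function(config, seed) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  bl <- draw_baseline(cfg)
  n <- cfg$n_patients
  fu <- pmin(cfg$max_follow_up, cfg$study_end - bl$entry_month)
  female <- bl$gender == "female"
  art12 <- bl$art_duration_entry / 12

  cd4 <- as.numeric(bl$cd4_entry)          # latent
  supp <- bl$vl_suppressed_entry
  cd4_meas <- cd4                          # last measured value (LOCF)
  supp_meas <- supp
  in_club <- rep(FALSE, n)
  club_t <- rep(NA_integer_, n)
  death_t <- rep(NA_integer_, n)
  reb_t <- rep(NA_integer_, n)

  cm <- cfg$club_model; om <- cfg$outcome_model; rm_ <- cfg$rebound_model
  dyn <- cfg$cd4_dynamics; sup <- cfg$suppression
  meas_list <- vector("list", cfg$max_follow_up)

  for (tt in 0:(max(fu) - 1L)) {
    at_risk <- is.na(death_t) & tt < fu
    if (!any(at_risk)) break
    idx <- which(at_risk)
    if (tt > 0L) {
      drift <- dyn$drift + dyn$club_drift * in_club[idx]
      cd4[idx] <- pmax(0, cd4[idx] + rnorm(length(idx), drift, dyn$sd))
      s <- supp[idx]
      u <- runif(length(idx))
      supp[idx] <- ifelse(s, u < sup$persistence, u < sup$resuppress_prob)
    }
    if (tt %% cfg$meas_interval == 0L) {
      cd4_meas[idx] <- round(cd4[idx])
      supp_meas[idx] <- supp[idx]
      meas_list[[tt + 1L]] <- data.table::data.table(
        patient_id = rep(bl$patient_id[idx], 2L),
        month = rep(bl$entry_month[idx] + tt, 2L),
        variable = rep(c("cd4", "vl_suppressed"), each = length(idx)),
        value = c(cd4_meas[idx], as.numeric(supp_meas[idx])))
    }
    if (tt >= 1L) {
      cand <- idx[!in_club[idx]]
      if (length(cand)) {
        pj <- plogis(cm$intercept + cm$cd4_per100 * cd4_meas[cand] / 100 +
                       cm$suppressed * supp_meas[cand] +
                       cm$female * female[cand] + cm$art_per12 * art12[cand])
        joins <- runif(length(cand)) < pj
        in_club[cand[joins]] <- TRUE
        club_t[cand[joins]] <- tt
      }
    }
    pd <- plogis(om$intercept + om$log_hr_club * in_club[idx] +
                   om$cd4_per100 * cd4_meas[idx] / 100 +
                   om$suppressed * supp_meas[idx])
    dies <- runif(length(idx)) < pd
    death_t[idx[dies]] <- tt
    rcand <- idx[bl$vl_suppressed_entry[idx] & is.na(reb_t[idx])]
    if (length(rcand)) {
      pr <- plogis(rm_$intercept + rm_$log_hr_club * in_club[rcand] +
                     rm_$cd4_per100 * cd4_meas[rcand] / 100)
      rebs <- runif(length(rcand)) < pr
      reb_t[rcand[rebs]] <- tt
    }
  }

  bl[, club_entry_month := entry_month + club_t]
  bl[, death_ltf_month := entry_month + death_t]
  bl[, rebound_month := entry_month + reb_t]
  bl[, admin_censor_month := entry_month + fu - 1L]
  meas <- data.table::rbindlist(meas_list)
  # drop measurements after a patient's exit (no post-mortem lab draws)
  exit_m <- pmin(bl$death_ltf_month, bl$admin_censor_month, na.rm = TRUE)
  meas <- meas[month <= exit_m[match(patient_id, bl$patient_id)]]
  data.table::setkey(meas, patient_id, month, variable)
  list(baseline = bl[], measurements = meas[])
}

#' True marginal hazard ratio by counterfactual simulation
#'
#' Simulates two counterfactual arms over identical confounder streams —
#' club entry forced at a time drawn at random from the *baseline-conditional*
#' entry law (the same law the stabilized weights' numerator model encodes:
#' entry may depend on baseline covariates and follow-up time but is
#' independent of the time-varying confounders), versus never-club — and
#' fits an unconfounded pooled logistic model (club indicator, spline
#' follow-up time, baseline covariates) to the pooled arms. This is exactly
#' the reference regime of the IPTW-weighted analysis, so the oracle and
#' the weighted estimator target the same projection even where the
#' marginal structural model is only an approximation. Both arms share
#' covariate paths and per-month outcome uniforms (common-random-number
#' variance reduction). Marginal hazard ratios under covariate-dependent
#' hazards have no closed form, hence simulation.
#'
#' @param config a [sim_config()]; requires `cd4_dynamics$club_drift == 0`
#'   (with treatment-affected confounders the two arms' covariate streams
#'   diverge and this shortcut is invalid).
#' @param n_large number of simulated patients per arm (>= 1e5 recommended).
#' @param seed RNG seed.
#' @return object of class `oracle_hr`: list with `hr`, `log_hr`, `se`
#'   (patient-clustered), `n`, and the fitted `entry_model` coefficients
#'   defining the entry law.
#' @export
oracle_marginal_hr <- function(config, n_large = 1e5, seed = 1L) {
  validate_sim_config(config)
  if (config$cd4_dynamics$club_drift != 0)
    stop("counterfactual oracle requires club_drift == 0", call. = FALSE)
  cfg <- config
  # baseline-conditional entry law, fitted on a factual run
  cfg_h <- cfg
  cfg_h$n_patients <- as.integer(min(n_large, 20000L))
  fact <- simulate_cohort(cfg_h, seed = seed)
  pm_f <- build_person_month_table(fact$baseline, fact$measurements,
                                   "death_ltf")
  knots_f <- spline_knots(pm_f$t)
  entry_mod <- fit_treatment_model(pm_f, blocks = "baseline", knots = knots_f)
  Tmax <- cfg$max_follow_up

  set.seed(seed + 1L)
  cfg2 <- cfg
  cfg2$n_patients <- as.integer(n_large)
  bl <- draw_baseline(cfg2)
  n <- cfg2$n_patients
  fu <- pmin(cfg$max_follow_up, cfg$study_end - bl$entry_month)
  cd4 <- as.numeric(bl$cd4_entry); supp <- bl$vl_suppressed_entry
  cd4_meas <- cd4; supp_meas <- supp
  dyn <- cfg$cd4_dynamics; sup <- cfg$suppression; om <- cfg$outcome_model
  # entry times drawn from the baseline-conditional law (no L-dependence)
  Xb <- baseline_design(bl)
  Efree <- rep(NA_integer_, n)
  for (tt in 1:(Tmax - 1L)) {
    cand <- which(is.na(Efree))
    if (!length(cand)) break
    Xt <- cbind(`(Intercept)` = 1, spline_basis(rep(tt, length(cand)), knots_f),
                Xb[cand, , drop = FALSE])
    pj <- plogis(drop(Xt %*% entry_mod$coef[colnames(Xt)]))
    Efree[cand[runif(length(cand)) < pj]] <- tt
  }
  death0 <- rep(NA_integer_, n)  # never-club arm
  death1 <- rep(NA_integer_, n)  # forced-entry arm
  for (tt in 0:(max(fu) - 1L)) {
    alive <- (is.na(death0) | is.na(death1)) & tt < fu
    if (!any(alive)) break
    idx <- which(alive)
    if (tt > 0L) {
      cd4[idx] <- pmax(0, cd4[idx] + rnorm(length(idx), dyn$drift, dyn$sd))
      s <- supp[idx]; u <- runif(length(idx))
      supp[idx] <- ifelse(s, u < sup$persistence, u < sup$resuppress_prob)
    }
    if (tt %% cfg$meas_interval == 0L) {
      cd4_meas[idx] <- round(cd4[idx]); supp_meas[idx] <- supp[idx]
    }
    base_lin <- om$intercept + om$cd4_per100 * cd4_meas[idx] / 100 +
      om$suppressed * supp_meas[idx]
    u <- runif(length(idx))                     # shared across arms
    a1 <- !is.na(Efree[idx]) & tt >= Efree[idx]
    d0 <- is.na(death0[idx]) & u < plogis(base_lin)
    d1 <- is.na(death1[idx]) & u < plogis(base_lin + om$log_hr_club * a1)
    death0[idx[d0]] <- tt
    death1[idx[d1]] <- tt
  }
  exit0 <- pmin(death0, fu - 1L, na.rm = TRUE)
  exit1 <- pmin(death1, fu - 1L, na.rm = TRUE)
  pooled <- data.table::rbindlist(list(
    expand_arm(bl, exit0, !is.na(death0) & death0 <= exit0, rep(NA_integer_, n)),
    expand_arm(bl, exit1, !is.na(death1) & death1 <= exit1, Efree)))
  knots <- spline_knots(pooled$t)
  X <- cbind(`(Intercept)` = 1, in_club = as.numeric(pooled$in_club),
             time_design(pooled, knots), baseline_design(pooled))
  fit <- logit_irls(X, pooled$y, w = NULL)
  vc <- sandwich_variance_clustered(X, pooled$y, fit$fitted,
                                    rep(1, nrow(X)), pooled$patient_id)
  lhr <- unname(fit$coef["in_club"])
  structure(list(hr = exp(lhr), log_hr = lhr,
                 se = sqrt(vc["in_club", "in_club"]),
                 n = n, entry_model = entry_mod$coef), class = "oracle_hr")
}

# expand one counterfactual arm into person-month rows
expand_arm <- function(bl, exit_t, event, entry_t) {
  n <- nrow(bl)
  len <- exit_t + 1L
  pm <- bl[rep(seq_len(n), len),
           .(patient_id, age_entry, gender, cd4_art_start, cd4_entry,
             vl_suppressed_entry, art_duration_entry, who_stage)]
  pm[, t := unlist(lapply(len, function(k) seq_len(k) - 1L))]
  pm[, y := 0L]
  last <- as.integer(cumsum(len))
  data.table::set(pm, i = last, j = "y", value = as.integer(event))
  e_rep <- rep(entry_t, len)
  pm[, in_club := !is.na(e_rep) & t >= e_rep]
  pm
}

#' @export
print.oracle_hr <- function(x, ...) {
  cat(sprintf("Counterfactual oracle marginal HR: %.3f (log-HR %.4f, MC se %.4f, n = %d per arm)\n",
              x$hr, x$log_hr, x$se, x$n))
  invisible(x)
}
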