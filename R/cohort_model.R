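#' Patient-level record
#'
#' Validating constructor for one patient's baseline covariates, dated
#' measurement series and event/censoring months. All dates are integer
#' calendar-month indices (month 0 = study opening); no real-date parsing.
#'
#' @param patient_id identifier (character or integer).
#' @param age_entry age in years at study entry (must be >= 18).
#' @param gender `"female"` or `"male"`.
#' @param cd4_art_start CD4 count (cells/ul) at ART initiation.
#' @param cd4_entry latest CD4 count at study entry; eligibility requires
#'   > 200 cells/ul.
#' @param vl_suppressed_entry logical, viral load < 400 copies/ml at entry.
#' @param art_duration_entry months on ART at entry (must be >= 18).
#' @param who_stage `"I/II"` or `"III/IV"`.
#' @param entry_month calendar month of study entry.
#' @param measurements data.frame with columns `month`, `variable`
#'   (`"cd4"` or `"vl_suppressed"`), `value`.
#' @param club_entry_month calendar month of first adherence-club visit, or
#'   `NA` if the patient never joined.
#' @param death_ltf_month calendar month of death or loss to follow-up
#'   (dated at last contact), or `NA`.
#' @param rebound_month calendar month of first viral load > 400 copies/ml,
#'   or `NA`.
#' @param admin_censor_month calendar month of administrative censoring
#'   (study closure or end of the follow-up window).
#' @return object of class `patient_record` (a named list).
#' @export
patient_record <- function(patient_id, age_entry, gender, cd4_art_start,
                           cd4_entry, vl_suppressed_entry, art_duration_entry,
                           who_stage, entry_month, measurements,
                           club_entry_month = NA_integer_,
                           death_ltf_month = NA_integer_,
                           rebound_month = NA_integer_,
                           admin_censor_month) {
  stopifnot(gender %in% c("female", "male"), who_stage %in% c("I/II", "III/IV"))
  if (age_entry < 18) stop("age_entry must be >= 18 (adult cohort)", call. = FALSE)
  if (art_duration_entry < 18)
    stop("art_duration_entry must be >= 18 months (eligibility)", call. = FALSE)
  if (cd4_entry <= 200)
    stop("cd4_entry must exceed 200 cells/ul (eligibility)", call. = FALSE)
  exit <- min(death_ltf_month, admin_censor_month, na.rm = TRUE)
  for (m in c(club_entry_month, death_ltf_month, rebound_month, admin_censor_month)) {
    if (!is.na(m) && m < entry_month)
      stop("event/censor month precedes entry_month for patient ", patient_id,
           call. = FALSE)
  }
  if (!is.na(club_entry_month) && club_entry_month > exit)
    stop("club_entry_month lies after exit for patient ", patient_id, call. = FALSE)
  structure(list(patient_id = patient_id, age_entry = age_entry, gender = gender,
                 cd4_art_start = cd4_art_start, cd4_entry = cd4_entry,
                 vl_suppressed_entry = as.logical(vl_suppressed_entry),
                 art_duration_entry = art_duration_entry, who_stage = who_stage,
                 entry_month = as.integer(entry_month),
                 measurements = as.data.frame(measurements),
                 club_entry_month = as.integer(club_entry_month),
                 death_ltf_month = as.integer(death_ltf_month),
                 rebound_month = as.integer(rebound_month),
                 admin_censor_month = as.integer(admin_censor_month)),
            class = "patient_record")
}

#' Eligibility screen: first qualifying month
#'
#' A patient enters the analysis at the first month within the study window
#' at which (i) they have been on ART for at least 18 months and (ii) their
#' latest CD4 count (last observation carried forward) exceeds 200 cells/ul.
#'
#' @param art_start_month calendar month ART was initiated (`NA` = unknown).
#' @param cd4_measurements data.frame with columns `month`, `value`
#'   (CD4, cells/ul), in calendar months.
#' @param study_start,study_end calendar-month bounds of the study window.
#' @return list with `eligible` (logical), `entry_month` (or `NA`) and
#'   `reason` (`"ok"`, `"missing_art_start"`, `"no_cd4"`,
#'   `"never_eligible_in_window"`).
#' @export
check_eligibility <- function(art_start_month, cd4_measurements,
                              study_start, study_end) {
  if (is.na(art_start_month) || is.null(art_start_month))
    return(list(eligible = FALSE, entry_month = NA_integer_,
                reason = "missing_art_start"))
  cm <- as.data.frame(cd4_measurements)
  if (nrow(cm) == 0)
    return(list(eligible = FALSE, entry_month = NA_integer_, reason = "no_cd4"))
  cm <- cm[order(cm$month), , drop = FALSE]
  for (m in seq.int(study_start, study_end)) {
    if (m - art_start_month < 18) next
    seen <- cm$value[cm$month <= m]
    if (length(seen) == 0) next
    if (seen[length(seen)] > 200)
      return(list(eligible = TRUE, entry_month = as.integer(m), reason = "ok"))
  }
  list(eligible = FALSE, entry_month = NA_integer_,
       reason = "never_eligible_in_window")
}

#' Expand one patient record into person-month rows
#'
#' Discrete-time expansion on the months-since-entry scale (t = 0, 1, ...).
#' For the combined death/LTF outcome the exit row is t at the event or
#' censoring month; the event flag sits on the final row. For the rebound
#' outcome, death/LTF acts as censoring and the record must have been
#' virologically suppressed at entry.
#'
#' Covariates are then filled by [apply_itt_carry_forward()] and
#' [locf_and_lag_covariates()]; this function only lays out the time grid,
#' the outcome and the censoring flags.
#'
#' @param record a [patient_record()].
#' @param outcome `"death_ltf"` or `"rebound"`.
#' @return `data.table` with one row per person-month: `patient_id`, `t`,
#'   `y`, `censored`, `cens_ltf` plus the baseline covariate columns.
#' @export
expand_person_months <- function(record, outcome = c("death_ltf", "rebound")) {
  outcome <- match.arg(outcome)
  r <- record
  entry <- r$entry_month
  if (!is.na(r$death_ltf_month) && r$death_ltf_month < entry)
    stop("event precedes entry for patient ", r$patient_id, call. = FALSE)
  if (outcome == "rebound") {
    if (!isTRUE(r$vl_suppressed_entry))
      stop("rebound analysis is limited to patients virologically suppressed at study entry; patient ",
           r$patient_id, " was not", call. = FALSE)
    if (!is.na(r$rebound_month) && r$rebound_month < entry)
      stop("event precedes entry for patient ", r$patient_id, call. = FALSE)
    exit_m <- min(r$rebound_month, r$death_ltf_month, r$admin_censor_month,
                  na.rm = TRUE)
    event <- !is.na(r$rebound_month) && r$rebound_month == exit_m
    ltf_cens <- !event && !is.na(r$death_ltf_month) && r$death_ltf_month == exit_m
  } else {
    exit_m <- min(r$death_ltf_month, r$admin_censor_month, na.rm = TRUE)
    event <- !is.na(r$death_ltf_month) && r$death_ltf_month == exit_m
    ltf_cens <- FALSE
  }
  tt <- seq.int(0L, exit_m - entry)
  n <- length(tt)
  data.table::data.table(
    patient_id = r$patient_id, t = tt,
    y = c(rep(0L, n - 1L), as.integer(event)),
    censored = c(rep(FALSE, n - 1L), !event),
    cens_ltf = c(rep(FALSE, n - 1L), ltf_cens),
    age_entry = r$age_entry, gender = r$gender,
    cd4_art_start = r$cd4_art_start, cd4_entry = r$cd4_entry,
    vl_suppressed_entry = r$vl_suppressed_entry,
    art_duration_entry = r$art_duration_entry, who_stage = r$who_stage,
    entry_month = entry)
}

#' Intention-to-treat club-status carry-forward
#'
#' Sets the ever-in-club indicator: `FALSE` strictly before the club-entry
#' month, `TRUE` from that month onward, never reverting (patients are
#' analysed as club members until the end of the study once they join).
#'
#' @param rows person-month `data.table` for one patient, sorted by `t`.
#' @param club_entry_month calendar month of club entry (`NA` = never).
#' @return `rows` with an `in_club` logical column.
#' @export
apply_itt_carry_forward <- function(rows, club_entry_month) {
  rows <- data.table::as.data.table(rows)
  if (is.na(club_entry_month)) {
    rows[, in_club := FALSE]
  } else {
    ct <- club_entry_month - rows$entry_month[1]
    rows[, in_club := t >= ct]
  }
  rows[]
}

#' Carry covariates forward and apply the 6-month CD4 lag
#'
#' `cd4_current` at month t is the last CD4 observed at or before t (LOCF);
#' `cd4_lag6` at t is `cd4_current` at t - `lag`, falling back to the study
#' entry value for t < `lag`. `vl_suppressed` is LOCF of the viral-load
#' suppression status. A CD4 and a viral-load status at or before entry are
#' required.
#'
#' @param rows person-month `data.table` for one patient (from
#'   [expand_person_months()]).
#' @param measurements data.frame with columns `month` (calendar),
#'   `variable` (`"cd4"`/`"vl_suppressed"`), `value`.
#' @param lag lag in months for the lagged CD4 covariate (default 6).
#' @return `rows` with `cd4_current`, `cd4_lag6`, `vl_suppressed` filled.
#' @export
locf_and_lag_covariates <- function(rows, measurements, lag = 6L) {
  rows <- data.table::as.data.table(rows)
  entry <- rows$entry_month[1]
  pid <- rows$patient_id[1]
  mm <- data.table::as.data.table(measurements)
  mm <- mm[order(month)]
  locf <- function(var) {
    mv <- mm[variable == var]
    if (nrow(mv) == 0 || min(mv$month) > entry)
      stop("no ", var, " measurement at or before entry for patient ", pid,
           call. = FALSE)
    idx <- findInterval(entry + rows$t, mv$month)
    mv$value[idx]
  }
  rows[, cd4_current := locf("cd4")]
  rows[, vl_suppressed := as.logical(locf("vl_suppressed"))]
  cd4_at <- function(tt) rows$cd4_current[match(pmax(tt, 0L), rows$t)]
  rows[, cd4_lag6 := ifelse(t < lag, cd4_current[t == 0], cd4_at(t - lag))]
  rows[]
}

#' Build the full person-month analysis table for a cohort
#'
#' Vectorised equivalent of running [expand_person_months()],
#' [apply_itt_carry_forward()] and [locf_and_lag_covariates()] patient by
#' patient, using data.table rolling joins; the two routes agree row for
#' row (this is tested). Patients failing the rebound restriction
#' (not suppressed at entry) are dropped for `outcome = "rebound"`.
#'
#' @param baseline cohort baseline table in the CSV schema (see
#'   [read_cohort()]): one row per patient.
#' @param measurements long measurement table (`patient_id`, `month`,
#'   `variable`, `value`).
#' @param outcome `"death_ltf"` or `"rebound"`.
#' @param lag CD4 lag in months.
#' @return person-month `data.table` with columns `patient_id`, `t`,
#'   `in_club`, `cd4_current`, `cd4_lag6`, `vl_suppressed`, `y`,
#'   `censored`, `cens_ltf` and the baseline covariates; attribute
#'   `outcome` records which endpoint the table encodes.
#' @export
build_person_month_table <- function(baseline, measurements,
                                     outcome = c("death_ltf", "rebound"),
                                     lag = 6L) {
  outcome <- match.arg(outcome)
  bl <- data.table::as.data.table(baseline)
  mm <- data.table::as.data.table(measurements)
  req <- c("patient_id", "age_entry", "gender", "cd4_art_start", "cd4_entry",
           "vl_suppressed_entry", "art_duration_entry", "who_stage",
           "entry_month", "club_entry_month", "death_ltf_month",
           "rebound_month", "admin_censor_month")
  miss <- setdiff(req, names(bl))
  if (length(miss))
    stop("baseline table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (outcome == "rebound") {
    if (!any(bl$vl_suppressed_entry))
      stop("rebound analysis requires patients virologically suppressed at study entry; none found",
           call. = FALSE)
    bl <- bl[vl_suppressed_entry == TRUE]
    exit_m <- pmin(bl$rebound_month, bl$death_ltf_month, bl$admin_censor_month,
                   na.rm = TRUE)
    event <- !is.na(bl$rebound_month) & bl$rebound_month == exit_m
    ltfc <- !event & !is.na(bl$death_ltf_month) & bl$death_ltf_month == exit_m
  } else {
    exit_m <- pmin(bl$death_ltf_month, bl$admin_censor_month, na.rm = TRUE)
    event <- !is.na(bl$death_ltf_month) & bl$death_ltf_month == exit_m
    ltfc <- rep(FALSE, nrow(bl))
  }
  if (any(exit_m < bl$entry_month))
    stop("event/censor month precedes entry for patient(s): ",
         paste(head(bl$patient_id[exit_m < bl$entry_month]), collapse = ", "),
         call. = FALSE)
  fu <- exit_m - bl$entry_month + 1L          # rows per patient
  pm <- bl[rep(seq_len(nrow(bl)), fu),
           .(patient_id, age_entry, gender, cd4_art_start, cd4_entry,
             vl_suppressed_entry, art_duration_entry, who_stage, entry_month,
             club_entry_month)]
  pm[, t := seq_len(.N) - 1L, by = patient_id]
  last <- pm[, .I[.N], by = patient_id]$V1
  pm[, `:=`(y = 0L, censored = FALSE, cens_ltf = FALSE)]
  pm[last, `:=`(y = as.integer(event), censored = !event, cens_ltf = ltfc)]
  pm[, in_club := !is.na(club_entry_month) & entry_month + t >= club_entry_month]
  pm[, month := entry_month + t]

  # LOCF via rolling joins on calendar month
  for (v in c("cd4", "vl_suppressed")) {
    mv <- mm[variable == v, .(patient_id, month, val = value)]
    data.table::setkey(mv, patient_id, month)
    pm[, (paste0(".", v)) := mv[pm, on = .(patient_id, month), roll = TRUE, x.val]]
  }
  if (anyNA(pm$.cd4) || anyNA(pm$.vl_suppressed)) {
    bad <- unique(pm$patient_id[is.na(pm$.cd4) | is.na(pm$.vl_suppressed)])
    stop("no pre-entry CD4/viral-load measurement for patient(s): ",
         paste(head(bad), collapse = ", "), call. = FALSE)
  }
  pm[, cd4_current := .cd4]
  pm[, vl_suppressed := as.logical(.vl_suppressed)]
  pm[, cd4_lag6 := data.table::shift(cd4_current, n = lag,
                                     fill = NA_real_), by = patient_id]
  pm[, cd4_lag6 := data.table::fifelse(is.na(cd4_lag6), cd4_current[t == 0][1],
                                       cd4_lag6), by = patient_id]
  pm[, c(".cd4", ".vl_suppressed", "month", "club_entry_month") := NULL]
  data.table::setcolorder(pm, c("patient_id", "t", "in_club", "cd4_current",
                                "cd4_lag6", "vl_suppressed", "y", "censored",
                                "cens_ltf"))
  data.table::setattr(pm, "outcome", outcome)
  pm[]
}

#' Read a cohort from its two-file CSV schema
#'
#' @param baseline_file CSV of one baseline row per patient.
#' @param measurements_file long CSV of dated measurements.
#' @return list with `baseline` and `measurements` data.tables.
#' @export
read_cohort <- function(baseline_file, measurements_file) {
  if (!file.exists(baseline_file))
    stop("baseline file not found: ", baseline_file, call. = FALSE)
  if (!file.exists(measurements_file))
    stop("measurements file not found: ", measurements_file, call. = FALSE)
  bl <- data.table::fread(baseline_file)
  mm <- data.table::fread(measurements_file)
  bl[, vl_suppressed_entry := as.logical(vl_suppressed_entry)]
  # all-NA event columns come back as logical; keep the schema integer
  for (col in c("club_entry_month", "death_ltf_month", "rebound_month",
                "admin_censor_month", "entry_month")) {
    if (col %in% names(bl)) bl[, (col) := as.integer(get(col))]
  }
  list(baseline = bl, measurements = mm)
}

#' Write a cohort to the two-file CSV schema
#'
#' @param cohort list with `baseline` and `measurements` (as produced by
#'   [simulate_cohort()]).
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bf <- file.path(dir, "baseline.csv")
  mf <- file.path(dir, "measurements.csv")
  bl <- data.table::copy(data.table::as.data.table(cohort$baseline))
  bl[, vl_suppressed_entry := as.integer(vl_suppressed_entry)]
  data.table::fwrite(bl, bf)
  data.table::fwrite(cohort$measurements, mf)
  invisible(c(baseline = bf, measurements = mf))
}
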