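# fixtures are built in code; no data files

# single patient with measurements at entry and month 7
toy_record <- function(club_entry_month = NA_integer_,
                       death_ltf_month = NA_integer_,
                       rebound_month = NA_integer_,
                       admin_censor_month = 12L,
                       vl_suppressed_entry = TRUE,
                       entry_month = 0L) {
  patient_record(
    patient_id = "tp1", age_entry = 34, gender = "female",
    cd4_art_start = 120, cd4_entry = 300,
    vl_suppressed_entry = vl_suppressed_entry,
    art_duration_entry = 30, who_stage = "III/IV", entry_month = entry_month,
    measurements = data.frame(
      month = c(entry_month, entry_month, entry_month + 7L),
      variable = c("cd4", "vl_suppressed", "cd4"),
      value = c(300, 1, 400)),
    club_entry_month = club_entry_month, death_ltf_month = death_ltf_month,
    rebound_month = rebound_month, admin_censor_month = admin_censor_month)
}

# 3-patient toy cohort: follow-ups 5, 3 and 8 months past entry (so 6, 4 and
# 9 rows including t = 0), one death/LTF event; used for hand-count checks
toy_cohort <- function() {
  baseline <- data.table::data.table(
    patient_id = c("a", "b", "c"),
    age_entry = c(24, 36, 47), gender = c("female", "male", "female"),
    cd4_art_start = c(45, 150, 220), cd4_entry = c(250, 320, 500),
    vl_suppressed_entry = c(TRUE, TRUE, FALSE),
    art_duration_entry = c(20, 40, 60),
    who_stage = c("I/II", "III/IV", "III/IV"),
    entry_month = c(0L, 2L, 1L),
    club_entry_month = c(NA_integer_, 4L, NA_integer_),
    death_ltf_month = c(5L, NA_integer_, NA_integer_),
    rebound_month = c(NA_integer_, NA_integer_, NA_integer_),
    admin_censor_month = c(10L, 5L, 9L))
  measurements <- data.table::data.table(
    patient_id = c("a", "a", "b", "b", "c", "c", "a"),
    month = c(0L, 0L, 2L, 2L, 1L, 1L, 3L),
    variable = c("cd4", "vl_suppressed", "cd4", "vl_suppressed",
                 "cd4", "vl_suppressed", "cd4"),
    value = c(250, 1, 320, 1, 500, 0, 280))
  list(baseline = baseline, measurements = measurements)
}

# small simulated cohort for property tests (fast)
small_sim <- function(seed = 42, n = 400L, preset_name = "confounded") {
  simulate_cohort(preset(preset_name, n_patients = n), seed = seed)
}

# deterministic 6-patient person-month fixture with an in-club contrast,
# used for sandwich-variance brute-force checks
six_patient_pm <- function() {
  set.seed(99)
  rows <- list()
  specs <- list(
    list(id = "s1", len = 4L, club = 2L, y = 1L),
    list(id = "s2", len = 6L, club = NA, y = 0L),
    list(id = "s3", len = 3L, club = 0L, y = 1L),
    list(id = "s4", len = 7L, club = 5L, y = 0L),
    list(id = "s5", len = 5L, club = NA, y = 1L),
    list(id = "s6", len = 6L, club = 3L, y = 0L))
  for (s in specs) {
    tt <- 0:(s$len - 1L)
    rows[[s$id]] <- data.table::data.table(
      patient_id = s$id, t = tt,
      in_club = if (is.na(s$club)) rep(FALSE, s$len) else tt >= s$club,
      y = c(rep(0L, s$len - 1L), s$y),
      censored = c(rep(FALSE, s$len - 1L), s$y == 0L),
      cens_ltf = FALSE,
      age_entry = round(runif(1, 20, 50), 1),
      gender = sample(c("female", "male"), 1),
      cd4_art_start = round(runif(1, 30, 250)),
      cd4_entry = round(runif(1, 210, 600)),
      vl_suppressed_entry = runif(1) < 0.8,
      art_duration_entry = round(runif(1, 18, 70)),
      who_stage = sample(c("I/II", "III/IV"), 1),
      entry_month = 0L,
      cd4_current = round(runif(s$len, 200, 600)),
      cd4_lag6 = round(runif(s$len, 200, 600)),
      vl_suppressed = runif(s$len) < 0.8)
  }
  data.table::rbindlist(rows)
}
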