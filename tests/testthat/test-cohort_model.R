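test_that("eligibility: first qualifying month, window exclusion, error codes", {
  # on ART 20 months with CD4 350 at study opening -> eligible immediately
  r <- check_eligibility(art_start_month = -20,
                         cd4_measurements = data.frame(month = -2, value = 350),
                         study_start = 0, study_end = 40)
  expect_true(r$eligible)
  expect_equal(r$entry_month, 0L)

  # CD4 150 at opening, 250 measured 4 months later -> eligible at month 4
  r <- check_eligibility(-24, data.frame(month = c(-1, 4), value = c(150, 250)),
                         0, 40)
  expect_true(r$eligible)
  expect_equal(r$entry_month, 4L)

  # reaches 18 months on ART only after study end -> ineligible
  r <- check_eligibility(30, data.frame(month = 31, value = 400), 0, 40)
  expect_false(r$eligible)
  expect_equal(r$reason, "never_eligible_in_window")

  # ART duration gates entry even when CD4 qualifies from the start
  r <- check_eligibility(-10, data.frame(month = -1, value = 500), 0, 40)
  expect_equal(r$entry_month, 8L)

  expect_equal(check_eligibility(NA, data.frame(month = 0, value = 300),
                                 0, 40)$reason, "missing_art_start")
  expect_equal(check_eligibility(-20, data.frame(month = numeric(),
                                                 value = numeric()),
                                 0, 40)$reason, "no_cd4")
})

test_that("person-month expansion: row counts, event and censor flags", {
  # death/LTF at t = 5 -> 6 rows, y = 1 only on the last
  rows <- expand_person_months(toy_record(death_ltf_month = 5L), "death_ltf")
  expect_equal(nrow(rows), 6L)
  expect_equal(rows$y, c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_false(any(rows$censored))

  # administrative censoring at t = 3 -> 4 rows, all y = 0, last censored
  rows <- expand_person_months(toy_record(admin_censor_month = 3L), "death_ltf")
  expect_equal(nrow(rows), 4L)
  expect_equal(sum(rows$y), 0L)
  expect_equal(rows$censored, c(FALSE, FALSE, FALSE, TRUE))

  # toy cohort hand count: follow-ups of 6, 4 and 9 rows = 19 person-months
  tc <- toy_cohort()
  pm <- build_person_month_table(tc$baseline, tc$measurements, "death_ltf")
  expect_equal(nrow(pm), 19L)
  expect_equal(sum(pm$y), 1L)

  # event before entry is a structural inconsistency
  bad <- toy_cohort()
  bad$baseline$death_ltf_month[2] <- 1L   # entry is month 2
  expect_error(build_person_month_table(bad$baseline, bad$measurements,
                                        "death_ltf"), "precedes entry")
})

test_that("rebound expansion restricts to entry-suppressed and censors at LTF", {
  r <- toy_record(death_ltf_month = 5L, rebound_month = 9L)
  rows <- expand_person_months(r, "rebound")
  # LTF at t=5 comes before the rebound: censored there, no event rows after
  expect_equal(nrow(rows), 6L)
  expect_equal(sum(rows$y), 0L)
  expect_true(rows$cens_ltf[6])
  expect_error(expand_person_months(toy_record(vl_suppressed_entry = FALSE),
                                    "rebound"), "suppressed at study entry")

  r2 <- toy_record(rebound_month = 4L)
  rows2 <- expand_person_months(r2, "rebound")
  expect_equal(rows2$y, c(0L, 0L, 0L, 0L, 1L))
})

test_that("ITT carry-forward is monotone and matches the stated patterns", {
  rows <- expand_person_months(toy_record(), "death_ltf")   # 13 rows, t=0..12
  r8 <- apply_itt_carry_forward(rows, club_entry_month = 8L)
  expect_equal(r8$in_club, c(rep(FALSE, 8), rep(TRUE, 5)))
  expect_true(all(diff(r8$in_club) >= 0))
  expect_false(any(apply_itt_carry_forward(rows, NA_integer_)$in_club))
  expect_true(all(apply_itt_carry_forward(rows, 0L)$in_club))
})

test_that("LOCF and the 6-month lag follow the stated boundary rules", {
  rows <- expand_person_months(toy_record(), "death_ltf")
  meas <- data.frame(month = c(0, 0, 7), variable = c("cd4", "vl_suppressed", "cd4"),
                     value = c(300, 1, 400))
  out <- locf_and_lag_covariates(rows, meas)
  expect_equal(out$cd4_current[out$t == 6], 300)
  expect_equal(out$cd4_current[out$t == 7], 400)
  # lag: value at t-6; below 6 months, the entry value
  expect_equal(out$cd4_lag6[out$t == 10], out$cd4_current[out$t == 4])
  expect_equal(out$cd4_lag6[out$t == 3], 300)
  expect_true(all(out$vl_suppressed))
  expect_error(locf_and_lag_covariates(rows,
                                       data.frame(month = 5, variable = "cd4",
                                                  value = 300)),
               "at or before entry")
})

test_that("vectorised table builder equals the per-record route", {
  co <- small_sim(seed = 7, n = 120L)
  pm_vec <- build_person_month_table(co$baseline, co$measurements, "death_ltf")
  per <- lapply(seq_len(nrow(co$baseline)), function(i) {
    b <- co$baseline[i]
    r <- patient_record(b$patient_id, b$age_entry, b$gender, b$cd4_art_start,
                        b$cd4_entry, b$vl_suppressed_entry,
                        b$art_duration_entry, b$who_stage, b$entry_month,
                        co$measurements[patient_id == b$patient_id,
                                        .(month, variable, value)],
                        b$club_entry_month, b$death_ltf_month,
                        b$rebound_month, b$admin_censor_month)
    rows <- expand_person_months(r, "death_ltf")
    rows <- apply_itt_carry_forward(rows, b$club_entry_month)
    locf_and_lag_covariates(rows, r$measurements)
  })
  pm_rec <- data.table::rbindlist(per, use.names = TRUE)
  data.table::setorder(pm_vec, patient_id, t)
  data.table::setorder(pm_rec, patient_id, t)
  for (col in c("t", "in_club", "cd4_current", "cd4_lag6", "vl_suppressed",
                "y", "censored")) {
    expect_equal(pm_vec[[col]], pm_rec[[col]], info = col)
  }
})

test_that("table invariants: conservation, order invariance, censor correctness", {
  co <- small_sim(seed = 9, n = 200L)
  bl <- co$baseline
  pm <- build_person_month_table(bl, co$measurements, "death_ltf")
  # person-months equal the summed follow-up lengths
  exit_m <- pmin(bl$death_ltf_month, bl$admin_censor_month, na.rm = TRUE)
  expect_equal(nrow(pm), sum(exit_m - bl$entry_month + 1L))
  # person-years from the table vs from entry/exit dates, within 1/12 py per
  # patient (identical here by construction of the monthly grid)
  expect_lt(abs(person_years(pm) - sum(exit_m - bl$entry_month + 1L) / 12),
            nrow(bl) / 12)
  # shuffled measurement order yields the identical table
  set.seed(3)
  mm_shuf <- co$measurements[sample(.N)]
  pm2 <- build_person_month_table(bl, mm_shuf, "death_ltf")
  data.table::setorder(pm, patient_id, t)
  data.table::setorder(pm2, patient_id, t)
  expect_identical(as.data.frame(pm), as.data.frame(pm2))
  # rebound table: no rows beyond an LTF month
  pr <- build_person_month_table(bl, co$measurements, "rebound")
  joined <- merge(pr[, .(last_t = max(t)), by = patient_id],
                  bl[, .(patient_id, entry_month, death_ltf_month)],
                  by = "patient_id")
  has_ltf <- !is.na(joined$death_ltf_month)
  expect_true(all(joined$last_t[has_ltf] <=
                    (joined$death_ltf_month - joined$entry_month)[has_ltf]))
})

test_that("cohort CSV round-trip preserves the tables", {
  co <- small_sim(seed = 5, n = 60L)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(file.path(d, "baseline.csv"),
                      file.path(d, "measurements.csv"))
  expect_equal(as.data.frame(back$baseline), as.data.frame(co$baseline))
  pm1 <- build_person_month_table(co$baseline, co$measurements, "death_ltf")
  pm2 <- build_person_month_table(back$baseline, back$measurements, "death_ltf")
  expect_equal(as.data.frame(pm1), as.data.frame(pm2))
})
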