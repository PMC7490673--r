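# Synthetic cohort generator: determinism, calendar labeling, signature
# injection, missingness, effect-size recovery.

test_that("identical config + seed gives identical output", {
  cfg <- cohort_config(n_participants = 2, days_per_participant = 40,
                       days_jitter_sd = 0, relapse_fraction = 0.5,
                       type2_missing_rate = 0.2, type1_missing_rate = 0.05,
                       seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$calendar, b$calendar)
})

test_that("event streams respect the study window and sleep uniqueness", {
  co <- small_cohort()
  ev <- merge(co$events, co$windows, by = "participant_id")
  d <- as.Date(ev$timestamp)
  expect_true(all(d >= ev$start_date & d <= ev$end_date))
  expect_true(all(co$events$duration >= 0, na.rm = TRUE))
  sl <- co$events[channel == "sleep"]
  expect_false(anyDuplicated(sl[, .(participant_id, date = as.Date(timestamp))]) > 0)
})

test_that("day labels partition the window consistently with relapse dates", {
  co <- small_cohort()
  dl <- co$calendar$day_labels
  expect_true(all(dl$label %in% c("DRH", "NR30", "relapse")))
  # NR30 iff 1 <= relapse_date - d <= 30 for some relapse of the participant
  rel <- co$calendar$relapses
  for (r in seq_len(nrow(rel))) {
    pid <- rel$participant_id[r]
    rd <- rel$relapse_date[r]
    sub <- dl[participant_id == pid]
    inwin <- sub$date >= rd - 30 & sub$date < rd
    expect_true(all(sub$label[inwin] %in% c("NR30", "relapse")))
    expect_identical(sub$label[sub$date == rd], "relapse")
  }
  # nonrelapse participants are all DRH
  nonrel <- setdiff(unique(dl$participant_id), rel$participant_id)
  expect_true(all(dl[participant_id %in% nonrel, label] == "DRH"))
})

test_that("empty signature is the identity and unknown features are rejected", {
  co <- small_cohort()
  out <- inject_relapse_signature(co$events, co$calendar, list(), seed = 5)
  expect_identical(as.data.frame(out), as.data.frame(co$events))
  expect_error(
    inject_relapse_signature(co$events, co$calendar,
                             list(bogus_feature = list(value = 2)),
                             seed = 5),
    "unknown signature feature.*valid features")
})

test_that("multiplicative 0 with full ramp annihilates NR30 conversations", {
  co <- small_cohort()
  sig <- list(n_conversations = list(kind = "multiplicative", value = 0,
                                     ramp_days = 1))
  out <- inject_relapse_signature(co$events, co$calendar, sig, seed = 5)
  nr <- co$calendar$day_labels[label == "NR30"]
  key_nr <- paste(nr$participant_id, nr$date)
  conv <- out[channel == "conversation"]
  expect_false(any(paste(conv$participant_id, as.Date(conv$timestamp))
                   %in% key_nr))
  # DRH days untouched
  drh <- co$calendar$day_labels[label == "DRH"]
  key_drh <- paste(drh$participant_id, drh$date)
  n_before <- sum(paste(co$events$participant_id,
                        as.Date(co$events$timestamp)) %in% key_drh &
                    co$events$channel == "conversation")
  n_after <- sum(paste(out$participant_id, as.Date(out$timestamp))
                 %in% key_drh & out$channel == "conversation")
  expect_equal(n_after, n_before)
})

test_that("additive sleep-onset shift moves the NR30 mean by the stated hours", {
  cfg <- cohort_config(n_participants = 4, days_per_participant = 90,
                       days_jitter_sd = 0, relapse_fraction = 1,
                       type2_missing_rate = 0, type1_missing_rate = 0,
                       seed = 31)
  co <- generate_cohort(cfg)
  sig <- list(sleep_onset = list(kind = "additive", value = 2, ramp_days = 1))
  out <- inject_relapse_signature(co$events, co$calendar, sig,
                                  nr30_len = 30, seed = 6)
  sl <- out[channel == "sleep"]
  sl[, date := as.Date(timestamp)]
  dl <- co$calendar$day_labels
  sl <- merge(sl, dl, by = c("participant_id", "date"))
  gap <- sl[label == "NR30", mean(onset)] - sl[label == "DRH", mean(onset)]
  expect_equal(gap, 2, tolerance = 0.2)
})

test_that("missingness: identity at zero rates, counting at 0.25", {
  co <- small_cohort()
  base <- generate_cohort(cohort_config(n_participants = 2,
                                        days_per_participant = 50,
                                        days_jitter_sd = 0,
                                        relapse_fraction = 0,
                                        type2_missing_rate = 0,
                                        type1_missing_rate = 0, seed = 8))
  m0 <- apply_missingness(base$events, 0, 0, seed = 1)
  expect_identical(as.data.frame(m0$events), as.data.frame(base$events))
  m25 <- apply_missingness(base$events, 0.25, 0, seed = 1,
                           windows = base$windows)
  total_hours <- sum(as.integer(base$windows$end_date -
                                  base$windows$start_date) + 1L) * 24
  frac <- nrow(m25$removed$type2) / total_hours
  # binomial SD at this cell count is ~0.009; allow 3 SDs
  expect_equal(frac, 0.25, tolerance = 0.027 / 0.25)
  # removed hours really have no non-sleep events left
  ev <- m25$events
  key_left <- paste(ev$participant_id, as.Date(ev$timestamp),
                    as.integer(format(ev$timestamp, "%H")))
  key_gone <- paste(m25$removed$type2$participant_id,
                    m25$removed$type2$date, m25$removed$type2$hour)
  expect_false(any(key_left[ev$channel != "sleep"] %in% key_gone))
})

test_that("type2_rate = 1 makes every hour fully missing downstream", {
  base <- generate_cohort(cohort_config(n_participants = 1,
                                        days_per_participant = 5,
                                        days_jitter_sd = 0,
                                        relapse_fraction = 0,
                                        type2_missing_rate = 0,
                                        type1_missing_rate = 0, seed = 9))
  m1 <- apply_missingness(base$events, 1, 0, seed = 2, windows = base$windows)
  expect_true(all(m1$events$channel == "sleep"))
  fm <- extract_hourly_features(m1$events, windows = base$windows)
  mm <- as.matrix(fm$mask[, sw_imputable_features(), with = FALSE])
  expect_true(all(rowSums(mm) == 0))
})

test_that("injected sleep-duration shift is recovered as Cohen's d and is monotone", {
  d_for_shift <- function(shift, seed) {
    cfg <- cohort_config(n_participants = 6, days_per_participant = 80,
                         days_jitter_sd = 0, relapse_fraction = 1,
                         type2_missing_rate = 0, type1_missing_rate = 0,
                         signature = list(sleep_duration = list(
                           kind = "additive", value = shift, unit = "sd",
                           ramp_days = 1)),
                         seed = seed)
    co <- generate_cohort(cfg)
    sl <- co$events[channel == "sleep"]
    sl[, date := as.Date(timestamp)]
    sl <- merge(sl, co$calendar$day_labels, by = c("participant_id", "date"))
    ds <- sl[, .(d = cohens_d(sleep_h[label == "NR30"],
                              sleep_h[label == "DRH"])),
             by = participant_id]
    mean(ds$d)
  }
  d15 <- d_for_shift(1.5, 21)
  expect_equal(d15, 1.5, tolerance = 0.3)
  d05 <- d_for_shift(0.5, 22)
  d10 <- d_for_shift(1.0, 22)
  d20 <- d_for_shift(2.0, 22)
  expect_true(d05 < d10 && d10 < d20)
})
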