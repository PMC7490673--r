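# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# Small cohort without injected signature: 4 participants, 70 days.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- cohort_config(n_participants = 4, days_per_participant = 70,
                         days_jitter_sd = 0, relapse_fraction = 0.25,
                         type2_missing_rate = 0.2, type1_missing_rate = 0.05,
                         seed = 42)
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

small_prep <- function() {
  if (is.null(.fixture_env$small_prep)) {
    .fixture_env$small_prep <-
      suppressMessages(prepare_cohort_features(small_cohort()))
  }
  .fixture_env$small_prep
}

# A tiny single-participant event log with hand-placed events, for
# exact featurization assertions.
tiny_events <- function() {
  ts <- function(s) as.POSIXct(s, tz = "UTC")
  rbind(
    data.table::data.table(
      participant_id = "T1", channel = "call",
      timestamp = c(ts("2020-01-06 10:10:00"), ts("2020-01-06 10:40:00"),
                    ts("2020-01-06 11:15:00")),
      subtype = c("outgoing", "outgoing", "missed"),
      duration = c(60, 30, 0)),
    data.table::data.table(
      participant_id = "T1", channel = "text",
      timestamp = c(ts("2020-01-06 10:05:00"), ts("2020-01-06 10:06:00")),
      subtype = c("sent", "received"), duration = 0),
    data.table::data.table(
      participant_id = "T1", channel = "acceleration",
      timestamp = c(ts("2020-01-06 10:30:00"), ts("2020-01-06 10:31:00")),
      subtype = NA_character_, duration = 0)[
        , `:=`(ax = c(3, 0), ay = c(4, 0), az = c(0, 5))],
    fill = TRUE)
}

# Standardized day-label table for split tests: one relapser (R1, 90
# days, relapse on day 61), one nonrelapser (N1, 60 days).
split_fixture <- function() {
  start <- as.Date("2020-01-01")
  rel_date <- start + 60
  dl <- rbind(
    data.table::data.table(participant_id = "R1", date = start + 0:89),
    data.table::data.table(participant_id = "N1", date = start + 0:59))
  dl[, label := "DRH"]
  dl[participant_id == "R1" & date >= rel_date - 30 & date < rel_date,
     label := "NR30"]
  dl[participant_id == "R1" & date == rel_date, label := "relapse"]
  list(day_labels = dl,
       relapses = data.table::data.table(participant_id = "R1",
                                         relapse_date = rel_date))
}

expect_same_table <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
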