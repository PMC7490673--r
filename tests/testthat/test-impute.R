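# Two-type imputation: zero-fill, hour-of-day means, location
# carry-forward, fill fraction, idempotence, mean preservation.

test_that("type-1 fills partially observed hours with zeros only", {
  ev <- tiny_events()
  win <- data.table::data.table(participant_id = "T1",
                                start_date = as.Date("2020-01-06"),
                                end_date = as.Date("2020-01-06"))
  fm <- extract_hourly_features(ev, windows = win)
  f1 <- fill_type1(fm)
  h11 <- f1$features[hour == 11]
  expect_equal(h11$n_sent_texts, 0)          # calls observed, texts not
  expect_equal(h11$mean_acceleration, 0)
  # fully missing hour untouched by type-1
  expect_true(is.na(f1$features[hour == 3]$n_sent_texts))
  # fully observed cells unchanged
  expect_equal(f1$features[hour == 10]$n_outgoing_calls, 2)
})

test_that("type-2 fills with hour-of-day means and carries location forward", {
  # constructed fixture: 3 days, every day has an observed 14:00 hour
  # with a known sent-text count except day 3 where 14:00 is type-2
  ts <- function(d, h, m = 30) as.POSIXct(sprintf("2020-01-%02d %02d:%02d:00", d, h, m), tz = "UTC")
  ev <- rbind(
    data.table::data.table(participant_id = "C1", channel = "text",
                           timestamp = c(rep(ts(6, 14), 2), rep(ts(7, 14), 4)),
                           subtype = "sent", duration = 0),
    # gps only on day 6 hour 13, in one place (becomes primary)
    data.table::data.table(participant_id = "C1", channel = "gps",
                           timestamp = ts(6, 13) + seq(0, 3000, 300),
                           subtype = NA_character_, duration = 0)[
      , `:=`(lat = 40, lon = -73)],
    fill = TRUE)
  win <- data.table::data.table(participant_id = "C1",
                                start_date = as.Date("2020-01-06"),
                                end_date = as.Date("2020-01-08"))
  fm <- extract_hourly_features(ev, windows = win)
  imp <- suppressMessages(impute_features(fm))
  f <- imp$features
  # observed 14:00 hours average 3 sent texts -> type-2 14:00 gets 3
  expect_equal(f[date == as.Date("2020-01-08") & hour == 14]$n_sent_texts, 3)
  # type-2 hour after the gps hour: full hour at last recorded place
  h15 <- f[date == as.Date("2020-01-06") & hour == 15]
  expect_equal(h15$time_in_primary, 3600)
  expect_equal(h15$time_in_secondary, 0)
  expect_equal(h15$distance_travelled, 0)
  # fill_fraction = 1 exactly on type-2 hours, < 1 elsewhere
  expect_true(all(f$fill_fraction[imp$type2$type2_flag] == 1))
  expect_true(all(f$fill_fraction[!imp$type2$type2_flag] < 1))
  # no missing values remain
  expect_false(anyNA(f[, sw_imputable_features(), with = FALSE]))
})

test_that("fill_fraction equals the independent imputed-cell count", {
  prep <- small_prep()
  co <- small_cohort()
  pid <- co$windows$participant_id[2]
  fm <- extract_hourly_features(co$events[participant_id == pid],
                                windows = co$windows[2])
  imp <- suppressMessages(impute_features(fm))
  mm <- as.matrix(fm$mask[, sw_imputable_features(), with = FALSE])
  oracle <- rowSums(!mm) / ncol(mm)
  expect_equal(imp$features$fill_fraction, oracle)
  # the fill_fraction column alone reconstructs the type-2 flag
  expect_equal(imp$features$fill_fraction == 1, imp$type2$type2_flag)
})

test_that("imputing an already-dense matrix is the identity", {
  ev <- tiny_events()
  win <- data.table::data.table(participant_id = "T1",
                                start_date = as.Date("2020-01-06"),
                                end_date = as.Date("2020-01-06"))
  fm <- extract_hourly_features(ev, windows = win)
  imp1 <- suppressMessages(impute_features(fm))
  # feed the dense result back through as a fully observed matrix
  fm2 <- fm
  fm2$features <- data.table::copy(imp1$features)
  for (f in sw_imputable_features()) {
    data.table::set(fm2$mask, j = f, value = rep(TRUE, nrow(fm2$mask)))
  }
  imp2 <- impute_features(fm2)
  expect_equal(as.data.frame(imp2$features[, sw_imputable_features(), with = FALSE]),
               as.data.frame(imp1$features[, sw_imputable_features(), with = FALSE]))
  expect_true(all(imp2$features$fill_fraction == 0))
})

test_that("hour-of-day means are preserved for non-location features", {
  co <- small_cohort()
  pid <- co$windows$participant_id[1]
  fm <- extract_hourly_features(co$events[participant_id == pid],
                                windows = co$windows[1])
  imp <- suppressMessages(impute_features(fm))
  mm <- as.matrix(fm$mask[, sw_imputable_features(), with = FALSE])
  type2 <- rowSums(mm) == 0
  f <- imp$features
  for (feat in c("n_sent_texts", "n_conversations", "screen_duration")) {
    obs <- fm$mask[[feat]]
    pre <- fm$features[[feat]]
    for (h in c(9, 15, 20)) {
      sel_obs <- obs & fm$features$hour == h
      sel_t2 <- type2 & f$hour == h
      if (sum(sel_obs) > 0 && sum(sel_t2) > 0) {
        expect_equal(mean(f[[feat]][sel_t2]), mean(pre[sel_obs]),
                     tolerance = 1e-12)
      }
    }
  }
})
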