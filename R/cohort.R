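# Synthetic sensing-cohort simulator: seeded raw event streams with
# circadian structure, participant-level heterogeneity, relapse calendars,
# configurable near-relapse behavioral signatures and two-type missingness.

# Hour-of-day activity multiplier: low overnight, ramping through the
# morning, flat through the day, tapering in the evening.
circadian_activity <- function(hours = 0:23) {
  act <- c(rep(0.05, 6), 0.2, 0.5, 0.8, rep(1, 12), 0.8, 0.5, 0.2)
  act[hours + 1L]
}

# Baseline per-active-hour event rates; each participant gets a
# log-normal random effect on every rate (sdlog = 0.3), so behavioral
# scale genuinely differs across participants and per-participant
# anomaly thresholds are needed downstream.
BASE_RATES <- c(
  incoming_call = 0.10, outgoing_call = 0.10, missed_call = 0.03,
  rejected_call = 0.012, blocked_call = 0.006,
  received_text = 0.50, sent_text = 0.45, draft_text = 0.03,
  outbox_text = 0.02, failed_text = 0.02, queued_text = 0.02,
  conversation = 0.50, screen_unlock = 2.0
)

# Feature names whose signatures the simulator can inject, mapped to the
# injection mechanics used.
injectable_features <- function() {
  c("mean_acceleration", "n_unique_apps",
    paste0("n_", CALL_SUBTYPES, "_calls"),
    c("incoming_call_duration", "outgoing_call_duration"),
    "n_conversations", "conversation_duration",
    "n_screen_unlocks", "screen_duration",
    "sleep_duration", "sleep_onset", "sleep_wake",
    paste0("n_", TEXT_SUBTYPES, "_texts"))
}

#' Configure a synthetic sensing cohort
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults
#' emulate the scale of a year-long outpatient passive-sensing study:
#' roughly 30% of participants relapse, around 300 days of data per
#' participant, a 30-day near-relapse window, and about a quarter of all
#' hours lost to whole-hour (type-2) missingness.
#'
#' @param n_participants Number of participants.
#' @param relapse_fraction Fraction of participants who relapse.
#' @param days_per_participant Mean days of data per participant.
#' @param days_jitter_sd SD of per-participant jitter on the day count.
#' @param relapse_events_prob Probability of 1, 2, 3 relapse events for a
#'   relapsing participant.
#' @param nr30_len Length of the near-relapse window, days.
#' @param signature Named list of behavioral shifts applied during the
#'   near-relapse window; see [inject_relapse_signature()].
#' @param type2_missing_rate Probability an hour loses all channels.
#' @param type1_missing_rate Probability a channel-hour is dropped.
#' @param accel_per_hour,gps_per_hour Raw sampling density per hour.
#' @param start_date First study day (all participants aligned).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class `sw_cohort_config`.
#' @export
cohort_config <- function(n_participants = 12,
                          relapse_fraction = 0.3,
                          days_per_participant = 300,
                          days_jitter_sd = 25,
                          relapse_events_prob = c(0.78, 0.05, 0.17),
                          nr30_len = 30,
                          signature = list(),
                          type2_missing_rate = 0.26,
                          type1_missing_rate = 0.05,
                          accel_per_hour = 12,
                          gps_per_hour = 6,
                          start_date = as.Date("2016-01-04"),
                          seed = 1L) {
  assert_that(n_participants >= 1, "n_participants must be >= 1")
  assert_that(relapse_fraction >= 0 && relapse_fraction <= 1,
              "relapse_fraction must be in [0, 1]")
  assert_that(type2_missing_rate >= 0 && type2_missing_rate <= 1,
              "type2_missing_rate must be in [0, 1]")
  assert_that(type1_missing_rate >= 0 && type1_missing_rate <= 1,
              "type1_missing_rate must be in [0, 1]")
  assert_that(days_per_participant >= 1, "days_per_participant must be >= 1")
  assert_that(nr30_len >= 1, "nr30_len must be >= 1")
  validate_signature(signature)
  if (length(signature) && floor(relapse_fraction * n_participants) < 1) {
    warning("signature supplied but no participant will relapse")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    relapse_fraction = relapse_fraction,
    days_per_participant = days_per_participant,
    days_jitter_sd = days_jitter_sd,
    relapse_events_prob = relapse_events_prob / sum(relapse_events_prob),
    nr30_len = as.integer(nr30_len),
    signature = signature,
    type2_missing_rate = type2_missing_rate,
    type1_missing_rate = type1_missing_rate,
    accel_per_hour = as.integer(accel_per_hour),
    gps_per_hour = as.integer(gps_per_hour),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "sw_cohort_config")
}

validate_signature <- function(signature) {
  if (!length(signature)) return(invisible(TRUE))
  ok <- injectable_features()
  bad <- setdiff(names(signature), ok)
  if (length(bad)) {
    stop("unknown signature feature(s): ", paste(bad, collapse = ", "),
         "; valid features are: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(signature)) {
    sp <- signature[[nm]]
    kind <- sp$kind %||% "multiplicative"
    assert_that(kind %in% c("multiplicative", "additive"),
                sprintf("signature '%s': kind must be multiplicative/additive", nm))
    if (kind == "additive") {
      assert_that(nm %in% c("sleep_duration", "sleep_onset", "sleep_wake"),
                  sprintf("additive shifts only supported for sleep features, not '%s'", nm))
    }
    assert_that(is.numeric(sp$value %||% NA_real_) && is.finite(sp$value),
                sprintf("signature '%s': numeric value required", nm))
  }
  invisible(TRUE)
}

# Per-participant ground-truth behavioral profile.
draw_profiles <- function(config) {
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  lapply(seq_len(n), function(i) {
    re <- rlnorm(length(BASE_RATES), 0, 0.3)
    rates <- BASE_RATES * re
    home <- c(lat = 40.7 + rnorm(1, 0, 0.05), lon = -73.9 + rnorm(1, 0, 0.05))
    # secondary anchor 1-8 km from home
    bearing <- runif(1, 0, 2 * pi)
    dist_deg <- runif(1, 1, 8) / 111.32
    sec <- c(lat = home[["lat"]] + dist_deg * cos(bearing),
             lon = home[["lon"]] + dist_deg * sin(bearing))
    list(
      participant_id = ids[i],
      rates = rates,
      call_dur = c(meanlog = log(150) + rnorm(1, 0, 0.2), sdlog = 0.8),
      conv_dur = c(meanlog = log(300) + rnorm(1, 0, 0.2), sdlog = 0.7),
      screen_dur = c(meanlog = log(180) + rnorm(1, 0, 0.2), sdlog = 0.8),
      accel_base = rlnorm(1, log(1.0), 0.05),
      accel_act = runif(1, 0.2, 0.5),
      n_apps = sample(10:20, 1),
      away_frac = runif(1, 0.3, 0.7),
      home = home, secondary = sec,
      sleep = c(onset_mu = rnorm(1, -0.5, 0.5),   # ~23:30, signed hours
                dur_mu = rnorm(1, 8, 0.5),
                onset_sd = 0.75, dur_sd = 0.75),
      # day-to-day SDs of the daily sleep features, used to interpret
      # signatures stated in SD units
      feature_sd = c(sleep_duration = 0.75, sleep_onset = 0.75,
                     sleep_wake = sqrt(2) * 0.75)
    )
  })
}

# Relapse dates and per-day DRH/NR30 labels.
draw_calendar <- function(config, n_days_by_pid) {
  n <- config$n_participants
  ids <- names(n_days_by_pid)
  n_rel <- floor(config$relapse_fraction * n)
  relapsers <- if (n_rel >= 1) sample(ids, n_rel) else character(0)
  rel_list <- list()
  for (pid in relapsers) {
    nd <- n_days_by_pid[[pid]]
    k <- sample(seq_along(config$relapse_events_prob), 1,
                prob = config$relapse_events_prob)
    # relapse day indices: leave room for a full NR30 window before the
    # first event and keep events >= 45 days apart
    lo <- config$nr30_len + 10
    hi <- nd - 5
    days_idx <- integer(0)
    for (attempt in seq_len(200)) {
      cand <- sort(sample(seq(lo, hi), min(k, max(1, (hi - lo) %/% 45))))
      if (length(cand) < 2 || min(diff(cand)) >= 45) {
        days_idx <- cand
        break
      }
    }
    rel_list[[pid]] <- config$start_date + days_idx - 1L
  }
  relapses <- if (length(rel_list)) {
    data.table(participant_id = rep(names(rel_list),
                                    lengths(rel_list)),
               relapse_date = as.Date(unlist(rel_list, use.names = FALSE),
                                      origin = "1970-01-01"))
  } else {
    data.table(participant_id = character(0), relapse_date = as.Date(character(0)))
  }
  day_labels <- data.table(
    participant_id = rep(ids, unlist(n_days_by_pid)),
    date = as.Date(unlist(lapply(n_days_by_pid, function(nd)
      config$start_date + seq_len(nd) - 1L)), origin = "1970-01-01")
  )
  day_labels[, label := "DRH"]
  if (nrow(relapses)) {
    for (r in seq_len(nrow(relapses))) {
      pid <- relapses$participant_id[r]
      rd <- relapses$relapse_date[r]
      # NR30: 1 <= relapse_date - d <= nr30_len; relapse day itself is
      # excluded from both NR30 and DRH
      day_labels[participant_id == pid &
                   date < rd & date >= rd - config$nr30_len,
                 label := "NR30"]
    }
    for (r in seq_len(nrow(relapses))) {
      day_labels[participant_id == relapses$participant_id[r] &
                   date == relapses$relapse_date[r], label := "relapse"]
    }
  }
  list(relapses = relapses, day_labels = day_labels)
}

# Hour grid for one cohort: participant x date x hour with hour-start
# timestamps and the circadian activity multiplier.
hour_grid <- function(windows) {
  g <- windows[, {
    dts <- seq(start_date, end_date, by = "day")
    CJ(date = dts, hour = 0:23)
  }, by = participant_id]
  g[, t0 := as.POSIXct(paste0(format(date), " ", hour, ":00:00"), tz = "UTC")]
  g[, act := circadian_activity(hour)]
  g[]
}

# Expand Poisson hourly counts into timestamped event rows.
expand_events <- function(grid, counts, channel, subtype = NA_character_,
                          dur_meanlog = NULL, dur_sdlog = NULL) {
  idx <- rep.int(seq_len(nrow(grid)), counts)
  if (!length(idx)) return(NULL)
  ev <- grid[idx, .(participant_id, timestamp = t0 + runif(length(idx), 0, 3599.9))]
  ev[, channel := channel]
  ev[, subtype := subtype]
  if (!is.null(dur_meanlog)) {
    ev[, duration := pmin(rlnorm(.N, dur_meanlog, dur_sdlog), 3500)]
  } else {
    ev[, duration := 0]
  }
  ev
}

# Generate baseline (pre-signature, pre-missingness) events for one
# participant. Returns a data.table in canonical event-log layout.
gen_participant_events <- function(profile, grid, config) {
  out <- list()
  # calls
  for (st in CALL_SUBTYPES) {
    r <- profile$rates[[paste0(st, "_call")]]
    cnt <- rpois(nrow(grid), r * grid$act)
    has_dur <- st %in% c("incoming", "outgoing")
    out[[paste0("call_", st)]] <- expand_events(
      grid, cnt, "call", st,
      if (has_dur) profile$call_dur[["meanlog"]],
      if (has_dur) profile$call_dur[["sdlog"]])
  }
  # texts
  for (st in TEXT_SUBTYPES) {
    r <- profile$rates[[paste0(st, "_text")]]
    cnt <- rpois(nrow(grid), r * grid$act)
    out[[paste0("text_", st)]] <- expand_events(grid, cnt, "text", st)
  }
  # conversations
  cnt <- rpois(nrow(grid), profile$rates[["conversation"]] * grid$act)
  out$conversation <- expand_events(grid, cnt, "conversation", NA_character_,
                                    profile$conv_dur[["meanlog"]],
                                    profile$conv_dur[["sdlog"]])
  # screen sessions
  cnt <- rpois(nrow(grid), profile$rates[["screen_unlock"]] * grid$act)
  out$screen <- expand_events(grid, cnt, "screen", "on",
                              profile$screen_dur[["meanlog"]],
                              profile$screen_dur[["sdlog"]])
  # app polls every 15 min while the participant is active
  poll <- grid[rep(seq_len(nrow(grid)), each = 4)]
  poll[, timestamp := t0 + rep(c(0, 900, 1800, 2700), nrow(grid)) +
         runif(.N, 0, 60)]
  poll <- poll[runif(.N) < act]
  if (nrow(poll)) {
    app_w <- 1 / seq_len(profile$n_apps)
    poll[, app_id := paste0("app", sample.int(profile$n_apps, .N,
                                              replace = TRUE, prob = app_w))]
    out$app <- poll[, .(participant_id, timestamp, channel = "app",
                        subtype = NA_character_, duration = 0, app_id)]
  }
  # acceleration: fixed number of samples per hour, norm set by the
  # circadian activity level, direction uniform on the sphere
  ns <- config$accel_per_hour
  acc <- grid[rep(seq_len(nrow(grid)), each = ns)]
  acc[, timestamp := t0 + runif(.N, 0, 3599.9)]
  norm_mu <- profile$accel_base * (1 + profile$accel_act * acc$act)
  r <- rlnorm(nrow(acc), log(norm_mu), 0.15)
  zc <- runif(nrow(acc), -1, 1)
  phi <- runif(nrow(acc), 0, 2 * pi)
  s <- sqrt(1 - zc^2)
  acc[, `:=`(ax = r * s * cos(phi), ay = r * s * sin(phi), az = r * zc,
             channel = "acceleration", subtype = NA_character_, duration = 0)]
  out$acceleration <- acc[, .(participant_id, timestamp, channel, subtype,
                              duration, ax, ay, az)]
  # gps: hourly anchor state (home overnight, away during the day with a
  # participant-specific propensity), several fixes per hour with jitter
  p_away <- ifelse(grid$hour >= 9 & grid$hour <= 17, profile$away_frac,
                   ifelse(grid$hour >= 7 & grid$hour <= 21,
                          profile$away_frac * 0.4, 0.02))
  u <- runif(nrow(grid))
  state <- ifelse(u < p_away * 0.7, "secondary",
                  ifelse(u < p_away, "other", "home"))
  ng <- config$gps_per_hour
  gps <- grid[rep(seq_len(nrow(grid)), each = ng)]
  gps[, state := rep(state, each = ng)]
  gps[, timestamp := t0 + (rep(seq_len(ng), nrow(grid)) - 0.5) * 3600 / ng]
  base_lat <- ifelse(gps$state == "home", profile$home[["lat"]],
                     profile$secondary[["lat"]])
  base_lon <- ifelse(gps$state == "home", profile$home[["lon"]],
                     profile$secondary[["lon"]])
  oth <- gps$state == "other"
  if (any(oth)) {
    # one transient place 2-10 km from home per hour-long visit
    b_h <- runif(nrow(grid), 0, 2 * pi)
    dd_h <- runif(nrow(grid), 2, 10) / 111.32
    b <- rep(b_h, each = ng)
    dd <- rep(dd_h, each = ng)
    base_lat[oth] <- profile$home[["lat"]] + (dd * cos(b))[oth]
    base_lon[oth] <- profile$home[["lon"]] + (dd * sin(b))[oth]
  }
  gps[, `:=`(lat = base_lat + rnorm(.N, 0, 3e-4),
             lon = base_lon + rnorm(.N, 0, 3e-4),
             channel = "gps", subtype = NA_character_, duration = 0)]
  out$gps <- gps[, .(participant_id, timestamp, channel, subtype, duration,
                     lat, lon)]
  # sleep: one daily record; onset in signed hours around midnight
  sl <- unique(grid[, .(participant_id, date)])
  sl[, onset := rnorm(.N, profile$sleep[["onset_mu"]], profile$sleep[["onset_sd"]])]
  sl[, sleep_h := pmin(pmax(rnorm(.N, profile$sleep[["dur_mu"]],
                                  profile$sleep[["dur_sd"]]), 3), 13)]
  sl[, wake := (onset + sleep_h) %% 24]
  sl[, `:=`(timestamp = as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC"),
            channel = "sleep", subtype = NA_character_, duration = 0)]
  out$sleep <- sl[, .(participant_id, timestamp, channel, subtype, duration,
                      onset, wake, sleep_h)]
  rbindlist(out, fill = TRUE)
}

#' Generate a synthetic sensing cohort
#'
#' Produces seeded raw sensor event streams (acceleration samples, app
#' polls, call/text logs, conversation episodes, GPS fixes, screen
#' sessions, daily sleep estimates), a relapse calendar with DRH/NR30 day
#' labels, and the generator's own ground truth. When the config carries a
#' behavioral signature, it is injected on near-relapse days via
#' [inject_relapse_signature()]; the configured missingness is then
#' applied via [apply_missingness()].
#'
#' @param config An `sw_cohort_config` from [cohort_config()].
#' @return Object of class `sw_cohort`: list with `events` (data.table
#'   event log), `calendar` (`$relapses`, `$day_labels`), `windows`
#'   (study window per participant), `ground_truth` (per-participant
#'   profiles), `removed` (missingness bookkeeping) and `config`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sw_cohort_config"),
              "config must come from cohort_config()")
  with_seed(config$seed, {
    profiles <- draw_profiles(config)
    names(profiles) <- vapply(profiles, `[[`, "", "participant_id")
    nd <- pmax(60L, as.integer(round(rnorm(config$n_participants,
                                           config$days_per_participant,
                                           config$days_jitter_sd))))
    n_days_by_pid <- as.list(setNames(nd, names(profiles)))
    calendar <- draw_calendar(config, n_days_by_pid)
    windows <- data.table(
      participant_id = names(profiles),
      start_date = config$start_date,
      end_date = config$start_date + nd - 1L)
    grid_all <- hour_grid(windows)
    events <- rbindlist(lapply(names(profiles), function(pid) {
      gen_participant_events(profiles[[pid]], grid_all[participant_id == pid],
                             config)
    }), fill = TRUE)
  })
  if (length(config$signature)) {
    events <- inject_relapse_signature(
      events, calendar, config$signature,
      ground_truth = profiles, nr30_len = config$nr30_len,
      seed = derive_seed(config$seed, 101))
  }
  removed <- NULL
  if (config$type2_missing_rate > 0 || config$type1_missing_rate > 0) {
    miss <- apply_missingness(events, config$type2_missing_rate,
                              config$type1_missing_rate,
                              seed = derive_seed(config$seed, 202),
                              windows = windows)
    events <- miss$events
    removed <- miss$removed
  }
  setkey(events, participant_id, timestamp)
  structure(list(events = events, calendar = calendar, windows = windows,
                 ground_truth = profiles, removed = removed, config = config),
            class = "sw_cohort")
}

#' @export
print.sw_cohort <- function(x, ...) {
  cat("Synthetic sensing cohort:", x$config$n_participants, "participants,",
      nrow(x$events), "events,",
      nrow(x$calendar$relapses), "relapse events\n")
  invisible(x)
}

# Ramp weight per near-relapse day: shifts ramp in linearly over
# `ramp_days` at the start of the window (mimicking a gradual prodrome).
nr30_ramp_weights <- function(day_labels, relapses, nr30_len, ramp_days) {
  nr <- day_labels[label == "NR30"]
  if (!nrow(nr)) return(nr[, .(participant_id, date, weight = numeric(0))])
  nr <- merge(nr, relapses, by = "participant_id", allow.cartesian = TRUE)
  nr[, days_to_relapse := as.integer(relapse_date - date)]
  nr <- nr[days_to_relapse >= 1 & days_to_relapse <= nr30_len]
  nr <- nr[, .(days_to_relapse = min(days_to_relapse)), by = .(participant_id, date)]
  nr[, weight := pmin(1, (nr30_len - days_to_relapse + 1) / max(1, ramp_days))]
  nr[, .(participant_id, date, weight)]
}

#' Inject a near-relapse behavioral signature into an event log
#'
#' Shifts the named behavioral features on NR30-labeled days only, with a
#' linear ramp-in over the first days of the window. Count features are
#' shifted multiplicatively by thinning or duplicating events; duration
#' features scale event durations; sleep features support additive shifts
#' in hours (or SD units when ground truth is supplied). DRH days are
#' untouched.
#'
#' @param events Event-log data.table.
#' @param calendar Calendar list with `$day_labels` and `$relapses`
#'   (as produced by [generate_cohort()]).
#' @param signature Named list: each element
#'   `list(kind = "multiplicative"|"additive", value =, unit = "natural"|"sd",
#'   ramp_days = 7)` keyed by feature name.
#' @param ground_truth Optional per-participant profiles; required to
#'   interpret `unit = "sd"`.
#' @param nr30_len Near-relapse window length, days.
#' @param seed Integer seed for the stochastic thinning/duplication.
#' @return Modified event-log data.table.
#' @export
inject_relapse_signature <- function(events, calendar, signature,
                                     ground_truth = NULL, nr30_len = 30,
                                     seed = 1L) {
  validate_signature(signature)
  if (!length(signature)) return(data.table::copy(events))
  events <- data.table::copy(events)
  events[, date := as.Date(timestamp)]
  feat_channel <- feature_injection_map()
  with_seed(seed, {
    for (nm in names(signature)) {
      sp <- signature[[nm]]
      sp$kind <- sp$kind %||% "multiplicative"
      sp$unit <- sp$unit %||% "natural"
      ramp <- sp$ramp_days %||% 7
      wts <- nr30_ramp_weights(calendar$day_labels, calendar$relapses,
                               nr30_len, ramp)
      if (!nrow(wts)) next
      events <- apply_one_shift(events, nm, sp, wts, feat_channel[[nm]],
                                ground_truth)
    }
  })
  events[, date := NULL]
  events[]
}

feature_injection_map <- function() {
  m <- list(
    mean_acceleration = list(channel = "acceleration", mode = "accel"),
    n_unique_apps = list(channel = "app", mode = "count"),
    n_conversations = list(channel = "conversation", mode = "count"),
    conversation_duration = list(channel = "conversation", mode = "duration"),
    n_screen_unlocks = list(channel = "screen", mode = "count"),
    screen_duration = list(channel = "screen", mode = "duration"),
    sleep_duration = list(channel = "sleep", mode = "sleep"),
    sleep_onset = list(channel = "sleep", mode = "sleep"),
    sleep_wake = list(channel = "sleep", mode = "sleep"),
    incoming_call_duration = list(channel = "call", subtype = "incoming",
                                  mode = "duration"),
    outgoing_call_duration = list(channel = "call", subtype = "outgoing",
                                  mode = "duration")
  )
  for (st in CALL_SUBTYPES) {
    m[[paste0("n_", st, "_calls")]] <- list(channel = "call", subtype = st,
                                            mode = "count")
  }
  for (st in TEXT_SUBTYPES) {
    m[[paste0("n_", st, "_texts")]] <- list(channel = "text", subtype = st,
                                            mode = "count")
  }
  m
}

# Fast numeric (participant, date) key for joins over large event logs.
day_key <- function(pid, date, levels) {
  match(pid, levels) * 1e6 + as.numeric(date)
}

apply_one_shift <- function(events, feature, sp, wts, target, ground_truth) {
  sel <- events$channel == target$channel
  if (!is.null(target$subtype)) sel <- sel & events$subtype == target$subtype
  lev <- sort(unique(c(events$participant_id, wts$participant_id)))
  key_ev <- day_key(events$participant_id, events$date, lev)
  key_w <- day_key(wts$participant_id, wts$date, lev)
  w <- wts$weight[match(key_ev, key_w)]
  hit <- sel & !is.na(w)
  if (!any(hit)) return(events)
  w_hit <- w[hit]
  if (target$mode == "sleep") {
    delta <- sp$value
    if (sp$unit == "sd") {
      assert_that(!is.null(ground_truth),
                  "unit='sd' requires generator ground truth")
      sdv <- vapply(events$participant_id[hit], function(pid)
        ground_truth[[pid]]$feature_sd[[feature]], numeric(1))
      delta <- sp$value * sdv
    }
    if (sp$kind == "additive") {
      if (feature == "sleep_onset") {
        events[hit, `:=`(onset = onset + delta * w_hit,
                         wake = (wake + delta * w_hit) %% 24)]
      } else if (feature == "sleep_wake") {
        events[hit, `:=`(wake = (wake + delta * w_hit) %% 24,
                         sleep_h = sleep_h + delta * w_hit)]
      } else {  # sleep_duration
        events[hit, `:=`(sleep_h = sleep_h + delta * w_hit,
                         wake = (wake + delta * w_hit) %% 24)]
      }
    } else {  # multiplicative on duration
      assert_that(feature == "sleep_duration",
                  "multiplicative sleep shifts only for sleep_duration")
      mult <- 1 + w_hit * (sp$value - 1)
      events[hit, `:=`(wake = (wake + sleep_h * (mult - 1)) %% 24,
                       sleep_h = sleep_h * mult)]
    }
    return(events)
  }
  assert_that(sp$kind == "multiplicative",
              sprintf("feature '%s' supports multiplicative shifts only", feature))
  mult_eff <- 1 + w_hit * (sp$value - 1)
  if (target$mode == "duration") {
    events[hit, duration := duration * mult_eff]
    return(events)
  }
  if (target$mode == "accel") {
    events[hit, `:=`(ax = ax * mult_eff, ay = ay * mult_eff,
                     az = az * mult_eff)]
    return(events)
  }
  # count mode: thin below 1, duplicate above 1
  idx <- which(hit)
  keep <- rep(TRUE, nrow(events))
  lo <- mult_eff < 1
  if (any(lo)) keep[idx[lo]] <- runif(sum(lo)) < mult_eff[lo]
  extra_rows <- NULL
  hi <- mult_eff > 1
  if (any(hi)) {
    n_extra <- rpois(sum(hi), mult_eff[hi] - 1)
    src <- rep(idx[hi], n_extra)
    if (length(src)) {
      extra_rows <- events[src]
      # jitter within the same civil hour to preserve hourly structure
      hstart <- as.POSIXct(trunc(extra_rows$timestamp, "hours"))
      extra_rows[, timestamp := hstart + runif(.N, 0, 3599.9)]
    }
  }
  out <- events[keep]
  if (!is.null(extra_rows)) out <- rbind(out, extra_rows)
  out
}

#' Apply two-type missingness to an event log
#'
#' Type-2 missingness removes whole participant-hours across every sensor
#' channel; type-1 removes individual channel-hours. Daily sleep records
#' are exempt from removal: their hourly observability downstream follows
#' device activity, so a type-2 hour still presents as fully missing.
#'
#' @param events Event-log data.table.
#' @param type2_rate Probability an hour is dropped entirely.
#' @param type1_rate Probability a remaining channel-hour is dropped.
#' @param seed Integer seed.
#' @param windows Optional study windows (participant_id, start_date,
#'   end_date); defaults to the observed event range per participant.
#' @return List: `events` (thinned log) and `removed` with bookkeeping
#'   tables `$type2` (participant, date, hour) and `$type1`
#'   (participant, date, hour, channel).
#' @export
apply_missingness <- function(events, type2_rate, type1_rate, seed = 1L,
                              windows = NULL) {
  assert_that(type2_rate >= 0 && type2_rate <= 1, "type2_rate in [0,1]")
  assert_that(type1_rate >= 0 && type1_rate <= 1, "type1_rate in [0,1]")
  if (type2_rate == 0 && type1_rate == 0) {
    return(list(events = data.table::copy(events),
                removed = list(type2 = NULL, type1 = NULL)))
  }
  if (is.null(windows)) {
    windows <- events[, .(start_date = as.Date(min(timestamp)),
                          end_date = as.Date(max(timestamp))),
                      by = participant_id]
  }
  grid <- windows[, CJ(date = seq(start_date, end_date, by = "day"),
                       hour = 0:23), by = participant_id]
  with_seed(seed, {
    grid[, drop2 := runif(.N) < type2_rate]
    t2 <- grid[drop2 == TRUE, .(participant_id, date, hour)]
    # type-1: channel-hours among hours that survive type-2
    chans <- setdiff(SENSOR_CHANNELS, "sleep")
    g1 <- grid[drop2 == FALSE, CJ(channel = chans), by = .(participant_id, date, hour)]
    g1 <- g1[runif(.N) < type1_rate]
  })
  ev <- data.table::copy(events)
  tsn <- as.numeric(ev$timestamp)
  ev_date <- as.Date(floor(tsn / 86400), origin = "1970-01-01")
  ev_hour <- (floor(tsn / 3600)) %% 24
  exempt <- ev$channel == "sleep"
  lev <- sort(unique(ev$participant_id))
  hkey <- function(pid, date, hour) {
    match(pid, lev) * 1e8 + as.numeric(date) * 24 + hour
  }
  key_ev <- hkey(ev$participant_id, ev_date, ev_hour)
  drop <- key_ev %in% hkey(t2$participant_id, t2$date, t2$hour) & !exempt
  if (nrow(g1)) {
    clev <- SENSOR_CHANNELS
    key_ev1 <- key_ev * 10 + match(ev$channel, clev)
    key_g1 <- hkey(g1$participant_id, g1$date, g1$hour) * 10 +
      match(g1$channel, clev)
    drop <- drop | (key_ev1 %in% key_g1 & !exempt)
  }
  ev <- ev[!drop]
  list(events = ev[],
       removed = list(type2 = t2,
                      type1 = g1[, .(participant_id, date, hour, channel)]))
}
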