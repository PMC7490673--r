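# Hourly featurization of raw event streams: channel aggregation,
# significant-place dwell/mobility features, daily sleep replication,
# and the per-feature observed mask that drives imputation.

#' Mean hourly acceleration
#'
#' Mean of the Euclidean norms of 3-axis acceleration samples within an
#' hour. An empty sample set yields `NA` (a missing marker for the
#' imputation stage), never zero.
#'
#' @param samples Matrix or data.frame with columns for the x, y, z
#'   components (first three columns are used), in g.
#' @return Mean vector norm in g, or `NA_real_` for no samples.
#' @export
mean_hourly_acceleration <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) return(NA_real_)
  mean(sqrt(rowSums(samples[, 1:3, drop = FALSE]^2)))
}

# Last-observation-carried-forward for an atomic vector.
locf <- function(v) {
  idx <- seq_along(v)
  idx[is.na(v)] <- 0L
  idx <- cummax(idx)
  out <- v[pmax(idx, 1L)]
  out[idx == 0L] <- v[NA_integer_]
  out
}

#' Hourly dwell and mobility features from labeled GPS fixes
#'
#' Dwell convention: the interval between consecutive fixes is attributed
#' to the earlier fix's place; leading/trailing partial intervals extend
#' to the hour boundaries. A single fix claims the whole hour. Distance
#' is the sum of haversine distances over consecutive fix pairs inside
#' the hour.
#'
#' @param fixes data.frame/data.table with `timestamp` (POSIXct) and
#'   `place` (factor/character: primary/secondary/other), time-ordered,
#'   all within one hour.
#' @param hour_start POSIXct start of the hour.
#' @return List with `dwell` (named seconds for primary/secondary/other)
#'   and `distance_km`.
#' @export
hourly_location_features <- function(fixes, hour_start) {
  fixes <- data.table::as.data.table(fixes)
  dw <- c(primary = 0, secondary = 0, other = 0)
  if (nrow(fixes) == 0) {
    return(list(dwell = dw, distance_km = NA_real_))
  }
  hour_end <- hour_start + 3600
  ts <- as.numeric(fixes$timestamp)
  pl <- as.character(fixes$place)
  nxt <- c(ts[-1], as.numeric(hour_end))
  seg <- nxt - ts
  seg[1] <- seg[1] + (ts[1] - as.numeric(hour_start))  # leading interval
  for (p in names(dw)) dw[p] <- sum(seg[pl == p])
  dist <- 0
  if (nrow(fixes) >= 2 && all(c("lat", "lon") %in% names(fixes))) {
    n <- nrow(fixes)
    dist <- sum(haversine_distance(fixes$lat[-n], fixes$lon[-n],
                                   fixes$lat[-1], fixes$lon[-1]))
  }
  list(dwell = dw, distance_km = dist)
}

# Vectorized dwell/distance for all hours of one participant.
gps_hour_features <- function(fx) {
  # fx: timestamp, lat, lon, place (sorted by time)
  fx <- fx[order(timestamp)]
  tsn0 <- as.numeric(fx$timestamp)
  fx[, t0h := as.POSIXct(floor(tsn0 / 3600) * 3600, tz = "UTC",
                         origin = "1970-01-01")]
  fx[, `:=`(date = as.Date(floor(tsn0 / 86400), origin = "1970-01-01"),
            hour = as.integer(floor(tsn0 / 3600) %% 24))]
  tn <- as.numeric(fx$timestamp)
  hend <- as.numeric(fx$t0h) + 3600
  nxt <- c(tn[-1], Inf)
  same_hour <- nxt <= hend & c(fx$t0h[-1] == fx$t0h[-nrow(fx)], FALSE)
  fx[, dwell := ifelse(same_hour, nxt - tn, hend - tn)]
  first_in_hour <- !duplicated(fx[, .(date, hour)])
  lead_secs <- tn - as.numeric(fx$t0h)   # offset of the fix into its hour
  fx[, dwell := dwell + first_in_hour * lead_secs]
  dw <- dcast(fx[, .(s = sum(dwell)), by = .(date, hour, place)],
              date + hour ~ place, value.var = "s", fill = 0, drop = FALSE)
  for (p in c("primary", "secondary", "other")) {
    if (!p %in% names(dw)) dw[, (p) := 0]
  }
  setnames(dw, c("primary", "secondary", "other"),
           LOCATION_DWELL_FEATURES)
  # distances over consecutive pairs within the hour
  n <- nrow(fx)
  dvec <- rep(0, n)
  if (n >= 2) {
    step <- haversine_distance(fx$lat[-n], fx$lon[-n], fx$lat[-1], fx$lon[-1])
    dvec[-n] <- ifelse(same_hour[-n], step, 0)
  }
  fx[, stepd := dvec]
  dist <- fx[, .(distance_travelled = sum(stepd)), by = .(date, hour)]
  # last known place per hour for the type-2 carry-forward rule
  lastp <- fx[, .(loc_carry = as.character(place)[.N]), by = .(date, hour)]
  merge(merge(dw, dist, by = c("date", "hour")), lastp,
        by = c("date", "hour"))
}

#' Extract the hourly feature matrix from a raw event log
#'
#' Builds one row per participant-hour of the study window with the
#' canonical features ([sw_feature_names()]) and a per-feature observed
#' mask. A feature is observed in an hour iff its sensing channel
#' produced at least one event in that hour; daily sleep estimates are
#' replicated across all 24 hours of their day but count as observed only
#' in hours with device activity, so an hour with no sensor readings at
#' all presents as fully missing (a type-2 candidate). Imputation is
#' deferred to [fill_type1()]/[fill_type2()].
#'
#' @param events Event-log data.table (one or more participants).
#' @param windows Optional study windows (participant_id, start_date,
#'   end_date); defaults to each participant's observed event range.
#' @param eps_km,min_samples DBSCAN parameters for significant-place
#'   clustering.
#' @return Object of class `sw_feature_matrix`: list with `features`
#'   (data.table: participant_id, date, hour, all features), `mask`
#'   (parallel logical data.table over imputable features), `meta`
#'   (per-hour carried location cluster) and `clustering` (per
#'   participant).
#' @export
extract_hourly_features <- function(events, windows = NULL, eps_km = 1,
                                    min_samples = 10) {
  ev <- data.table::as.data.table(events)
  assert_that(nrow(ev) > 0, "empty event log")
  ev <- data.table::copy(ev)
  # payload columns may be absent when a channel never fired
  for (col in c("subtype", "app_id")) {
    if (!col %in% names(ev)) ev[, (col) := NA_character_]
  }
  for (col in c("duration", "ax", "ay", "az", "lat", "lon",
                "onset", "wake", "sleep_h")) {
    if (!col %in% names(ev)) ev[, (col) := NA_real_]
  }
  tsn <- as.numeric(ev$timestamp)   # UTC civil time by construction
  ev[, `:=`(date = as.Date(floor(tsn / 86400), origin = "1970-01-01"),
            hour = as.integer(floor(tsn / 3600) %% 24))]
  if (is.null(windows)) {
    windows <- ev[, .(start_date = min(date), end_date = max(date)),
                  by = participant_id]
  }
  # drop (and log) events outside the study window
  ev <- merge(ev, windows, by = "participant_id")
  outside <- ev$date < ev$start_date | ev$date > ev$end_date
  if (any(outside)) {
    message(sum(outside), " events outside the study window dropped")
    ev <- ev[!outside]
  }
  ev[, c("start_date", "end_date") := NULL]
  grid <- windows[, CJ(date = seq(start_date, end_date, by = "day"),
                       hour = 0:23), by = participant_id]
  setkey(grid, participant_id, date, hour)

  by3 <- c("participant_id", "date", "hour")
  agg <- list()
  acc <- ev[channel == "acceleration",
            .(mean_acceleration = mean(sqrt(ax^2 + ay^2 + az^2))), by = by3]
  app <- ev[channel == "app", .(n_unique_apps = uniqueN(app_id)), by = by3]
  calls <- ev[channel == "call",
              .(n = .N, dur = pmin(sum(duration), 3600)),
              by = c(by3, "subtype")]
  texts <- ev[channel == "text", .(n = .N), by = c(by3, "subtype")]
  conv <- ev[channel == "conversation",
             .(n_conversations = .N,
               conversation_duration = pmin(sum(duration), 3600)), by = by3]
  scr <- ev[channel == "screen",
            .(n_screen_unlocks = .N,
              screen_duration = pmin(sum(duration), 3600)), by = by3]

  fm <- data.table::copy(grid)
  merge_in <- function(fm, x) {
    if (nrow(x)) merge(fm, x, by = by3, all.x = TRUE) else fm
  }
  fm <- merge_in(fm, acc)
  fm <- merge_in(fm, app)
  fm <- merge_in(fm, conv)
  fm <- merge_in(fm, scr)
  if (nrow(calls)) {
    cw <- dcast(calls, participant_id + date + hour ~ subtype,
                value.var = c("n", "dur"), fill = 0)
    for (st in CALL_SUBTYPES) {
      ncol_ <- paste0("n_", st)
      dcol_ <- paste0("dur_", st)
      if (!ncol_ %in% names(cw)) cw[, (ncol_) := 0]
      if (!dcol_ %in% names(cw)) cw[, (dcol_) := 0]
    }
    setnames(cw, paste0("n_", CALL_SUBTYPES),
             paste0("n_", CALL_SUBTYPES, "_calls"))
    setnames(cw, paste0("dur_", CALL_SUBTYPES),
             paste0(CALL_SUBTYPES, "_call_duration"))
    fm <- merge(fm, cw, by = by3, all.x = TRUE)
  }
  if (nrow(texts)) {
    tw <- dcast(texts, participant_id + date + hour ~ subtype,
                value.var = "n", fill = 0)
    for (st in TEXT_SUBTYPES) if (!st %in% names(tw)) tw[, (st) := 0]
    setnames(tw, TEXT_SUBTYPES, paste0("n_", TEXT_SUBTYPES, "_texts"))
    fm <- merge(fm, tw, by = by3, all.x = TRUE)
  }

  # location features per participant
  data.table::setDT(fm)
  gps <- ev[channel == "gps"]
  clusterings <- list()
  if (nrow(gps)) {
    loc <- rbindlist(lapply(split(gps, gps$participant_id), function(fx) {
      cl <- cluster_locations(fx[, .(lat, lon)], eps_km = eps_km,
                              min_samples = min_samples)
      clusterings[[fx$participant_id[1]]] <<- cl
      fx[, place := cl$place]
      g <- gps_hour_features(fx[, .(timestamp, lat, lon, place)])
      g[, participant_id := fx$participant_id[1]]
      g
    }), fill = TRUE)
    fm <- merge(fm, loc, by = by3, all.x = TRUE)
  } else {
    fm[, (LOCATION_DWELL_FEATURES) := NA_real_]
    fm[, distance_travelled := NA_real_]
    fm[, loc_carry := NA_character_]
  }

  # sleep: replicate the daily record across the day's 24 hours
  sl <- ev[channel == "sleep",
           .(sleep_duration = sleep_h[1], sleep_onset = onset[1],
             sleep_wake = wake[1]), by = .(participant_id, date)]
  if (nrow(sl)) {
    fm <- merge(fm, sl, by = c("participant_id", "date"), all.x = TRUE)
  } else {
    fm[, `:=`(sleep_duration = NA_real_, sleep_onset = NA_real_,
              sleep_wake = NA_real_)]
  }

  # per-channel observedness: any event of the channel in the hour;
  # sleep observed in an hour iff the day has a record AND the hour has
  # any device activity
  obs_ch <- unique(ev[channel != "sleep",
                      c(by3, "channel"), with = FALSE])
  obs_ch[, observed := TRUE]
  obsw <- dcast(obs_ch, participant_id + date + hour ~ channel,
                value.var = "observed", fill = FALSE)
  fm <- merge(fm, obsw, by = by3, all.x = TRUE)
  data.table::setDT(fm)
  active <- rep(FALSE, nrow(fm))
  for (ch in setdiff(SENSOR_CHANNELS, "sleep")) {
    v <- if (ch %in% names(fm)) fm[[ch]] else rep(FALSE, nrow(fm))
    v[is.na(v)] <- FALSE
    data.table::set(fm, j = ch, value = v)
    active <- active | v
  }
  sleep_obs <- !is.na(fm$sleep_duration) & active

  # assemble the mask over imputable features
  cmap <- channel_feature_map()
  mask <- fm[, c(by3), with = FALSE]
  for (ch in setdiff(SENSOR_CHANNELS, "sleep")) {
    for (f in cmap[[ch]]) mask[, (f) := fm[[ch]]]
  }
  for (f in cmap$sleep) mask[, (f) := sleep_obs]

  # carried location: last fix's place at or before the hour, forward
  setkey(fm, participant_id, date, hour)
  setkey(mask, participant_id, date, hour)
  fm[, loc_carry := locf(loc_carry), by = participant_id]
  meta <- fm[, c(by3, "loc_carry"), with = FALSE]

  # calendar context + placeholder fill_fraction
  fm[, day_of_week := as.integer(format(date, "%w"))]
  fm[, hour_of_day := hour]
  fm[, fill_fraction := NA_real_]

  keep_cols <- c(by3, sw_feature_names())
  for (f in sw_feature_names()) if (!f %in% names(fm)) fm[, (f) := NA_real_]
  feats <- fm[, keep_cols, with = FALSE]
  # unobserved features are NA at this stage
  for (f in sw_imputable_features()) {
    v <- feats[[f]]
    v[!mask[[f]]] <- NA_real_
    v[mask[[f]] & is.na(v)] <- 0  # observed channel, zero activity
    data.table::set(feats, j = f, value = v)
  }
  structure(list(features = feats, mask = mask, meta = meta,
                 clustering = clusterings),
            class = "sw_feature_matrix")
}

#' @export
print.sw_feature_matrix <- function(x, ...) {
  cat("Hourly feature matrix:", nrow(x$features), "participant-hours,",
      length(sw_feature_names()), "features\n")
  invisible(x)
}
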