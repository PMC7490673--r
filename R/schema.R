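# Hourly feature schema shared by the simulator, featurizer, imputer and
# models. Order is the canonical column order of the feature matrix.

CALL_SUBTYPES <- c("incoming", "outgoing", "missed", "rejected", "blocked")
TEXT_SUBTYPES <- c("received", "sent", "draft", "outbox", "failed", "queued")
SENSOR_CHANNELS <- c("acceleration", "app", "call", "text", "screen",
                     "conversation", "gps", "sleep")

#' Canonical hourly feature names
#'
#' Returns the ordered names of the hourly behavioral features: mean
#' acceleration, unique apps, call counts/durations by subtype,
#' conversations, significant-place dwell times and distance travelled,
#' screen use, daily sleep summaries replicated hourly, text counts by
#' subtype, plus the calendar context features (`day_of_week`,
#' `hour_of_day`) and the imputation indicator `fill_fraction`.
#'
#' @return Character vector of feature names.
#' @export
sw_feature_names <- function() {
  c("mean_acceleration",
    "n_unique_apps",
    as.vector(rbind(paste0("n_", CALL_SUBTYPES, "_calls"),
                    paste0(CALL_SUBTYPES, "_call_duration"))),
    "n_conversations", "conversation_duration",
    "time_in_primary", "time_in_secondary", "time_in_other",
    "distance_travelled",
    "n_screen_unlocks", "screen_duration",
    "sleep_duration", "sleep_onset", "sleep_wake",
    paste0("n_", TEXT_SUBTYPES, "_texts"),
    "day_of_week", "hour_of_day", "fill_fraction")
}

#' Imputable hourly features
#'
#' The subset of [sw_feature_names()] that participates in the two-type
#' imputation scheme. Calendar context features and `fill_fraction`
#' itself are always defined and never imputed, so they are excluded
#' from the fill-fraction denominator.
#'
#' @return Character vector of feature names.
#' @export
sw_imputable_features <- function() {
  setdiff(sw_feature_names(), c("day_of_week", "hour_of_day", "fill_fraction"))
}

# Features by sensing channel; used to set per-channel observed masks.
channel_feature_map <- function() {
  list(
    acceleration = "mean_acceleration",
    app = "n_unique_apps",
    call = as.vector(rbind(paste0("n_", CALL_SUBTYPES, "_calls"),
                           paste0(CALL_SUBTYPES, "_call_duration"))),
    text = paste0("n_", TEXT_SUBTYPES, "_texts"),
    screen = c("n_screen_unlocks", "screen_duration"),
    conversation = c("n_conversations", "conversation_duration"),
    gps = c("time_in_primary", "time_in_secondary", "time_in_other",
            "distance_travelled"),
    sleep = c("sleep_duration", "sleep_onset", "sleep_wake")
  )
}

LOCATION_DWELL_FEATURES <- c("time_in_primary", "time_in_secondary",
                             "time_in_other")
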