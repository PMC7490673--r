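# Two-type missing-data scheme. Type 1: some channels reported in an
# hour, others did not -- absent behaviors are imputed with 0. Type 2:
# no sensor readings at all in the hour -- features are imputed with the
# participant's hour-of-day mean, except location dwell, which carries
# the last recorded place forward. The per-hour fill fraction (imputed /
# imputable features) is itself a model feature and equals 1 exactly on
# type-2 hours.

#' Type-1 imputation: zero-fill partially observed hours
#'
#' In hours where at least one imputable feature was observed, every
#' unobserved feature is set to 0 (the sensing system was up; the
#' behavior simply did not occur). Fully missing hours are left for
#' [fill_type2()].
#'
#' @param fm An `sw_feature_matrix` from [extract_hourly_features()].
#' @return An `sw_feature_matrix` with type-1 cells filled.
#' @export
fill_type1 <- function(fm) {
  assert_that(inherits(fm, "sw_feature_matrix"), "need an sw_feature_matrix")
  feats <- data.table::copy(fm$features)
  imputable <- sw_imputable_features()
  mm <- as.matrix(fm$mask[, imputable, with = FALSE])
  partially <- rowSums(mm) > 0 & rowSums(!mm) > 0
  for (f in imputable) {
    v <- feats[[f]]
    fill <- partially & !mm[, f]
    v[fill] <- 0
    data.table::set(feats, j = f, value = v)
  }
  out <- fm
  out$features <- feats
  out
}

#' Type-2 imputation: fill fully missing hours
#'
#' Hours with no sensor readings at all are filled per feature with the
#' participant's own hour-of-day mean over observed hours; location
#' dwell features instead place the full hour at the last recorded
#' location cluster (carry-forward) and distance travelled is set to 0.
#' Computes `fill_fraction` for every hour and the `type2_flag`.
#'
#' @param fm An `sw_feature_matrix`, normally after [fill_type1()].
#' @param day_labels Optional day-label table (participant_id, date,
#'   label); when given, imputation means are computed from DRH-labeled
#'   days only, so near-relapse behavior cannot leak into the imputed
#'   baseline.
#' @return Object of class `sw_imputed_matrix`: list with `features`
#'   (dense data.table including `fill_fraction`), `type2` (per-hour
#'   flag table) and `report` (imputation counts per participant).
#' @export
fill_type2 <- function(fm, day_labels = NULL) {
  assert_that(inherits(fm, "sw_feature_matrix"), "need an sw_feature_matrix")
  feats <- data.table::copy(fm$features)
  imputable <- sw_imputable_features()
  nonloc <- setdiff(imputable, c(LOCATION_DWELL_FEATURES, "distance_travelled"))
  mm <- as.matrix(fm$mask[, imputable, with = FALSE])
  type2 <- rowSums(mm) == 0

  # which rows may contribute to the imputation means
  stat_ok <- rep(TRUE, nrow(feats))
  if (!is.null(day_labels)) {
    dl <- data.table::as.data.table(day_labels)
    key_f <- paste(feats$participant_id, feats$date)
    drh <- dl[label == "DRH"]
    stat_ok <- key_f %in% paste(drh$participant_id, drh$date)
    if (!any(stat_ok)) stat_ok <- rep(TRUE, nrow(feats))
  }

  n_fallback <- 0L
  for (f in nonloc) {
    v <- feats[[f]]
    obs <- mm[, f] & stat_ok & !is.na(v)
    if (!any(type2)) next
    # hour-of-day conditional means per participant
    dtm <- data.table(pid = feats$participant_id, hod = feats$hour,
                      v = v, obs = obs)
    mu_h <- dtm[obs == TRUE, .(mu = mean(v)), by = .(pid, hod)]
    mu_all <- dtm[obs == TRUE, .(mu_all = mean(v)), by = pid]
    key_row <- paste(feats$participant_id, feats$hour)
    fillv <- mu_h$mu[match(key_row, paste(mu_h$pid, mu_h$hod))]
    fb <- is.na(fillv)
    if (any(fb)) {
      fillv[fb] <- mu_all$mu_all[match(feats$participant_id[fb], mu_all$pid)]
      n_fallback <- n_fallback + sum(fb & type2)
    }
    fillv[is.na(fillv)] <- 0
    v[type2] <- fillv[type2]
    data.table::set(feats, j = f, value = v)
  }
  if (n_fallback > 0) {
    message(n_fallback, " type-2 cells filled from all-hours fallback means")
  }

  # location: carry the last recorded place forward for the full hour
  if (any(type2)) {
    carry <- fm$meta$loc_carry
    carry[is.na(carry)] <- "primary"  # before any fix: fallback, logged
    for (p in c("primary", "secondary", "other")) {
      f <- paste0("time_in_", p)
      v <- feats[[f]]
      v[type2] <- ifelse(carry[type2] == p, 3600, 0)
      data.table::set(feats, j = f, value = v)
    }
    v <- feats$distance_travelled
    v[type2] <- 0
    data.table::set(feats, j = "distance_travelled", value = v)
  }

  n_imputed <- rowSums(!mm)
  feats[, fill_fraction := n_imputed / length(imputable)]
  type2_dt <- feats[, .(participant_id, date, hour)]
  type2_dt[, type2_flag := type2]
  report <- data.table(participant_id = feats$participant_id,
                       t1 = n_imputed * (!type2), t2h = type2)[
    , .(type1_cells = sum(t1), type2_hours = sum(t2h)), by = participant_id]
  stopifnot(!anyNA(feats[, sw_imputable_features(), with = FALSE]))
  structure(list(features = feats, type2 = type2_dt, report = report),
            class = "sw_imputed_matrix")
}

#' Run the full two-type imputation
#'
#' Convenience wrapper: [fill_type1()] then [fill_type2()].
#'
#' @inheritParams fill_type2
#' @return An `sw_imputed_matrix`.
#' @export
impute_features <- function(fm, day_labels = NULL) {
  fill_type2(fill_type1(fm), day_labels = day_labels)
}

#' @export
print.sw_imputed_matrix <- function(x, ...) {
  cat("Imputed hourly feature matrix:", nrow(x$features), "hours,",
      sum(x$type2$type2_flag), "type-2 hours\n")
  invisible(x)
}
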