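# End-to-end orchestration: simulate -> featurize -> impute -> split ->
# train -> score -> evaluate -> posthoc, as one seeded experiment.

#' Featurize and impute a cohort
#'
#' @param cohort An `sw_cohort` from [generate_cohort()].
#' @param eps_km,min_samples Significant-place clustering parameters.
#' @return List: `imputed` (`sw_imputed_matrix`), `day_labels`,
#'   `relapse_ids`.
#' @export
prepare_cohort_features <- function(cohort, eps_km = 1, min_samples = 10) {
  fm <- extract_hourly_features(cohort$events, windows = cohort$windows,
                                eps_km = eps_km, min_samples = min_samples)
  imp <- impute_features(fm, day_labels = cohort$calendar$day_labels)
  list(imputed = imp, day_labels = cohort$calendar$day_labels,
       relapse_ids = unique(cohort$calendar$relapses$participant_id))
}

# Matrix of model features for a set of rows of the imputed table.
feature_matrix_rows <- function(feats, rows) {
  as.matrix(feats[rows, sw_feature_names(), with = FALSE])
}

# Hourly scores for a set of hours, handling each architecture's
# reconstruction route and the l-times-predicted filter.
score_hours <- function(model, feats, rows, segment, dist = NULL) {
  X <- feature_matrix_rows(feats, rows)
  if (model$arch == "lof") {
    err <- matrix(reconstruct(model, X), ncol = 1)
    kept <- seq_len(nrow(X))
  } else if (model$arch == "fnn_ad") {
    rc <- reconstruct(model, X)
    err <- reconstruction_errors(rc$x, rc$xhat)
    kept <- seq_len(nrow(X))
  } else {
    rc <- reconstruct(model, X, segment = segment)
    if (!length(rc$start)) {
      return(NULL)
    }
    cons <- consolidate_hour_predictions(rc$xhat, rc$start, model$l, nrow(X))
    Xs <- apply_scaler(X, model$scaler)
    err <- reconstruction_errors(Xs[cons$hours, , drop = FALSE], cons$xhat)
    kept <- cons$hours
  }
  if (is.null(dist)) {
    return(list(err = err, kept = kept))
  }
  list(score = mahalanobis_score(err, dist), kept = kept)
}

#' Run one model configuration over the Monte Carlo design
#'
#' Trains one model on the pooled healthy training set (LOF: one model
#' per relapse participant), fits the Gaussian error model on healthy
#' validation errors, scores every pooled mixed-set hour once, then for
#' each Monte Carlo iteration partitions the mixed pool, learns
#' per-participant thresholds on N_CV and evaluates flags on N_T.
#'
#' @param prep Output of [prepare_cohort_features()].
#' @param arch One of "fnn_ad", "gru_seq2seq", "lof".
#' @param hidden_units Hidden size (neural architectures).
#' @param pct_drh_in_train Percent of relapse-participant DRH routed to
#'   the healthy sets (0, 20, 40, 60, 80).
#' @param mc_iterations Number of Monte Carlo iterations.
#' @param base_seed Integer seed driving splits, training and partitions.
#' @param block_len_days Subsequence block length in days.
#' @param ... Passed to the architecture's training function.
#' @return List: records (per iteration x participant metrics), flags
#'   (per iteration flag table), thresholds, daily (pooled daily
#'   scores), model, splits, config tag.
#' @export
run_config <- function(prep, arch = "fnn_ad", hidden_units = 20,
                       pct_drh_in_train = 80, mc_iterations = 10,
                       base_seed = 1L, block_len_days = 5, ...) {
  feats <- prep$imputed$features
  dl <- prep$day_labels
  blocks <- make_blocks(dl, block_len_days)
  splits <- assign_splits(blocks, prep$relapse_ids, pct_drh_in_train,
                          seed = derive_seed(base_seed, 11))
  days <- day_assignment(splits, dl)
  feats_key <- paste(feats$participant_id, feats$date)
  day_set <- days$set[match(feats_key, paste(days$participant_id, days$date))]
  # block segment id per hour (windows must not straddle blocks/splits)
  bl <- data.table::as.data.table(splits)
  seg_of_day <- bl[, .(participant_id, start_date, end_date, block_id)][
    data.table::as.data.table(dl),
    on = .(participant_id, start_date <= date, end_date >= date),
    .(participant_id = i.participant_id, date = i.date, block_id = x.block_id)]
  seg_id <- paste(feats$participant_id,
                  seg_of_day$block_id[match(feats_key,
                    paste(seg_of_day$participant_id, seg_of_day$date))])

  rows_hr <- which(day_set == "H_R")
  rows_hcv <- which(day_set == "H_CV")
  rows_np <- which(day_set == "N_pool")
  assert_that(length(rows_hr) > 0 && length(rows_hcv) > 0,
              "empty healthy sets; check pct_drh_in_train and cohort size")
  config_tag <- sprintf("%s_h%d_p%d", arch, hidden_units, pct_drh_in_train)

  if (arch == "lof") {
    # per relapse participant
    models <- list()
    daily_list <- list()
    for (pid in prep$relapse_ids) {
      phr <- rows_hr[feats$participant_id[rows_hr] == pid]
      phcv <- rows_hcv[feats$participant_id[rows_hcv] == pid]
      pnp <- rows_np[feats$participant_id[rows_np] == pid]
      if (length(phr) < 12 || length(phcv) < 2 || !length(pnp)) next
      mod <- fit_lof(feature_matrix_rows(feats, phr),
                     feature_matrix_rows(feats, phcv))
      ecv <- score_hours(mod, feats, phcv, NULL)
      dist <- fit_error_distribution(ecv$err)
      sc <- score_hours(mod, feats, pnp, NULL, dist = dist)
      daily_list[[pid]] <- daily_scores(data.table(
        participant_id = pid, date = feats$date[pnp[sc$kept]],
        score = sc$score))
      models[[pid]] <- mod
    }
    daily <- rbindlist(daily_list)
    model <- models
  } else {
    trainer <- if (arch == "fnn_ad") train_fnn_ad else train_gru_seq2seq
    args <- list(feature_matrix_rows(feats, rows_hr),
                 feature_matrix_rows(feats, rows_hcv),
                 hidden_units = hidden_units,
                 seed = derive_seed(base_seed, 22), ...)
    if (arch == "gru_seq2seq") {
      args$segment_r <- seg_id[rows_hr]
      args$segment_cv <- seg_id[rows_hcv]
    }
    model <- do.call(trainer, args)
    ecv <- score_hours(model, feats, rows_hcv, seg_id[rows_hcv])
    dist <- fit_error_distribution(ecv$err)
    sc <- score_hours(model, feats, rows_np, seg_id[rows_np], dist = dist)
    assert_that(!is.null(sc), "no scorable mixed-pool hours")
    daily <- daily_scores(data.table(
      participant_id = feats$participant_id[rows_np[sc$kept]],
      date = feats$date[rows_np[sc$kept]],
      score = sc$score))
  }
  lab_key <- paste(dl$participant_id, dl$date)
  daily[, label := dl$label[match(paste(participant_id, date), lab_key)]]

  records <- list()
  flags_all <- list()
  taus <- list()
  for (it in seq_len(mc_iterations)) {
    part <- suppressWarnings(
      monte_carlo_partition(splits, it, derive_seed(base_seed, 33)))
    dmap <- day_assignment(part, dl)
    dkey <- paste(dmap$participant_id, dmap$date)
    dset <- dmap$set[match(paste(daily$participant_id, daily$date), dkey)]
    ncv <- daily[dset == "N_CV" & label %in% c("NR30", "DRH")]
    nt <- daily[dset == "N_T" & label %in% c("NR30", "DRH")]
    if (!nrow(ncv) || !nrow(nt)) next
    th <- suppressWarnings(learn_threshold(ncv))
    if (!nrow(th)) next
    fl <- flag_anomalies(nt, th)
    flags_all[[it]] <- cbind(fl, iteration = it)
    taus[[it]] <- cbind(th, iteration = it)
    for (pid in unique(fl$participant_id)) {
      d <- fl[participant_id == pid]
      if (!any(d$label == "NR30") || !any(d$label == "DRH")) next
      cm <- confusion_metrics(d$flag, d$label)
      fpr_floor <- 1 / (sum(d$label == "DRH") + 1)
      records[[length(records) + 1]] <- data.table(
        config = config_tag, iteration = it, participant_id = pid,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        tpr = cm$tpr, fpr = cm$fpr,
        ratio = cm$tpr / max(cm$fpr, fpr_floor))
    }
  }
  list(records = rbindlist(records), flags = rbindlist(flags_all),
       thresholds = rbindlist(taus), daily = daily, model = model,
       splits = splits, config = config_tag)
}

#' Run a full experiment sweep
#'
#' Simulates (or accepts) a cohort, runs every configuration in the
#' sweep grid, aggregates the Monte Carlo records, ranks configurations,
#' regresses metrics on data-quality parameters and computes the
#' anomaly-rate timeline for the best configuration.
#'
#' @param cohort_cfg An `sw_cohort_config`, or an already generated
#'   `sw_cohort`.
#' @param archs,hidden_grid,pct_grid Sweep grids.
#' @param mc_iterations Monte Carlo iterations per configuration.
#' @param base_seed Integer seed.
#' @param block_len_days Block length in days.
#' @param out_dir Optional directory; when given, summary CSV/JSON
#'   artifacts and a manifest are written there.
#' @param ... Passed to [run_config()] (and through to the trainers).
#' @return List: summary (ranked config table), records, runs (per
#'   config results), timeline, quality regression (or NULL if fewer
#'   than the required rows), prep.
#' @export
run_experiment <- function(cohort_cfg, archs = "fnn_ad", hidden_grid = 20,
                           pct_grid = 80, mc_iterations = 10, base_seed = 1L,
                           block_len_days = 5, out_dir = NULL, ...) {
  cohort <- if (inherits(cohort_cfg, "sw_cohort")) cohort_cfg else
    generate_cohort(cohort_cfg)
  prep <- prepare_cohort_features(cohort)
  runs <- list()
  for (arch in archs) {
    for (h in hidden_grid) {
      for (p in pct_grid) {
        run <- run_config(prep, arch = arch, hidden_units = h,
                          pct_drh_in_train = p,
                          mc_iterations = mc_iterations,
                          base_seed = base_seed,
                          block_len_days = block_len_days, ...)
        runs[[run$config]] <- run
      }
    }
  }
  records <- rbindlist(lapply(runs, `[[`, "records"))
  agg <- aggregate_monte_carlo(records)
  summary_dt <- agg$config
  if (length(runs) >= 2) {
    rk <- rank_models(records)
    summary_dt <- merge(summary_dt, rk, by = "config")
    setorder(summary_dt, mean_rank)
  }
  best <- runs[[summary_dt$config[1]]]
  timeline <- NULL
  if (nrow(cohort$calendar$relapses) && nrow(best$flags)) {
    fl <- best$flags[, .(flag = any(flag)), by = .(participant_id, date)]
    timeline <- anomaly_rate_timeline(fl, cohort$calendar$relapses)
  }
  quality <- quality_rows(cohort, prep, best)
  qreg <- NULL
  if (!is.null(quality) &&
      nrow(quality) >= 6) {
    qreg <- tryCatch(data_quality_regression(quality),
                     error = function(e) NULL)
  }
  out <- list(summary = summary_dt, records = records, runs = runs,
              timeline = timeline, quality = quality, regression = qreg,
              prep = prep, cohort = cohort)
  if (!is.null(out_dir)) write_experiment(out, out_dir, base_seed)
  out
}

# Per relapse participant data-quality covariates + achieved metrics.
# "Days per NR30 period" counts observed days (>= 1 non-type-2 hour),
# so it can differ from 30 only through data coverage.
quality_rows <- function(cohort, prep, run) {
  if (!nrow(run$records)) return(NULL)
  dl <- cohort$calendar$day_labels
  rel <- cohort$calendar$relapses
  t2 <- prep$imputed$type2
  obs_days <- t2[, .(observed = any(!type2_flag)), by = .(participant_id, date)]
  per <- run$records[, .(sensitivity = median(sensitivity, na.rm = TRUE),
                         specificity = median(specificity, na.rm = TRUE)),
                     by = participant_id]
  ok <- paste(obs_days$participant_id[obs_days$observed],
              obs_days$date[obs_days$observed])
  rows <- list()
  for (pid in per$participant_id) {
    d <- dl[participant_id == pid]
    n_nr <- sum(d$label == "NR30" & paste(pid, d$date) %in% ok)
    n_ev <- sum(rel$participant_id == pid)
    rows[[pid]] <- data.table(
      participant_id = pid,
      days_raw = nrow(d),
      days_per_nr30 = if (n_ev > 0) n_nr / n_ev else 0,
      pct_near_relapse = 100 * n_nr / nrow(d),
      n_relapses = n_ev,
      sensitivity = per$sensitivity[per$participant_id == pid],
      specificity = per$specificity[per$participant_id == pid])
  }
  rbindlist(rows)
}

write_experiment <- function(out, out_dir, base_seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out$summary, file.path(out_dir, "summary.csv"))
  data.table::fwrite(out$records, file.path(out_dir, "records.csv"))
  if (!is.null(out$timeline)) {
    data.table::fwrite(out$timeline, file.path(out_dir, "timeline.csv"))
  }
  if (!is.null(out$regression)) {
    data.table::fwrite(out$regression, file.path(out_dir, "quality_regression.csv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sensewarn")),
    base_seed = base_seed,
    configs = names(out$runs),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
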