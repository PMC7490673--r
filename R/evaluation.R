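# Evaluation: confusion metrics per participant, aggregation over Monte
# Carlo iterations, model ranking by TPR/FPR, regression of metrics on
# data-quality parameters, and the anomaly-rate-vs-days-to-relapse curve.

#' Confusion metrics for daily anomaly flags
#'
#' TPR (= sensitivity) is the fraction of NR30 days flagged; FPR is the
#' fraction of DRH days flagged; specificity = 1 - FPR exactly.
#'
#' @param flag Logical vector of daily anomaly flags.
#' @param label Character vector in {"NR30", "DRH"}, same length.
#' @return Named list: tpr, fpr, sensitivity, specificity, ratio
#'   (TPR/FPR, `Inf` when FPR = 0 and TPR > 0, NaN when both 0).
#' @export
confusion_metrics <- function(flag, label) {
  assert_that(length(flag) == length(label), "flag/label length mismatch")
  nr <- label == "NR30"
  drh <- label == "DRH"
  if (!any(nr)) {
    warning("no NR30 days: sensitivity undefined")
    return(list(tpr = NA_real_, fpr = sum(flag & drh) / sum(drh),
                sensitivity = NA_real_,
                specificity = 1 - sum(flag & drh) / sum(drh),
                ratio = NA_real_))
  }
  tpr <- sum(flag & nr) / sum(nr)
  fpr <- if (any(drh)) sum(flag & drh) / sum(drh) else NA_real_
  list(tpr = tpr, fpr = fpr, sensitivity = tpr, specificity = 1 - fpr,
       ratio = tpr / fpr)
}

#' Aggregate per-iteration metrics over the Monte Carlo design
#'
#' Per participant, metrics are summarized over iterations by the
#' median; the configuration level then reports the median and IQR
#' across participants (the nesting order is a documented choice).
#'
#' @param records data.table with columns config, iteration,
#'   participant_id, sensitivity, specificity.
#' @return List: `participant` (per config x participant medians) and
#'   `config` (median and quartiles across participants).
#' @export
aggregate_monte_carlo <- function(records) {
  rec <- data.table::as.data.table(records)
  assert_that(nrow(rec) >= 1, "no records to aggregate")
  per_part <- rec[, .(sensitivity = median(sensitivity, na.rm = TRUE),
                      specificity = median(specificity, na.rm = TRUE)),
                  by = .(config, participant_id)]
  per_config <- per_part[, {
    qs <- quartiles(sensitivity)
    qp <- quartiles(specificity)
    .(sens_median = qs[2], sens_q1 = qs[1], sens_q3 = qs[3],
      spec_median = qp[2], spec_q1 = qp[1], spec_q3 = qp[3],
      n_participants = .N)
  }, by = config]
  list(participant = per_part[], config = per_config[])
}

#' Rank model configurations by TPR/FPR ratio
#'
#' Within each participant, configurations are ranked by their TPR/FPR
#' ratio (rank 1 = highest ratio; ties get fractional mean ranks); the
#' mean rank across participants is reported per configuration, lowest
#' being best.
#'
#' @param records data.table with columns config, participant_id, ratio.
#' @return data.table: config, mean_rank, ordered best first.
#' @export
rank_models <- function(records) {
  rec <- data.table::as.data.table(records)
  assert_that(length(unique(rec$config)) >= 2, "need at least 2 configs")
  rec <- rec[, .(ratio = median(ratio, na.rm = TRUE)),
             by = .(config, participant_id)]
  rec[, rank_in_part := rank(-ratio, ties.method = "average"),
      by = participant_id]
  out <- rec[, .(mean_rank = mean(rank_in_part)), by = config]
  setorder(out, mean_rank)
  out[]
}

#' Regress detection metrics on data-quality parameters
#'
#' Ordinary least squares of each z-standardized outcome on the
#' z-standardized predictors (so the intercept is ~0 by construction),
#' with 95% CI and p value per coefficient.
#'
#' @param rows data.frame of per-participant rows: predictor columns
#'   plus outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @param predictors Character vector of predictor column names
#'   (defaults to all non-outcome columns that are numeric).
#' @return data.table: outcome, term, beta, ci_lo, ci_hi, p.
#' @export
data_quality_regression <- function(rows,
                                    outcomes = c("sensitivity", "specificity"),
                                    predictors = NULL) {
  rows <- as.data.frame(rows)
  if (is.null(predictors)) {
    num <- names(rows)[vapply(rows, is.numeric, logical(1))]
    # never let one outcome act as a predictor for the other
    predictors <- setdiff(num, c(outcomes, "sensitivity", "specificity",
                                 "tpr", "fpr", "participant_id"))
  }
  assert_that(nrow(rows) >= length(predictors) + 2,
              "need at least #predictors + 2 rows")
  zs <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) return(v * 0)
    (v - mean(v)) / s
  }
  Xz <- as.data.frame(lapply(rows[predictors], zs))
  # collinearity check
  if (length(predictors) > 1) {
    qx <- qr(as.matrix(Xz))
    if (qx$rank < length(predictors)) {
      warning("collinear predictors: design matrix is rank deficient")
    }
  }
  out <- list()
  for (oc in outcomes) {
    df <- cbind(y = zs(rows[[oc]]), Xz)
    fit <- lm(y ~ ., data = df)
    ci <- confint(fit)
    sm <- summary(fit)$coefficients
    terms <- rownames(sm)
    out[[oc]] <- data.table(
      outcome = oc,
      term = sub("^\\(Intercept\\)$", "intercept", terms),
      beta = unname(sm[, 1]),
      ci_lo = unname(ci[terms, 1]),
      ci_hi = unname(ci[terms, 2]),
      p = unname(sm[, 4]))
  }
  rbindlist(out)
}

#' Anomaly rate by days before relapse
#'
#' For each offset k = `window` .. 1 days before a relapse event, the
#' mean daily anomaly flag rate across participant-relapse pairs with
#' coverage at that offset, with a normal-approximation 95% CI. Offsets
#' with no coverage are returned as gaps (NA).
#'
#' @param flags data.table: participant_id, date, flag (logical).
#' @param relapses data.table: participant_id, relapse_date.
#' @param window Days before relapse to cover (default 35).
#' @return data.table: offset_days (window..1), mean_rate, lo, hi, n.
#' @export
anomaly_rate_timeline <- function(flags, relapses, window = 35) {
  fl <- data.table::as.data.table(flags)
  rl <- data.table::as.data.table(relapses)
  assert_that(nrow(rl) >= 1, "need at least one relapse event")
  rows <- list()
  for (k in window:1) {
    vals <- numeric(0)
    for (r in seq_len(nrow(rl))) {
      d <- rl$relapse_date[r] - k
      v <- fl[participant_id == rl$participant_id[r] & date == d, flag]
      if (length(v) == 1) vals <- c(vals, as.numeric(v))
    }
    if (!length(vals)) {
      rows[[length(rows) + 1]] <- data.table(offset_days = k,
                                             mean_rate = NA_real_,
                                             lo = NA_real_, hi = NA_real_,
                                             n = 0L)
    } else {
      mu <- mean(vals)
      se <- if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0
      rows[[length(rows) + 1]] <- data.table(
        offset_days = k, mean_rate = mu,
        lo = max(0, mu - 1.96 * se), hi = min(1, mu + 1.96 * se),
        n = length(vals))
    }
  }
  rbindlist(rows)
}
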