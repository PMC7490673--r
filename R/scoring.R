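# Anomaly scoring: reconstruction error vectors, the l-times-predicted
# filter, the Gaussian error model fitted on healthy validation errors,
# hourly Mahalanobis scores, daily aggregation, and the per-participant
# threshold that maximizes TPR/FPR on the mixed validation set.

#' Elementwise absolute reconstruction error
#'
#' @param x,xhat Aligned numeric vectors or matrices (rows = hours).
#' @return `abs(x - xhat)`, same shape.
#' @export
reconstruction_errors <- function(x, xhat) {
  x <- as.matrix(x)
  xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) {
    stop("x and reconstruction have mismatched dimensions", call. = FALSE)
  }
  abs(x - xhat)
}

#' Consolidate per-window reconstructions into per-hour predictions
#'
#' With stride-1 windows of length `l` over a series of `L` hours, an
#' hour can be predicted up to `l` times. Only hours predicted exactly
#' `l` times are retained; their `l` reconstructions are combined by the
#' arithmetic mean. For `l = 1` this is a pass-through. The decoder
#' emits windows in reverse order: output position `j` of the window
#' starting at hour `s` reconstructs hour `s + l - j`.
#'
#' @param xhat_windows Array (n_windows x l x m) of reconstructions in
#'   decoder (reversed) order, or an (n x m) matrix when `l = 1`.
#' @param start Integer vector of window start rows (into the original
#'   series), same length as the first array dimension.
#' @param l Window length.
#' @param L Series length in hours.
#' @return List: `xhat` matrix (retained hours x m), `hours` retained
#'   row indices, `coverage` full coverage-count vector of length L.
#' @export
consolidate_hour_predictions <- function(xhat_windows, start, l, L) {
  if (l == 1) {
    xh <- if (length(dim(xhat_windows)) == 3) {
      matrix(xhat_windows[, 1, ], nrow = dim(xhat_windows)[1])
    } else {
      as.matrix(xhat_windows)
    }
    cov_cnt <- integer(L)
    cov_cnt[start] <- 1L
    return(list(xhat = xh, hours = start, coverage = cov_cnt))
  }
  nw <- dim(xhat_windows)[1]
  m <- dim(xhat_windows)[3]
  acc <- matrix(0, L, m)
  cov_cnt <- integer(L)
  for (j in seq_len(l)) {
    rows <- start + l - j          # hour reconstructed by output j
    acc[rows, ] <- acc[rows, , drop = FALSE] +
      matrix(xhat_windows[, j, ], nrow = nw)
    cov_cnt[rows] <- cov_cnt[rows] + 1L
  }
  keep <- which(cov_cnt == l)
  list(xhat = acc[keep, , drop = FALSE] / l, hours = keep,
       coverage = cov_cnt)
}

#' Fit the Gaussian model of expected reconstruction error
#'
#' Sample mean and covariance of healthy-validation error vectors, with
#' ridge shrinkage `lambda * I` where `lambda = 1e-6 * trace(Sigma)/m`,
#' raised tenfold until the condition number drops below 1e10, so the
#' covariance is always invertible.
#'
#' @param E Matrix of error vectors (rows = hours, cols = features).
#' @return Object of class `sw_error_dist`: `mu`, `sigma` (regularized),
#'   `chol` factor, `lambda`.
#' @export
fit_error_distribution <- function(E) {
  E <- as.matrix(E)
  assert_that(nrow(E) >= 2, "need at least 2 error vectors")
  m <- ncol(E)
  mu <- colMeans(E)
  S <- cov(E)
  if (nrow(E) <= m) {
    message("fewer error vectors than features + 1; shrinkage is load-bearing")
  }
  lambda <- 1e-6 * sum(diag(S)) / m
  if (lambda <= 0) lambda <- 1e-8
  repeat {
    Sr <- S + diag(lambda, m)
    ev <- eigen(Sr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < 1e10) break
    lambda <- lambda * 10
  }
  structure(list(mu = mu, sigma = Sr, chol = chol(Sr), lambda = lambda),
            class = "sw_error_dist")
}

#' Mahalanobis anomaly score
#'
#' `s = sqrt((e - mu)^T Sigma^{-1} (e - mu))` of an error vector (or
#' rows of a matrix) under the fitted Gaussian error model.
#'
#' @param e Error vector or matrix (rows = hours).
#' @param dist An `sw_error_dist` from [fit_error_distribution()].
#' @return Nonnegative score(s).
#' @export
mahalanobis_score <- function(e, dist) {
  E <- if (is.null(dim(e))) matrix(e, nrow = 1) else as.matrix(e)
  if (!all(is.finite(E))) stop("non-finite error vector", call. = FALSE)
  D <- sweep(E, 2, dist$mu, "-")
  # solve via the stored Cholesky factor: s^2 = || L^-T d ||^2
  Z <- backsolve(dist$chol, t(D), transpose = TRUE)
  s <- sqrt(colSums(Z^2))
  unname(s)
}

#' Aggregate hourly scores into daily anomaly scores
#'
#' The daily score is the mean of the day's retained hourly Mahalanobis
#' scores; days with no retained hours are excluded (logged).
#'
#' @param scores data.table/data.frame with columns participant_id,
#'   date, score (one row per retained hour).
#' @return data.table: participant_id, date, s_d, n_hours.
#' @export
daily_scores <- function(scores) {
  sc <- data.table::as.data.table(scores)
  out <- sc[, .(s_d = mean(score), n_hours = .N),
            by = .(participant_id, date)]
  out[]
}

# Confusion counts of daily flags against NR30/DRH labels.
confusion_at <- function(s_d, label, tau) {
  flag <- s_d > tau
  nr <- label == "NR30"
  c(tp = sum(flag & nr), fn = sum(!flag & nr),
    fp = sum(flag & !nr), tn = sum(!flag & !nr))
}

#' Learn the per-participant daily-score threshold
#'
#' Chooses tau maximizing TPR/FPR over the daily scores of the mixed
#' validation set, searching the range [0, 20]. Candidates are all
#' observed daily scores (clipped to the range) plus midpoints between
#' consecutive ones, which realizes every achievable confusion table.
#' FPR = 0 is floored at `1 / (#DRH days + 1)` so perfect-separation
#' thresholds win but remain comparable; argmax ties break toward the
#' largest tau (fewest anomalies, favoring specificity).
#'
#' @param daily data.table with columns participant_id, date, s_d and
#'   `label` in {"NR30", "DRH"}.
#' @param tau_range Search range (default c(0, 20)).
#' @return data.table per participant: tau, tpr, fpr, ratio, degenerate.
#'   Participants with no NR30 or no DRH day are excluded with a warning.
#' @export
learn_threshold <- function(daily, tau_range = c(0, 20)) {
  dd <- data.table::as.data.table(daily)
  assert_that(all(c("s_d", "label") %in% names(dd)),
              "daily scores need s_d and label columns")
  out <- list()
  for (pid in unique(dd$participant_id)) {
    d <- dd[participant_id == pid]
    n_nr <- sum(d$label == "NR30")
    n_drh <- sum(d$label == "DRH")
    if (n_nr == 0 || n_drh == 0) {
      warning("participant ", pid, " lacks NR30 or DRH days in N_CV; excluded")
      next
    }
    s <- sort(unique(pmin(pmax(d$s_d, tau_range[1]), tau_range[2])))
    cand <- unique(c(tau_range[1], s, tau_range[2],
                     if (length(s) > 1) (s[-1] + s[-length(s)]) / 2))
    cand <- sort(cand)
    fpr_floor <- 1 / (n_drh + 1)
    best <- NULL
    for (tau in cand) {
      cc <- confusion_at(d$s_d, d$label, tau)
      tpr <- cc[["tp"]] / n_nr
      fpr <- cc[["fp"]] / n_drh
      ratio <- tpr / max(fpr, fpr_floor)
      if (is.null(best) || ratio > best$ratio + 1e-12 ||
          (abs(ratio - best$ratio) <= 1e-12 && tau > best$tau)) {
        best <- list(tau = tau, tpr = tpr, fpr = fpr, ratio = ratio)
      }
    }
    # degenerate: no threshold discriminates (best ratio at or below 1,
    # e.g. all scores identical, where only TPR = FPR tables exist)
    degenerate <- best$tpr == 0 || best$ratio <= 1
    if (degenerate) {
      warning("participant ", pid, ": no threshold with TPR/FPR > 1 ",
              "exists for the observed scores (degenerate)")
    }
    out[[pid]] <- data.table(participant_id = pid, tau = best$tau,
                             tpr = best$tpr, fpr = best$fpr,
                             ratio = best$ratio, degenerate = degenerate)
  }
  rbindlist(out)
}

#' Flag anomalous days with a learned threshold
#'
#' A day is an anomaly iff its daily score strictly exceeds the
#' participant's tau (a day with `s_d == tau` is normal). The threshold
#' is never re-optimized on the set being flagged.
#'
#' @param daily data.table with participant_id, date, s_d.
#' @param thresholds data.table with participant_id, tau (from
#'   [learn_threshold()]).
#' @return `daily` with a logical `flag` column (participants without a
#'   threshold are dropped).
#' @export
flag_anomalies <- function(daily, thresholds) {
  dd <- data.table::as.data.table(daily)
  th <- data.table::as.data.table(thresholds)
  out <- merge(dd, th[, .(participant_id, tau)], by = "participant_id")
  out[, flag := s_d > tau]
  out[]
}
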