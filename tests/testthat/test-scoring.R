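# Error vectors, window consolidation, Gaussian error model,
# Mahalanobis scores, daily aggregation, threshold learning, flagging.

test_that("reconstruction errors are elementwise absolute differences", {
  expect_equal(as.vector(reconstruction_errors(c(1, 2), c(3, 0))), c(2, 2))
  expect_equal(as.vector(reconstruction_errors(1:4, 1:4)), rep(0, 4))
  set.seed(1)
  x <- matrix(rnorm(50), 10)
  xh <- matrix(rnorm(50), 10)
  oracle <- matrix(NA_real_, 10, 5)
  for (i in 1:10) for (j in 1:5) oracle[i, j] <- abs(x[i, j] - xh[i, j])
  expect_identical(reconstruction_errors(x, xh), oracle)
  expect_error(reconstruction_errors(1:3, 1:4), "mismatch")
})

test_that("consolidation keeps only l-times-predicted hours", {
  # l = 1: pass-through
  xh <- matrix(rnorm(12), 6)
  c1 <- consolidate_hour_predictions(xh, 1:6, l = 1, L = 6)
  expect_equal(c1$hours, 1:6)
  expect_equal(c1$xhat, xh)
  # L = 48, l = 24: exactly hours 24..25 are covered 24 times
  L <- 48; l <- 24; m <- 2
  nw <- L - l + 1
  arr <- array(0, c(nw, l, m))
  hour_of <- function(s, j) s + l - j
  for (w in seq_len(nw)) for (j in seq_len(l)) arr[w, j, ] <- hour_of(w, j)
  cc <- consolidate_hour_predictions(arr, seq_len(nw), l, L)
  expect_equal(cc$hours, 24:25)
  # enumeration oracle for the coverage counts
  cov_oracle <- vapply(1:L, function(i)
    sum(vapply(seq_len(nw), function(s) i >= s && i <= s + l - 1, logical(1))),
    numeric(1))
  expect_equal(cc$coverage, as.integer(cov_oracle))
  # identical reconstructions across windows consolidate to themselves
  expect_true(all(cc$xhat[, 1] == cc$hours))
})

test_that("error distribution fit and Mahalanobis score match oracles", {
  # identical error vectors: mu = vector, Sigma = lambda I, score(mu)=0
  E0 <- matrix(rep(c(1, 2, 3), each = 10), 10)
  d0 <- fit_error_distribution(E0)
  expect_equal(d0$mu, c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(d0$sigma, diag(d0$lambda, 3), ignore_attr = TRUE)
  expect_equal(mahalanobis_score(d0$mu, d0), 0)
  # standard-normal errors at n = 10000: mu ~ 0, Sigma ~ I
  set.seed(2)
  E <- matrix(rnorm(10000 * 3), ncol = 3)
  dn <- fit_error_distribution(E)
  expect_lt(max(abs(dn$mu)), 0.05)
  expect_lt(max(abs(dn$sigma - diag(3))), 0.06)
  # Euclidean reduction: mu = 0, Sigma = I, e = (3,4) -> 5
  dI <- list(mu = c(0, 0), sigma = diag(2), chol = chol(diag(2)))
  class(dI) <- "sw_error_dist"
  expect_equal(mahalanobis_score(c(3, 4), dI), 5)
  # random instances vs explicit solve-based oracle
  for (i in 1:100) {
    m <- sample(2:5, 1)
    A <- matrix(rnorm(m * m), m)
    S <- crossprod(A) + diag(m) * 0.5
    mu <- rnorm(m)
    e <- rnorm(m)
    dd <- list(mu = mu, sigma = S, chol = chol(S))
    class(dd) <- "sw_error_dist"
    oracle <- sqrt(drop(t(e - mu) %*% solve(S) %*% (e - mu)))
    expect_equal(mahalanobis_score(e, dd), oracle, tolerance = 1e-10)
  }
  expect_error(mahalanobis_score(c(NA, 1), dI), "non-finite")
  expect_error(fit_error_distribution(matrix(1, 1, 3)), "at least 2")
})

test_that("shift invariance: adding a constant to all errors leaves scores alone", {
  set.seed(3)
  E <- matrix(abs(rnorm(200 * 4)), ncol = 4)
  e_test <- abs(rnorm(4))
  d1 <- fit_error_distribution(E)
  shift <- c(5, -2, 3, 10)
  d2 <- fit_error_distribution(sweep(E, 2, shift, "+"))
  expect_equal(mahalanobis_score(e_test, d1),
               mahalanobis_score(e_test + shift, d2), tolerance = 1e-8)
})

test_that("daily scores are per-day means of hourly scores", {
  sc <- data.table::data.table(
    participant_id = "P", date = as.Date("2020-01-01") + c(0, 0, 1, 1, 1),
    score = c(2, 4, 3, 3, 3))
  ds <- daily_scores(sc)
  expect_equal(ds$s_d, c(3, 3))
  expect_equal(ds$n_hours, c(2L, 3L))
  set.seed(4)
  sc2 <- data.table::data.table(participant_id = "P",
                                date = as.Date("2020-01-01"),
                                score = runif(24))
  expect_equal(daily_scores(sc2)$s_d, mean(sc2$score))
})

test_that("threshold learning matches the exhaustive-scan oracle", {
  # separable case: NR30 {5,6}, DRH {1,2}: any tau in (2,5) is optimal,
  # ties break toward the largest tau among equal-ratio candidates
  d <- data.table::data.table(
    participant_id = "P", date = as.Date("2020-01-01") + 0:3,
    s_d = c(5, 6, 1, 2), label = c("NR30", "NR30", "DRH", "DRH"))
  th <- learn_threshold(d)
  expect_gt(th$tau, 2)
  expect_lt(th$tau, 5)
  expect_equal(th$tpr, 1)
  expect_equal(th$fpr, 0)
  # brute-force oracle over a fine grid on random instances
  ratio_at <- function(s, lab, tau, floor_) {
    tpr <- sum(s > tau & lab == "NR30") / sum(lab == "NR30")
    fpr <- sum(s > tau & lab == "DRH") / sum(lab == "DRH")
    tpr / max(fpr, floor_)
  }
  set.seed(5)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    lab <- sample(c("NR30", "DRH"), n, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (!any(lab == "NR30") || !any(lab == "DRH")) next
    s <- round(runif(n, 0, 20), 2)
    d <- data.table::data.table(participant_id = "P",
                                date = as.Date("2020-01-01") + seq_len(n),
                                s_d = s, label = lab)
    th <- suppressWarnings(learn_threshold(d))
    floor_ <- 1 / (sum(lab == "DRH") + 1)
    # every achievable confusion table corresponds to an interval
    # between consecutive distinct scores: scan one tau per interval
    # plus the range endpoints
    su <- sort(unique(s))
    cuts <- c(0, 20, su, (su[-1] + su[-length(su)]) / 2, su - 1e-9)
    cuts <- cuts[cuts >= 0 & cuts <= 20]
    best_oracle <- max(vapply(cuts, function(t0)
      ratio_at(s, lab, t0, floor_), numeric(1)))
    expect_equal(th$ratio, best_oracle, tolerance = 1e-9)
  }
  # degenerate: all scores identical
  dd <- data.table::data.table(
    participant_id = "P", date = as.Date("2020-01-01") + 0:3,
    s_d = rep(2, 4), label = c("NR30", "NR30", "DRH", "DRH"))
  expect_warning(thd <- learn_threshold(dd), "degenerate")
  expect_true(thd$degenerate)
})

test_that("flagging is strict and never re-optimized", {
  daily <- data.table::data.table(
    participant_id = "P", date = as.Date("2020-01-01") + 0:2,
    s_d = c(1, 2, 3))
  th <- data.table::data.table(participant_id = "P", tau = 2)
  fl <- flag_anomalies(daily, th)
  expect_equal(fl$flag, c(FALSE, FALSE, TRUE))  # s_d == tau is normal
  th0 <- data.table::data.table(participant_id = "P", tau = 0)
  expect_true(all(flag_anomalies(daily, th0)$flag))
  # elementwise comparison oracle
  set.seed(6)
  daily2 <- data.table::data.table(participant_id = "P",
                                   date = as.Date("2020-01-01") + 1:50,
                                   s_d = runif(50, 0, 10))
  th2 <- data.table::data.table(participant_id = "P", tau = 4.2)
  expect_equal(flag_anomalies(daily2, th2)$flag, daily2$s_d > 4.2)
})
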