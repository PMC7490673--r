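# Confusion metrics, Monte Carlo aggregation, model ranking,
# data-quality regression, anomaly-rate timeline.

test_that("confusion metrics match the contingency-table oracle", {
  lab <- c(rep("NR30", 10), rep("DRH", 20))
  fl <- c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 2), rep(FALSE, 18))
  cm <- confusion_metrics(fl, lab)
  expect_equal(unlist(cm[c("tpr", "fpr", "sensitivity", "specificity")]),
               c(tpr = 0.3, fpr = 0.1, sensitivity = 0.3, specificity = 0.9))
  cm_all <- confusion_metrics(rep(TRUE, 30), lab)
  expect_equal(unlist(cm_all[c("tpr", "fpr", "specificity")]),
               c(tpr = 1, fpr = 1, specificity = 0))
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    lab <- sample(c("NR30", "DRH"), n, replace = TRUE)
    fl <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab == "NR30")) next
    tab <- table(factor(fl, c(FALSE, TRUE)), factor(lab, c("DRH", "NR30")))
    cm <- confusion_metrics(fl, lab)
    expect_equal(cm$tpr, tab["TRUE", "NR30"] / sum(tab[, "NR30"]))
    if (any(lab == "DRH")) {
      expect_equal(cm$fpr, tab["TRUE", "DRH"] / sum(tab[, "DRH"]))
      expect_equal(cm$specificity + cm$fpr, 1)
    }
  }
  expect_warning(confusion_metrics(c(TRUE, FALSE), c("DRH", "DRH")),
                 "no NR30")
})

test_that("Monte Carlo aggregation nests median-over-iterations then quartiles", {
  rec1 <- data.table::data.table(config = "a", iteration = 1,
                                 participant_id = "P1",
                                 sensitivity = 0.4, specificity = 0.9)
  agg1 <- aggregate_monte_carlo(rec1)
  expect_equal(agg1$config$sens_median, 0.4)
  expect_equal(agg1$config$sens_q1, agg1$config$sens_q3)
  rec3 <- data.table::data.table(config = "a", iteration = 1,
                                 participant_id = c("P1", "P2", "P3"),
                                 sensitivity = c(0.2, 0.3, 0.4),
                                 specificity = c(0.8, 0.9, 1.0))
  expect_equal(aggregate_monte_carlo(rec3)$config$sens_median, 0.3)
  # quartiles agree with an independent sort-and-interpolate oracle
  set.seed(2)
  vals <- runif(11)
  rec <- data.table::data.table(config = "a", iteration = 1,
                                participant_id = paste0("P", 1:11),
                                sensitivity = vals, specificity = rev(vals))
  agg <- aggregate_monte_carlo(rec)
  sv <- sort(vals)
  interp <- function(p) {
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }
  expect_equal(agg$config$sens_q1, interp(0.25))
  expect_equal(agg$config$sens_median, interp(0.5))
  expect_equal(agg$config$sens_q3, interp(0.75))
  # permutation invariance over iterations
  rec_it <- data.table::data.table(
    config = "a", iteration = rep(1:5, each = 2),
    participant_id = rep(c("P1", "P2"), 5),
    sensitivity = runif(10), specificity = runif(10))
  a1 <- aggregate_monte_carlo(rec_it)
  a2 <- aggregate_monte_carlo(rec_it[sample(.N)])
  expect_equal(as.data.frame(a1$config), as.data.frame(a2$config))
})

test_that("model ranking uses fractional mean ranks of TPR/FPR", {
  rec <- data.table::data.table(
    config = rep(c("a", "b"), each = 3),
    participant_id = rep(c("P1", "P2", "P3"), 2),
    ratio = c(3, 2, 5, 1, 1, 2))
  rk <- rank_models(rec)
  expect_equal(rk$config, c("a", "b"))
  expect_equal(rk$mean_rank, c(1, 2))
  # identical ratios everywhere: equal mean ranks
  rec_t <- data.table::copy(rec)[, ratio := 1]
  expect_equal(unique(rank_models(rec_t)$mean_rank), 1.5)
  # random ratios vs rank-matrix oracle
  set.seed(3)
  rec_r <- data.table::data.table(
    config = rep(letters[1:4], each = 6),
    participant_id = rep(paste0("P", 1:6), 4),
    ratio = runif(24))
  rk_r <- rank_models(rec_r)
  M <- matrix(rec_r$ratio, nrow = 6)   # participants x configs
  oracle <- colMeans(t(apply(M, 1, function(r) rank(-r))))
  expect_equal(rk_r$mean_rank[order(rk_r$config)], unname(oracle))
})

test_that("data-quality regression recovers planted standardized betas", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 4), n)
  beta <- c(0.6, -0.4, 0, 0)
  y <- X %*% beta + rnorm(n, 0, 0.3)
  rows <- data.frame(X)
  names(rows) <- c("days_raw", "days_per_nr30", "pct_near_relapse",
                   "n_relapses")
  rows$sensitivity <- as.vector(y)
  rows$specificity <- as.vector(-y + rnorm(n, 0, 0.3))
  reg <- data_quality_regression(rows)
  sens <- reg[reg$outcome == "sensitivity", ]
  # standardized y: planted coefficients shrink by sd(y); compare on
  # that scale
  b_std <- beta / sd(y)
  for (i in 1:4) {
    row <- sens[sens$term == names(rows)[i], ]
    expect_gt(b_std[i], row$ci_lo)
    expect_lt(b_std[i], row$ci_hi)
  }
  # intercept of the standardized fit is ~0
  expect_lt(abs(sens[sens$term == "intercept", ]$beta), 1e-10)
  # outcome equal to a predictor: its beta = 1, others ~ 0
  rows2 <- rows
  rows2$sensitivity <- rows2$days_raw
  # perfect fit by construction; lm warns about it, which is expected
  reg2 <- suppressWarnings(data_quality_regression(rows2,
                                                   outcomes = "sensitivity"))
  expect_equal(reg2[reg2$term == "days_raw", ]$beta, 1, tolerance = 1e-9)
  expect_lt(max(abs(reg2[!reg2$term %in% c("days_raw", "intercept"), ]$beta)),
            1e-9)
})

test_that("anomaly-rate timeline steps up inside the labeled window", {
  rel <- data.table::data.table(participant_id = c("A", "B"),
                                relapse_date = as.Date("2020-03-01"))
  dates <- as.Date("2020-01-01") + 0:89
  fl <- data.table::rbindlist(lapply(c("A", "B"), function(p)
    data.table::data.table(participant_id = p, date = dates,
                           flag = dates >= as.Date("2020-03-01") - 30)))
  tl <- anomaly_rate_timeline(fl, rel, window = 35)
  expect_true(all(tl$mean_rate[tl$offset_days > 30] == 0))
  expect_true(all(tl$mean_rate[tl$offset_days <= 30] == 1))
  expect_true(all(tl$mean_rate >= 0 & tl$mean_rate <= 1, na.rm = TRUE))
  # all-zero flags give a flat zero curve
  fl0 <- data.table::copy(fl)[, flag := FALSE]
  expect_true(all(anomaly_rate_timeline(fl0, rel)$mean_rate == 0))
})
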