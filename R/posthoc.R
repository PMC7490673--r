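# Post hoc interpretation of flagged anomalies: per-feature effect
# sizes with the conventional class boundaries, top-5 signature
# recovery, missingness odds ratio, and the pooled one-sided
# Mann-Whitney test on type-2 hours.

#' Cohen's d (pooled SD)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the classical (nA-1, nB-1)
#' pooled standard deviation. Positive d means group A is higher.
#' Returns NA (with a warning) when the pooled SD is zero.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2,
              "both groups need at least 2 values")
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    warning("pooled SD is zero: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Classify an effect size
#'
#' Large for |d| > 0.8, medium for 0.5 < |d| <= 0.8, below-medium
#' otherwise.
#'
#' @param d Cohen's d value(s).
#' @return Character vector of classes.
#' @export
effect_class <- function(d) {
  ad <- abs(d)
  ifelse(is.na(ad), NA_character_,
         ifelse(ad > 0.8, "large",
                ifelse(ad > 0.5, "medium", "below-medium")))
}

#' Per-feature effect sizes of NR30 anomalies vs all DRH
#'
#' For one participant, compares hourly feature values on flagged
#' NR30 days against hourly values on all DRH days, computing Cohen's d
#' per feature (positive = higher on NR30 anomalies), the effect class,
#' and the top-5 features by |d|.
#'
#' @param features Hourly feature data.table for the participant
#'   (columns date plus feature columns).
#' @param flagged_days Dates of flagged anomalous NR30 days.
#' @param drh_days Dates of all DRH days.
#' @param feature_names Features to rank (defaults to all behavioral
#'   features, i.e. excluding calendar context and fill_fraction).
#' @return Object of class `sw_effect_report`: data.table (feature, d,
#'   class, in_top5) plus attributes `top5`.
#' @export
feature_effect_ranking <- function(features, flagged_days, drh_days,
                                   feature_names = NULL) {
  ft <- data.table::as.data.table(features)
  if (is.null(feature_names)) {
    feature_names <- setdiff(sw_feature_names(),
                             c("day_of_week", "hour_of_day", "fill_fraction"))
    feature_names <- intersect(feature_names, names(ft))
  }
  if (!length(flagged_days)) {
    warning("no flagged NR30 days: empty effect report")
    return(structure(data.table(feature = character(0), d = numeric(0),
                                class = character(0), in_top5 = logical(0)),
                     class = c("sw_effect_report", "data.table", "data.frame"),
                     top5 = character(0)))
  }
  ga <- ft[date %in% as.Date(flagged_days)]
  gb <- ft[date %in% as.Date(drh_days)]
  d <- vapply(feature_names, function(f) {
    a <- ga[[f]]
    b <- gb[[f]]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    suppressWarnings(cohens_d(a, b))
  }, numeric(1))
  out <- data.table(feature = feature_names, d = d,
                    class = effect_class(d))
  ranked <- out[!is.na(d)][order(-abs(d))]
  top5 <- head(ranked$feature, 5)
  out[, in_top5 := feature %in% top5]
  out <- out[order(-abs(d), na.last = TRUE)]
  structure(out, class = c("sw_effect_report", class(out)), top5 = top5)
}

#' Odds ratio for type-2 missingness on anomalous days
#'
#' Cross-product odds ratio of the 2x2 table (day contains >= 1 type-2
#' hour) x (day flagged anomalous within NR30), with the Haldane
#' correction (+0.5 to every cell) when any cell is zero.
#'
#' @param has_type2 Logical per day: contains at least one type-2 hour.
#' @param is_anomaly Logical per day: flagged anomaly (within NR30).
#' @return List: or, table (2x2), corrected (logical).
#' @export
missingness_odds_ratio <- function(has_type2, is_anomaly) {
  assert_that(length(has_type2) == length(is_anomaly), "length mismatch")
  a <- sum(has_type2 & is_anomaly)
  b <- sum(!has_type2 & is_anomaly)
  c_ <- sum(has_type2 & !is_anomaly)
  d_ <- sum(!has_type2 & !is_anomaly)
  if ((a + b) == 0 || (c_ + d_) == 0 || (a + c_) == 0 || (b + d_) == 0) {
    warning("empty margin: odds ratio undefined")
    return(list(or = NA_real_, table = matrix(c(a, b, c_, d_), 2),
                corrected = FALSE))
  }
  corrected <- any(c(a, b, c_, d_) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d_ <- d_ + 0.5
  }
  list(or = (a * d_) / (b * c_),
       table = matrix(c(a, b, c_, d_), 2,
                      dimnames = list(c("type2", "no_type2"),
                                      c("anomaly", "other"))),
       corrected = corrected)
}

# Exact null distribution of the Mann-Whitney U statistic (with ties,
# via enumeration of all group assignments of the pooled ranks).
mw_exact_p <- function(a, b, u_obs) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  r <- rank(pooled)
  u_all <- apply(idx, 2, function(ix) {
    sum(r[ix]) - na * (na + 1) / 2
  })
  mean(u_all <= u_obs + 1e-9)
}

#' One-sided Mann-Whitney U test for fewer type-2 hours on anomalies
#'
#' Tests whether values in group `a` (type-2 hour counts on anomalous
#' days) are stochastically smaller than in group `b` (all other days).
#' U counts pairs where a < b is violated in rank terms: we report the
#' rank-sum-based U of group `a`, so small U favors the hypothesis.
#' Exact enumeration when both groups have <= 8 values; otherwise the
#' normal approximation with midranks, tie-corrected variance and
#' continuity correction. The two one-sided statistics satisfy
#' `U + U' = nA * nB` (asserted).
#'
#' @param a,b Numeric vectors (nonempty).
#' @return List: U, p (one-sided, alternative "a smaller"), method.
#' @export
mannwhitney_type2 <- function(a, b) {
  assert_that(length(a) >= 1 && length(b) >= 1, "both groups nonempty")
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2          # number of (a > b) pairs, ties 0.5
  Ub <- sum(r[na + seq_len(nb)]) - nb * (nb + 1) / 2
  stopifnot(abs(U + Ub - na * nb) < 1e-8)
  if (all(c(a, b) == c(a, b)[1])) {
    return(list(U = U, p = 0.5, method = "degenerate"))
  }
  if (na <= 8 && nb <= 8) {
    p <- mw_exact_p(a, b, U)
    return(list(U = U, p = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * (n + 1 - tie_term)
  mu <- na * nb / 2
  z <- (U - mu + 0.5) / sqrt(sigma2)   # continuity-corrected, lower tail
  list(U = U, p = pnorm(z), method = "normal")
}
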