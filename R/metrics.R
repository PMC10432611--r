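#' Survival and classification evaluation metrics
#'
#' Implements the evaluation stack used throughout the package: ROC AUC by
#' the Mann-Whitney statistic, F1 and Matthews Correlation Coefficient,
#' DeLong's test for paired AUCs, the Kaplan-Meier product-limit estimator
#' with log-rank risk stratification, Harrell's concordance index and the
#' censoring-robust IPCW (Uno) concordance index.
#'
#' @name survival-metrics
NULL

#' Construct a set of survival records
#'
#' A survival record holds the right-censored follow-up of one subject,
#' measured in days from the latest scan: an event indicator (1 = death
#' from a cardiac or respiratory cause, 0 = censored), the follow-up time,
#' and the cause of death for non-survivors.
#'
#' @param time numeric vector of non-negative follow-up times (days from
#'   the latest scan).
#' @param event 0/1 event indicators.
#' @param cause character vector; one of `"none"`, `"cardiac"`,
#'   `"respiratory"`. Must be `"none"` exactly when `event == 0`.
#' @return a data.frame of class `survival_records`.
#' @export
survival_records <- function(time, event, cause = NULL) {
  if (length(time) != length(event))
    stop_invalid("time and event must have equal length")
  if (any(!is.finite(time)) || any(time < 0))
    stop_invalid("follow-up times must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    stop_invalid("event must be 0 (censored) or 1 (death)")
  if (is.null(cause)) cause <- ifelse(event == 1, "unspecified", "none")
  if (any(event == 0 & cause != "none") || any(event == 1 & cause == "none"))
    stop_invalid("cause must be 'none' iff event == 0")
  structure(data.frame(time = as.numeric(time), event = as.integer(event),
                       cause = as.character(cause),
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)} via midranks, which is exact
#' for any tie pattern.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 class labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_invalid("scores and labels must have equal length")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_invalid("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score and Matthews Correlation Coefficient from confusion counts
#'
#' @param tp,fp,tn,fn non-negative confusion-matrix counts.
#' @return list with elements `f1` and `mcc`. A zero denominator yields
#'   `mcc = 0` with attribute `degenerate = TRUE`.
#' @export
f1_mcc <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("confusion counts must be non-negative integers")
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    mcc <- structure(0, degenerate = TRUE)
  } else {
    mcc <- (tp * tn - fp * fn) / den
  }
  list(f1 = f1, mcc = mcc)
}

#' Compare two paired AUCs with DeLong's test
#'
#' Uses the structural-components (placement value) estimator of the
#' covariance between two AUCs measured on the same subjects, and a
#' two-sided normal test for their difference.
#'
#' @param scores_a,scores_b paired score vectors on identical subjects.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop_invalid("scores must be paired with labels")
  labels <- as.integer(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop_invalid("both classes must be present")
  placements <- function(s) {
    sp <- s[pos]; sn <- s[neg]
    # V10[i] = mean_j psi(sp_i, sn_j); V01[j] = mean_i psi(sp_i, sn_j)
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= 0 || !is.finite(v)) {
    z <- 0; p <- 1
    if (abs(d) > 0) warning("zero variance estimate with unequal AUCs")
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param records a `survival_records` data.frame (or anything with
#'   `time`/`event` columns).
#' @return object of class `km_curve`: data.frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `surv`); `S(0) = 1`
#'   implicitly. Evaluate with [km_surv()].
#' @export
km_fit <- function(records) {
  time <- records$time; event <- records$event
  if (length(time) == 0) stop_invalid("empty input")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step function with `S(t) = 1` before the first event.
#'
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @param left if `TRUE`, evaluate the left limit `S(t-)` instead.
#' @export
km_surv <- function(curve, t, left = FALSE) {
  vapply(t, function(ti) {
    idx <- if (left) curve$time < ti else curve$time <= ti
    if (!any(idx)) 1 else curve$surv[max(which(idx))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' @param records `survival_records`.
#' @param group logical or 0/1 group membership.
#' @return list with `chisq`, `p`, and observed/expected counts.
#' @export
logrank_test <- function(records, group) {
  group <- as.logical(group)
  time <- records$time; event <- records$event
  et <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in et) {
    n <- sum(time >= t); n1 <- sum(time >= t & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(list(chisq = 0, p = 1, observed = o1, expected = e1))
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1)
}

#' Stratify a cohort by predicted mortality probability
#'
#' Splits subjects at `threshold` (the high-risk group has probability
#' strictly greater than the threshold), fits a Kaplan-Meier curve per
#' group, and compares them with the log-rank test.
#'
#' @param records `survival_records`.
#' @param probabilities predicted mortality probabilities in \[0, 1\].
#' @param threshold decision threshold, default 0.5.
#' @return list `high`, `low` (both `km_curve`), `logrank` (list), and
#'   `n_high`/`n_low`.
#' @export
km_stratify <- function(records, probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1))
    stop_invalid("probabilities must lie in [0, 1]")
  hi <- probabilities > threshold
  if (all(hi) || !any(hi)) {
    warning("degenerate stratification: one group is empty")
    return(list(high = if (any(hi)) km_fit(records[hi, ]) else NULL,
                low = if (any(!hi)) km_fit(records[!hi, ]) else NULL,
                logrank = list(chisq = NA_real_, p = NA_real_),
                n_high = sum(hi), n_low = sum(!hi)))
  }
  list(high = km_fit(records[hi, , drop = FALSE]),
       low = km_fit(records[!hi, , drop = FALSE]),
       logrank = logrank_test(records, hi),
       n_high = sum(hi), n_low = sum(!hi))
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the subject with the shorter
#' observed survival has the higher risk score. A pair is comparable when
#' the earlier of the two times is an event and the times differ; score
#' ties count one half.
#'
#' @param records `survival_records`.
#' @param risk numeric risk scores (higher = worse prognosis).
#' @return concordance in \[0, 1\].
#' @export
harrell_cindex <- function(records, risk) {
  time <- records$time; event <- records$event
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comp <- time > time[i]
    den <- den + sum(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) stop_invalid("no comparable pairs")
  num / den
}

#' IPCW (Uno) concordance index
#'
#' Truncated, inverse-probability-of-censoring-weighted concordance.
#' Pairs (i, j) with an event at \eqn{T_i < T_j} and \eqn{T_i < \tau}
#' contribute with weight \eqn{1/\hat G(T_i-)^2}, where \eqn{\hat G} is
#' the Kaplan-Meier estimate of the censoring survival function computed
#' on the training records. With no censoring this reduces exactly to
#' Harrell's index.
#'
#' @param train_records `survival_records` used to estimate the censoring
#'   distribution.
#' @param test_records `survival_records` being evaluated.
#' @param risk risk scores for the test records.
#' @param tau truncation horizon; default the 95th percentile of observed
#'   test times (reported via the `tau` attribute).
#' @return concordance in \[0, 1\] with attribute `tau`.
#' @export
ipcw_cindex <- function(train_records, test_records, risk, tau = NULL) {
  if (is.null(tau)) tau <- as.numeric(quantile(test_records$time, 0.95))
  cens <- train_records
  cens$event <- 1 - cens$event
  gkm <- km_fit(cens)
  time <- test_records$time; event <- test_records$event
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    g <- km_surv(gkm, time[i], left = TRUE)
    if (g <= 0)
      stop_invalid("censoring survival estimate is zero at time ", time[i])
    w <- 1 / g^2
    comp <- time > time[i]
    den <- den + w * sum(comp)
    num <- num + w * (sum(risk[i] > risk[comp]) +
                      0.5 * sum(risk[i] == risk[comp]))
  }
  if (den == 0) stop_invalid("no comparable pairs below tau")
  structure(num / den, tau = tau)
}

#' Summarise per-fold cross-validation metrics
#'
#' @param fold_metrics a list (one element per fold) of named numeric
#'   vectors, or a data.frame with one row per fold.
#' @return data.frame with columns `metric`, `mean`, `sd`, `formatted`
#'   (`"mean (sd)"` with 3 decimals, the field's reporting convention).
#' @export
cv_report <- function(fold_metrics) {
  if (is.data.frame(fold_metrics)) {
    m <- as.matrix(fold_metrics)
  } else {
    if (length(fold_metrics) < 2) stop_invalid("need at least 2 folds")
    nm <- names(fold_metrics[[1]])
    for (k in seq_along(fold_metrics)) {
      miss <- setdiff(nm, names(fold_metrics[[k]]))
      if (length(miss))
        stop_invalid("fold ", k, " missing metric(s): ",
                     paste(miss, collapse = ", "))
    }
    m <- do.call(rbind, lapply(fold_metrics, function(x) x[nm]))
  }
  if (nrow(m) < 2) stop_invalid("need at least 2 folds")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  data.frame(metric = colnames(m), mean = mu, sd = s,
             formatted = sprintf("%.3f (%.3f)", mu, s),
             row.names = NULL, stringsAsFactors = FALSE)
}
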