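test_that("roc_auc matches exhaustive pairwise Mann-Whitney comparison", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq_len(8), n, replace = TRUE) / 8  # force ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(scores, labels), brute)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("f1_mcc matches the closed formulas and symmetry properties", {
  r <- f1_mcc(2, 1, 2, 1)
  expect_equal(r$f1, 2 / 3)
  expect_equal(as.numeric(r$mcc), 1 / 3)
  perf <- f1_mcc(5, 0, 5, 0)
  expect_equal(perf$f1, 1); expect_equal(as.numeric(perf$mcc), 1)
  bal <- f1_mcc(1, 1, 1, 1)
  expect_equal(as.numeric(bal$mcc), 0)
  deg <- f1_mcc(0, 0, 4, 0)
  expect_true(isTRUE(attr(deg$mcc, "degenerate")))
  # MCC symmetric under simultaneous label/prediction swap; F1 is not
  a <- f1_mcc(7, 2, 9, 3)
  b <- f1_mcc(9, 3, 7, 2)  # swap positives <-> negatives
  expect_equal(as.numeric(a$mcc), as.numeric(b$mcc))
  expect_false(isTRUE(all.equal(a$f1, b$f1)))
  expect_error(f1_mcc(-1, 0, 0, 0), "non-negative")
})

test_that("delong_compare: identity, AUC consistency, bootstrap variance", {
  set.seed(1)
  n <- 200
  labels <- rbinom(n, 1, 0.4)
  sa <- rnorm(n, labels); sb <- 0.6 * sa + rnorm(n, 0.5 * labels)
  same <- delong_compare(sa, sa, labels)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  r <- delong_compare(sa, sb, labels)
  expect_equal(r$auc_a, roc_auc(sa, labels))
  expect_equal(r$auc_b, roc_auc(sb, labels))
  expect_true(r$p >= 0 && r$p <= 1)
  # variance of the AUC difference vs a 2000-rep bootstrap
  d_obs <- r$auc_a - r$auc_b
  v_dl <- (d_obs / r$z)^2
  boots <- replicate(2000, {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(labels[i])) < 2) return(NA_real_)
    roc_auc(sa[i], labels[i]) - roc_auc(sb[i], labels[i])
  })
  v_boot <- stats::var(boots, na.rm = TRUE)
  expect_lt(abs(v_dl - v_boot) / v_boot, 0.15)
})

test_that("km_fit reproduces hand product-limit values and survfit", {
  # 4 uncensored deaths at distinct times
  k <- km_fit(survival_records(c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_equal(k$surv, c(0.75, 0.5, 0.25, 0))
  # censored middle subject
  k2 <- km_fit(survival_records(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km_surv(k2, 1), 2 / 3)
  expect_equal(km_surv(k2, 3), 0)
  # all censored
  k3 <- km_fit(survival_records(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(nrow(k3), 0)
  expect_equal(km_surv(k3, 10), 1)
  expect_error(km_fit(survival_records(numeric(0), integer(0))),
               "empty")
  # against the survival package on random censored data
  set.seed(9)
  rec <- survival_records(rexp(40, 0.1), rbinom(40, 1, 0.6))
  k4 <- km_fit(rec)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  expect_equal(km_surv(k4, sf$time[sf$n.event > 0]),
               sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("km_stratify and the log-rank test behave per contract", {
  set.seed(3)
  rec <- survival_records(rexp(60, 0.05), rbinom(60, 1, 0.7))
  # clairvoyant: probabilities equal to event indicators
  st <- km_stratify(rec, rec$event * 0.9 + 0.05)
  tgrid <- sort(unique(rec$time))
  expect_true(all(km_surv(st$high, tgrid) <= km_surv(st$low, tgrid) + 1e-12))
  # identical groups duplicated -> statistic 0
  rec2 <- survival_records(rep(rec$time, 2), rep(rec$event, 2))
  lr <- logrank_test(rec2, rep(c(TRUE, FALSE), each = nrow(rec)))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  # against survival::survdiff
  grp <- rbinom(nrow(rec), 1, 0.5)
  ours <- logrank_test(rec, grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = rec)
  expect_equal(ours$chisq, sd$chisq, tolerance = 1e-8)
  # degenerate stratification warns
  expect_warning(km_stratify(rec, rep(0.1, nrow(rec))), "degenerate")
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(100, {
    rec <- survival_records(rexp(40, 0.05), rbinom(40, 1, 0.7))
    logrank_test(rec, rbinom(40, 1, 0.5))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("harrell_cindex matches pair enumeration", {
  rec <- survival_records(c(1, 2, 3), c(1, 1, 1))
  expect_equal(harrell_cindex(rec, c(3, 1, 2)), 2 / 3)
  rec2 <- survival_records(c(5, 3, 9, 1), c(1, 1, 1, 1))
  expect_equal(harrell_cindex(rec2, -rec2$time), 1)
  set.seed(5)
  rec3 <- survival_records(rexp(400, 0.1), rep(1, 400))
  expect_lt(abs(harrell_cindex(rec3, rnorm(400)) - 0.5), 0.05)
  expect_error(harrell_cindex(survival_records(1, 1), 0), "comparable")
})

test_that("ipcw_cindex equals Harrell without censoring and the oracle", {
  set.seed(8)
  rec <- survival_records(rexp(50, 0.1), rep(1, 50))
  risk <- rnorm(50)
  expect_equal(as.numeric(ipcw_cindex(rec, rec, risk, tau = Inf)),
               harrell_cindex(rec, risk), tolerance = 1e-12)
  # brute-force weighted-pair oracle on censored cohorts
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    tr <- survival_records(rexp(n, 0.1), rbinom(n, 1, 0.6))
    te <- survival_records(rexp(n, 0.1), rbinom(n, 1, 0.6))
    if (sum(te$event) == 0) next
    risk <- rnorm(n)
    tau <- quantile(te$time, 0.9)
    expect_equal(as.numeric(ipcw_cindex(tr, te, risk, tau = tau)),
                 ipcw_oracle(tr, te, risk, tau), tolerance = 1e-10)
  }
  # perfect risk ordering under independent censoring
  t_ev <- rexp(80, 0.1)
  rec2 <- survival_records(pmin(t_ev, 40), as.integer(t_ev <= 40))
  expect_equal(as.numeric(ipcw_cindex(rec2, rec2, -t_ev, tau = Inf)), 1)
})

test_that("rank metrics are invariant under monotone score transforms", {
  set.seed(12)
  rec <- survival_records(rexp(30, 0.1), rbinom(30, 1, 0.6))
  risk <- rnorm(30)
  labels <- rbinom(30, 1, 0.5)
  if (sum(rec$event) > 0 && length(unique(labels)) == 2) {
    mono <- function(x) exp(2 * x) + 1
    expect_equal(roc_auc(mono(risk), labels), roc_auc(risk, labels))
    expect_equal(harrell_cindex(rec, mono(risk)),
                 harrell_cindex(rec, risk))
    expect_equal(as.numeric(ipcw_cindex(rec, rec, mono(risk), tau = Inf)),
                 as.numeric(ipcw_cindex(rec, rec, risk, tau = Inf)))
  }
})

test_that("cv_report formats fold summaries", {
  r <- cv_report(list(c(auc = 0.7), c(auc = 0.8)))
  expect_equal(r$mean, 0.75)
  expect_equal(r$sd, 0.0707, tolerance = 1e-3)
  expect_equal(r$formatted, "0.750 (0.071)")
  same <- cv_report(list(c(auc = 0.7, f1 = 0.5), c(auc = 0.7, f1 = 0.5)))
  expect_equal(same$sd, c(0, 0))
  expect_error(cv_report(list(c(auc = 0.7))), "2 folds")
  expect_error(cv_report(list(c(auc = 0.7), c(f1 = 0.5))), "missing")
})
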