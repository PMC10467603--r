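test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # times (1,2,3), events (1,1,0): S = 2/3 after t=1, 1/3 after t=2
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)
  expect_equal(km$surv[km$time == 3], 1 / 3)
  # all censored: curve stays at 1
  km2 <- kmEstimate(c(5, 8, 9), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")

  # random fixtures vs the independent product-limit oracle
  set.seed(101)
  for (i in 1:20) {
    o <- random_outcomes(sample(5:25, 1))
    km <- kmEstimate(o$time, o$event)
    ora <- oracle_km(o$time, o$event)
    got <- km[km$n_event > 0, c("time", "surv")]
    rownames(got) <- NULL
    expect_equal(got, ora, tolerance = 1e-12)
  }
})

test_that("log-rank test reproduces hand-computed O-E and variance", {
  # 4-sample fixture: group A events at 1,2; group B events at 3,4;
  # by hand U = 7/6, V = 17/36, chi2 = 49/17 = 2.882...
  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # identical groups: chi2 0, p 1
  lr0 <- logrankTest(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2),
                     rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-10)
  # three identical groups: p = 1, df = 2
  lr3 <- logrankTest(rep(c(1, 2, 3), 3), rep(c(1, 0, 1), 3),
                     rep(c("A", "B", "C"), each = 3))
  expect_equal(lr3$df, 2L)
  expect_equal(lr3$p, 1, tolerance = 1e-10)
  # zero events in total
  lrz <- logrankTest(c(1, 2, 3, 4), c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_equal(lrz$chisq, 0)
  expect_equal(lrz$p, 1)
  expect_error(logrankTest(1:3, c(1, 1, 1), rep("A", 3)), "2 nonempty")
})

test_that("log-rank is label-swap invariant and matches the oracle", {
  set.seed(202)
  for (i in 1:25) {
    o <- random_outcomes(sample(8:30, 1))
    grp <- rbinom(length(o$time), 1, 0.5)
    if (length(unique(grp)) < 2) grp[1:2] <- c(0, 1)
    a <- logrankTest(o$time, o$event, grp)
    b <- logrankTest(o$time, o$event, 1 - grp)
    expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
    ora <- oracle_logrank2(o$time, o$event, grp == 1)
    expect_equal(a$chisq, ora$chisq, tolerance = 1e-8)
  }
})

test_that("optimal cutpoint equals the exhaustive scan oracle", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(12:60, 1)
    o <- random_outcomes(n)
    x <- if (i %% 3 == 0) sample(0:6, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) < 2) next
    got <- tryCatch(optimalCutpoint(x, o$time, o$event),
                    error = function(e) NULL)
    ora <- oracle_cutpoint(x, o$time, o$event)
    if (is.null(ora)) {
      expect_null(got)
    } else {
      expect_equal(got$cutpoint, ora$cutpoint)
      expect_equal(got$statistic, ora$z, tolerance = 1e-9)
    }
  }
})

test_that("cutpoint recovers perfect separation and rejects degenerate input", {
  # values > 5 relapse early; the rest censored late
  x <- 1:10
  time <- c(rep(100, 5), 1:5)
  event <- c(rep(0, 5), rep(1, 5))
  cp <- optimalCutpoint(x, time, event, minprop = 0.1)
  expect_gt(cp$cutpoint, 5)
  expect_lte(cp$cutpoint, 6)
  expect_equal(cp$direction, "unfavorable")
  expect_error(optimalCutpoint(rep(2, 12), rexp(12), rbinom(12, 1, .5)),
               "no admissible split")
})

test_that("Cox fit recovers a planted hazard ratio and flags bad designs", {
  set.seed(406)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(1.0 * x))
  time <- pmin(t_ev, 60)
  event <- as.integer(t_ev <= 60)
  fit <- coxFit(data.frame(x = x), time, event)
  expect_true(fit$converged)
  expect_lt(abs(fit$table$loghr - 1.0), 0.2)
  expect_true(fit$table$lower < fit$table$hr & fit$table$hr < fit$table$upper)
  expect_equal(fit$table$hr, exp(fit$table$loghr))

  # covariate independent of outcome: CI covers 1
  fit0 <- coxFit(data.frame(z = z), time, event)
  expect_true(fit0$table$lower < 1 & 1 < fit0$table$upper)

  # duplicated covariate: singular design flagged
  fit2 <- coxFit(data.frame(x = x, x2 = x), time, event)
  expect_false(fit2$converged)
  expect_error(coxFit(data.frame(k = rep(1, n)), time, event), "constant")
})

test_that("ROC AUC equals brute-force pairwise concordance", {
  # perfect separation and all-tied scores
  expect_equal(rocAnalysis(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(rocAnalysis(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(rocAnalysis(1:4, rep(1, 4)), "both")
  set.seed(505)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    scores <- sample(0:8, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(rocAnalysis(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-10)
  }
})

test_that("ROC operating point maximizes the Youden index", {
  set.seed(42)
  scores <- c(rnorm(40, 0), rnorm(40, 1.5))
  labels <- rep(c(0, 1), each = 40)
  r <- rocAnalysis(scores, labels)
  yo <- r$curve$sensitivity + r$curve$specificity - 1
  best <- max(yo[is.finite(r$curve$threshold)])
  expect_equal(r$sensitivity + r$specificity - 1, best, tolerance = 1e-12)
  expect_equal(r$accuracy,
               mean(as.integer(scores > r$threshold) == labels))
})

test_that("risk-of-recurrence curve recovers a logistic truth", {
  set.seed(607)
  n <- 1000
  score <- sample(0:15, n, replace = TRUE)
  p_true <- plogis(-2.5 + 0.35 * score)
  relapse <- rbinom(n, 1, p_true)
  # relapse events within the horizon; non-relapsers followed past it
  time <- ifelse(relapse == 1, runif(n, 1, 119), 130)
  rc <- riskOfRecurrenceCurve(score, time, relapse, horizon = 120)
  expect_lt(rc$p, 0.01)
  expect_false(rc$degenerate)
  truth <- plogis(-2.5 + 0.35 * rc$curve$score)
  inside <- truth >= rc$curve$lower & truth <= rc$curve$upper
  expect_gt(mean(inside), 0.85)
  expect_true(all(rc$curve$risk >= 0 & rc$curve$risk <= 1))

  # constant scores are rejected; degenerate outcomes flagged
  expect_error(riskOfRecurrenceCurve(rep(3, 50), rexp(50), rbinom(50, 1, .5)),
               "2 values")
  rc0 <- riskOfRecurrenceCurve(c(rep(0, 25), rep(5, 25)), rep(130, 50),
                               rep(0, 50), horizon = 120)
  expect_true(rc0$degenerate)
  expect_equal(unique(rc0$curve$risk), 0)
})

test_that("censored-before-horizon samples are excluded from the risk fit", {
  score <- c(0, 0, 5, 5, 10, 10)
  time <- c(30, 130, 40, 130, 50, 130)
  event <- c(0, 0, 1, 0, 1, 0)
  rc <- riskOfRecurrenceCurve(score, time, event, horizon = 120)
  expect_equal(rc$n_used, 5L)  # the score-0 censored-at-30 sample drops out
})
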