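#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit] returning the step function as a
#' data frame. Censored times enter the risk sets only; the curve starts at
#' 1 and is nonincreasing.
#'
#' @param time nonnegative event/censoring times (months).
#' @param event 0/1 event indicator (1 = relapse/death).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (one row per distinct observed time).
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one outcome is required")
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank (Mantel-Cox) test
#'
#' Wrapper over [survival::survdiff]: observed-minus-expected events over
#' pooled risk sets with hypergeometric variance, chi-square reference on
#' `groups - 1` degrees of freedom. Zero events across all groups yields
#' chi-square 0 and p = 1.
#'
#' @param time,event outcome vectors.
#' @param group group labels (>= 2 nonempty groups).
#' @return list with `chisq`, `df`, `p`, `observed`, `expected`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("log-rank test needs >= 2 nonempty groups")
  if (sum(event) == 0)
    return(list(chisq = 0, df = nlevels(group) - 1L, p = 1,
                observed = setNames(rep(0, nlevels(group)), levels(group)),
                expected = setNames(rep(0, nlevels(group)), levels(group))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = setNames(as.vector(sd$obs), levels(group)),
       expected = setNames(as.vector(sd$exp), levels(group)))
}

#' Optimal survival cutpoint (maximally selected log-rank statistic)
#'
#' Exhaustively scans the midpoints between consecutive sorted unique
#' values of `x` whose induced high/low split leaves at least a `minprop`
#' fraction of samples on each side, and returns the cut maximizing the
#' standardized two-group log-rank statistic |U|/sqrt(V). Ties are broken
#' deterministically by the smallest cutpoint. The `direction` is
#' `"unfavorable"` when the high-expression group has more events than
#' expected (worse survival), `"favorable"` otherwise.
#'
#' @param x per-sample values (e.g. one gene's expression).
#' @param time,event outcome vectors.
#' @param minprop minimum fraction of samples in each group (default 0.1).
#' @return list with `cutpoint`, `statistic` (standardized), `chisq`, `p`
#'   (naive chi-square p at the selected cut, as used throughout the
#'   screening pipeline), `direction`, `n_high`, `n_low`, `minprop`.
#' @export
optimalCutpoint <- function(x, time, event, minprop = 0.1) {
  stopifnot(length(x) == length(time), length(x) == length(event))
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must be in (0, 0.5)")
  if (any(!is.finite(x))) stop("x must be finite")
  res <- cpp_maxsel_scan(as.numeric(x), as.numeric(time),
                         as.integer(event), minprop)
  if (!isTRUE(res$admissible))
    stop("no admissible split: fewer than ", ceiling(minprop * length(x)),
         " samples on one side of every candidate cutpoint")
  list(cutpoint = res$cutpoint, statistic = res$statistic,
       chisq = res$chisq,
       p = stats::pchisq(res$chisq, 1L, lower.tail = FALSE),
       direction = if (res$U > 0) "unfavorable"
                   else if (res$U < 0) "favorable" else NA_character_,
       n_high = res$n_high, n_low = res$n_low, minprop = minprop)
}

#' Cox proportional-hazards fit
#'
#' Wrapper over [survival::coxph] with the Efron tie approximation
#' (accurate with the many ties produced by integer recurrence scores).
#' Reports per-covariate log hazard ratios with Wald confidence intervals
#' and p values, and flags non-convergence or singular/separated designs.
#'
#' @param design data.frame of covariates (numeric or factor).
#' @param time,event outcome vectors.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return list with `table` (data.frame: `term`, `loghr`, `hr`, `lower`,
#'   `upper`, `se`, `p`) and `converged` (FALSE when the fit is singular,
#'   hit its iteration limit, or produced non-finite estimates).
#' @export
coxFit <- function(design, time, event, conf_level = 0.95) {
  design <- as.data.frame(design)
  if (ncol(design) == 0L) stop("empty design")
  if (sum(event) < ncol(design))
    stop("fewer events than covariates")
  const <- vapply(design, function(v) length(unique(v)) < 2L, TRUE)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(design)[const], collapse = ", "))
  dat <- cbind(design, .time = time, .event = event)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                        ties = "efron"))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  converged <- is.null(attr(fit, "flagged")) && all(is.finite(beta)) &&
    all(is.finite(se))
  tab <- data.frame(term = names(beta), loghr = unname(beta),
                    hr = exp(unname(beta)),
                    lower = exp(unname(beta) - z * se),
                    upper = exp(unname(beta) + z * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    row.names = NULL)
  list(table = tab, converged = converged,
       flag = attr(fit, "flagged"))
}

#' ROC analysis of a score against relapse labels
#'
#' AUC is the pairwise concordance probability (ties count 1/2), computed
#' via [pROC::roc]; the reported operating point maximizes the Youden
#' index (sensitivity + specificity - 1), with the smallest such threshold
#' on ties. Accuracy is (TP + TN)/n at that operating point.
#'
#' @param scores per-sample real scores (higher = more likely to relapse).
#' @param labels binary relapse labels (both classes must be present).
#' @return list with `auc`, `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, and the full `curve` (data.frame of threshold,
#'   sensitivity, specificity).
#' @export
rocAnalysis <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both relapse classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      sensitivity = r$sensitivities,
                      specificity = r$specificities)
  youden <- curve$sensitivity + curve$specificity - 1
  finite <- is.finite(curve$threshold)
  if (!any(finite)) {
    # constant scores: no informative operating point
    return(list(auc = as.numeric(r$auc), threshold = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                accuracy = max(mean(labels), 1 - mean(labels)),
                curve = curve))
  }
  best <- which(finite & youden == max(youden[finite]))
  best <- best[which.min(curve$threshold[best])]
  thr <- curve$threshold[best]
  pred <- as.integer(scores > thr)
  list(auc = as.numeric(r$auc), threshold = thr,
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best],
       accuracy = mean(pred == labels), curve = curve)
}

#' Risk-of-recurrence curve over a recurrence score
#'
#' Binomial generalized linear model of relapse-by-horizon on the integer
#' recurrence score. Samples censored before the horizon without an event
#' carry no information on the horizon-restricted outcome and are
#' excluded; events after the horizon count as non-relapse within the
#' horizon. Predictions carry pointwise Wald confidence bands on the
#' response scale; the association p value is the Wald test of the slope.
#'
#' @param scores per-sample integer recurrence scores (>= 2 distinct).
#' @param time,event RFS outcome.
#' @param horizon months (default 120 = 10 years).
#' @param conf_level confidence level for the band.
#' @return list with `curve` (data.frame: `score`, `risk`, `lower`,
#'   `upper`), `p` (slope Wald p; NA for a degenerate fit), `n_used`,
#'   `degenerate` (TRUE when all or no used samples relapsed).
#' @export
riskOfRecurrenceCurve <- function(scores, time, event, horizon = 120,
                                  conf_level = 0.95) {
  if (length(unique(scores)) < 2L)
    stop("scores must span at least 2 values")
  used <- !(time < horizon & event == 0)
  y <- as.integer(event == 1 & time <= horizon)[used]
  s <- as.numeric(scores)[used]
  if (length(y) < 2L) stop("no usable samples at this horizon")
  grid <- seq(min(scores), max(scores), by = 1)
  degenerate <- length(unique(y)) < 2L
  if (degenerate) {
    risk <- rep(mean(y), length(grid))
    return(list(curve = data.frame(score = grid, risk = risk,
                                   lower = risk, upper = risk),
                p = NA_real_, n_used = length(y), degenerate = TRUE))
  }
  fit <- stats::glm(y ~ s, family = stats::binomial())
  pr <- stats::predict(fit, newdata = data.frame(s = grid), se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- summary(fit)$coefficients
  list(curve = data.frame(score = grid,
                          risk = stats::plogis(pr$fit),
                          lower = stats::plogis(pr$fit - z * pr$se.fit),
                          upper = stats::plogis(pr$fit + z * pr$se.fit)),
       p = co["s", "Pr(>|z|)"], n_used = length(y), degenerate = FALSE)
}
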