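#' Evaluate a signature on a cohort
#'
#' Computes recurrence scores, classifies samples high/low (using the
#' signature's frozen score cut-off for this cohort when present,
#' otherwise re-optimizing it), and reports the Kaplan-Meier/log-rank
#' comparison, the two-group hazard ratio (Cox fit on the binary label),
#' and the ROC of the scores against relapse labels with the
#' Youden-optimal operating point. Relapse labels are relapse-ever by
#' default, or relapse-by-horizon.
#'
#' @param sig a [GeneSignature-class].
#' @param cohort a [SurvCohort-class] containing the signature genes.
#' @param endpoint `"RFS"` (default) or `"OS"` for the KM/HR part; ROC
#'   always uses relapse (RFS events).
#' @param minprop minimum group fraction for cutpoints.
#' @param roc_horizon `NULL` (relapse-ever, default) or months: relapse
#'   labels restricted to events by the horizon, with samples censored
#'   earlier excluded from the ROC.
#' @return list of class `performance_report` with `endpoint`, `hr`,
#'   `hr_lower`, `hr_upper`, `logrank_p`, `logrank_chisq`, `auc`,
#'   `sensitivity`, `specificity`, `accuracy`, `threshold`, `n_high`,
#'   `n_low`, `score_cutoff`, plus `scores`, `labels`, `km` (per-group
#'   curves).
#' @export
evaluateSignature <- function(sig, cohort, endpoint = "RFS", minprop = 0.1,
                              roc_horizon = NULL) {
  endpoint <- match.arg(toupper(endpoint), c("RFS", "OS"))
  scores <- recurrenceScores(sig, cohort, minprop)
  rfs <- survOutcomes(cohort, "RFS")
  nm <- cohortName(cohort)
  if (nm %in% names(sig@scoreCutoff)) {
    cutoff <- sig@scoreCutoff[[nm]]
    labels <- setNames(ifelse(scores > cutoff, "high", "low"), names(scores))
  } else {
    cl <- classifyHighLow(scores, rfs[, 1L], rfs[, 2L], minprop)
    labels <- cl$labels
    cutoff <- cl$score_cutoff
  }
  if (length(unique(labels)) < 2L)
    stop("high/low classification is degenerate on this cohort")
  sv <- survOutcomes(cohort, endpoint)
  lr <- logrankTest(sv[, 1L], sv[, 2L], labels)
  cx <- coxFit(data.frame(high = as.integer(labels == "high")),
               sv[, 1L], sv[, 2L])
  if (is.null(roc_horizon)) {
    relapse <- rfs[, 2L]
    roc_scores <- scores
  } else {
    used <- !(rfs[, 1L] < roc_horizon & rfs[, 2L] == 0)
    relapse <- as.integer(rfs[, 2L] == 1 & rfs[, 1L] <= roc_horizon)[used]
    roc_scores <- scores[used]
  }
  roc <- rocAnalysis(roc_scores, relapse)
  km <- lapply(split(seq_along(labels), labels), function(idx)
    kmEstimate(sv[idx, 1L], sv[idx, 2L]))
  structure(list(endpoint = endpoint,
                 hr = cx$table$hr[1L], hr_lower = cx$table$lower[1L],
                 hr_upper = cx$table$upper[1L], hr_p = cx$table$p[1L],
                 logrank_p = lr$p, logrank_chisq = lr$chisq,
                 auc = roc$auc, sensitivity = roc$sensitivity,
                 specificity = roc$specificity, accuracy = roc$accuracy,
                 threshold = roc$threshold,
                 n_high = sum(labels == "high"),
                 n_low = sum(labels == "low"), score_cutoff = cutoff,
                 scores = scores, labels = labels, km = km),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "Signature performance (%s): HR = %.3g (%.3g-%.3g), log-rank p = %.3g\n",
    x$endpoint, x$hr, x$hr_lower, x$hr_upper, x$logrank_p))
  cat(sprintf(
    "  AUC = %.3f; sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
    x$auc, 100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  cat(sprintf("  n high/low = %d/%d (score cut-off %.1f)\n",
              x$n_high, x$n_low, x$score_cutoff))
  invisible(x)
}

#' Multivariate Cox model of signature and clinicopathologic covariates
#'
#' Joint proportional-hazards fit of the high/low signature label and the
#' requested covariates (complete cases only). Covariates are coded as in
#' clinical reporting: pT 4 vs 3, grade 3 vs 1+2, MSS vs MSI, KRAS mut vs
#' wt; constant covariates are dropped with a warning.
#'
#' @param cohort a [SurvCohort-class].
#' @param labels high/low labels (e.g. from [evaluateSignature()]).
#' @param covariates subset of `c("pt", "grade", "msi", "kras", "age",
#'   "sex")` to adjust for.
#' @param endpoint `"RFS"` or `"OS"`.
#' @return list with `table` (per-variable HR, CI, p), `converged`, `n`.
#' @export
multivariateReport <- function(cohort, labels,
                               covariates = c("pt", "grade", "msi"),
                               endpoint = "RFS") {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  design <- data.frame(row.names = rownames(cd))
  for (cov in covariates) {
    if (!(cov %in% colnames(cd))) next
    v <- cd[[cov]]
    design[[cov]] <- switch(cov,
      pt = as.integer(v == "4"),
      grade = as.integer(v == "3"),
      msi = as.integer(v == "MSS"),
      kras = as.integer(v == "mut"),
      as.numeric(v))
  }
  design$signature_high <- as.integer(labels[rownames(design)] == "high")
  keep <- stats::complete.cases(design)
  design <- design[keep, , drop = FALSE]
  const <- vapply(design, function(v) length(unique(v)) < 2L, TRUE)
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(colnames(design)[const], collapse = ", "))
    design <- design[, !const, drop = FALSE]
  }
  sv <- survOutcomes(cohort[, keep], endpoint)
  fit <- coxFit(design, sv[, 1L], sv[, 2L])
  pretty <- c(pt = "pT (4 vs. 3)", grade = "Grade (3 vs. 1+2)",
              msi = "MSS vs. MSI", kras = "KRAS (mut vs. wt)",
              signature_high = "signature (high vs. low)")
  fit$table$term <- ifelse(fit$table$term %in% names(pretty),
                           pretty[fit$table$term], fit$table$term)
  list(table = fit$table, converged = fit$converged, n = nrow(design))
}

#' Combined signature/pT stratification
#'
#' Four-group Kaplan-Meier analysis (signature high/low crossed with
#' pT3/pT4) with pairwise log-rank contrasts of pT4 vs pT3 within each
#' signature stratum. Strata lacking both pT levels are omitted with a
#' warning.
#'
#' @param cohort a [SurvCohort-class] with a `pt` covariate.
#' @param labels high/low signature labels.
#' @param endpoint `"RFS"` or `"OS"`.
#' @return list with `groups` (per-group n, events, KM curve) and
#'   `contrasts` (data.frame: stratum, p, chisq).
#' @export
combinedPtStratification <- function(cohort, labels, endpoint = "RFS") {
  cd <- SummarizedExperiment::colData(cohort)
  if (!"pt" %in% colnames(cd)) stop("cohort has no 'pt' covariate")
  pt <- as.character(cd$pt)
  keep <- !is.na(pt)
  sv <- survOutcomes(cohort[, keep], endpoint)
  lab <- labels[keep]; pt <- pt[keep]
  grp <- paste0(lab, "/pT", pt)
  groups <- lapply(split(seq_along(grp), grp), function(idx)
    list(n = length(idx), events = sum(sv[idx, 2L]),
         km = kmEstimate(sv[idx, 1L], sv[idx, 2L])))
  contrasts <- list()
  for (stratum in c("high", "low")) {
    idx <- which(lab == stratum)
    if (length(unique(pt[idx])) < 2L) {
      warning("stratum '", stratum,
              "' lacks both pT levels; contrast omitted")
      next
    }
    lr <- logrankTest(sv[idx, 1L], sv[idx, 2L], pt[idx])
    contrasts[[stratum]] <- data.frame(stratum = stratum, p = lr$p,
                                       chisq = lr$chisq)
  }
  list(groups = groups,
       contrasts = if (length(contrasts)) do.call(rbind, contrasts)
                   else data.frame(stratum = character(), p = numeric(),
                                   chisq = numeric()))
}

#' Compare two signatures on the same cohort
#'
#' Evaluates both signatures, cross-tabulates their high/low calls patient
#' by patient, and reports the difference in high-risk counts (how many
#' patients one signature would spare from a high-risk call relative to
#' the other).
#'
#' @param sigA,sigB [GeneSignature-class] objects.
#' @param cohort a [SurvCohort-class].
#' @param endpoint `"RFS"` or `"OS"`.
#' @param minprop minimum group fraction.
#' @return list with `reportA`, `reportB`, `concordance` (2x2 table of
#'   calls), `concordant_fraction`, `high_risk_difference`
#'   (nB_high - nA_high).
#' @export
compareSignatures <- function(sigA, sigB, cohort, endpoint = "RFS",
                              minprop = 0.1) {
  ra <- evaluateSignature(sigA, cohort, endpoint, minprop)
  rb <- evaluateSignature(sigB, cohort, endpoint, minprop)
  conc <- table(A = ra$labels, B = rb$labels)
  list(reportA = ra, reportB = rb, concordance = conc,
       concordant_fraction =
         sum(ra$labels == rb$labels) / length(ra$labels),
       high_risk_difference = rb$n_high - ra$n_high)
}
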