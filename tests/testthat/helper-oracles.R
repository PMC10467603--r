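# Independent brute-force oracles used to verify the survival primitives.
# These deliberately re-derive everything from first principles (explicit
# loops over event times, all-pairs comparisons, full subset enumeration)
# and share no code with the implementation paths they check.

# exact Kaplan-Meier product-limit: S(t) = prod_{t_i <= t} (1 - d_i / n_i)
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in ts) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    surv <- surv * (1 - d / n_at_risk)
    out <- rbind(out, data.frame(time = t, surv = surv))
  }
  out
}

# two-group log-rank score (observed - expected events in the high group)
# with hypergeometric variance, summed over event times
oracle_logrank2 <- function(time, event, high) {
  ts <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & high)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(U = U, V = V, chisq = if (V > 0) U^2 / V else 0)
}

# exhaustive maximally-selected scan: every midpoint between consecutive
# sorted unique values, minimum group sizes enforced, max |U|/sqrt(V),
# smallest cutpoint on ties
oracle_cutpoint <- function(x, time, event, minprop = 0.1) {
  u <- sort(unique(x))
  n <- length(x)
  mg <- max(1, ceiling(minprop * n))
  best <- NULL
  for (i in seq_len(length(u) - 1)) {
    cut <- (u[i] + u[i + 1]) / 2
    hi <- x > cut
    if (sum(hi) < mg || sum(!hi) < mg) next
    lr <- oracle_logrank2(time, event, hi)
    z <- if (lr$V > 0) abs(lr$U) / sqrt(lr$V) else 0
    if (is.null(best) || z > best$z)
      best <- list(cutpoint = cut, z = z, chisq = lr$chisq)
  }
  best
}

# AUC as the all-pairs concordance probability, ties counting 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# random censored-survival fixture
random_outcomes <- function(n, event_frac = 0.6) {
  time <- round(rexp(n, 0.02), 2)
  event <- rbinom(n, 1, event_frac)
  list(time = time, event = event)
}

# minimal cohort builder from raw vectors
make_cohort <- function(expr, time, event, name = "test", pt = NULL,
                        os_time = NULL, os_event = NULL) {
  if (is.null(dim(expr)))
    expr <- matrix(expr, nrow = 1,
                   dimnames = list("G1", paste0("s", seq_along(expr))))
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  clin <- data.frame(sample_id = colnames(expr), rfs_time = time,
                     rfs_event = event, stringsAsFactors = FALSE)
  if (!is.null(pt)) clin$pt <- as.character(pt)
  if (!is.null(os_time)) {
    clin$os_time <- os_time
    clin$os_event <- os_event
  }
  suppressMessages(SurvCohort(expr, clin, name))
}

# exhaustive per-size best over all gene subsets, via the single-combination
# evaluator (a different code path from the beam's batch evaluator)
oracle_best_per_k <- function(pool, directions, cohort, minprop = 0.1) {
  out <- data.frame(k = integer(), p = numeric(), genes = character())
  for (k in 2:length(pool)) {
    combos <- utils::combn(pool, k, simplify = FALSE)
    evals <- lapply(combos, evaluateCombination, cohort = cohort,
                    directions = directions, minprop = minprop)
    ps <- vapply(evals, `[[`, numeric(1), "p")
    chis <- vapply(evals, `[[`, numeric(1), "chisq")
    keys <- vapply(evals, function(e) paste(e$genes, collapse = ","), "")
    best <- order(ps, -chis, keys, method = "radix")[1]
    out <- rbind(out, data.frame(k = k, p = ps[best], genes = keys[best],
                                 stringsAsFactors = FALSE))
  }
  out
}
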