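#' Screening configuration
#'
#' Settings for the genome-wide per-gene survival screen: a gene is called
#' prognostic when its optimal-cutpoint log-rank test is significant at
#' `alpha` in at least `min_cohorts` cohorts, with a consistent direction
#' among the significant cohorts. No multiple-testing correction is
#' applied across genes; the replication requirement across cohorts is the
#' error control.
#'
#' @param alpha per-cohort significance level (default 0.05).
#' @param min_cohorts minimum number of significant cohorts (default 4,
#'   as in a six-cohort screen requiring at least four).
#' @param minprop minimum group fraction for the cutpoint scan.
#' @return list of class `screen_config`.
#' @export
screenConfig <- function(alpha = 0.05, min_cohorts = 4L, minprop = 0.1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_cohorts < 1L) stop("min_cohorts must be >= 1")
  structure(list(alpha = alpha, min_cohorts = as.integer(min_cohorts),
                 minprop = minprop), class = "screen_config")
}

#' Screen one gene across cohorts
#'
#' In each cohort containing the gene: find the optimal expression
#' cut-off, dichotomize, and test the split by log-rank; the per-cohort
#' direction is `"unfavorable"` when the high-expression group has worse
#' RFS. Cohorts lacking the gene (or with no admissible split) count as
#' non-significant. The verdict is the shared direction when the gene is
#' significant in at least `min_cohorts` cohorts and all significant
#' cohorts agree in direction; otherwise `"excluded"`.
#'
#' @param gene gene symbol.
#' @param cohorts list of [SurvCohort-class] objects.
#' @param cfg a [screenConfig()].
#' @return list with `gene`, `verdict`, `n_significant`, `min_p`, and
#'   `per_cohort` (data.frame: cohort, cutpoint, chisq, p, direction,
#'   significant).
#' @export
screenGene <- function(gene, cohorts, cfg = screenConfig()) {
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, cohortName, "")
  present <- vapply(cohorts, function(co) gene %in% rownames(exprs(co)), TRUE)
  if (!any(present)) stop("gene '", gene, "' absent from every cohort")
  rows <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    if (!(gene %in% rownames(exprs(co))))
      return(data.frame(cohort = nm, cutpoint = NA_real_, chisq = NA_real_,
                        p = NA_real_, direction = NA_character_,
                        significant = FALSE))
    sv <- survOutcomes(co)
    cp <- tryCatch(optimalCutpoint(exprs(co)[gene, ], sv[, 1L], sv[, 2L],
                                   cfg$minprop),
                   error = function(e) NULL)
    if (is.null(cp))
      return(data.frame(cohort = nm, cutpoint = NA_real_, chisq = NA_real_,
                        p = NA_real_, direction = NA_character_,
                        significant = FALSE))
    data.frame(cohort = nm, cutpoint = cp$cutpoint, chisq = cp$chisq,
               p = cp$p, direction = cp$direction,
               significant = is.finite(cp$p) && cp$p < cfg$alpha &&
                 !is.na(cp$direction))
  })
  per_cohort <- do.call(rbind, rows)
  sig <- per_cohort[per_cohort$significant, , drop = FALSE]
  n_sig <- nrow(sig)
  verdict <- "excluded"
  if (n_sig >= cfg$min_cohorts && length(unique(sig$direction)) == 1L)
    verdict <- unique(sig$direction)
  list(gene = gene, verdict = verdict, n_significant = n_sig,
       min_p = if (any(is.finite(per_cohort$p)))
         min(per_cohort$p, na.rm = TRUE) else NA_real_,
       per_cohort = per_cohort)
}

#' Screen all shared genes across cohorts
#'
#' Runs [screenGene()] for every gene in the intersection of the cohorts'
#' gene sets and returns one row per gene, ordered by the minimum
#' per-cohort p value. The verdict is invariant to cohort ordering.
#'
#' @param cohorts list of [SurvCohort-class] objects.
#' @param cfg a [screenConfig()].
#' @param verbose print a summary line (default FALSE).
#' @return data.frame with columns `gene`, `verdict`, `n_significant`,
#'   `min_p`, and per-cohort `p_<cohort>`, `cutpoint_<cohort>`,
#'   `direction_<cohort>` columns; attribute `"summary"` holds the
#'   favorable/unfavorable counts.
#' @export
screenAll <- function(cohorts, cfg = screenConfig(), verbose = FALSE) {
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, cohortName, "")
  genes <- Reduce(intersect, lapply(cohorts, function(co)
    rownames(exprs(co))))
  if (length(genes) == 0L) stop("cohorts share no genes")
  # precompute per-cohort outcome vectors once
  svs <- lapply(cohorts, survOutcomes)
  mats <- lapply(cohorts, exprs)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    rec <- list(gene = g)
    n_sig <- 0L; dirs <- character(); pmin_g <- Inf
    for (nm in names(cohorts)) {
      sv <- svs[[nm]]
      cp <- tryCatch(optimalCutpoint(mats[[nm]][g, ], sv[, 1L], sv[, 2L],
                                     cfg$minprop),
                     error = function(e) NULL)
      if (is.null(cp)) {
        rec[[paste0("p_", nm)]] <- NA_real_
        rec[[paste0("cutpoint_", nm)]] <- NA_real_
        rec[[paste0("direction_", nm)]] <- NA_character_
        next
      }
      rec[[paste0("p_", nm)]] <- cp$p
      rec[[paste0("cutpoint_", nm)]] <- cp$cutpoint
      rec[[paste0("direction_", nm)]] <- cp$direction
      pmin_g <- min(pmin_g, cp$p)
      if (is.finite(cp$p) && cp$p < cfg$alpha && !is.na(cp$direction)) {
        n_sig <- n_sig + 1L
        dirs <- c(dirs, cp$direction)
      }
    }
    verdict <- "excluded"
    if (n_sig >= cfg$min_cohorts && length(unique(dirs)) == 1L)
      verdict <- dirs[1L]
    rec$verdict <- verdict
    rec$n_significant <- n_sig
    rec$min_p <- if (is.finite(pmin_g)) pmin_g else NA_real_
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$min_p, out$gene, method = "radix"), ]
  rownames(out) <- NULL
  first <- c("gene", "verdict", "n_significant", "min_p")
  out <- out[, c(first, setdiff(colnames(out), first))]
  summary_counts <- c(favorable = sum(out$verdict == "favorable"),
                      unfavorable = sum(out$verdict == "unfavorable"))
  attr(out, "summary") <- summary_counts
  if (verbose)
    message(sprintf("screened %d genes: %d unfavorable, %d favorable",
                    nrow(out), summary_counts[["unfavorable"]],
                    summary_counts[["favorable"]]))
  out
}

#' Write screen results as TSV
#'
#' @param screen data.frame from [screenAll()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScreenResults <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
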