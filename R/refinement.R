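# Precompute the n x G matrix of direction-specific 0/1 gene points for a
# candidate pool, with per-gene cut-offs from the maximally selected
# log-rank scan (fixed once per cohort, as cut-offs are per gene, not per
# combination).
.pool_points <- function(pool, directions, cohort, minprop = 0.1) {
  m <- exprs(cohort)
  absent <- setdiff(pool, rownames(m))
  if (length(absent))
    stop("pool gene(s) absent from cohort: ", paste(absent, collapse = ", "))
  sv <- survOutcomes(cohort)
  time <- sv[, 1L]; event <- sv[, 2L]
  P <- matrix(0L, nrow = ncol(m), ncol = length(pool),
              dimnames = list(colnames(m), pool))
  cuts <- setNames(numeric(length(pool)), pool)
  for (i in seq_along(pool)) {
    g <- pool[i]
    cp <- optimalCutpoint(m[g, ], time, event, minprop)
    cuts[i] <- cp$cutpoint
    P[, i] <- genePoint(m[g, ], cp$cutpoint, directions[[g]])
  }
  list(points = P, cutoffs = cuts, time = time, event = event)
}

.combo_key <- function(genes) paste(sort(genes), collapse = ",")

#' Evaluate one gene combination's recurrence-score classifier
#'
#' Computes the combination's integer recurrence score, classifies
#' high/low by the maximally selected log-rank cut on the score, and
#' records the resulting log-rank p value. A combination whose score
#' vector admits no valid split (e.g. constant) is uninformative and gets
#' p = 1 with a flag. Deterministic, and invariant to sample order.
#'
#' @param genes gene subset (no duplicates).
#' @param cohort a [SurvCohort-class].
#' @param directions named character vector of directions covering `genes`.
#' @param minprop minimum group fraction.
#' @return list with `genes`, `p`, `chisq`, `score_cutoff`,
#'   `uninformative`.
#' @export
evaluateCombination <- function(genes, cohort, directions, minprop = 0.1) {
  if (anyDuplicated(genes)) stop("duplicate genes in combination")
  pp <- .pool_points(genes, directions, cohort, minprop)
  scores <- as.integer(rowSums(pp$points))
  cl <- tryCatch(classifyHighLow(scores, pp$time, pp$event, minprop),
                 error = function(e) NULL)
  if (is.null(cl))
    return(list(genes = sort(genes), p = 1, chisq = 0,
                score_cutoff = NA_real_, uninformative = TRUE))
  list(genes = sort(genes), p = cl$p, chisq = cl$chisq,
       score_cutoff = cl$score_cutoff, uninformative = FALSE)
}

# internal beam state: list(k, keys, genes (list), scores (n x |beam| int
# matrix), p, chisq, cutoff)
.beam_order <- function(p, keys, chisq) {
  order(p, -chisq, keys, method = "radix")
}

.eval_extensions <- function(parent_scores, P, parent_idx, gene_idx,
                             surv_ord, minprop) {
  res <- cpp_beam_eval(parent_scores, P, as.integer(parent_idx),
                       as.integer(gene_idx), surv_ord$ord, surv_ord$time_o,
                       surv_ord$event_o, minprop)
  p <- ifelse(res[, "admissible"] > 0,
              stats::pchisq(res[, "chisq"], 1L, lower.tail = FALSE), 1)
  list(p = p, chisq = res[, "chisq"], cutoff = res[, "cutoff"],
       uninformative = res[, "admissible"] == 0)
}

#' One beam-search step
#'
#' Extends every beam member by every pool gene it does not already
#' contain, deduplicates extensions by set identity, evaluates each
#' extension's recurrence-score classifier, and retains the top `B` by
#' log-rank p value. Ties at the B-th rank are broken by lexicographic
#' gene order, making the step fully deterministic.
#'
#' @param state beam state from [beamRefine()]'s internals (list with
#'   `k`, `genes`, `scores`, `p`, `chisq`, `cutoff`, `keys`).
#' @param pool candidate gene symbols (columns of the point matrix).
#' @param points n x G 0/1 point matrix for the pool.
#' @param surv_ord precomputed survival ordering (internal).
#' @param B beam width (may be `Inf`).
#' @param minprop minimum group fraction.
#' @return the next beam state with `k + 1`-gene members.
#' @keywords internal
.beam_step <- function(state, pool, points, surv_ord, B, minprop) {
  if (length(state$genes) == 0L) stop("empty beam")
  G <- length(pool)
  # candidate extensions: (parent, gene not in parent)
  parent_idx <- integer(); gene_idx <- integer(); keys <- character()
  for (b in seq_along(state$genes)) {
    add <- which(!(pool %in% state$genes[[b]]))
    parent_idx <- c(parent_idx, rep.int(b, length(add)))
    gene_idx <- c(gene_idx, add)
  }
  if (length(parent_idx) == 0L) stop("no extension possible: pool exhausted")
  keys <- vapply(seq_along(parent_idx), function(e)
    .combo_key(c(state$genes[[parent_idx[e]]], pool[gene_idx[e]])),
    character(1L))
  keep <- !duplicated(keys)
  parent_idx <- parent_idx[keep]; gene_idx <- gene_idx[keep]
  keys <- keys[keep]
  ev <- .eval_extensions(state$scores, points, parent_idx, gene_idx,
                         surv_ord, minprop)
  ord <- .beam_order(ev$p, keys, ev$chisq)
  take <- ord[seq_len(min(B, length(ord)))]
  new_genes <- lapply(take, function(e)
    sort(c(state$genes[[parent_idx[e]]], pool[gene_idx[e]])))
  new_scores <- state$scores[, parent_idx[take], drop = FALSE] +
    points[, gene_idx[take], drop = FALSE]
  storage.mode(new_scores) <- "integer"
  list(k = state$k + 1L, genes = new_genes, scores = new_scores,
       p = ev$p[take], chisq = ev$chisq[take], cutoff = ev$cutoff[take],
       keys = keys[take])
}

#' Beam-search refinement of a gene signature
#'
#' Breadth-limited combinatorial search for the gene subset whose
#' recurrence-score classifier is most significantly associated with RFS.
#' All 2-gene combinations from the pool are evaluated and the top `B`
#' kept; each subsequent step adds one more gene from the remaining pool
#' genes to every retained combination, keeping the top `B` at each size,
#' until `max_k` genes. The trace records the most significant
#' combination at every size.
#'
#' @param pool candidate gene symbols (>= 2).
#' @param directions named character vector (`"favorable"`/
#'   `"unfavorable"`) covering the pool.
#' @param cohort a [SurvCohort-class] (typically pooled training data).
#' @param B beam width (default 2000; use `Inf` for exhaustive search of
#'   small pools).
#' @param max_k largest combination size (default: pool size).
#' @param minprop minimum group fraction for cutpoints.
#' @param prune_once if TRUE, the beam is truncated to `B` only at size 2
#'   and grows unboundedly afterwards (alternative reading of a
#'   single-pruning search); default FALSE keeps width `B` at every size.
#' @return a [RefinementTrace-class].
#' @export
beamRefine <- function(pool, directions, cohort, B = 2000,
                       max_k = length(pool), minprop = 0.1,
                       prune_once = FALSE) {
  pool <- as.character(pool)
  if (length(pool) < 2L) stop("pool must contain at least 2 genes")
  if (anyDuplicated(pool)) stop("duplicate genes in pool")
  if (!all(pool %in% names(directions)))
    stop("directions missing for some pool genes")
  max_k <- min(max_k, length(pool))
  pp <- .pool_points(pool, directions, cohort, minprop)
  surv_ord <- local({
    ord <- order(pp$time)
    list(ord = as.integer(ord), time_o = pp$time[ord],
         event_o = as.integer(pp$event[ord]))
  })
  P <- pp$points
  n <- nrow(P)

  # size-2 seeds: all C(G, 2) pairs as single-gene parents + one extension
  pairs <- utils::combn(length(pool), 2L)
  ev <- .eval_extensions(P, P, pairs[1L, ], pairs[2L, ], surv_ord, minprop)
  keys <- vapply(seq_len(ncol(pairs)), function(e)
    .combo_key(pool[pairs[, e]]), character(1L))
  ord <- .beam_order(ev$p, keys, ev$chisq)
  take <- ord[seq_len(min(B, length(ord)))]
  state <- list(k = 2L,
                genes = lapply(take, function(e) sort(pool[pairs[, e]])),
                scores = {
                  s <- P[, pairs[1L, take], drop = FALSE] +
                    P[, pairs[2L, take], drop = FALSE]
                  storage.mode(s) <- "integer"; s
                },
                p = ev$p[take], chisq = ev$chisq[take],
                cutoff = ev$cutoff[take], keys = keys[take])

  trace <- list(.trace_row(state))
  while (state$k < max_k) {
    width <- if (prune_once) Inf else B
    state <- .beam_step(state, pool, P, surv_ord, width, minprop)
    trace[[length(trace) + 1L]] <- .trace_row(state)
  }
  tb <- do.call(rbind, trace)
  rownames(tb) <- NULL
  methods::new("RefinementTrace", table = tb, pool = pool,
               directions = directions[pool], beamWidth = as.numeric(B),
               cohortName = cohortName(cohort))
}

.trace_row <- function(state) {
  best <- .beam_order(state$p, state$keys, state$chisq)[1L]
  data.frame(k = state$k, p = state$p[best], chisq = state$chisq[best],
             score_cutoff = state$cutoff[best],
             genes = paste(state$genes[[best]], collapse = ","),
             stringsAsFactors = FALSE)
}

#' Select the signature size from a refinement trace
#'
#' Picks `k* = argmax -log10(p)` over the trace (the smallest size on
#' ties) and returns the winning combination as a [GeneSignature-class]
#' with its score cut-off frozen for the search cohort.
#'
#' @param trace a [RefinementTrace-class].
#' @return list with `k`, `p`, and `signature`.
#' @export
selectSignatureSize <- function(trace) {
  tb <- trace@table
  if (nrow(tb) == 0L) stop("empty refinement trace")
  best <- which(tb$p == min(tb$p))
  best <- best[which.min(tb$k[best])]
  genes <- strsplit(tb$genes[best], ",", fixed = TRUE)[[1L]]
  sig <- GeneSignature(genes, unname(trace@directions[genes]),
                       score_cutoff = setNames(tb$score_cutoff[best],
                                               trace@cohortName))
  list(k = tb$k[best], p = tb$p[best], signature = sig)
}

#' Serialize a refinement trace
#'
#' Writes the per-size best combinations as TSV (`k`, `p`, `chisq`,
#' `score_cutoff`, `genes`) or JSON.
#'
#' @param trace a [RefinementTrace-class].
#' @param path output path; `.json` extension selects JSON.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(trace@table, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(trace@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
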