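#' Cohort of tumor expression profiles with survival outcomes
#'
#' `SurvCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' cohort name. The single assay `"exprs"` holds a genes x samples
#' expression matrix (platform-normalized scale); `colData` carries the
#' survival outcomes (`rfs_time`, `rfs_event`, optionally `os_time`,
#' `os_event`) and the clinical covariates (`pt`, `grade`, `msi`, `kras`,
#' `age`, `sex`), any of which may be missing except the RFS outcome.
#'
#' @slot cohortName single character, the cohort label.
#' @seealso [SurvCohort()] for construction from matrices/tables.
#' @aliases SurvCohort-class
#' @exportClass SurvCohort
setClass("SurvCohort",
  contains = "SummarizedExperiment",
  representation(cohortName = "character")
)

setValidity("SurvCohort", function(object) {
  msg <- character()
  if (length(object@cohortName) != 1L || is.na(object@cohortName) ||
      !nzchar(object@cohortName))
    msg <- c(msg, "'cohortName' must be a single non-empty string")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("rfs_time", "rfs_event") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'rfs_time' and 'rfs_event'")
  } else {
    tm <- cd$rfs_time
    ev <- cd$rfs_event
    if (anyNA(tm) || anyNA(ev))
      msg <- c(msg, "RFS time/event must be complete for every sample")
    else {
      if (any(tm < 0)) msg <- c(msg, "rfs_time must be nonnegative")
      if (!all(ev %in% c(0, 1))) msg <- c(msg, "rfs_event must be 0/1")
    }
  }
  if (nrow(object) > 0) {
    m <- SummarizedExperiment::assay(object)
    if (!all(is.finite(m))) msg <- c(msg, "expression values must be finite")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate gene symbols are not allowed in a cohort")
  }
  if (length(msg)) msg else TRUE
})

#' Pooled multi-cohort expression/survival data
#'
#' `PooledSurvCohort` is a [SurvCohort-class] whose samples come from
#' several source cohorts; `colData$source` records each sample's origin.
#' Pooled cohorts are built by [poolCohorts()] from per-cohort z-scored
#' data, so within each source cohort every retained gene has mean 0 and
#' unit sample standard deviation.
#'
#' @aliases PooledSurvCohort-class
#' @exportClass PooledSurvCohort
setClass("PooledSurvCohort", contains = "SurvCohort")

setValidity("PooledSurvCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"source" %in% colnames(cd))
    return("colData must contain a 'source' column")
  TRUE
})

#' NanoString-style raw count table
#'
#' `NanoStringSet` extends [SummarizedExperiment::SummarizedExperiment]
#' with probe-class annotation. The assay `"counts"` is a nonnegative
#' probes x samples matrix; `rowData$probe_class` labels each probe as
#' `endogenous`, `housekeeping` or `positive_control`. The housekeeping
#' gene symbols are kept in `metadata(x)$hk_genes` (defaulting to the
#' six-gene colorectal reference panel, see [nanostringHousekeeping()]).
#'
#' @aliases NanoStringSet-class
#' @exportClass NanoStringSet
setClass("NanoStringSet", contains = "SummarizedExperiment")

setValidity("NanoStringSet", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!"probe_class" %in% colnames(rd))
    return("rowData must contain 'probe_class'")
  cls <- as.character(rd$probe_class)
  ok <- c("endogenous", "housekeeping", "positive_control")
  if (!all(cls %in% ok))
    msg <- c(msg, sprintf("probe_class must be one of %s",
                          paste(ok, collapse = ", ")))
  m <- SummarizedExperiment::assay(object)
  if (any(m < 0) || !all(is.finite(m)))
    msg <- c(msg, "counts must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Gene signature with direction-specific scoring cut-offs
#'
#' A `GeneSignature` is an ordered set of genes with prognostic directions
#' (`"unfavorable"`: high expression implies poor survival, scores a point
#' above its cut-off; `"favorable"`: high expression implies good survival,
#' scores a point below its cut-off). Per-cohort expression cut-offs for
#' each gene and a per-cohort cut-off on the summed recurrence score may be
#' frozen into the object, so a trained signature can be applied unchanged
#' to new samples.
#'
#' @slot genes character vector of gene symbols (no duplicates).
#' @slot directions character vector (`"favorable"`/`"unfavorable"`),
#'   parallel to `genes`.
#' @slot cutoffs named list: cohort name -> named numeric vector of
#'   per-gene expression cut-offs.
#' @slot scoreCutoff named numeric: cohort name -> recurrence-score
#'   cut-off for high/low classification.
#' @aliases GeneSignature-class
#' @exportClass GeneSignature
setClass("GeneSignature",
  representation(genes = "character", directions = "character",
                 cutoffs = "list", scoreCutoff = "numeric")
)

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "signature has no genes")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in signature")
  if (length(object@directions) != length(object@genes))
    msg <- c(msg, "directions must parallel genes")
  if (!all(object@directions %in% c("favorable", "unfavorable")))
    msg <- c(msg, "directions must be 'favorable' or 'unfavorable'")
  for (nm in names(object@cutoffs)) {
    co <- object@cutoffs[[nm]]
    if (!all(names(co) %in% object@genes))
      msg <- c(msg, sprintf("cutoffs for cohort '%s' name unknown genes", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Beam-search refinement trace
#'
#' Records, for every combination size k visited by [beamRefine()], the most
#' significant gene combination found: its log-rank p value, chi-square,
#' score cut-off and member genes. `selectSignatureSize()` picks the size
#' maximizing -log10(p).
#'
#' @slot table data.frame with columns `k`, `p`, `chisq`, `score_cutoff`,
#'   `genes` (comma-separated member genes).
#' @slot pool character vector, the candidate genes searched.
#' @slot directions named character, direction per pool gene.
#' @slot beamWidth integer beam width used.
#' @slot cohortName cohort the search ran on.
#' @aliases RefinementTrace-class
#' @exportClass RefinementTrace
setClass("RefinementTrace",
  representation(table = "data.frame", pool = "character",
                 directions = "character", beamWidth = "numeric",
                 cohortName = "character")
)

setValidity("RefinementTrace", function(object) {
  tb <- object@table
  need <- c("k", "p", "chisq", "score_cutoff", "genes")
  if (!all(need %in% colnames(tb)))
    return(sprintf("trace table must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(tb) && any(diff(tb$k) <= 0))
    return("trace table must be ordered by increasing k")
  TRUE
})
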