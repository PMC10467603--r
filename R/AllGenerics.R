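#' @name prognosig-accessors
#' @title Accessors for prognosig classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x a prognosig object.
#' @param endpoint `"RFS"` (relapse-free survival, default) or `"OS"`.
#' @return `cohortName`: the cohort label. `exprs`: the genes x samples
#'   expression matrix. `survOutcomes`: a [survival::Surv] object for the
#'   requested endpoint. `sourceCohort`: per-sample source cohort labels.
#'   `signatureGenes`/`signatureDirections`: signature membership.
NULL

#' @rdname prognosig-accessors
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname prognosig-accessors
#' @export
setMethod("cohortName", "SurvCohort", function(x) x@cohortName)

#' @rdname prognosig-accessors
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname prognosig-accessors
#' @export
setMethod("exprs", "SurvCohort", function(x) SummarizedExperiment::assay(x))

#' @rdname prognosig-accessors
#' @export
setGeneric("survOutcomes", function(x, endpoint = "RFS")
  standardGeneric("survOutcomes"))

#' @rdname prognosig-accessors
#' @export
setMethod("survOutcomes", "SurvCohort", function(x, endpoint = "RFS") {
  endpoint <- match.arg(toupper(endpoint), c("RFS", "OS"))
  cd <- SummarizedExperiment::colData(x)
  if (endpoint == "RFS") {
    survival::Surv(cd$rfs_time, cd$rfs_event)
  } else {
    if (!all(c("os_time", "os_event") %in% colnames(cd)))
      stop("cohort '", cohortName(x), "' carries no OS outcome")
    keep <- !is.na(cd$os_time) & !is.na(cd$os_event)
    if (!all(keep))
      stop("OS outcome incomplete; subset the cohort to samples with OS data")
    survival::Surv(cd$os_time, cd$os_event)
  }
})

#' @rdname prognosig-accessors
#' @export
setGeneric("sourceCohort", function(x) standardGeneric("sourceCohort"))

#' @rdname prognosig-accessors
#' @export
setMethod("sourceCohort", "PooledSurvCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$source))

#' @rdname prognosig-accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname prognosig-accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname prognosig-accessors
#' @export
setGeneric("signatureDirections", function(x)
  standardGeneric("signatureDirections"))

#' @rdname prognosig-accessors
#' @export
setMethod("signatureDirections", "GeneSignature", function(x)
  setNames(x@directions, x@genes))

setMethod("show", "SurvCohort", function(object) {
  cat(sprintf("%s cohort '%s': %d genes x %d samples\n",
              class(object), object@cohortName,
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  ev <- sum(cd$rfs_event)
  cat(sprintf("  RFS events: %d/%d; median follow-up %.1f months\n",
              ev, ncol(object), stats::median(cd$rfs_time)))
  if ("source" %in% colnames(cd)) {
    src <- table(cd$source)
    cat(sprintf("  sources: %s\n",
                paste(sprintf("%s (%d)", names(src), src), collapse = ", ")))
  }
})

setMethod("show", "NanoStringSet", function(object) {
  cls <- table(SummarizedExperiment::rowData(object)$probe_class)
  cat(sprintf("NanoStringSet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  probe classes: %s\n",
              paste(sprintf("%s (%d)", names(cls), cls), collapse = ", ")))
})

setMethod("show", "GeneSignature", function(object) {
  nu <- sum(object@directions == "unfavorable")
  nf <- sum(object@directions == "favorable")
  cat(sprintf("GeneSignature: %d genes (%d unfavorable, %d favorable)\n",
              length(object@genes), nu, nf))
  cat("  genes:", paste(object@genes, collapse = ", "), "\n")
  if (length(object@cutoffs))
    cat("  frozen cut-offs for cohorts:",
        paste(names(object@cutoffs), collapse = ", "), "\n")
})

setMethod("show", "RefinementTrace", function(object) {
  tb <- object@table
  cat(sprintf("RefinementTrace over %d candidate genes (beam width %s)\n",
              length(object@pool),
              if (is.finite(object@beamWidth)) object@beamWidth else "Inf"))
  if (nrow(tb)) {
    best <- tb[which.max(-log10(tb$p)), ]
    cat(sprintf("  sizes k = %d..%d; best at k = %d (log-rank p = %.3g)\n",
                min(tb$k), max(tb$k), best$k, best$p))
  }
})
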