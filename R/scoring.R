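#' Construct a gene signature
#'
#' @param genes gene symbols.
#' @param directions `"favorable"`/`"unfavorable"` per gene (recycled if
#'   length 1).
#' @param cutoffs optional named list of per-cohort gene cut-offs.
#' @param score_cutoff optional named numeric of per-cohort score cut-offs.
#' @return a [GeneSignature-class].
#' @export
GeneSignature <- function(genes, directions, cutoffs = list(),
                          score_cutoff = numeric()) {
  if (length(directions) == 1L)
    directions <- rep(directions, length(genes))
  methods::new("GeneSignature", genes = as.character(genes),
               directions = as.character(directions),
               cutoffs = cutoffs, scoreCutoff = score_cutoff)
}

#' Direction-specific 0/1 gene point
#'
#' An unfavorable gene scores 1 when expression lies strictly above its
#' cut-off; a favorable gene scores 1 strictly below it. Expression exactly
#' at the cut-off scores 0 under either direction (conservative tie
#' convention; measure-zero for continuous data).
#'
#' @param x expression value(s), finite.
#' @param cutoff cut-off value.
#' @param direction `"favorable"` or `"unfavorable"`.
#' @return integer 0/1, vectorized over `x`.
#' @export
genePoint <- function(x, cutoff, direction) {
  direction <- match.arg(direction, c("favorable", "unfavorable"))
  if (any(!is.finite(x))) stop("expression must be finite")
  if (direction == "unfavorable") as.integer(x > cutoff)
  else as.integer(x < cutoff)
}

# per-gene cut-offs for a signature in a cohort: frozen ones if present,
# otherwise computed by the maximally selected log-rank scan
.signature_cutoffs <- function(sig, cohort, minprop = 0.1) {
  nm <- cohortName(cohort)
  if (nm %in% names(sig@cutoffs)) {
    co <- sig@cutoffs[[nm]]
    missing <- setdiff(sig@genes, names(co))
    if (length(missing) == 0L) return(co[sig@genes])
  }
  m <- exprs(cohort)
  absent <- setdiff(sig@genes, rownames(m))
  if (length(absent))
    stop("signature gene(s) absent from cohort '", nm, "': ",
         paste(absent, collapse = ", "))
  sv <- survOutcomes(cohort)
  vapply(sig@genes, function(g)
    optimalCutpoint(m[g, ], sv[, 1L], sv[, 2L], minprop)$cutpoint,
    numeric(1L))
}

#' Freeze per-cohort gene cut-offs into a signature
#'
#' Computes (or recomputes) the per-gene optimal cut-offs on `cohort` and
#' stores them in the signature, so it can later be applied with frozen
#' cut-offs to new samples.
#'
#' @param sig a [GeneSignature-class].
#' @param cohort a [SurvCohort-class].
#' @param minprop minimum group fraction for the cutpoint scan.
#' @return the signature with `cutoffs[[cohortName(cohort)]]` filled.
#' @export
trainCutoffs <- function(sig, cohort, minprop = 0.1) {
  co <- .signature_cutoffs(sig, cohort, minprop)
  sig@cutoffs[[cohortName(cohort)]] <- co
  methods::validObject(sig)
  sig
}

#' Per-sample recurrence scores for a signature
#'
#' Sums the direction-specific 0/1 gene points over all signature genes:
#' a high score marks high expression of unfavorable genes and low
#' expression of favorable genes. Cut-offs frozen in the signature for
#' this cohort are used when present, otherwise computed from the cohort's
#' RFS outcome.
#'
#' @param sig a [GeneSignature-class].
#' @param cohort a [SurvCohort-class] containing all signature genes.
#' @param minprop minimum group fraction for cutpoint computation.
#' @return named integer vector in `[0, length(signatureGenes(sig))]`.
#' @export
recurrenceScores <- function(sig, cohort, minprop = 0.1) {
  m <- exprs(cohort)
  absent <- setdiff(sig@genes, rownames(m))
  if (length(absent))
    stop("signature gene(s) absent from cohort '", cohortName(cohort),
         "': ", paste(absent, collapse = ", "))
  cuts <- .signature_cutoffs(sig, cohort, minprop)
  pts <- vapply(seq_along(sig@genes), function(i)
    genePoint(m[sig@genes[i], ], cuts[[i]], sig@directions[i]),
    integer(ncol(m)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)  # single sample
  setNames(as.integer(rowSums(pts)), colnames(m))
}

#' Classify samples as high/low recurrence score
#'
#' Applies the maximally selected log-rank cutpoint scan to the integer
#' recurrence score; samples strictly above the selected cut-off are
#' "high". The cut-off is reproducible bit-exactly for fixed inputs.
#'
#' @param scores integer recurrence scores (>= 2 distinct values).
#' @param time,event RFS outcome.
#' @param minprop minimum group fraction.
#' @return list with `labels` (character "high"/"low" per sample),
#'   `score_cutoff`, `chisq`, `p`.
#' @export
classifyHighLow <- function(scores, time, event, minprop = 0.1) {
  if (length(unique(scores)) < 2L)
    stop("constant recurrence scores cannot be classified")
  cp <- optimalCutpoint(as.numeric(scores), time, event, minprop)
  labels <- ifelse(scores > cp$cutpoint, "high", "low")
  list(labels = setNames(labels, names(scores)),
       score_cutoff = cp$cutpoint, chisq = cp$chisq, p = cp$p)
}

# symbol aliases: non-official symbols appearing in signature definitions
.symbol_aliases <- c(KI67 = "MKI67")

.resolve_symbol <- function(genes, available) {
  out <- genes
  for (i in seq_along(out)) {
    if (!(out[i] %in% available) && out[i] %in% names(.symbol_aliases))
      out[i] <- .symbol_aliases[[out[i]]]
  }
  out
}

#' Oncotype DX colon unscaled recurrence score
#'
#' Published linear comparator score over seven genes:
#' `RS_U = 0.15 * (BGN + FAP + INHBA)/3 - 0.3 * (MYBL2 + KI67 + MYC)/3 +
#' 0.15 * GADD45B`. `KI67` is resolved to the official symbol `MKI67` when
#' the input uses it.
#'
#' @param expr named numeric vector or genes x samples matrix containing
#'   the seven genes.
#' @return numeric RS_U per sample.
#' @export
oncotypeRsU <- function(expr) {
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1L,
                                         dimnames = list(names(expr), "s1"))
  need <- c("BGN", "FAP", "INHBA", "MYBL2", "KI67", "MYC", "GADD45B")
  have <- rownames(expr)
  resolved <- .resolve_symbol(need, have)
  missing <- resolved[!(resolved %in% have)]
  if (length(missing))
    stop("missing Oncotype gene(s): ", paste(missing, collapse = ", "))
  g <- function(sym) expr[resolved[match(sym, need)], ]
  rs <- 0.15 * (g("BGN") + g("FAP") + g("INHBA")) / 3 -
    0.30 * (g("MYBL2") + g("KI67") + g("MYC")) / 3 +
    0.15 * g("GADD45B")
  if (!all(is.finite(rs))) stop("Oncotype inputs must be finite")
  rs
}

#' Cut-off-based Oncotype DX colon recurrence score
#'
#' Applies this package's 0/1 cut-off scoring to the seven Oncotype DX
#' colon genes, with directions taken from the signs of the RS_U formula
#' (BGN, FAP, INHBA, GADD45B unfavorable; MYBL2, KI67/MKI67, MYC
#' favorable). The resulting integer score ranges over `[0, 7]`.
#'
#' @param cohort a [SurvCohort-class] containing the seven genes.
#' @param minprop minimum group fraction for cutpoints.
#' @return list with `scores` (integer vector) and `signature` (the
#'   7-gene [GeneSignature-class] with trained cut-offs).
#' @export
oncotypeScore <- function(cohort, minprop = 0.1) {
  sig <- oncotypeSignature(available = rownames(exprs(cohort)))
  sig <- trainCutoffs(sig, cohort, minprop)
  list(scores = recurrenceScores(sig, cohort, minprop), signature = sig)
}

#' Packaged signature definitions
#'
#' `prognosticSignature15()` returns the 15-gene relapse signature (nine
#' unfavorable, six favorable genes); `oncotypeSignature()` the 7-gene
#' Oncotype DX colon set with RS_U-sign directions. Definitions are read
#' from JSON files under `inst/extdata`.
#'
#' @param available optional character vector of available gene symbols,
#'   used to resolve aliases (e.g. KI67 -> MKI67).
#' @return a [GeneSignature-class].
#' @export
prognosticSignature15 <- function() {
  readSignature(system.file("extdata", "signature15.json",
                            package = "prognosig", mustWork = TRUE))
}

#' @rdname prognosticSignature15
#' @export
oncotypeSignature <- function(available = NULL) {
  sig <- readSignature(system.file("extdata", "oncotype7.json",
                                   package = "prognosig", mustWork = TRUE))
  if (!is.null(available)) sig@genes <- .resolve_symbol(sig@genes, available)
  sig
}

#' Read/write signature definition files
#'
#' JSON with fields `genes`, `directions`, and optional `cutoffs` (cohort
#' -> gene -> value) and `score_cutoff` (cohort -> value).
#'
#' @param path file path.
#' @param sig a [GeneSignature-class] (for writing).
#' @return `readSignature`: a [GeneSignature-class]; `writeSignature`:
#'   `path`, invisibly.
#' @export
readSignature <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoffs <- list()
  if (!is.null(js$cutoffs))
    cutoffs <- lapply(js$cutoffs, function(co) unlist(co))
  score_cutoff <- numeric()
  if (!is.null(js$score_cutoff)) score_cutoff <- unlist(js$score_cutoff)
  GeneSignature(js$genes, js$directions, cutoffs, score_cutoff)
}

#' @rdname readSignature
#' @export
writeSignature <- function(sig, path) {
  out <- list(genes = sig@genes, directions = sig@directions)
  if (length(sig@cutoffs)) out$cutoffs <- lapply(sig@cutoffs, as.list)
  if (length(sig@scoreCutoff)) out$score_cutoff <- as.list(sig@scoreCutoff)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
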