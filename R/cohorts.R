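#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV with one identifier column (probes or genes as rows) and
#' one header row of sample ids. Duplicate probe ids are retained — probe
#' rows mapping to the same gene are merged later by [collapseProbes()].
#' Every data cell must parse as a finite number; a non-numeric or missing
#' cell is a parse error naming its row and column.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension by default
#'   (`","` for `.csv`, tab otherwise).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`,
#'   in which case the matrix is transposed after reading.
#' @return numeric matrix (genes/probes x samples) with dimnames.
#' @export
readExpressionMatrix <- function(path, sep = NULL,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression file: ", path)
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (orientation == "samples_in_rows") num <- t(num)
  num
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [readExpressionMatrix()]; values are written with full
#' precision (17 significant digits) so finite decimals round-trip exactly.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path; `.csv` extension selects comma separation.
#' @param id_col name for the identifier column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, id_col = "gene") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' For genes targeted by multiple probes, the gene-level value is the sum of
#' its probes' values in every sample. Probes without a map entry are
#' dropped with a warning.
#'
#' @param m probes x samples matrix (probe ids as rownames).
#' @param probe_map named character vector or two-column data.frame
#'   (probe, gene).
#' @return genes x samples matrix with one row per gene.
#' @export
collapseProbes <- function(m, probe_map) {
  if (is.data.frame(probe_map))
    probe_map <- setNames(as.character(probe_map[[2L]]),
                          as.character(probe_map[[1L]]))
  probes <- rownames(m)
  mapped <- probes %in% names(probe_map)
  if (!any(mapped))
    stop("no probe in the matrix has a probe-map entry")
  if (!all(mapped))
    warning(sum(!mapped), " unmapped probe(s) dropped: ",
            paste(utils::head(probes[!mapped], 5L), collapse = ", "),
            if (sum(!mapped) > 5L) ", ..." else "")
  m <- m[mapped, , drop = FALSE]
  gene <- probe_map[rownames(m)]
  out <- rowsum(m, group = gene, reorder = TRUE)
  out
}

#' Read a clinical table
#'
#' CSV with columns `sample_id`, `rfs_time_months`, `rfs_event`, and
#' optionally `os_time_months`, `os_event`, `pt`, `grade`, `msi`, `kras`,
#' `age`, `sex`. Optional columns may be absent or empty.
#'
#' @param path file path.
#' @return data.frame keyed by `sample_id`.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ok <- "sample_id" %in% colnames(df) && "rfs_event" %in% colnames(df) &&
    any(c("rfs_time_months", "rfs_time") %in% colnames(df))
  if (!ok)
    stop("clinical table must contain columns: sample_id, ",
         "rfs_time_months (or rfs_time), rfs_event")
  df
}

.covariate_levels <- list(
  pt = c("3", "4"), grade = c("1", "2", "3"),
  msi = c("MSS", "MSI"), kras = c("wt", "mut"))

#' Construct a survival cohort
#'
#' Joins an expression matrix to a clinical table by sample id. Samples
#' lacking a complete RFS outcome, or absent from either input, are
#' excluded (with a message) per the complete-data rule; covariate values
#' outside their allowed levels are rejected.
#'
#' @param exprs genes x samples numeric matrix (duplicate gene rows must be
#'   collapsed first, see [collapseProbes()]).
#' @param clinical data.frame as returned by [readClinicalTable()], or one
#'   with columns `sample_id`, `rfs_time`/`rfs_time_months`, `rfs_event`
#'   (and optional `os_*`, covariates).
#' @param name cohort label.
#' @return a [SurvCohort-class].
#' @export
SurvCohort <- function(exprs, clinical, name) {
  cl <- as.data.frame(clinical, stringsAsFactors = FALSE)
  if ("rfs_time_months" %in% colnames(cl) && !"rfs_time" %in% colnames(cl))
    cl$rfs_time <- cl$rfs_time_months
  if ("os_time_months" %in% colnames(cl) && !"os_time" %in% colnames(cl))
    cl$os_time <- cl$os_time_months
  if (!all(c("sample_id", "rfs_time", "rfs_event") %in% colnames(cl)))
    stop("clinical data must provide sample_id, rfs_time(_months), rfs_event")
  if (anyDuplicated(cl$sample_id)) stop("duplicate sample_id in clinical data")
  rownames(cl) <- cl$sample_id

  common <- intersect(colnames(exprs), cl$sample_id)
  complete <- common[!is.na(cl[common, "rfs_time"]) &
                     !is.na(cl[common, "rfs_event"])]
  dropped <- setdiff(union(colnames(exprs), cl$sample_id), complete)
  if (length(dropped))
    message(length(dropped), " sample(s) excluded from cohort '", name,
            "' for incomplete expression or RFS data")
  if (length(complete) == 0L)
    stop("no sample with complete expression and RFS data")
  cl <- cl[complete, setdiff(colnames(cl), "sample_id"), drop = FALSE]
  for (cov in names(.covariate_levels)) {
    if (cov %in% colnames(cl)) {
      v <- as.character(cl[[cov]])
      v[!is.na(v) & v == ""] <- NA
      ok <- is.na(v) | v %in% .covariate_levels[[cov]]
      if (!all(ok))
        stop("covariate '", cov, "' has values outside {",
             paste(.covariate_levels[[cov]], collapse = ", "), "}")
      cl[[cov]] <- v
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs[, complete, drop = FALSE]),
    colData = S4Vectors::DataFrame(cl))
  methods::new("SurvCohort", se, cohortName = as.character(name))
}

#' Z-score each gene across a cohort's tumors
#'
#' Transforms each gene row to `(x - mean) / sd` using the sample standard
#' deviation (n - 1 divisor). Genes with zero variance carry no prognostic
#' information and are removed with a warning.
#'
#' @param cohort a [SurvCohort-class] with at least 2 samples.
#' @return the cohort with standardized expression (possibly fewer genes).
#' @export
zscoreGenes <- function(cohort) {
  stopifnot(methods::is(cohort, "SurvCohort"))
  m <- exprs(cohort)
  if (ncol(m) < 2L) stop("z-scoring requires at least 2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  keep <- s > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) removed: ",
            paste(utils::head(rownames(m)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  if (!any(keep)) stop("all genes have zero variance")
  z <- (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
  out <- cohort[keep, ]
  SummarizedExperiment::assay(out) <- z
  methods::validObject(out)
  out
}

#' Merge z-scored cohorts into one pooled cohort
#'
#' Restricts to the intersection of the member cohorts' gene sets and
#' concatenates samples. Sample ids are prefixed `"cohort:sample"` so
#' provenance is lossless and collisions impossible; `colData$source`
#' records the origin. Inputs must already be per-gene z-scored (see
#' [zscoreGenes()]); this is checked to 1e-6.
#'
#' @param cohorts list of [SurvCohort-class] objects (>= 2).
#' @return a [PooledSurvCohort-class].
#' @export
poolCohorts <- function(cohorts) {
  if (length(cohorts) < 2L) stop("pooling requires at least 2 cohorts")
  stopifnot(all(vapply(cohorts, methods::is, TRUE, "SurvCohort")))
  genes <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(genes) == 0L) stop("cohorts share no genes")
  cd_cols <- Reduce(intersect, lapply(cohorts, function(x)
    colnames(SummarizedExperiment::colData(x))))
  # repeated cohort labels (e.g. a cohort pooled with itself) are
  # disambiguated so prefixed sample ids stay unique
  labels <- make.unique(vapply(cohorts, cohortName, ""), sep = "#")
  mats <- list(); cds <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    m <- exprs(co)[genes, , drop = FALSE]
    mu <- rowMeans(m); s <- apply(m, 1L, stats::sd)
    if (max(abs(mu)) > 1e-6 || max(abs(s - 1)) > 1e-6)
      stop("cohort '", cohortName(co),
           "' is not z-scored per gene; run zscoreGenes() first")
    colnames(m) <- paste(labels[i], colnames(m), sep = ":")
    cd <- SummarizedExperiment::colData(co)[, cd_cols, drop = FALSE]
    rownames(cd) <- colnames(m)
    cd$source <- labels[i]
    mats[[i]] <- m
    cds[[i]] <- cd
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = do.call(cbind, mats)),
    colData = do.call(rbind, cds))
  methods::new("PooledSurvCohort", se, cohortName = "pooled")
}
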