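#' Default housekeeping panel
#'
#' The six-gene reference panel used for colorectal tumors (lowest
#' between-tumor variation): AKAP1, DNAJC14, SF3A1, TBC1D10B, TKL2, TMUB2.
#' `TKL2` is kept as printed in the source panel (the official symbol is
#' likely TLK2); callers may override the panel when constructing a
#' [NanoStringSet-class].
#'
#' @return character vector of six gene symbols.
#' @export
nanostringHousekeeping <- function() {
  c("AKAP1", "DNAJC14", "SF3A1", "TBC1D10B", "TKL2", "TMUB2")
}

#' Construct a NanoString-style count set
#'
#' @param counts nonnegative probes x samples matrix.
#' @param probe_class character vector (`endogenous`, `housekeeping`,
#'   `positive_control`) parallel to the rows.
#' @param hk_genes housekeeping symbols (default [nanostringHousekeeping()]).
#' @return a [NanoStringSet-class].
#' @export
NanoStringSet <- function(counts, probe_class,
                          hk_genes = nanostringHousekeeping()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(probe_class = as.character(probe_class)))
  obj <- methods::new("NanoStringSet", se)
  S4Vectors::metadata(obj)$hk_genes <- hk_genes
  obj
}

#' Read a NanoString-style count CSV
#'
#' Simplified stand-in for instrument exports: columns `probe`, `class`
#' (`endogenous`/`housekeeping`/`positive_control`), then one column per
#' sample.
#'
#' @param path file path.
#' @return a [NanoStringSet-class].
#' @export
readNanoStringCounts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe", "class") %in% colnames(df)))
    stop("count file must have 'probe' and 'class' columns")
  m <- as.matrix(df[, setdiff(colnames(df), c("probe", "class")),
                    drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe
  NanoStringSet(m, df$class)
}

# geometric mean of control-class counts; zero counts are replaced by 0.5
# (control classes only) so log(0) is avoided while nonzero counts keep
# the exact multiplicative scale relations the normalization relies on
.control_geomean <- function(m) {
  m[m == 0] <- 0.5
  exp(colMeans(log(m)))
}

.class_rows <- function(x, cls) {
  which(SummarizedExperiment::rowData(x)$probe_class == cls)
}

#' Positive-control normalization between samples and lanes
#'
#' Scales each sample by (grand geometric mean of positive-control
#' counts) / (that sample's positive-control geometric mean), removing
#' lane/handling variation; positive-control geometric means are
#' equalized across samples afterwards.
#'
#' @param x a [NanoStringSet-class] with positive-control probes.
#' @return the set with all counts rescaled; per-sample factors in
#'   `metadata(x)$pos_factors`.
#' @export
positiveControlNormalize <- function(x) {
  pc <- .class_rows(x, "positive_control")
  if (length(pc) == 0L) stop("no positive-control probes")
  m <- SummarizedExperiment::assay(x)
  zero <- colSums(m[pc, , drop = FALSE]) == 0
  if (any(zero))
    stop("all-zero positive controls in sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  raw_gm <- .control_geomean(m[pc, , drop = FALSE])
  factors <- exp(mean(log(raw_gm))) / raw_gm
  out <- x
  SummarizedExperiment::assay(out) <- sweep(m, 2L, factors, `*`)
  S4Vectors::metadata(out)$pos_factors <- factors
  S4Vectors::metadata(out)$pos_normalized <- TRUE
  out
}

#' Housekeeping normalization to endogenous expression
#'
#' Second normalization step: scales each sample by the grand geometric
#' mean over its housekeeping-probe geometric mean, then returns the
#' endogenous genes only. Requires [positiveControlNormalize()] first.
#'
#' @param x a positive-control-normalized [NanoStringSet-class].
#' @return endogenous genes x samples numeric matrix.
#' @export
housekeepingNormalize <- function(x) {
  if (!isTRUE(S4Vectors::metadata(x)$pos_normalized))
    stop("apply positiveControlNormalize() before housekeeping normalization")
  hk <- .class_rows(x, "housekeeping")
  if (length(hk) == 0L) stop("no housekeeping probes")
  endo <- .class_rows(x, "endogenous")
  if (length(endo) == 0L) stop("no endogenous probes")
  m <- SummarizedExperiment::assay(x)
  zero <- colSums(m[hk, , drop = FALSE]) == 0
  if (any(zero))
    stop("all-zero housekeeping counts in sample(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  gm <- .control_geomean(m[hk, , drop = FALSE])
  factors <- exp(mean(log(gm))) / gm
  sweep(m[endo, , drop = FALSE], 2L, factors, `*`)
}

#' Remove genes with very low average expression
#'
#' Genes whose mean count across samples is strictly below `threshold`
#' (default 10 counts/sample) are removed and listed.
#'
#' @param m genes x samples matrix of (normalized) counts.
#' @param threshold mean-count threshold (> 0).
#' @return list with `matrix` (retained genes) and `removed` (data.frame
#'   of removed genes with their mean counts).
#' @export
lowExpressionFilter <- function(m, threshold = 10) {
  if (threshold < 0) stop("threshold must be nonnegative")
  mu <- rowMeans(m)
  low <- mu < threshold
  if (all(low)) stop("all genes fall below the expression threshold")
  list(matrix = m[!low, , drop = FALSE],
       removed = data.frame(gene = rownames(m)[low],
                            mean_count = unname(mu[low]),
                            stringsAsFactors = FALSE))
}

#' Flag dispersed outlier samples (RLE + PCA)
#'
#' Computes each sample's relative log expression (RLE: log2 ratios to
#' gene-wise medians) and flags samples whose RLE median or IQR, or whose
#' position on the first two principal components, lies more than `k_mad`
#' robust (MAD-based) deviations from the cohort center. Deterministic
#' for fixed input.
#'
#' @param m genes x samples matrix of normalized counts (>= 5 samples).
#' @param k_mad robust-deviation threshold (default 3.5).
#' @return list of class `nanostring_qc` with `excluded_samples`,
#'   `reason` (named character), and the per-sample `metrics` data.frame.
#' @export
qcFlagOutliers <- function(m, k_mad = 3.5) {
  if (ncol(m) < 5L) stop("QC needs at least 5 samples")
  lm2 <- log2(m + 0.5)
  if (stats::var(as.vector(lm2)) == 0) stop("degenerate (constant) matrix")
  rle <- lm2 - apply(lm2, 1L, stats::median)
  rle_med <- apply(rle, 2L, stats::median)
  rle_iqr <- apply(rle, 2L, stats::IQR)
  pc <- stats::prcomp(t(lm2), center = TRUE, scale. = FALSE)
  pcs <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]

  robust_z <- function(v) {
    s <- stats::mad(v)
    if (s == 0) s <- max(stats::sd(v), .Machine$double.eps)
    abs(v - stats::median(v)) / s
  }
  z_med <- robust_z(rle_med)
  z_iqr <- robust_z(rle_iqr)
  z_pc <- apply(pcs, 2L, robust_z)
  flag_rle <- z_med > k_mad | z_iqr > k_mad
  flag_pc <- apply(z_pc > k_mad, 1L, any)
  flagged <- flag_rle | flag_pc
  reason <- character(0)
  if (any(flagged)) {
    reason <- vapply(which(flagged), function(i) {
      parts <- c(if (flag_rle[i]) "dispersed RLE",
                 if (flag_pc[i]) "principal-component outlier")
      paste(parts, collapse = " + ")
    }, character(1L))
    names(reason) <- colnames(m)[flagged]
  }
  structure(list(excluded_samples = colnames(m)[flagged], reason = reason,
                 metrics = data.frame(sample = colnames(m),
                                      rle_median = rle_med,
                                      rle_iqr = rle_iqr,
                                      z_rle_median = z_med,
                                      z_rle_iqr = z_iqr,
                                      row.names = NULL)),
            class = "nanostring_qc")
}

#' Full NanoString normalization + QC pipeline
#'
#' Positive-control normalization, housekeeping normalization, low-mean
#' gene filter, and outlier-sample flagging, returning the cleaned
#' endogenous matrix plus a QC report.
#'
#' @param x a [NanoStringSet-class].
#' @param threshold low-expression threshold (mean counts/sample).
#' @param k_mad QC robust-deviation threshold.
#' @return list with `matrix` (filtered genes x retained samples),
#'   `removed_genes`, `qc` (the `nanostring_qc` report).
#' @export
nanostringNormalize <- function(x, threshold = 10, k_mad = 3.5) {
  norm <- housekeepingNormalize(positiveControlNormalize(x))
  qc <- qcFlagOutliers(norm, k_mad)
  keep <- setdiff(colnames(norm), qc$excluded_samples)
  filt <- lowExpressionFilter(norm[, keep, drop = FALSE], threshold)
  list(matrix = filt$matrix, removed_genes = filt$removed, qc = qc)
}
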