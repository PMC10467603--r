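# small hand-built count set: 2 endogenous, 2 housekeeping, 2 positive
# control probes
tiny_nanostring <- function(counts) {
  NanoStringSet(counts, c("endogenous", "endogenous", "housekeeping",
                          "housekeeping", "positive_control",
                          "positive_control"))
}

test_that("positive-control normalization equalizes control geometric means", {
  m <- rbind(E1 = c(100, 200), E2 = c(50, 100), HK1 = c(300, 600),
             HK2 = c(300, 600), POSA = c(1000, 2000), POSB = c(250, 500))
  colnames(m) <- c("a", "b")
  x <- positiveControlNormalize(tiny_nanostring(m))
  out <- SummarizedExperiment::assay(x)
  gm <- exp(colMeans(log(out[c("POSA", "POSB"), ])))
  expect_equal(gm[["a"]], gm[["b"]], tolerance = 1e-9)
  # identical samples are untouched
  m2 <- m; m2[, 2] <- m2[, 1]
  x2 <- positiveControlNormalize(tiny_nanostring(m2))
  expect_equal(SummarizedExperiment::assay(x2), m2, tolerance = 1e-12)
  # hand geometric means: control geomeans (10, 20, 40) -> factors (2, 1, 0.5)
  m3 <- rbind(E1 = rep(5, 3), E2 = rep(5, 3), HK1 = rep(9, 3),
              HK2 = rep(9, 3),
              POSA = c(5, 10, 20), POSB = c(20, 40, 80))
  colnames(m3) <- c("a", "b", "c")
  x3 <- positiveControlNormalize(tiny_nanostring(m3))
  expect_equal(unname(S4Vectors::metadata(x3)$pos_factors), c(2, 1, 0.5),
               tolerance = 1e-9)
  # an all-zero-control sample is an error naming it
  m4 <- m; m4[c("POSA", "POSB"), "b"] <- 0
  expect_error(positiveControlNormalize(tiny_nanostring(m4)), "b")
})

test_that("housekeeping normalization undoes per-sample scale factors", {
  set.seed(10)
  base <- rbind(E1 = rep(400, 4), E2 = rep(80, 4), HK1 = rep(300, 4),
                HK2 = rep(500, 4), POSA = rep(2000, 4), POSB = rep(100, 4))
  colnames(base) <- paste0("s", 1:4)
  doubled <- base; doubled[, 2] <- 2 * base[, 2]
  norm <- housekeepingNormalize(positiveControlNormalize(
    tiny_nanostring(doubled)))
  # the doubled sample returns to baseline endogenous values
  expect_equal(norm[, 2], norm[, 1], tolerance = 1e-9)
  expect_setequal(rownames(norm), c("E1", "E2"))
  # ordering: the positive-control step is mandatory first
  expect_error(housekeepingNormalize(tiny_nanostring(base)),
               "positiveControlNormalize")
})

test_that("normalization is invariant to scaling any sample's raw counts", {
  set.seed(20)
  m <- matrix(rpois(6 * 6, 300), nrow = 6,
              dimnames = list(c("E1", "E2", "HK1", "HK2", "POSA", "POSB"),
                              paste0("s", 1:6)))
  ref <- housekeepingNormalize(positiveControlNormalize(tiny_nanostring(m)))
  # grand-geomean anchoring rescales the whole matrix by c^(1/n) when one
  # sample is scaled by c, so the invariant is the sample's profile up to
  # one common scalar
  for (c_fac in c(0.5, 3)) {
    m2 <- m; m2[, 3] <- m[, 3] * c_fac
    got <- housekeepingNormalize(positiveControlNormalize(
      tiny_nanostring(m2)))
    ratio <- got[, 3] / ref[, 3]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
    expect_equal(unname(ratio[1]), c_fac^(1 / ncol(m)), tolerance = 1e-9)
  }
})

test_that("low-expression filter removes genes strictly below threshold", {
  m <- rbind(lowA = rep(9.9, 4), edge = rep(10, 4), hi = rep(50, 4))
  colnames(m) <- paste0("s", 1:4)
  res <- lowExpressionFilter(m, threshold = 10)
  expect_equal(res$removed$gene, "lowA")       # 9.9 < 10 removed
  expect_true("edge" %in% rownames(res$matrix)) # exactly 10 retained
  res0 <- lowExpressionFilter(m, threshold = 0)
  expect_equal(nrow(res0$removed), 0L)
  expect_error(lowExpressionFilter(m, threshold = 1000), "all genes")
})

test_that("QC flags gross outliers and passes homogeneous samples", {
  set.seed(30)
  m <- matrix(rpois(40 * 12, 200), nrow = 40,
              dimnames = list(sprintf("E%02d", 1:40), sprintf("s%02d", 1:12)))
  qc <- qcFlagOutliers(m)
  expect_length(qc$excluded_samples, 0L)
  # one sample with all counts x10 is flagged
  m2 <- m; m2[, 5] <- m[, 5] * 10
  qc2 <- qcFlagOutliers(m2)
  expect_true("s05" %in% qc2$excluded_samples)
  expect_error(qcFlagOutliers(m[, 1:4]), "at least 5")
  expect_error(qcFlagOutliers(matrix(1, 5, 6)), "degenerate")
})

test_that("the generator's planted low genes and outliers are recovered", {
  cfg <- simConfig(seed = 3, nanostring = list(n_samples = 60))
  sim <- simulateNanoString(cfg)
  res <- nanostringNormalize(sim$counts)
  # planted dispersed samples all flagged, nothing else
  expect_setequal(res$qc$excluded_samples, sim$truth$outlier_samples)
  # planted low-expression genes all removed
  expect_true(all(sim$truth$low_genes %in% res$removed_genes$gene))
  # relative abundances of retained genes recovered within 10%
  kept <- rownames(res$matrix)
  est <- exp(rowMeans(log(res$matrix + 0.5)))
  ratio <- est / sim$truth$means[kept]
  ratio <- ratio / exp(mean(log(ratio)))
  expect_lt(max(abs(ratio - 1)), 0.1)
})

test_that("count tables round-trip through the CSV reader", {
  m <- rbind(E1 = c(10, 20), E2 = c(5, 2), HK1 = c(9, 9), HK2 = c(7, 3),
             POSA = c(100, 120), POSB = c(30, 40))
  colnames(m) <- c("a", "b")
  x <- tiny_nanostring(m)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(probe = rownames(m),
                   class = SummarizedExperiment::rowData(x)$probe_class, m,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  back <- readNanoStringCounts(path)
  expect_equal(SummarizedExperiment::assay(back), m)
  expect_equal(SummarizedExperiment::rowData(back)$probe_class,
               SummarizedExperiment::rowData(x)$probe_class)
})

test_that("gene filter and sample QC commute on unaffected features", {
  sim <- simulateNanoString(simConfig(seed = 13,
                                      nanostring = list(n_samples = 60)))
  norm <- housekeepingNormalize(positiveControlNormalize(sim$counts))
  # qc then filter
  qc_first <- qcFlagOutliers(norm)
  keep1 <- setdiff(colnames(norm), qc_first$excluded_samples)
  removed1 <- lowExpressionFilter(norm[, keep1])$removed$gene
  # filter then qc
  filt <- lowExpressionFilter(norm)
  qc_second <- qcFlagOutliers(filt$matrix)
  expect_setequal(qc_first$excluded_samples, qc_second$excluded_samples)
  # genes whose means sit near the threshold can legitimately flip when
  # dispersed samples are dropped first; compare the clear-cut genes
  borderline <- rownames(norm)[abs(rowMeans(norm) - 10) < 3 |
                                 abs(rowMeans(norm[, keep1]) - 10) < 3]
  expect_setequal(setdiff(removed1, borderline),
                  setdiff(filt$removed$gene, borderline))
})
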