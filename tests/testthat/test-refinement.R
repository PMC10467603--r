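# pooled-style cohort with a few informative genes for search tests
refine_fixture <- function(seed = 1, n = 120, n_genes = 8, n_strong = 3) {
  set.seed(seed)
  z <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              paste0("s", 1:n)))
  beta <- c(rep(0.8, n_strong), rep(0, n_genes - n_strong))
  eta <- as.vector(crossprod(z, beta))
  t_ev <- rexp(n, 0.004 * exp(eta))
  cens <- pmin(120, rexp(n, 1 / 150))
  co <- make_cohort(z, pmin(t_ev, cens), as.integer(t_ev <= cens),
                    name = "pooledfix")
  dirs <- setNames(rep("unfavorable", n_genes), rownames(z))
  list(cohort = co, directions = dirs, pool = rownames(z),
       strong = rownames(z)[seq_len(n_strong)])
}

test_that("combination evaluation is deterministic and order-invariant", {
  fx <- refine_fixture(seed = 11)
  ev <- evaluateCombination(c("g01", "g02", "g05"), fx$cohort,
                            fx$directions)
  expect_false(ev$uninformative)
  # permuted sample order gives the identical p
  perm <- sample(ncol(fx$cohort))
  co2 <- fx$cohort[, perm]
  ev2 <- evaluateCombination(c("g01", "g02", "g05"), co2, fx$directions)
  expect_equal(ev2$p, ev$p, tolerance = 1e-12)
  expect_error(evaluateCombination(c("g01", "g01"), fx$cohort,
                                   fx$directions), "duplicate")
})

test_that("informative pairs beat null pairs in expectation", {
  fx <- refine_fixture(seed = 12)
  strong <- evaluateCombination(c("g01", "g02"), fx$cohort, fx$directions)
  null2 <- evaluateCombination(c("g07", "g08"), fx$cohort, fx$directions)
  expect_lt(strong$p, null2$p)
})

test_that("beam counting: full width enumerates all subsets, B=1 is greedy", {
  fx <- refine_fixture(seed = 13, n_genes = 6)
  # with B = Inf the trace covers k = 2..6 (C(6,k) sets searched at each k)
  tr <- beamRefine(fx$pool, fx$directions, fx$cohort, B = Inf)
  expect_equal(tr@table$k, 2:6)
  # pool of exactly 2 genes: a single trace entry at k = 2
  tr2 <- beamRefine(fx$pool[1:2], fx$directions, fx$cohort, B = Inf)
  expect_equal(tr2@table$k, 2L)
  # B = 1 behaves like greedy forward selection: each best set nests the
  # previous one
  trg <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 1)
  sets <- strsplit(trg@table$genes, ",")
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_error(beamRefine(fx$pool[1], fx$directions, fx$cohort), "2 genes")
})

test_that("exhaustive beam equals brute-force subset enumeration", {
  fx <- refine_fixture(seed = 14, n_genes = 7)
  tr <- beamRefine(fx$pool, fx$directions, fx$cohort, B = Inf)
  ora <- oracle_best_per_k(fx$pool, fx$directions, fx$cohort)
  expect_equal(tr@table$p, ora$p, tolerance = 1e-9)
  expect_equal(tr@table$genes, ora$genes)
})

test_that("a wider beam never yields a worse per-size best", {
  fx <- refine_fixture(seed = 15, n_genes = 9, n_strong = 4)
  narrow <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 3)
  wide <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 30)
  expect_true(all(wide@table$p <= narrow@table$p + 1e-12))
})

test_that("refinement is byte-identical across reruns", {
  fx <- refine_fixture(seed = 16)
  t1 <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 5)
  t2 <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 5)
  expect_identical(t1@table, t2@table)
})

test_that("signature-size selection takes the peak, smallest k on ties", {
  mk_trace <- function(k, p) methods::new(
    "RefinementTrace",
    table = data.frame(k = k, p = p, chisq = -log(p),
                       score_cutoff = 0.5,
                       genes = vapply(k, function(i)
                         paste(sprintf("g%02d", 1:i), collapse = ","), "")),
    pool = sprintf("g%02d", 1:max(k)),
    directions = setNames(rep("unfavorable", max(k)),
                          sprintf("g%02d", 1:max(k))),
    beamWidth = 10, cohortName = "x")
  # monotone increasing significance: selects the largest size
  sel <- selectSignatureSize(mk_trace(2:5, c(1e-2, 1e-3, 1e-4, 1e-5)))
  expect_equal(sel$k, 5L)
  # unimodal: selects the peak
  sel2 <- selectSignatureSize(mk_trace(2:6, c(1e-2, 1e-6, 1e-9, 1e-6, 1e-3)))
  expect_equal(sel2$k, 4L)
  # exact tie: the smaller size wins
  sel3 <- selectSignatureSize(mk_trace(2:4, c(1e-2, 1e-6, 1e-6)))
  expect_equal(sel3$k, 3L)
  expect_s4_class(sel3$signature, "GeneSignature")
  expect_length(signatureGenes(sel3$signature), 3L)
})

test_that("the selected signature carries directions and the score cut-off", {
  fx <- refine_fixture(seed = 17)
  tr <- beamRefine(fx$pool, fx$directions, fx$cohort, B = Inf, max_k = 4)
  sel <- selectSignatureSize(tr)
  sig <- sel$signature
  expect_true(all(signatureGenes(sig) %in% fx$pool))
  expect_equal(unname(signatureDirections(sig)),
               unname(fx$directions[signatureGenes(sig)]))
  expect_true("pooledfix" %in% names(sig@scoreCutoff))
  # trace serialization round-trips
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrace(tr, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$k, tr@table$k)
  expect_equal(back$genes, tr@table$genes)
})

test_that("one beam step extends sets by exactly one gene, counting C(G,k)", {
  fx <- refine_fixture(seed = 18, n_genes = 8)
  pp <- prognosig:::.pool_points(fx$pool, fx$directions, fx$cohort, 0.1)
  surv_ord <- local({
    ord <- order(pp$time)
    list(ord = as.integer(ord), time_o = pp$time[ord],
         event_o = as.integer(pp$event[ord]))
  })
  # seed a full k = 2 beam by hand, then step with unlimited width
  pairs <- utils::combn(fx$pool, 2, simplify = FALSE)
  scores <- vapply(pairs, function(gs)
    as.integer(rowSums(pp$points[, gs])), integer(ncol(fx$cohort)))
  state <- list(k = 2L, genes = pairs, scores = scores,
                p = rep(0.5, length(pairs)), chisq = rep(0, length(pairs)),
                cutoff = rep(0.5, length(pairs)),
                keys = vapply(pairs, paste, "", collapse = ","))
  st3 <- prognosig:::.beam_step(state, fx$pool, pp$points, surv_ord,
                                B = Inf, minprop = 0.1)
  expect_equal(st3$k, 3L)
  expect_equal(length(st3$genes), choose(8, 3))  # dedup to distinct sets
  expect_true(all(vapply(st3$genes, length, 0L) == 3L))
  # pool of 3 at k = 2 extends to exactly one 3-gene set
  sub <- fx$pool[1:3]
  pairs3 <- utils::combn(sub, 2, simplify = FALSE)
  st <- list(k = 2L, genes = pairs3,
             scores = vapply(pairs3, function(gs)
               as.integer(rowSums(pp$points[, gs])),
               integer(ncol(fx$cohort))),
             p = rep(0.5, 3), chisq = rep(0, 3), cutoff = rep(0.5, 3),
             keys = vapply(pairs3, paste, "", collapse = ","))
  one <- prognosig:::.beam_step(st, sub, pp$points, surv_ord, Inf, 0.1)
  expect_equal(length(one$genes), 1L)
  expect_setequal(one$genes[[1]], sub)
})

test_that("single-pruning search never does worse than the fixed-width beam", {
  fx <- refine_fixture(seed = 19, n_genes = 7, n_strong = 3)
  fixed <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 3)
  once <- beamRefine(fx$pool, fx$directions, fx$cohort, B = 3,
                     prune_once = TRUE)
  expect_true(all(once@table$p <= fixed@table$p + 1e-12))
})
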