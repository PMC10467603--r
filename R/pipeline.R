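# ---- pipeline orchestration ------------------------------------------------
# Each stage reads a validated config list (usually from YAML), runs the
# corresponding package functions, writes plain-text artifacts into
# config$out, and records a manifest (config snapshot, seed, package
# version, md5 of inputs and outputs) so every artifact is traceable and
# reruns are checkable by checksum.

.stage_names <- c("simulate", "normalize", "screen", "refine", "score",
                  "evaluate", "compare")

#' Read a pipeline run configuration
#'
#' @param path YAML (or JSON) config file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.require_fields <- function(config, fields, stage) {
  missing <- setdiff(fields, names(config))
  if (length(missing))
    stop("config for stage '", stage, "' lacks field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

.check_inputs_exist <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input path(s) do not exist: ", paste(absent, collapse = ", "))
  invisible(TRUE)
}

.write_manifest <- function(out, stage, config, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("prognosig")),
    seed = config$seed,
    config = config,
    inputs = as.list(tools::md5sum(unlist(inputs, use.names = FALSE))),
    outputs = as.list(tools::md5sum(unlist(outputs, use.names = FALSE))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# load a cohort described as list(name=, expression=, clinical=)
.load_cohort <- function(desc) {
  expr <- readExpressionMatrix(desc$expression)
  clin <- readClinicalTable(desc$clinical)
  suppressMessages(SurvCohort(expr, clin, desc$name))
}

.write_cohort <- function(cohort, dir) {
  nm <- cohortName(cohort)
  ep <- file.path(dir, paste0(nm, "_expression.tsv"))
  cp <- file.path(dir, paste0(nm, "_clinical.csv"))
  writeExpressionMatrix(exprs(cohort), ep)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  cd <- cbind(sample_id = rownames(cd), cd)
  utils::write.csv(cd, cp, row.names = FALSE)
  c(ep, cp)
}

#' Run one pipeline stage
#'
#' Orchestrates the package's phases as independently re-runnable stages.
#' Config validation failures are reported before any computation; every
#' stage writes its artifacts plus a `manifest.json` under `config$out`.
#' Rerunning a stage with the same config and seed reproduces identical
#' artifact checksums.
#'
#' Stages and their config fields:
#' \describe{
#'   \item{simulate}{`seed`, optional generator overrides (`n_cohorts`,
#'     `n_samples`, `n_genes`, ...): writes per-cohort expression TSV and
#'     clinical CSV plus the planted truth.}
#'   \item{normalize}{`counts` (NanoString CSV): two-step normalization,
#'     low-expression filter, QC; writes the normalized matrix and QC
#'     report.}
#'   \item{screen}{`cohorts` (list of name/expression/clinical),
#'     optional `alpha`, `min_cohorts`, `minprop`: writes the screen TSV.}
#'   \item{refine}{`cohorts`, `screen` (screen TSV for pool and
#'     directions), optional `beam`, `max_k`: pools the z-scored cohorts,
#'     runs the beam search, writes the trace and the selected signature.}
#'   \item{score}{`signature` (JSON), `cohort`: writes per-sample scores.}
#'   \item{evaluate}{`signature`, `cohort`, optional `endpoint`: writes a
#'     performance report.}
#'   \item{compare}{`signature_a`, `signature_b`, `cohort`: writes the
#'     comparison report.}
#' }
#'
#' @param stage one of `simulate`, `normalize`, `screen`, `refine`,
#'   `score`, `evaluate`, `compare`.
#' @param config named list (see [readRunConfig()]); must contain `out`.
#' @return list with `stage`, `outputs` (paths) and `manifest`, invisibly.
#' @export
runStage <- function(stage, config) {
  stage <- match.arg(stage, .stage_names)
  .require_fields(config, "out", stage)
  runner <- switch(stage,
    simulate = .stage_simulate, normalize = .stage_normalize,
    screen = .stage_screen, refine = .stage_refine,
    score = .stage_score, evaluate = .stage_evaluate,
    compare = .stage_compare)
  # validate before creating anything
  inputs <- runner(config, validate_only = TRUE)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  outputs <- runner(config, validate_only = FALSE)
  manifest <- .write_manifest(config$out, stage, config, inputs, outputs)
  invisible(list(stage = stage, outputs = outputs, manifest = manifest))
}

.stage_simulate <- function(config, validate_only = FALSE) {
  .require_fields(config, "seed", "simulate")
  known <- setdiff(names(formals(simConfig)), "nanostring")
  args <- config[intersect(names(config), known)]
  cfg <- do.call(simConfig, args)
  if (validate_only) return(character())
  suite <- simulateTrainingSuite(cfg)
  outputs <- unlist(lapply(suite$cohorts, .write_cohort, dir = config$out))
  truth_path <- file.path(config$out, "truth.json")
  jsonlite::write_json(
    list(planted = suite$truth$planted,
         direction = as.list(suite$truth$direction[suite$truth$planted]),
         cohort_seeds = suite$truth$cohort_seeds),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(outputs, truth_path)
}

.stage_normalize <- function(config, validate_only = FALSE) {
  .require_fields(config, "counts", "normalize")
  .check_inputs_exist(config$counts)
  if (validate_only) return(config$counts)
  x <- readNanoStringCounts(config$counts)
  res <- nanostringNormalize(
    x, threshold = if (is.null(config$threshold)) 10 else config$threshold,
    k_mad = if (is.null(config$k_mad)) 3.5 else config$k_mad)
  mp <- file.path(config$out, "normalized_expression.tsv")
  qp <- file.path(config$out, "qc_report.json")
  writeExpressionMatrix(res$matrix, mp)
  jsonlite::write_json(
    list(excluded_samples = res$qc$excluded_samples,
         reason = as.list(res$qc$reason),
         removed_genes = res$removed_genes),
    qp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(mp, qp)
}

.cohort_input_paths <- function(cohorts) {
  unlist(lapply(cohorts, function(d) c(d$expression, d$clinical)))
}

.stage_screen <- function(config, validate_only = FALSE) {
  .require_fields(config, "cohorts", "screen")
  paths <- .cohort_input_paths(config$cohorts)
  .check_inputs_exist(paths)
  if (validate_only) return(paths)
  cohorts <- lapply(config$cohorts, .load_cohort)
  names(cohorts) <- vapply(cohorts, cohortName, "")
  cfg <- screenConfig(
    alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
    min_cohorts = if (is.null(config$min_cohorts)) 4L else config$min_cohorts,
    minprop = if (is.null(config$minprop)) 0.1 else config$minprop)
  res <- screenAll(cohorts, cfg)
  sp <- file.path(config$out, "screen.tsv")
  writeScreenResults(res, sp)
  sp
}

.stage_refine <- function(config, validate_only = FALSE) {
  .require_fields(config, c("cohorts", "screen"), "refine")
  paths <- c(.cohort_input_paths(config$cohorts), config$screen)
  .check_inputs_exist(paths)
  if (validate_only) return(paths)
  screen <- utils::read.delim(config$screen, stringsAsFactors = FALSE)
  hits <- screen[screen$verdict %in% c("favorable", "unfavorable"), ]
  if (nrow(hits) < 2L) stop("screen provides fewer than 2 candidate genes")
  cohorts <- lapply(config$cohorts, .load_cohort)
  pooled <- poolCohorts(lapply(cohorts, zscoreGenes))
  directions <- setNames(hits$verdict, hits$gene)
  trace <- beamRefine(
    hits$gene, directions, pooled,
    B = if (is.null(config$beam)) 2000 else config$beam,
    max_k = if (is.null(config$max_k)) length(hits$gene) else config$max_k,
    minprop = if (is.null(config$minprop)) 0.1 else config$minprop)
  sel <- selectSignatureSize(trace)
  tp <- file.path(config$out, "refinement_trace.tsv")
  gp <- file.path(config$out, "selected_signature.json")
  writeTrace(trace, tp)
  writeSignature(sel$signature, gp)
  c(tp, gp)
}

.stage_score <- function(config, validate_only = FALSE) {
  .require_fields(config, c("signature", "cohort"), "score")
  paths <- c(config$signature, .cohort_input_paths(list(config$cohort)))
  .check_inputs_exist(paths)
  if (validate_only) return(paths)
  sig <- readSignature(config$signature)
  cohort <- .load_cohort(config$cohort)
  scores <- recurrenceScores(sig, cohort)
  sp <- file.path(config$out, "recurrence_scores.csv")
  utils::write.csv(data.frame(sample_id = names(scores), score = scores),
                   sp, row.names = FALSE)
  sp
}

.stage_evaluate <- function(config, validate_only = FALSE) {
  .require_fields(config, c("signature", "cohort"), "evaluate")
  paths <- c(config$signature, .cohort_input_paths(list(config$cohort)))
  .check_inputs_exist(paths)
  if (validate_only) return(paths)
  sig <- readSignature(config$signature)
  cohort <- .load_cohort(config$cohort)
  endpoint <- if (is.null(config$endpoint)) "RFS" else config$endpoint
  rep <- evaluateSignature(sig, cohort, endpoint)
  rp <- file.path(config$out, "performance_report.json")
  jsonlite::write_json(
    rep[c("endpoint", "hr", "hr_lower", "hr_upper", "logrank_p", "auc",
          "sensitivity", "specificity", "accuracy", "n_high", "n_low",
          "score_cutoff")],
    rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rp
}

.stage_compare <- function(config, validate_only = FALSE) {
  .require_fields(config, c("signature_a", "signature_b", "cohort"),
                  "compare")
  paths <- c(config$signature_a, config$signature_b,
             .cohort_input_paths(list(config$cohort)))
  .check_inputs_exist(paths)
  if (validate_only) return(paths)
  sa <- readSignature(config$signature_a)
  sb <- readSignature(config$signature_b)
  cohort <- .load_cohort(config$cohort)
  cmp <- compareSignatures(sa, sb, cohort)
  rp <- file.path(config$out, "comparison_report.json")
  jsonlite::write_json(
    list(signature_a = cmp$reportA[c("hr", "logrank_p", "auc",
                                     "sensitivity", "specificity")],
         signature_b = cmp$reportB[c("hr", "logrank_p", "auc",
                                     "sensitivity", "specificity")],
         concordance = as.data.frame(cmp$concordance),
         concordant_fraction = cmp$concordant_fraction,
         high_risk_difference = cmp$high_risk_difference),
    rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rp
}
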