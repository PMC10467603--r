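#' Simulation configuration
#'
#' Parameters of the synthetic multi-cohort generator. The defaults
#' emulate a six-cohort stage II colorectal cancer discovery setting: 150
#' tumors per cohort, 520 genes of which 20 carry proportional-hazards
#' effects on relapse (12 unfavorable, 8 favorable, |log-HR| 0.8 per SD of
#' expression), a baseline relapse hazard of 0.004/month (about 21%
#' relapse by five years), administrative censoring at 120 months plus
#' exponential dropout, cohort-specific batch location/scale shifts, a
#' pT4 covariate (prevalence 0.2, log-HR log 2.4), and a NanoString block
#' with negative-binomial counts, a positive-control dilution series, six
#' housekeeping probes, planted low-expression genes and dispersed
#' outlier samples.
#'
#' @param n_cohorts,n_samples,n_genes cohort structure.
#' @param n_unfavorable,n_favorable planted prognostic gene counts (the
#'   first `n_unfavorable + n_favorable` genes, in that order).
#' @param effect_size |log hazard ratio| per SD of expression.
#' @param baseline_hazard exponential relapse hazard per month.
#' @param horizon administrative censoring, months.
#' @param dropout_rate exponential dropout hazard per month.
#' @param batch_location_sd,batch_scale_range per-cohort gene location
#'   shift SD and global scale factor range.
#' @param pt4_prevalence,pt_loghr pT4 covariate model.
#' @param os_attenuation,os_frailty_sd,os_baseline_hazard overall-survival
#'   model: OS shares the relapse linear predictor attenuated by
#'   `os_attenuation` plus a normal frailty.
#' @param nanostring list: `n_endogenous`, `n_low` (planted low-expression
#'   genes), `n_housekeeping`, `n_positive`, `n_samples`, `lane_sd`
#'   (log-normal lane factor SD), `nb_size` (negative-binomial size),
#'   `n_outliers`, `outlier_sd` (log-scale dispersion inflation).
#' @param seed mandatory integer master seed.
#' @return list of class `sim_config`.
#' @export
simConfig <- function(n_cohorts = 6L, n_samples = 150L, n_genes = 520L,
                      n_unfavorable = 12L, n_favorable = 8L,
                      effect_size = 0.8, baseline_hazard = 0.004,
                      horizon = 120, dropout_rate = 1 / 150,
                      batch_location_sd = 0.5,
                      batch_scale_range = c(0.7, 1.4),
                      pt4_prevalence = 0.2, pt_loghr = log(2.4),
                      os_attenuation = 0.6, os_frailty_sd = 0.5,
                      os_baseline_hazard = 0.003,
                      nanostring = list(), seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  ns <- utils::modifyList(
    list(n_endogenous = 61L, n_low = 9L, n_housekeeping = 6L,
         n_positive = 6L, n_samples = 210L, lane_sd = 0.3, nb_size = 20,
         n_outliers = 5L, outlier_sd = 1.5), nanostring)
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_unfavorable = as.integer(n_unfavorable),
              n_favorable = as.integer(n_favorable),
              effect_size = effect_size, baseline_hazard = baseline_hazard,
              horizon = horizon, dropout_rate = dropout_rate,
              batch_location_sd = batch_location_sd,
              batch_scale_range = batch_scale_range,
              pt4_prevalence = pt4_prevalence, pt_loghr = pt_loghr,
              os_attenuation = os_attenuation,
              os_frailty_sd = os_frailty_sd,
              os_baseline_hazard = os_baseline_hazard,
              nanostring = ns, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_cohorts, cfg$n_samples, cfg$n_genes, cfg$n_unfavorable,
              cfg$n_favorable, cfg$nanostring$n_endogenous,
              cfg$nanostring$n_low, cfg$nanostring$n_outliers)
  if (any(counts < 0)) stop("all counts must be nonnegative")
  if (cfg$n_unfavorable + cfg$n_favorable > cfg$n_genes)
    stop("more planted genes than genes")
  if (!is.finite(cfg$effect_size)) stop("effect size must be finite")
  if (cfg$baseline_hazard <= 0 || cfg$horizon <= 0)
    stop("hazard and horizon must be positive")
  if (cfg$nanostring$n_low > cfg$nanostring$n_endogenous)
    stop("more planted low genes than endogenous genes")
  invisible(TRUE)
}

.planted_truth <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  beta <- setNames(rep(0, cfg$n_genes), genes)
  nu <- cfg$n_unfavorable; nf <- cfg$n_favorable
  if (nu > 0) beta[seq_len(nu)] <- cfg$effect_size
  if (nf > 0) beta[nu + seq_len(nf)] <- -cfg$effect_size
  direction <- ifelse(beta > 0, "unfavorable",
                      ifelse(beta < 0, "favorable", "null"))
  list(genes = genes, beta = beta, direction = setNames(direction, genes),
       planted = genes[beta != 0])
}

#' Simulate one expression/survival cohort
#'
#' Expression is standard normal per gene (the biological signal), shifted
#' by cohort-specific per-gene batch locations and a cohort scale factor.
#' The relapse hazard is `baseline * exp(sum_g beta_g z_ig +
#' pt_loghr * 1[pT4])`; event times are exponential given the hazard, and
#' censoring is the minimum of the administrative horizon and an
#' exponential dropout time. OS is generated from the same linear
#' predictor attenuated by `os_attenuation` plus a per-sample normal
#' frailty, so OS effects are weaker than RFS effects.
#'
#' @param cfg a [simConfig()].
#' @param cohort_index integer; determines the cohort's derived seed and
#'   label.
#' @param cohort_seed optional explicit seed overriding the derived one.
#' @return list with `cohort` (a [SurvCohort-class]) and `truth`
#'   (planted directions/effects and the per-sample linear predictor).
#' @export
simulateCohort <- function(cfg, cohort_index = 1L, cohort_seed = NULL) {
  .validate_sim_config(cfg)
  if (is.null(cohort_seed))
    cohort_seed <- (cfg$seed * 1009L + 97L * as.integer(cohort_index)) %%
      .Machine$integer.max
  set.seed(cohort_seed)
  tr <- .planted_truth(cfg)
  n <- cfg$n_samples; G <- cfg$n_genes
  z <- matrix(rnorm(G * n), nrow = G,
              dimnames = list(tr$genes, sprintf("S%03d", seq_len(n))))
  batch_loc <- rnorm(G, 0, cfg$batch_location_sd)
  batch_scale <- runif(1L, cfg$batch_scale_range[1L],
                       cfg$batch_scale_range[2L])
  expr <- batch_loc + batch_scale * z

  pt4 <- rbinom(n, 1L, cfg$pt4_prevalence)
  eta <- as.vector(crossprod(z, tr$beta)) + cfg$pt_loghr * pt4
  t_rfs <- rexp(n, rate = cfg$baseline_hazard * exp(eta))
  dropout <- rexp(n, rate = cfg$dropout_rate)
  cens <- pmin(cfg$horizon, dropout)
  rfs_time <- pmin(t_rfs, cens)
  rfs_event <- as.integer(t_rfs <= cens)

  frailty <- rnorm(n, 0, cfg$os_frailty_sd)
  t_os <- rexp(n, rate = cfg$os_baseline_hazard *
                 exp(cfg$os_attenuation * eta + frailty))
  os_time <- pmin(t_os, cens)
  os_event <- as.integer(t_os <= cens)

  clinical <- data.frame(sample_id = colnames(expr),
                         rfs_time = rfs_time, rfs_event = rfs_event,
                         os_time = os_time, os_event = os_event,
                         pt = as.character(3L + pt4),
                         stringsAsFactors = FALSE)
  cohort <- suppressMessages(
    SurvCohort(expr, clinical, name = sprintf("sim%02d", cohort_index)))
  list(cohort = cohort,
       truth = list(beta = tr$beta, direction = tr$direction,
                    planted = tr$planted, eta = eta,
                    cohort_seed = cohort_seed))
}

#' Simulate a multi-cohort training suite
#'
#' Independent cohorts sharing the same planted truth (gene identities,
#' directions and effect sizes) but with distinct batch effects; each
#' cohort's seed is derived deterministically from the master seed.
#'
#' @param cfg a [simConfig()].
#' @return list with `cohorts` (named list of [SurvCohort-class]) and
#'   `truth` (shared planted directions plus per-cohort seeds).
#' @export
simulateTrainingSuite <- function(cfg) {
  .validate_sim_config(cfg)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_cohorts)
  sims <- lapply(seq_len(cfg$n_cohorts), function(i)
    simulateCohort(cfg, i, cohort_seed = seeds[i]))
  cohorts <- lapply(sims, `[[`, "cohort")
  names(cohorts) <- vapply(cohorts, cohortName, "")
  tr <- .planted_truth(cfg)
  list(cohorts = cohorts,
       truth = list(beta = tr$beta, direction = tr$direction,
                    planted = tr$planted, cohort_seeds = seeds))
}

#' Simulate a NanoString-style raw count table
#'
#' Endogenous counts are negative binomial around gene means drawn
#' log-uniformly (planted low-expression genes below 10 counts/sample;
#' the rest between 30 and 2000), multiplied by sample-specific
#' log-normal lane factors that also act on the housekeeping probes and
#' the positive-control dilution series. Planted outlier samples get
#' additional per-gene log-normal dispersion on their endogenous counts,
#' emulating dispersed expression profiles.
#'
#' @param cfg a [simConfig()]; uses its `nanostring` block and seed.
#' @return list with `counts` (a [NanoStringSet-class]) and `truth`
#'   (gene means, low genes, outlier samples, lane factors).
#' @export
simulateNanoString <- function(cfg) {
  .validate_sim_config(cfg)
  ns <- cfg$nanostring
  set.seed(cfg$seed + 7L)
  n <- ns$n_samples
  samples <- sprintf("T%03d", seq_len(n))
  genes <- sprintf("E%02d", seq_len(ns$n_endogenous))
  low_genes <- if (ns$n_low > 0) genes[seq_len(ns$n_low)] else character()
  means <- setNames(exp(runif(ns$n_endogenous, log(30), log(2000))), genes)
  means[low_genes] <- exp(runif(ns$n_low, log(1), log(8)))
  hk <- sprintf("HK_%s", nanostringHousekeeping()[seq_len(ns$n_housekeeping)])
  hk_means <- setNames(exp(runif(ns$n_housekeeping, log(200), log(800))), hk)
  pos <- sprintf("POS_%s", LETTERS[seq_len(ns$n_positive)])
  pos_means <- setNames(60 * 128 / 4^(seq_len(ns$n_positive) - 1), pos)

  lane <- exp(rnorm(n, 0, ns$lane_sd))
  outliers <- if (ns$n_outliers > 0) samples[n - seq_len(ns$n_outliers) + 1L]
              else character()

  draw <- function(mu_g) {
    t(vapply(mu_g, function(mu)
      rnbinom(n, mu = mu * lane, size = ns$nb_size), numeric(n)))
  }
  endo_counts <- draw(means)
  if (length(outliers)) {
    oi <- match(outliers, samples)
    noise <- matrix(exp(rnorm(length(means) * length(oi), 0,
                              ns$outlier_sd)),
                    nrow = length(means))
    endo_counts[, oi] <- round(endo_counts[, oi] * noise)
  }
  counts <- rbind(endo_counts, draw(hk_means), draw(pos_means))
  dimnames(counts) <- list(c(genes, hk, pos), samples)
  cls <- c(rep("endogenous", length(genes)),
           rep("housekeeping", length(hk)),
           rep("positive_control", length(pos)))
  list(counts = NanoStringSet(counts, cls),
       truth = list(means = means, low_genes = low_genes,
                    outlier_samples = outliers, lane_factors = lane,
                    hk_means = hk_means, pos_means = pos_means))
}
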