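#' Simulation configuration for synthetic cohorts
#'
#' Defines the study conditions for the synthetic-cohort generator: a
#' two-group cohort (bipolar-spectrum, BDS, vs non-BDS) genotyped at
#' biallelic SNPs in Hardy-Weinberg equilibrium with block LD, methylated at
#' beta-distributed CpG probes with planted group-differential probes, and
#' measured on structural brain endophenotypes generated as linear functions
#' of true genetic (G), environmental (E) and GxE effects plus covariates.
#' Defaults mirror the cohort the pipeline targets (119 subjects, 55 BDS,
#' 44 brain measures) at desk-scale marker counts.
#'
#' @param n_subjects,n_bds Cohort size and BDS group size (`n_bds <= n_subjects`).
#' @param n_snps,n_causal_snps Number of simulated SNPs and of causal SNPs
#'   carrying true risk weights.
#' @param ld_block_size,ld_rho Size of adjacent-variant LD blocks and the
#'   latent-Gaussian correlation within a block (`0 <= ld_rho < 1`).
#' @param maf_range Interval within (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly.
#' @param missing_rate Probability that a genotype call is missing
#'   (missing completely at random; default 0).
#' @param n_probes,n_signal_probes Number of CpG probes and of planted
#'   group-differential probes.
#' @param probe_effect_delta Beta-scale mean shift applied to signal probes in
#'   the BDS group (signed per-probe by a random direction).
#' @param type2_fraction Fraction of probes assigned Illumina design type II.
#' @param type2_compression Multiplicative compression of type II betas toward
#'   0.5 (1 = none), emulating the type II dynamic-range bias that BMIQ
#'   normalization corrects.
#' @param n_measures Number of brain structure measures (default 44).
#' @param n_affected_measures Number of measures carrying the planted
#'   G/E/GxE effects; the rest are pure covariate + noise.
#' @param beta_G,beta_E,beta_GxE Standardized effect sizes of the true genetic
#'   score, true environmental score and their product on affected measures.
#' @param noise_sd Residual standard deviation of the brain measures.
#' @param measure_shared_sd Standard deviation of a per-subject global
#'   component shared by all brain measures, emulating the positive
#'   correlation that intracranial-volume scaling induces among real
#'   volumetric measures.
#' @param covariate_effects Named numeric vector of effects for
#'   `age`, `age2`, `gender`, `race`, `smoking` on every measure.
#' @param cles_cor Correlation between the latent driving the simulated
#'   childhood-trauma count (CLES, 0-11) and the true environmental score.
#' @param fh_slope Log-odds slope of family history on the true genetic score.
#' @param seed Integer seed; all generators are fully deterministic given it.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_subjects = 119,
                       n_bds = 55,
                       n_snps = 2000,
                       n_causal_snps = 20,
                       ld_block_size = 10,
                       ld_rho = 0.3,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0,
                       n_probes = 1000,
                       n_signal_probes = 20,
                       probe_effect_delta = 0.1,
                       type2_fraction = 0.8,
                       type2_compression = 0.8,
                       n_measures = 44,
                       n_affected_measures = 4,
                       beta_G = 0.3,
                       beta_E = 0.4,
                       beta_GxE = 0.4,
                       noise_sd = 1,
                       measure_shared_sd = 0.6,
                       covariate_effects = c(age = 0.02, age2 = -5e-4,
                                             gender = 0.2, race = 0.1,
                                             smoking = 0.1),
                       cles_cor = 0.3,
                       fh_slope = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_bds = as.integer(n_bds),
    n_snps = as.integer(n_snps), n_causal_snps = as.integer(n_causal_snps),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    maf_range = maf_range, missing_rate = missing_rate,
    n_probes = as.integer(n_probes),
    n_signal_probes = as.integer(n_signal_probes),
    probe_effect_delta = probe_effect_delta,
    type2_fraction = type2_fraction, type2_compression = type2_compression,
    n_measures = as.integer(n_measures),
    n_affected_measures = as.integer(n_affected_measures),
    beta_G = beta_G, beta_E = beta_E, beta_GxE = beta_GxE,
    noise_sd = noise_sd, measure_shared_sd = measure_shared_sd,
    covariate_effects = covariate_effects,
    cles_cor = cles_cor, fh_slope = fh_slope,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects > 0, cfg$n_bds > 0, cfg$n_bds <= cfg$n_subjects,
    cfg$n_snps > 0, cfg$n_causal_snps >= 0, cfg$n_causal_snps <= cfg$n_snps,
    cfg$ld_block_size > 0, cfg$ld_rho >= 0, cfg$ld_rho < 1,
    length(cfg$maf_range) == 2,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$n_probes > 0, cfg$n_signal_probes >= 0,
    cfg$n_signal_probes <= cfg$n_probes,
    cfg$type2_fraction >= 0, cfg$type2_fraction <= 1,
    cfg$type2_compression > 0, cfg$type2_compression <= 1,
    cfg$n_measures > 0, cfg$n_affected_measures >= 0,
    cfg$n_affected_measures <= cfg$n_measures,
    cfg$noise_sd > 0, cfg$measure_shared_sd >= 0,
    length(cfg$covariate_effects) == 5,
    abs(cfg$cles_cor) < 1
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d subjects (%d BDS), %d SNPs (%d causal, LD blocks ",
           "of %d at rho=%.2f), %d probes (%d signal, delta=%.2f), ",
           "%d measures (%d affected; bG=%.2f bE=%.2f bGxE=%.2f), seed=%d\n"),
    x$n_subjects, x$n_bds, x$n_snps, x$n_causal_snps, x$ld_block_size,
    x$ld_rho, x$n_probes, x$n_signal_probes, x$probe_effect_delta,
    x$n_measures, x$n_affected_measures, x$beta_G, x$beta_E, x$beta_GxE,
    x$seed
  ))
  invisible(x)
}
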