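# Synthetic-cohort generators. Each generator derives its RNG stream from
# config$seed plus a fixed per-stage offset, so stages are individually and
# jointly deterministic.

seed_offset <- c(genotypes = 1L, truth = 2L, gwas = 3L, group = 4L,
                 methylation = 5L, subjects = 6L, brain = 7L)

stage_seed <- function(config, stage) {
  (config$seed + seed_offset[[stage]]) %% .Machine$integer.max
}

#' Simulate biallelic genotypes with block LD under Hardy-Weinberg equilibrium
#'
#' Two haplotypes per subject are generated independently; within each LD
#' block, a haplotype's latent allele liabilities share a common Gaussian
#' factor with pairwise correlation `ld_rho` and are thresholded at the
#' Hardy-Weinberg quantile of each variant's minor-allele frequency. Summing
#' the two haplotypes yields dosages in HWE in expectation, with LD controlled
#' independently of MAF.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with variants laid out contiguously along 22
#'   chromosomes (10 kb spacing, so an LD block spans well under the default
#'   clumping window).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config, "genotypes"), {
    n <- config$n_subjects
    m <- config$n_snps
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    block <- ceiling(seq_len(m) / config$ld_block_size)
    thr <- qnorm(maf)

    draw_haplotype <- function() {
      H <- matrix(0L, n, m)
      for (b in unique(block)) {
        idx <- which(block == b)
        f <- rnorm(n)
        z <- sqrt(config$ld_rho) * f +
          sqrt(1 - config$ld_rho) * matrix(rnorm(n * length(idx)), n)
        H[, idx] <- (z < matrix(thr[idx], n, length(idx), byrow = TRUE)) + 0L
      }
      H
    }
    dosage <- draw_haplotype() + draw_haplotype()

    if (config$missing_rate > 0) {
      miss <- matrix(runif(n * m) < config$missing_rate, n, m)
      dosage[miss] <- NA_integer_
    }

    # contiguous chromosome chunks, 10 kb spacing within chromosome
    chrom <- rep(seq_len(22), each = ceiling(m / 22), length.out = m)
    alleles <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
    variants <- tibble(
      id = sprintf("rs%06d", seq_len(m)),
      chrom = chrom,
      ref = alleles[, 1],
      alt = alleles[, 2]
    ) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(pos = 100000L + 10000L * (dplyr::row_number() - 1L)) |>
      dplyr::ungroup() |>
      dplyr::select("id", "chrom", "pos", "ref", "alt")

    rownames(dosage) <- sprintf("S%04d", seq_len(n))
    attr_maf <- maf
    out <- geno_matrix(dosage, variants)
    attr(out, "true_maf") <- attr_maf
    out
  })
}

#' Draw the cohort's ground truth (causal SNPs, signal probes, planted effects)
#'
#' @param config A [sim_config()].
#' @param genotypes The [geno_matrix()] the truth refers to.
#' @return A `cohort_truth` list: `causal_snp_ids`, `true_snp_weights`
#'   (log-odds per ALT allele), `signal_probe_ids`, `true_probe_directions`
#'   (+1/-1), and `true_effects` (tibble with per-measure `beta_G`, `beta_E`,
#'   `beta_GxE`).
#' @export
make_cohort_truth <- function(config, genotypes) {
  validate_sim_config(config)
  with_seed(stage_seed(config, "truth"), {
    causal <- sort(sample(genotypes$variants$id, config$n_causal_snps))
    weights <- sample(c(-1, 1), config$n_causal_snps, replace = TRUE) *
      runif(config$n_causal_snps, 0.2, 0.5)
    signal <- sort(sample(sprintf("cg%06d", seq_len(config$n_probes)),
                          config$n_signal_probes))
    directions <- sample(c(-1, 1), config$n_signal_probes, replace = TRUE)
    measures <- measure_names(config$n_measures)
    affected <- sort(sample(seq_len(config$n_measures),
                            config$n_affected_measures))
    eff <- tibble(
      measure = measures,
      beta_G = ifelse(seq_len(config$n_measures) %in% affected, config$beta_G, 0),
      beta_E = ifelse(seq_len(config$n_measures) %in% affected, config$beta_E, 0),
      beta_GxE = ifelse(seq_len(config$n_measures) %in% affected, config$beta_GxE, 0)
    )
    structure(
      list(causal_snp_ids = causal,
           true_snp_weights = setNames(weights, causal),
           signal_probe_ids = signal,
           true_probe_directions = setNames(directions, signal),
           true_effects = eff),
      class = "cohort_truth"
    )
  })
}

# 44 brain structural measure names in the style of the target battery:
# tissue fractions, regional cortical thicknesses, bilateral and whole
# subcortical volumes, and thalamic subnuclei.
measure_names <- function(n = 44) {
  base <- c(
    "wbf", "gmf", "wmf",
    paste0(c("frontal", "parietal", "temporal", "occipital", "cingulate",
             "insula", "global"), "_cortex_thickness"),
    paste0(rep(c("left_", "right_"), each = 7),
           rep(c("accumbens", "amygdala", "caudate", "hippocampus",
                 "pallidum", "putamen", "thalamus"), 2)),
    c("accumbens", "amygdala", "caudate", "hippocampus", "pallidum",
      "putamen", "thalamus"),
    "claustrum",
    paste0(c("anterior", "centromedian", "habenula", "lateral",
             "lateral_geniculate", "medial", "medial_geniculate",
             "mediodorsal", "pulvinar"), "_thalamus"),
    "mtt_thalamus", "subthalamic_nucleus", "ventral_diencephalon"
  )
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("measure_%02d", seq_len(n - length(base))))
}

#' Simulate a GWAS summary-statistics table with planted risk SNPs
#'
#' Causal variants receive their true log-odds weights (sign-adjusted to the
#' reported effect allele, which is the ALT or REF allele with equal
#' probability) and small p-values; non-causal variants receive weights near
#' zero and Uniform(0,1) p-values.
#'
#' @param config A [sim_config()].
#' @param truth A [make_cohort_truth()] result.
#' @param genotypes The matching [geno_matrix()].
#' @return A tibble with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight`, `p_value`.
#' @export
simulate_gwas_weights <- function(config, truth, genotypes) {
  with_seed(stage_seed(config, "gwas"), {
    v <- genotypes$variants
    m <- nrow(v)
    is_causal <- v$id %in% truth$causal_snp_ids
    weight_alt <- rnorm(m, 0, 0.02)  # near-zero background weights
    weight_alt[is_causal] <- truth$true_snp_weights[v$id[is_causal]]
    p <- runif(m)
    p[is_causal] <- 10^(-runif(sum(is_causal), 4, 8))
    use_alt <- runif(m) < 0.5
    tibble(
      id = v$id, chrom = v$chrom, pos = v$pos,
      effect_allele = ifelse(use_alt, v$alt, v$ref),
      other_allele = ifelse(use_alt, v$ref, v$alt),
      weight = ifelse(use_alt, weight_alt, -weight_alt),
      p_value = pmin(pmax(p, .Machine$double.xmin), 1)
    )
  })
}

#' Simulate EPIC-like methylation beta values with planted group effects
#'
#' Probes are assigned one of three methylation states (unmethylated /
#' hemimethylated / methylated) and per-subject betas are drawn from a beta
#' distribution around the probe's state mean. Signal probes are shifted by
#' `probe_effect_delta` (signed by the truth's per-probe direction) in BDS
#' subjects. Type II probes are compressed toward 0.5 by
#' `type2_compression` to exercise BMIQ normalization. Detection-p and
#' bead-count matrices are emitted alongside.
#'
#' @param config A [sim_config()].
#' @param truth A [make_cohort_truth()] result.
#' @param group_labels Character vector, `"BDS"` / `"non-BDS"`, one per subject.
#' @return A [meth_matrix()].
#' @export
simulate_methylation <- function(config, truth, group_labels) {
  stopifnot(length(group_labels) == config$n_subjects)
  with_seed(stage_seed(config, "methylation"), {
    n <- config$n_subjects
    m <- config$n_probes
    probe_ids <- sprintf("cg%06d", seq_len(m))
    state <- sample(c("U", "H", "M"), m, replace = TRUE,
                    prob = c(0.35, 0.15, 0.5))
    mu <- ifelse(state == "U", runif(m, 0.03, 0.15),
                 ifelse(state == "H", runif(m, 0.40, 0.60),
                        runif(m, 0.80, 0.97)))
    kappa <- runif(m, 30, 80)
    is_bds <- group_labels == "BDS"
    dir <- setNames(rep(0, m), probe_ids)
    dir[truth$signal_probe_ids] <- truth$true_probe_directions
    # signal probes start mid-range so the planted shift is not truncated by
    # the (0.02, 0.98) mean clamp in either direction
    if (length(truth$signal_probe_ids) > 0) {
      lo <- max(0.25, 0.02 + config$probe_effect_delta)
      hi <- min(0.75, 0.98 - config$probe_effect_delta)
      if (lo >= hi) { lo <- 0.5; hi <- 0.5 }
      sig_idx <- match(truth$signal_probe_ids, probe_ids)
      mu[sig_idx] <- runif(length(sig_idx), lo, hi)
      state[sig_idx] <- "H"
    }

    mu_mat <- matrix(mu, n, m, byrow = TRUE) +
      outer(as.numeric(is_bds), dir[probe_ids] * config$probe_effect_delta)
    mu_mat <- pmin(pmax(mu_mat, 0.02), 0.98)
    k_mat <- matrix(kappa, n, m, byrow = TRUE)
    beta <- matrix(rbeta(n * m, mu_mat * k_mat, (1 - mu_mat) * k_mat), n, m)

    design <- ifelse(runif(m) < config$type2_fraction, "II", "I")
    ii <- design == "II"
    beta[, ii] <- 0.5 + config$type2_compression * (beta[, ii] - 0.5)
    beta <- clamp_unit(beta)

    snp_overlap <- runif(m) < 0.02
    snp_overlap[probe_ids %in% truth$signal_probe_ids] <- FALSE

    detection_p <- matrix(rbeta(n * m, 1, 999), n, m)
    bead_count <- matrix(rpois(n * m, 15), n, m)

    probes <- tibble(
      probe_id = probe_ids,
      chrom = sample(seq_len(22), m, replace = TRUE),
      pos = sample.int(2e6, m, replace = TRUE),
      design_type = design,
      snp_overlap = snp_overlap
    )
    out <- meth_matrix(beta, probes, detection_p = detection_p,
                       bead_count = bead_count)
    rownames(out$beta) <- sprintf("S%04d", seq_len(n))
    attr(out, "state") <- state
    out
  })
}

#' Simulate brain structure measures from true scores and covariates
#'
#' Each measure is `beta_G * G + beta_E * E + beta_GxE * G * E` plus covariate
#' terms (age, age squared, gender, race, smoking), a per-subject global
#' component shared across all measures (`measure_shared_sd`), and independent
#' Gaussian noise. `G` and `E` are standardized before use.
#'
#' @param config A [sim_config()].
#' @param truth A [make_cohort_truth()] result.
#' @param prs_true,mps_true Per-subject true genetic and environmental scores.
#' @param covariates Data frame with `age`, `gender`, `race`, `smoking`.
#' @return A tibble: `subject_id` plus one column per measure.
#' @export
simulate_brain_measures <- function(config, truth, prs_true, mps_true,
                                    covariates) {
  validate_table(covariates, c("age", "gender", "race", "smoking"), "covariates")
  n <- length(prs_true)
  stopifnot(length(mps_true) == n, nrow(covariates) == n)
  with_seed(stage_seed(config, "brain"), {
    G <- as.numeric(scale(prs_true))
    E <- as.numeric(scale(mps_true))
    ce <- config$covariate_effects
    cov_term <- ce[[1]] * covariates$age +
      ce[[2]] * covariates$age^2 +
      ce[[3]] * as.numeric(covariates$gender == "Male") +
      ce[[4]] * as.numeric(covariates$race != "Caucasian") +
      ce[[5]] * as.numeric(covariates$smoking == "Yes")
    shared <- rnorm(n, 0, config$measure_shared_sd)
    eff <- truth$true_effects
    y <- vapply(seq_len(nrow(eff)), function(j) {
      eff$beta_G[j] * G + eff$beta_E[j] * E + eff$beta_GxE[j] * G * E +
        cov_term + shared + rnorm(n, 0, config$noise_sd)
    }, numeric(n))
    colnames(y) <- eff$measure
    sid <- if (!is.null(rownames(covariates)) &&
               !identical(rownames(covariates), as.character(seq_len(n)))) {
      rownames(covariates)
    } else if ("subject_id" %in% names(covariates)) {
      covariates$subject_id
    } else {
      sprintf("S%04d", seq_len(n))
    }
    dplyr::bind_cols(tibble(subject_id = sid), as_tibble(y))
  })
}

#' Simulate a complete cohort with known ground truth
#'
#' Orchestrates all generators: genotypes, truth, GWAS weights, group
#' assignment (driven by the true genetic score, with exact group sizes),
#' methylation, subject covariates (age 15-30, gender, race, smoking), family
#' history (Bernoulli with log-odds increasing in the true genetic score),
#' CLES trauma counts (0-11, correlated `cles_cor` with the true
#' environmental score), and brain measures.
#'
#' @param config A [sim_config()].
#' @return A `gxe_cohort` list: `config`, `truth`, `genotypes`, `gwas`,
#'   `methylation`, `subjects`, `brain`, `scores_true`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  genotypes <- simulate_genotypes(config)
  truth <- make_cohort_truth(config, genotypes)
  gwas <- simulate_gwas_weights(config, truth, genotypes)

  # true genetic score: mean-imputed causal dosages weighted by true effects
  cd <- genotypes$dosage[, truth$causal_snp_ids, drop = FALSE]
  if (anyNA(cd)) {
    mu <- colMeans(cd, na.rm = TRUE)
    idx <- which(is.na(cd), arr.ind = TRUE)
    cd[idx] <- mu[idx[, 2]]
  }
  prs_raw <- as.numeric(cd %*% truth$true_snp_weights)
  prs_true <- if (sd(prs_raw) > 0) as.numeric(scale(prs_raw)) else prs_raw

  grp_lat <- with_seed(stage_seed(config, "group"),
                       0.5 * prs_true + rnorm(config$n_subjects))
  group <- ifelse(rank(-grp_lat, ties.method = "first") <= config$n_bds,
                  "BDS", "non-BDS")

  methylation <- simulate_methylation(config, truth, group)
  Msig <- log2(methylation$beta[, truth$signal_probe_ids, drop = FALSE] /
                 (1 - methylation$beta[, truth$signal_probe_ids, drop = FALSE]))
  mps_raw <- as.numeric(Msig %*% truth$true_probe_directions)
  mps_true <- if (sd(mps_raw) > 0) as.numeric(scale(mps_raw)) else mps_raw

  subjects <- with_seed(stage_seed(config, "subjects"), {
    n <- config$n_subjects
    lat <- config$cles_cor * mps_true +
      sqrt(1 - config$cles_cor^2) * rnorm(n)
    tibble(
      subject_id = subject_ids(genotypes),
      group = group,
      family_history = rbinom(n, 1, plogis(qlogis(0.2) + config$fh_slope * prs_true)),
      cles = qbinom(pnorm(lat), 11, 0.4),
      age = round(runif(n, 15, 30), 1),
      gender = sample(c("Female", "Male"), n, replace = TRUE, prob = c(0.65, 0.35)),
      race = sample(c("Caucasian", "African American", "Asian"), n,
                    replace = TRUE, prob = c(0.78, 0.16, 0.06)),
      smoking = sample(c("No", "Yes", "Unknown"), n, replace = TRUE,
                       prob = c(0.64, 0.22, 0.14))
    )
  })

  brain <- simulate_brain_measures(
    config, truth, prs_true, mps_true,
    covariates = as.data.frame(subjects[, c("age", "gender", "race", "smoking")],
                               row.names = subjects$subject_id)
  )
  brain$subject_id <- subjects$subject_id

  structure(
    list(config = config, truth = truth, genotypes = genotypes, gwas = gwas,
         methylation = methylation, subjects = subjects, brain = brain,
         scores_true = tibble(subject_id = subjects$subject_id,
                              prs_true = prs_true, mps_true = mps_true)),
    class = "gxe_cohort"
  )
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat(sprintf("<gxe_cohort> %d subjects (%d BDS), %d SNPs, %d probes, %d measures\n",
              x$config$n_subjects, sum(x$subjects$group == "BDS"),
              x$config$n_snps, x$config$n_probes, x$config$n_measures))
  invisible(x)
}

#' Generate a Mendelian child from two parents' dosages
#'
#' Transmits one allele from each parent per variant (an allele is transmitted
#' with probability dosage/2), producing a parent-offspring pair for
#' relatedness checks.
#'
#' @param dosage_a,dosage_b Parental dosage vectors in \{0,1,2\}.
#' @param seed Integer seed.
#' @return Child dosage vector.
#' @export
mendelian_child <- function(dosage_a, dosage_b, seed = 1L) {
  stopifnot(length(dosage_a) == length(dosage_b))
  with_seed(seed, {
    rbinom(length(dosage_a), 1, dosage_a / 2) +
      rbinom(length(dosage_b), 1, dosage_b / 2)
  })
}
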