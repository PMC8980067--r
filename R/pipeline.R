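#' Full association analysis of molecular and clinical gene-environment factors
#'
#' The statistical stage: restricted to BDS subjects with brain measures, it
#' computes, for each factor (family history, CLES, PRS, MPS) and each
#' standardized brain measure, the Spearman correlation and the
#' covariate-adjusted main-effect fit with partial R-squared; Storey q-values
#' within each factor across measures (configurable to one pooled family);
#' and, per measure, the clinical and molecular interaction models plus the
#' bootstrap comparison of their partial R-squared.
#'
#' @param subjects Subject tibble (`subject_id`, `group`, `family_history`,
#'   `cles`, covariates).
#' @param brain Brain-measure tibble (`subject_id` + measures). Every brain
#'   row must match a subject row; orphans are an error.
#' @param prs,mps Score tibbles (`subject_id`, `score`) or the corresponding
#'   result objects.
#' @param covariates Covariate columns (default
#'   `c("age", "gender", "race", "smoking")`; `"age"` implies age squared).
#' @param fdr_family `"per_factor"` (default) or `"pooled"`.
#' @param n_boot Bootstrap replicates per measure (default 2000).
#' @param seed Seed for the bootstrap streams.
#' @param bds_only Restrict model fitting to the BDS group (default TRUE).
#' @return A `gxe_analysis` object: tibbles `table1`, `main_effects`
#'   (factor x measure), `interactions` (both pairs x measure, with q),
#'   `bootstrap` (per measure), plus provenance fields.
#' @export
run_full_analysis <- function(subjects, brain, prs, mps,
                              covariates = c("age", "gender", "race", "smoking"),
                              fdr_family = c("per_factor", "pooled"),
                              n_boot = 2000, seed = 1L, bds_only = TRUE) {
  fdr_family <- match.arg(fdr_family)
  validate_table(subjects, c("subject_id", "group", "family_history", "cles",
                             covariates), "subjects")
  validate_table(brain, "subject_id", "brain")
  score_tbl <- function(x, nm) {
    if (inherits(x, "prs_result")) x <- x$scores
    x <- as_tibble(x)
    validate_table(x, c("subject_id", "score"), nm)
    setNames(x, c("subject_id", nm))
  }
  prs <- score_tbl(prs, "prs")
  mps <- score_tbl(mps, "mps")

  orphans <- setdiff(brain$subject_id, subjects$subject_id)
  if (length(orphans) > 0) {
    stop(sprintf("brain measures for unknown subject(s): %s",
                 paste(head(orphans, 10), collapse = ", ")), call. = FALSE)
  }

  table1 <- describe_cohort(
    dplyr::mutate(
      dplyr::left_join(dplyr::left_join(subjects, prs, by = "subject_id"),
                       mps, by = "subject_id"),
      childhood_trauma = as.integer(.data$cles > 0)
    )
  )

  data <- subjects |>
    dplyr::inner_join(brain, by = "subject_id") |>
    dplyr::left_join(prs, by = "subject_id") |>
    dplyr::left_join(mps, by = "subject_id")
  if (bds_only) data <- data[data$group == "BDS", , drop = FALSE]
  missing_scores <- data$subject_id[is.na(data$prs) | is.na(data$mps)]
  if (length(missing_scores) > 0) {
    stop(sprintf("analysis subject(s) without PRS/MPS: %s",
                 paste(head(missing_scores, 10), collapse = ", ")), call. = FALSE)
  }
  measures <- setdiff(names(brain), "subject_id")
  data[measures] <- lapply(measures, function(mcol) zscore(data[[mcol]], mcol))

  factors <- c("family_history", "cles", "prs", "mps")
  main_effects <- purrr::map_dfr(factors, function(f) {
    purrr::map_dfr(measures, function(mcol) {
      row <- fit_main_model(data, mcol, f, covariates)
      row$spearman_r <- spearman_corr(as_binary_numeric(data[[f]], f),
                                      data[[mcol]])
      row
    })
  })
  main_effects$q <- NA_real_
  if (fdr_family == "per_factor") {
    for (f in factors) {
      idx <- main_effects$factor == f
      main_effects$q[idx] <- suppressWarnings(storey_qvalues(main_effects$p[idx]))
    }
  } else {
    main_effects$q <- suppressWarnings(storey_qvalues(main_effects$p))
  }

  pairs <- list(clinical = c("family_history", "cles"),
                molecular = c("prs", "mps"))
  interactions <- purrr::map_dfr(names(pairs), function(pn) {
    rows <- purrr::map_dfr(measures, function(mcol) {
      fit_interaction_model(data, mcol, pairs[[pn]][1], pairs[[pn]][2],
                            covariates)
    })
    rows$pair <- pn
    rows$q <- suppressWarnings(storey_qvalues(rows$p))
    rows
  })

  bootstrap <- purrr::map_dfr(seq_along(measures), function(i) {
    bootstrap_compare_partial_r2(
      data, measures[i], pairs$clinical, pairs$molecular, covariates,
      n_boot = n_boot, seed = (seed + i) %% .Machine$integer.max
    )
  })

  structure(
    list(table1 = table1, main_effects = main_effects,
         interactions = interactions, bootstrap = bootstrap,
         n_analysis = nrow(data), measures = measures, factors = factors,
         covariates = covariates, fdr_family = fdr_family,
         n_boot = n_boot, seed = seed),
    class = "gxe_analysis"
  )
}

#' @export
print.gxe_analysis <- function(x, ...) {
  cat(sprintf(
    "<gxe_analysis> %d subjects, %d measures x %d factors; %d-rep bootstrap\n",
    x$n_analysis, length(x$measures), length(x$factors), x$n_boot))
  sig <- x$main_effects[x$main_effects$q < 0.1, c("factor", "measure", "q")]
  if (nrow(sig) > 0) {
    cat("main effects at FDR < 0.1:\n")
    print(as.data.frame(sig), row.names = FALSE)
  } else {
    cat("no main effects at FDR < 0.1\n")
  }
  invisible(x)
}

#' @export
tidy.gxe_analysis <- function(x, ...) x$main_effects

#' @export
glance.gxe_analysis <- function(x, ...) {
  tibble(
    n_analysis = x$n_analysis,
    n_measures = length(x$measures),
    n_factors = length(x$factors),
    n_main_fdr10 = sum(x$main_effects$q < 0.1, na.rm = TRUE),
    n_interaction_fdr10 = sum(x$interactions$q < 0.1, na.rm = TRUE),
    mean_partial_r2_molecular =
      mean(x$interactions$partial_r2[x$interactions$pair == "molecular"]),
    mean_partial_r2_clinical =
      mean(x$interactions$partial_r2[x$interactions$pair == "clinical"])
  )
}

#' Run configuration for the end-to-end pipeline
#'
#' Defaults for every stage: QC thresholds, clumping parameters, the PRS
#' threshold grid, LASSO settings, covariates, bootstrap size, FDR level and
#' seed. `read_run_config()` loads a YAML file and overlays it on these
#' defaults.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function(...) {
  cfg <- list(
    genotype_format = "vcf",
    call_rate_min = 0.95, maf_min = 0.01, hwe_min_p = 1e-6,
    gencall_min = 0.2, subject_call_rate_min = 0.95,
    clump_r2 = 0.1, clump_window_kb = 250,
    pt_grid = seq(0.01, 0.5, by = 0.01),
    prune_r2 = 0.2, prune_window = 50, prune_step = 5,
    pi_hat_max = 0.14,
    detection_p_max = 0.01, detection_fail_frac = 0.01,
    bead_min = 3, bead_fail_frac = 0.05,
    sample_pc_sd_limit = 4,
    lasso_nfolds = 5, lasso_rule = "1se",
    covariates = c("age", "gender", "race", "smoking"),
    n_boot = 2000, fdr_level = 0.1, fdr_family = "per_factor",
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop(sprintf("unknown run_config field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(modifyList(cfg, over), class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  over <- yaml::read_yaml(path)
  do.call(default_run_config, over %||% list())
}

#' Run the complete pipeline from files on disk
#'
#' Reads the cohort files, applies genotype QC and relatedness checks, clumps
#' and scores the PRS over the threshold grid with logistic threshold
#' selection, applies methylation QC, BMIQ normalization and the M-value
#' transform, fits the LASSO MPS, runs the full association stage, and writes
#' all result tables plus a JSON manifest (config, seed, package and R
#' versions, input checksums, warnings) to `out_dir`. Outputs are
#' byte-reproducible from the manifest's config and seed.
#'
#' @param paths Named list of input paths: `genotypes` (VCF, or dosage TSV
#'   with `variants`), `gwas`, `methylation_beta`, `methylation_probes`,
#'   optional `methylation_detection_p` / `methylation_bead_count`,
#'   `subjects`, `brain`.
#' @param out_dir Output directory.
#' @param config A [default_run_config()].
#' @return The `gxe_analysis` object, invisibly; results are on disk.
#' @export
run_pipeline <- function(paths, out_dir, config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("genotypes", "gwas", "methylation_beta", "methylation_probes",
              "subjects", "brain")) {
    if (is.null(paths[[p]])) stop(sprintf("missing input path: %s", p),
                                  call. = FALSE)
    if (!file.exists(paths[[p]])) stop(sprintf("input file not found: %s",
                                               paths[[p]]), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_notes <- character(0)
  note <- function(...) log_notes <<- c(log_notes, sprintf(...))

  subjects <- read_subjects(paths$subjects)
  brain <- read_brain_measures(paths$brain)
  geno <- read_genotypes(paths$genotypes, format = config$genotype_format,
                         variants_path = paths$variants)
  gwas <- read_gwas(paths$gwas)
  meth <- read_methylation(paths$methylation_beta, paths$methylation_probes,
                           detection_p_path = paths$methylation_detection_p,
                           bead_count_path = paths$methylation_bead_count)

  # --- genotype stage ---
  qc <- snp_qc(geno, call_rate_min = config$call_rate_min,
               maf_min = config$maf_min, hwe_min_p = config$hwe_min_p,
               gencall_min = config$gencall_min,
               subject_call_rate_min = config$subject_call_rate_min)
  note("genotype QC removed %d variants, %d subjects",
       qc$report$n_variants_removed, qc$report$n_subjects_removed)

  pruned <- ld_prune(qc$genotypes, r2_threshold = config$prune_r2,
                     window = config$prune_window, step = config$prune_step)
  ibd <- suppressWarnings(ibd_estimate(qc$genotypes, pruned))
  related <- ibd[ibd$pi_hat >= config$pi_hat_max, ]
  note("%d subject pair(s) with pi_hat >= %.2f", nrow(related),
       config$pi_hat_max)

  clumped <- greedy_clump(gwas, qc$genotypes, r2_threshold = config$clump_r2,
                          window_kb = config$clump_window_kb)
  fh <- subjects$family_history[match(subject_ids(qc$genotypes),
                                      subjects$subject_id)]
  prs <- optimize_threshold(qc$genotypes, gwas, clumped, fh,
                            grid = config$pt_grid)
  note("PRS threshold selected: p_T = %g (%d variants)",
       prs$p_threshold, length(prs$variant_ids))

  # --- methylation stage ---
  pqc <- probe_qc(meth, detection_p_max = config$detection_p_max,
                  detection_fail_frac = config$detection_fail_frac,
                  bead_min = config$bead_min,
                  bead_fail_frac = config$bead_fail_frac)
  note("probe QC removed %d probes", pqc$n_removed[["total"]])
  outliers <- sample_qc_pca(pqc$methylation, sd_limit = config$sample_pc_sd_limit)
  meth_clean <- pqc$methylation
  if (any(outliers$outlier)) {
    note("excluded %d methylation outlier subject(s)", sum(outliers$outlier))
    meth_clean <- subset_meth(meth_clean, subjects = which(!outliers$outlier))
  }
  normed <- withCallingHandlers(
    bmiq_normalize(meth_clean),
    warning = function(w) {
      note("bmiq: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  M <- logit_transform(normed)
  grp <- subjects$group[match(rownames(M), subjects$subject_id)]
  mps_model <- suppressWarnings(
    fit_lasso_mps(M, grp, nfolds = config$lasso_nfolds,
                  rule = config$lasso_rule, seed = config$seed))
  if (mps_model$n_selected == 0 && config$lasso_rule == "1se") {
    # an all-zero score is unusable downstream; retry at the CV minimum
    note("lasso: 1se rule selected no probes; refit with the min-CV lambda")
    mps_model <- suppressWarnings(
      fit_lasso_mps(M, grp, nfolds = config$lasso_nfolds,
                    rule = "min", seed = config$seed))
  }
  mps <- compute_mps(M, mps_model)
  note("MPS uses %d probes at lambda = %.4g", mps_model$n_selected,
       mps_model$lambda)

  # --- association stage ---
  analysis <- run_full_analysis(
    subjects, brain, prs$scores, mps,
    covariates = config$covariates, fdr_family = config$fdr_family,
    n_boot = config$n_boot, seed = config$seed
  )

  # --- outputs ---
  readr::write_tsv(prs$scores, file.path(out_dir, "prs_scores.tsv"), progress = FALSE)
  readr::write_tsv(prs$scan, file.path(out_dir, "prs_scan.tsv"), progress = FALSE)
  readr::write_tsv(mps, file.path(out_dir, "mps_scores.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(probes = mps_model$probes, intercept = mps_model$intercept,
         lambda = mps_model$lambda, rule = mps_model$rule, cv = mps_model$cv),
    file.path(out_dir, "mps_model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  readr::write_tsv(analysis$table1, file.path(out_dir, "table1.tsv"), progress = FALSE)
  readr::write_tsv(analysis$main_effects, file.path(out_dir, "main_effects.tsv"),
                   progress = FALSE)
  readr::write_tsv(analysis$interactions, file.path(out_dir, "interactions.tsv"),
                   progress = FALSE)
  readr::write_tsv(analysis$bootstrap, file.path(out_dir, "bootstrap.tsv"),
                   progress = FALSE)
  readr::write_tsv(ibd, file.path(out_dir, "ibd_pairs.tsv"), progress = FALSE)

  manifest <- list(
    package = "gxescore",
    package_version = as.character(packageVersion("gxescore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    inputs = lapply(paths[!vapply(paths, is.null, logical(1))], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    notes = log_notes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(analysis)
}
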