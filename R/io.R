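# Readers and writers for the pipeline's on-disk formats: VCF v4.2 or dosage
# TSV genotypes, GWAS summary TSV, methylation beta/annotation TSVs, subject
# and brain-measure TSVs, and a truth/provenance JSON.

#' Write genotypes as VCF v4.2
#'
#' Emits GT-only biallelic records (1-based positions); dosage 0/1/2 maps to
#' `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param geno A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- t(geno$dosage)  # variants x subjects
  gt <- matrix(gt_codes[as.character(d)], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gxescore",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosage)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load genotypes from VCF or dosage TSV
#'
#' For VCF, the dosage counts the ALT allele; non-biallelic sites are skipped
#' with a warning giving their count, and `./.` becomes missing. For TSV, two
#' files are used: a wide dosage table (`subject_id` plus one column per
#' variant) and a variant annotation table (`id`, `chrom`, `pos`, `ref`,
#' `alt`; `alt` is the counted allele).
#'
#' @param path VCF path, or dosage TSV path when `format = "tsv"`.
#' @param format `"vcf"` or `"tsv"`.
#' @param variants_path Variant annotation TSV (required for `format = "tsv"`).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), variants_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("genotype file not found: %s", path),
                               call. = FALSE)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    pos <- suppressWarnings(as.integer(fix$POS))
    if (anyNA(pos)) {
      stop(sprintf("malformed VCF record(s) at data line(s): %s (non-numeric POS)",
                   paste(which(is.na(pos)), collapse = ", ")), call. = FALSE)
    }
    multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | nchar(fix$REF) != 1 |
      nchar(fix$ALT) != 1
    if (any(multi)) {
      warning(sprintf("skipped %d non-biallelic/non-SNP site(s)", sum(multi)),
              call. = FALSE)
    }
    keep <- !multi
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    gt <- gsub("\\|", "/", gt)
    code <- c(`0/0` = 0, `0/1` = 1, `1/0` = 1, `1/1` = 2)
    d <- matrix(code[gt], nrow(gt), ncol(gt))
    unknown <- !is.na(gt) & gt != "./." & is.na(d)
    if (any(unknown)) {
      stop(sprintf("unparseable genotype call(s) in %d record(s)",
                   length(unique(which(unknown, arr.ind = TRUE)[, 1]))),
           call. = FALSE)
    }
    variants <- tibble(
      id = fix$ID[keep], chrom = suppressWarnings(as.integer(fix$CHROM[keep])),
      pos = pos[keep], ref = fix$REF[keep], alt = fix$ALT[keep]
    )
    dosage <- t(d)
    rownames(dosage) <- colnames(gt)
    geno_matrix(dosage, variants)
  } else {
    if (is.null(variants_path)) {
      stop("variants_path is required for dosage TSV input", call. = FALSE)
    }
    dos <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    validate_table(dos, "subject_id", "dosage table")
    variants <- readr::read_tsv(variants_path, show_col_types = FALSE,
                                progress = FALSE)
    validate_table(variants, c("id", "chrom", "pos", "ref", "alt"), "variants")
    m <- as.matrix(dos[, setdiff(names(dos), "subject_id"), drop = FALSE])
    rownames(m) <- dos$subject_id
    if (!identical(colnames(m), variants$id)) {
      missing_v <- setdiff(colnames(m), variants$id)
      if (length(missing_v)) {
        stop(sprintf("dosage columns lack annotation: %s",
                     paste(head(missing_v, 5), collapse = ", ")), call. = FALSE)
      }
      variants <- variants[match(colnames(m), variants$id), ]
    }
    geno_matrix(m, variants)
  }
}

write_dosage_tsv <- function(geno, path, variants_path) {
  d <- as_tibble(geno$dosage)
  out <- dplyr::bind_cols(tibble(subject_id = rownames(geno$dosage)), d)
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(geno$variants, variants_path, progress = FALSE)
  invisible(path)
}

#' Read / write GWAS summary statistics
#'
#' The TSV uses PLINK-style columns `SNP`, `CHR`, `BP`, `A1` (effect allele),
#' `A2`, `BETA` (log-odds weight) and `P`. An `OR` column is accepted in place
#' of `BETA` and log-transformed on read.
#'
#' @param path TSV path.
#' @return Tibble with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight`, `p_value`.
#' @export
read_gwas <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(x, c("SNP", "CHR", "BP", "A1", "A2", "P"), "GWAS summary")
  if (!("BETA" %in% names(x)) && !("OR" %in% names(x))) {
    stop("GWAS summary needs a BETA or OR column", call. = FALSE)
  }
  w <- if ("BETA" %in% names(x)) x$BETA else log(x$OR)
  out <- tibble(id = x$SNP, chrom = x$CHR, pos = x$BP,
                effect_allele = x$A1, other_allele = x$A2,
                weight = w, p_value = x$P)
  if (any(!is.finite(out$weight))) stop("non-finite GWAS weights", call. = FALSE)
  if (any(out$p_value <= 0 | out$p_value > 1)) {
    stop("GWAS p-values must lie in (0, 1]", call. = FALSE)
  }
  out
}

#' @rdname read_gwas
#' @param gwas Tibble as returned by [simulate_gwas_weights()] or [read_gwas()].
#' @export
write_gwas <- function(gwas, path) {
  readr::write_tsv(
    tibble(SNP = gwas$id, CHR = gwas$chrom, BP = gwas$pos,
           A1 = gwas$effect_allele, A2 = gwas$other_allele,
           BETA = gwas$weight, P = gwas$p_value),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read / write methylation matrices
#'
#' The beta TSV is probes x subjects (first column `probe_id`) or its
#' transpose (first column `subject_id`); the orientation is auto-detected
#' from the header. Optional detection-p and bead-count TSVs mirror the beta
#' layout. The probe annotation TSV carries `probe_id`, `chrom`, `pos`,
#' `design_type`, `snp_overlap`.
#'
#' @param beta_path,annot_path,detection_p_path,bead_count_path File paths.
#' @return A [meth_matrix()].
#' @export
read_methylation <- function(beta_path, annot_path,
                             detection_p_path = NULL, bead_count_path = NULL) {
  read_layout <- function(path) {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    first <- names(x)[1]
    if (!first %in% c("probe_id", "subject_id")) {
      stop(sprintf("first column of %s must be 'probe_id' or 'subject_id'",
                   path), call. = FALSE)
    }
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x[[1]]
    if (first == "probe_id") m <- t(m)  # to subjects x probes
    m
  }
  beta <- read_layout(beta_path)
  probes <- readr::read_tsv(annot_path, show_col_types = FALSE, progress = FALSE)
  validate_table(probes, c("probe_id", "chrom", "pos", "design_type", "snp_overlap"),
                 "probe annotation")
  probes <- probes[match(colnames(beta), probes$probe_id), ]
  if (anyNA(probes$probe_id)) {
    stop("beta matrix has probes missing from the annotation", call. = FALSE)
  }
  dp <- if (is.null(detection_p_path)) NULL else read_layout(detection_p_path)
  bc <- if (is.null(bead_count_path)) NULL else read_layout(bead_count_path)
  meth_matrix(beta, probes, detection_p = dp, bead_count = bc)
}

write_methylation <- function(meth, dir, prefix = "methylation") {
  write_layout <- function(m, path) {
    out <- dplyr::bind_cols(tibble(probe_id = colnames(m)), as_tibble(t(m)))
    readr::write_tsv(out, path, progress = FALSE)
  }
  beta_path <- file.path(dir, paste0(prefix, "_beta.tsv"))
  write_layout(meth$beta, beta_path)
  readr::write_tsv(meth$probes, file.path(dir, paste0(prefix, "_probes.tsv")),
                   progress = FALSE)
  if (!is.null(meth$detection_p)) {
    write_layout(meth$detection_p, file.path(dir, paste0(prefix, "_detection_p.tsv")))
  }
  if (!is.null(meth$bead_count)) {
    write_layout(meth$bead_count, file.path(dir, paste0(prefix, "_bead_count.tsv")))
  }
  invisible(beta_path)
}

#' Write a simulated cohort to disk
#'
#' Emits the exact formats the analysis stages read: genotypes (VCF v4.2 or
#' dosage + variant TSVs), GWAS summary TSV, methylation beta / annotation /
#' detection-p / bead-count TSVs, subject TSV, brain-measure TSV, and the
#' ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @param genotype_format `"vcf"` or `"tsv"`.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("vcf", "tsv")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (genotype_format == "vcf") {
    paths$genotypes <- file.path(dir, "genotypes.vcf")
    write_vcf(cohort$genotypes, paths$genotypes)
  } else {
    paths$genotypes <- file.path(dir, "dosages.tsv")
    paths$variants <- file.path(dir, "variants.tsv")
    write_dosage_tsv(cohort$genotypes, paths$genotypes, paths$variants)
  }
  paths$gwas <- file.path(dir, "gwas.tsv")
  write_gwas(cohort$gwas, paths$gwas)
  write_methylation(cohort$methylation, dir)
  paths$methylation_beta <- file.path(dir, "methylation_beta.tsv")
  paths$methylation_probes <- file.path(dir, "methylation_probes.tsv")
  paths$methylation_detection_p <- file.path(dir, "methylation_detection_p.tsv")
  paths$methylation_bead_count <- file.path(dir, "methylation_bead_count.tsv")
  paths$subjects <- file.path(dir, "subjects.tsv")
  readr::write_tsv(cohort$subjects, paths$subjects, progress = FALSE)
  paths$brain <- file.path(dir, "brain_measures.tsv")
  readr::write_tsv(cohort$brain, paths$brain, progress = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(causal_snp_ids = cohort$truth$causal_snp_ids,
         true_snp_weights = as.list(cohort$truth$true_snp_weights),
         signal_probe_ids = cohort$truth$signal_probe_ids,
         true_probe_directions = as.list(cohort$truth$true_probe_directions),
         true_effects = cohort$truth$true_effects,
         seed = cohort$config$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read subject and brain-measure tables
#'
#' @param path TSV path.
#' @return A tibble; required columns are validated before return.
#' @export
read_subjects <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(x, c("subject_id", "group", "family_history", "cles", "age",
                      "gender", "race", "smoking"), "subjects")
  x
}

#' @rdname read_subjects
#' @export
read_brain_measures <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(x, "subject_id", "brain measures")
  x
}
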