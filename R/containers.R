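#' Genotype matrix container
#'
#' Bundles an additive-dosage matrix (subjects x variants, values 0/1/2 or NA
#' counting the ALT / declared counted allele) with its variant metadata and an
#' optional per-call quality matrix (GenCall-like score in \[0,1\]).
#'
#' @param dosage Numeric matrix, subjects in rows, variants in columns.
#'   Row names are subject ids, column names variant ids.
#' @param variants Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param quality Optional numeric matrix of the same shape as `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, quality = NULL) {
  variants <- as_tibble(variants)
  validate_table(variants, c("id", "chrom", "pos", "ref", "alt"), "variants")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique", call. = FALSE)
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage columns and variant records differ in number", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- variants$id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("dosage values must lie in [0, 2]", call. = FALSE)
  }
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    if (!all(dim(quality) == dim(dosage))) {
      stop("quality matrix must match dosage dimensions", call. = FALSE)
    }
    dimnames(quality) <- dimnames(dosage)
  }
  structure(
    list(dosage = dosage, variants = variants, quality = quality),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d subjects x %d variants (%.2f%% missing)%s\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage)),
    if (is.null(x$quality)) "" else ", with per-call quality"
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

subject_ids <- function(x) rownames(x$dosage)

# Subset a geno_matrix by subject and/or variant index or id.
subset_geno <- function(geno, subjects = NULL, variants = NULL) {
  si <- if (is.null(subjects)) seq_len(nrow(geno$dosage)) else subjects
  vi <- if (is.null(variants)) seq_len(ncol(geno$dosage)) else variants
  if (is.character(vi)) vi <- match(vi, geno$variants$id)
  if (is.character(si)) si <- match(si, rownames(geno$dosage))
  geno_matrix(
    geno$dosage[si, vi, drop = FALSE],
    geno$variants[vi, , drop = FALSE],
    quality = if (is.null(geno$quality)) NULL else geno$quality[si, vi, drop = FALSE]
  )
}

#' Methylation matrix container
#'
#' Beta values (strictly inside (0,1) after load-time clamping) for subjects x
#' probes, plus probe annotation and optional detection-p and bead-count
#' matrices mirroring the beta layout.
#'
#' @param beta Numeric matrix, subjects in rows, probes in columns.
#' @param probes Tibble with columns `probe_id`, `chrom`, `pos`, `design_type`
#'   (values `"I"` or `"II"`) and `snp_overlap` (logical: SNP at the CpG
#'   interrogation or single-base-extension site).
#' @param detection_p,bead_count Optional matrices of the same shape as `beta`.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(beta, probes, detection_p = NULL, bead_count = NULL) {
  probes <- as_tibble(probes)
  validate_table(probes, c("probe_id", "chrom", "pos", "design_type", "snp_overlap"),
                 "probes")
  if (anyDuplicated(probes$probe_id)) stop("probe ids must be unique", call. = FALSE)
  if (!all(probes$design_type %in% c("I", "II"))) {
    stop("design_type must be 'I' or 'II'", call. = FALSE)
  }
  beta <- as.matrix(beta)
  if (ncol(beta) != nrow(probes)) {
    stop("beta columns and probe records differ in number", call. = FALSE)
  }
  if (is.null(rownames(beta))) rownames(beta) <- sprintf("S%04d", seq_len(nrow(beta)))
  colnames(beta) <- probes$probe_id
  beta[] <- clamp_unit(beta)
  chk <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(beta))) stop(sprintf("%s must match beta dimensions", nm),
                                        call. = FALSE)
    dimnames(m) <- dimnames(beta)
    m
  }
  structure(
    list(beta = beta, probes = probes,
         detection_p = chk(detection_p, "detection_p"),
         bead_count = chk(bead_count, "bead_count")),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "<meth_matrix> %d subjects x %d probes (type I: %d, type II: %d)%s%s\n",
    nrow(x$beta), ncol(x$beta),
    sum(x$probes$design_type == "I"), sum(x$probes$design_type == "II"),
    if (is.null(x$detection_p)) "" else ", detection-p",
    if (is.null(x$bead_count)) "" else ", bead-count"
  ))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

subset_meth <- function(meth, subjects = NULL, probes = NULL) {
  si <- if (is.null(subjects)) seq_len(nrow(meth$beta)) else subjects
  pi_ <- if (is.null(probes)) seq_len(ncol(meth$beta)) else probes
  if (is.character(pi_)) pi_ <- match(pi_, meth$probes$probe_id)
  if (is.character(si)) si <- match(si, rownames(meth$beta))
  meth_matrix(
    meth$beta[si, pi_, drop = FALSE],
    meth$probes[pi_, , drop = FALSE],
    detection_p = if (is.null(meth$detection_p)) NULL else meth$detection_p[si, pi_, drop = FALSE],
    bead_count = if (is.null(meth$bead_count)) NULL else meth$bead_count[si, pi_, drop = FALSE]
  )
}
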