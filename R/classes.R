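#' Construct a genotype dataset
#'
#' The central container every genetic stage of the pipeline transforms: a
#' sample-by-variant dosage matrix counting copies of `allele_1` (the PLINK
#' A1 allele), together with per-sample and per-variant metadata.
#'
#' Dosages are integers in `{0, 1, 2}` with `NA` for missing calls. All
#' downstream allele arithmetic (scoring, harmonization, frequency
#' estimation) refers to copies of `allele_1`; this convention is fixed
#' package-wide so effect signs are never ambiguous.
#'
#' @param dosage integer matrix, `n_samples x n_variants`, values in
#'   `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `allele_1`, `allele_2`, and optionally `imputation_r2` in `[0, 1]`.
#' @param samples data.frame with column `sample_id` and optionally `sex`
#'   (`"male"`, `"female"`, `"unknown"`), `age`, `diagnosis`, quantitative
#'   phenotype columns, `population`, `ancestry_label`.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  ds <- structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset's invariants
#'
#' Checks dimension agreement between dosage and metadata, dosage range,
#' uniqueness of sample ids, 1-based positions, distinct alleles, and the
#' `[0, 1]` range of any imputation r-squared values.
#'
#' @param ds a `genotype_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (nrow(ds$dosage) != nrow(ds$samples))
    stop("dosage row count (", nrow(ds$dosage), ") != sample count (",
         nrow(ds$samples), ")")
  if (ncol(ds$dosage) != nrow(ds$variants))
    stop("dosage column count (", ncol(ds$dosage), ") != variant count (",
         nrow(ds$variants), ")")
  d <- ds$dosage[!is.na(ds$dosage)]
  if (length(d) && (min(d) < 0L || max(d) > 2L))
    stop("dosages must be in {0, 1, 2, NA}")
  req_v <- c("id", "chrom", "pos", "allele_1", "allele_2")
  miss <- setdiff(req_v, names(ds$variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(ds$samples)) stop("samples lacks sample_id")
  if (anyDuplicated(ds$samples$sample_id))
    stop("duplicate sample ids")
  if (nrow(ds$variants)) {
    if (any(ds$variants$pos < 1)) stop("positions must be 1-based integers >= 1")
    if (any(ds$variants$allele_1 == ds$variants$allele_2))
      stop("allele_1 must differ from allele_2")
    if ("imputation_r2" %in% names(ds$variants)) {
      r2 <- ds$variants$imputation_r2
      if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
        stop("imputation_r2 must lie in [0, 1]")
    }
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset by samples and/or variants
#'
#' @param ds a `genotype_dataset`.
#' @param samples logical/integer/character index over samples (default all).
#' @param variants logical/integer/character index over variants (default all).
#' @return a `genotype_dataset` restricted to the selection.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, ds$samples$sample_id, nrow(ds$samples))
  vi <- resolve_index(variants, ds$variants$id, nrow(ds$variants))
  genotype_dataset(
    dosage = ds$dosage[si, vi, drop = FALSE],
    variants = ds$variants[vi, , drop = FALSE],
    samples = ds$samples[si, , drop = FALSE]
  )
}

resolve_index <- function(idx, ids, n) {
  if (is.null(idx)) return(seq_len(n))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ids: ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) {
    stopifnot(length(idx) == n)
    return(which(idx))
  }
  as.integer(idx)
}

#' Allele-1 frequency per variant
#'
#' Missing calls are excluded from both numerator and denominator.
#'
#' @param ds a `genotype_dataset`.
#' @return numeric vector of allele_1 frequencies (NaN if all calls missing).
#' @export
allele_freq <- function(ds) {
  colMeans(ds$dosage, na.rm = TRUE) / 2
}
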