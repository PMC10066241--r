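# Sequential genotype quality control: variant missingness, sample
# missingness, heterozygosity deviation (fhet), re-filtered variant
# missingness, exact Hardy-Weinberg, duplicate removal, strand-ambiguous
# removal, imputation-quality filtering. Statistics are recomputed on the
# currently retained samples before each step.

#' Quality-control configuration
#'
#' Thresholds of the sequential QC filters, applied in this fixed order:
#' variant missingness > `snp_miss_1`; sample missingness > `sample_miss`;
#' |fhet| > `fhet_limit`; variant missingness > `snp_miss_2`;
#' Hardy-Weinberg exact p < `hwe_p`; duplicated variants (same chromosome,
#' position and allele set; first kept); strand-ambiguous variants (A/T,
#' C/G); imputation r-squared <= `imputation_r2_min` (only when the dataset
#' carries imputation quality). All comparisons are strict, so values
#' exactly at a threshold are retained.
#'
#' @param snp_miss_1 first variant-missingness threshold (default 0.05).
#' @param sample_miss sample-missingness threshold (default 0.02).
#' @param fhet_limit absolute inbreeding-coefficient limit (default 0.2).
#' @param snp_miss_2 second variant-missingness threshold (default 0.02).
#' @param hwe_p Hardy-Weinberg exact-test removal level (default 1e-6).
#' @param imputation_r2_min minimum (exclusive) imputation r-squared
#'   (default 0.8).
#' @param drop_duplicates,drop_ambiguous logical switches for the last two
#'   variant filters.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(snp_miss_1 = 0.05, sample_miss = 0.02,
                      fhet_limit = 0.2, snp_miss_2 = 0.02, hwe_p = 1e-6,
                      imputation_r2_min = 0.8, drop_duplicates = TRUE,
                      drop_ambiguous = TRUE) {
  thr <- c(snp_miss_1, sample_miss, fhet_limit, snp_miss_2, hwe_p,
           imputation_r2_min)
  if (any(thr <= 0 | thr >= 1)) stop("all thresholds must lie in (0, 1)")
  structure(list(snp_miss_1 = snp_miss_1, sample_miss = sample_miss,
                 fhet_limit = fhet_limit, snp_miss_2 = snp_miss_2,
                 hwe_p = hwe_p, imputation_r2_min = imputation_r2_min,
                 drop_duplicates = drop_duplicates,
                 drop_ambiguous = drop_ambiguous),
            class = "qc_config")
}

#' Per-variant missing-call fraction
#'
#' @param ds a [genotype_dataset].
#' @return numeric vector, missing calls / n_samples per variant.
#' @export
variant_missingness <- function(ds) {
  if (nrow(ds$samples) == 0) stop("empty dataset")
  colMeans(is.na(ds$dosage))
}

#' Per-sample missing-call fraction
#'
#' @param ds a [genotype_dataset].
#' @return numeric vector, missing calls / n_variants per sample.
#' @export
sample_missingness <- function(ds) {
  if (nrow(ds$variants) == 0) stop("empty dataset")
  rowMeans(is.na(ds$dosage))
}

#' Per-sample inbreeding coefficient (fhet)
#'
#' The method-of-moments estimator F = (O_hom - E_hom) / (m - E_hom),
#' where over the sample's non-missing variants O_hom is the observed
#' homozygote count, E_hom = sum(1 - 2 p (1 - p)) the expected count at the
#' cohort allele frequencies, and m the non-missing variant count. Samples
#' whose non-missing variants are all monomorphic have an undefined F and
#' are reported as 0 with a warning flag.
#'
#' @param ds a [genotype_dataset] (frequencies estimated from its samples).
#' @return data.frame: `sample_id`, `fhet`, `undefined` (logical flag).
#' @export
compute_fhet <- function(ds) {
  if (nrow(ds$samples) < 2) stop("need >= 2 samples to estimate frequencies")
  p <- allele_freq(ds)
  exp_hom_v <- 1 - 2 * p * (1 - p)
  obs <- ds$dosage != 1L                     # TRUE at homozygotes, NA at missing
  nonmiss <- !is.na(ds$dosage)
  o_hom <- rowSums(obs, na.rm = TRUE)
  e_hom <- (nonmiss %*% exp_hom_v)[, 1]
  m <- rowSums(nonmiss)
  denom <- m - e_hom
  undefined <- abs(denom) < .Machine$double.eps^0.5
  fhet <- ifelse(undefined, 0, (o_hom - e_hom) / denom)
  if (any(undefined))
    warning(sum(undefined), " sample(s) had undefined fhet (all variants ",
            "monomorphic); reported as 0")
  data.frame(sample_id = ds$samples$sample_id, fhet = fhet,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Exact Hardy-Weinberg equilibrium test per variant
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' probabilities of all possible heterozygote counts are enumerated and
#' those no larger than the observed configuration's probability are
#' summed (plain, not mid-p). Monomorphic variants return p = 1.
#'
#' @param ds a [genotype_dataset], or a 3-column matrix of genotype counts
#'   (n_hom_a1, n_het, n_hom_a2) with one row per variant.
#' @return numeric vector of exact p-values.
#' @export
hwe_test <- function(ds) {
  counts <- if (inherits(ds, "genotype_dataset")) genotype_counts(ds) else ds
  apply(counts, 1L, function(cc) hwe_exact_p(cc[1], cc[2], cc[3]))
}

genotype_counts <- function(ds) {
  d <- ds$dosage
  cbind(n_hom_a1 = colSums(d == 2L, na.rm = TRUE),
        n_het = colSums(d == 1L, na.rm = TRUE),
        n_hom_a2 = colSums(d == 0L, na.rm = TRUE))
}

# exact HWE p for one variant; enumeration over heterozygote counts
# conditional on allele counts, in log space for numerical range
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)                   # monomorphic
  hets <- seq.int(rare %% 2, rare, by = 2L)  # feasible heterozygote counts
  # P(n_het = h | n_a, n_b) proportional to 2^h / (n_aa! n_ab! n_bb!)
  hom_r <- (rare - hets) / 2
  hom_c <- n - hets - hom_r                  # common-allele homozygotes
  logp <- hets * log(2) - lfactorial(hom_r) - lfactorial(hets) -
    lfactorial(hom_c)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_ab, hets)]
  sum(prob[prob <= obs + 1e-12 * obs])
}

#' Is a variant strand-ambiguous?
#'
#' A/T and C/G allele pairs cannot be resolved against an unknown strand.
#'
#' @param allele_1,allele_2 character vectors of alleles in {A,C,G,T}.
#' @return logical vector.
#' @export
strand_ambiguous <- function(allele_1, allele_2) {
  (allele_1 == "A" & allele_2 == "T") | (allele_1 == "T" & allele_2 == "A") |
    (allele_1 == "C" & allele_2 == "G") | (allele_1 == "G" & allele_2 == "C")
}

#' Apply the sequential quality-control filters
#'
#' Runs the filters in the fixed order documented at [qc_config()],
#' recomputing missingness, allele frequencies and Hardy-Weinberg
#' statistics on the retained data before each step, and returns the
#' filtered dataset with a per-step report.
#'
#' @param ds a [genotype_dataset].
#' @param config a [qc_config()].
#' @return list: `ds` (filtered), `report` (data.frame with one row per
#'   step: step name, axis, number removed, remaining dimensions), `fhet`
#'   (per-sample fhet table), `hwe_p` (per-variant p-values at the HWE
#'   step, named by variant id).
#' @export
apply_qc <- function(ds, config = qc_config()) {
  validate_genotype_dataset(ds)
  steps <- list()
  note <- function(step, axis, removed) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, axis = axis, n_removed = removed,
      n_samples = nrow(ds$samples), n_variants = nrow(ds$variants),
      stringsAsFactors = FALSE)
  }
  check_empty <- function() {
    if (nrow(ds$samples) == 0 || nrow(ds$variants) == 0)
      stop("empty after QC")
  }

  keep <- variant_missingness(ds) <= config$snp_miss_1
  ds <- subset_dataset(ds, variants = keep)
  note("variant_missingness_1", "variant", sum(!keep)); check_empty()

  keep <- sample_missingness(ds) <= config$sample_miss
  ds <- subset_dataset(ds, samples = keep)
  note("sample_missingness", "sample", sum(!keep)); check_empty()

  fhet <- compute_fhet(ds)
  keep <- abs(fhet$fhet) <= config$fhet_limit
  ds <- subset_dataset(ds, samples = keep)
  note("fhet", "sample", sum(!keep)); check_empty()

  keep <- variant_missingness(ds) <= config$snp_miss_2
  ds <- subset_dataset(ds, variants = keep)
  note("variant_missingness_2", "variant", sum(!keep)); check_empty()

  hwe_p <- hwe_test(ds)
  names(hwe_p) <- ds$variants$id
  keep <- hwe_p >= config$hwe_p
  ds <- subset_dataset(ds, variants = keep)
  note("hwe", "variant", sum(!keep)); check_empty()

  if (config$drop_duplicates) {
    key <- with(ds$variants, paste(chrom, pos,
                                   pmin(allele_1, allele_2),
                                   pmax(allele_1, allele_2)))
    keep <- !duplicated(key)
    ds <- subset_dataset(ds, variants = keep)
    note("duplicates", "variant", sum(!keep)); check_empty()
  }

  if (config$drop_ambiguous) {
    keep <- !strand_ambiguous(ds$variants$allele_1, ds$variants$allele_2)
    ds <- subset_dataset(ds, variants = keep)
    note("strand_ambiguous", "variant", sum(!keep)); check_empty()
  }

  if ("imputation_r2" %in% names(ds$variants)) {
    keep <- is.na(ds$variants$imputation_r2) |
      ds$variants$imputation_r2 > config$imputation_r2_min
    ds <- subset_dataset(ds, variants = keep)
    note("imputation_r2", "variant", sum(!keep)); check_empty()
  }

  report <- do.call(rbind, steps)
  list(ds = ds, report = report, fhet = fhet, hwe_p = hwe_p)
}
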