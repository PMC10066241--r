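# KING-robust kinship estimation, relationship classification at the
# standard kin/k0 thresholds, and pruning of related samples.

#' Greedy LD pruning
#'
#' Left-to-right scan within each chromosome over variants sorted by
#' position: a variant is dropped when its squared dosage correlation with
#' any already-retained variant within `window_bp` upstream exceeds
#' `r2_max`. Monomorphic variants have no defined correlation; they are
#' skipped and are not eligible for retention.
#'
#' @param ds a [genotype_dataset] with variants sorted by (chrom, pos).
#' @param window_bp physical window in base pairs (default 1e7).
#' @param r2_max maximum squared correlation with retained variants
#'   (default 0.1, i.e. correlation sqrt(0.1)).
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(ds, window_bp = 1e7, r2_max = 0.1) {
  v <- ds$variants
  unsorted <- tapply(v$pos, factor(v$chrom, levels = unique(v$chrom)),
                     is.unsorted)
  if (any(unsorted))
    stop("variants must be sorted by position within each chromosome")
  x <- mean_impute(ds$dosage)
  sds <- apply(x, 2L, stats::sd)
  poly <- sds > 0
  retained <- integer(0)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    kept_chr <- integer(0)
    for (j in idx) {
      if (!poly[j]) next
      inwin <- kept_chr[v$pos[kept_chr] >= v$pos[j] - window_bp]
      drop <- FALSE
      if (length(inwin)) {
        r <- suppressWarnings(
          stats::cor(x[, j], x[, inwin, drop = FALSE]))
        drop <- any(r^2 > r2_max, na.rm = TRUE)
      }
      if (!drop) kept_chr <- c(kept_chr, j)
    }
    retained <- c(retained, kept_chr)
  }
  v$id[sort(retained)]
}

mean_impute <- function(d) {
  x <- d
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- mu[na_idx[, 2]]
    x[is.na(x)] <- 0  # all-missing column
  }
  x
}

#' KING-robust pairwise kinship and zero-IBD estimates
#'
#' For each unordered sample pair, over the variants non-missing in both
#' members: kin = (N_both_het - 2 N_opposite_hom) / (N_het_i + N_het_j),
#' the KING-robust within-family estimator; k0 is the observed
#' opposite-homozygote count divided by its expectation for an unrelated
#' pair at cohort allele frequencies, E0 = sum over used variants of
#' 2 p^2 (1 - p)^2. True values by relationship: MZ 0.5/0,
#' parent-offspring 0.25/0, full siblings 0.25/0.25, second degree
#' 0.125/0.5, unrelated 0/1. Pairs with no heterozygotes in either member
#' have undefined kin and are flagged and labelled unrelated.
#'
#' @param ds a [genotype_dataset].
#' @param variant_ids optional subset of variant ids (e.g. from
#'   [ld_prune()]); default all.
#' @param classify logical; attach relationship labels via
#'   [classify_relationship()] (default TRUE).
#' @param freqs optional allele_1 frequencies for the k0 expectation,
#'   aligned to the (subset) variants; defaults to frequencies estimated
#'   from `ds` itself. Supply cohort-level frequencies when `ds` holds
#'   only the pair of interest.
#' @return data.frame of class `kinship_result`: `id1`, `id2`, `kin`,
#'   `k0`, `n_informative` (shared non-missing variants), `undefined`,
#'   and `label` when classified.
#' @export
king_kinship <- function(ds, variant_ids = NULL, classify = TRUE,
                         freqs = NULL) {
  if (!is.null(variant_ids)) ds <- subset_dataset(ds, variants = variant_ids)
  d <- ds$dosage
  n <- nrow(d)
  if (n < 2) stop("need >= 2 samples")
  H <- (d == 1L); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  A <- (d == 2L); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- (d == 0L); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  M <- !is.na(d); storage.mode(M) <- "double"
  p <- if (is.null(freqs)) allele_freq(ds) else freqs
  if (length(p) != ncol(d)) stop("freqs length must match variant count")
  w0 <- 2 * p^2 * (1 - p)^2
  w0[is.na(w0)] <- 0

  both_het <- tcrossprod(H)
  opp <- tcrossprod(A, B); opp <- opp + t(opp)
  het_i_shared <- tcrossprod(H, M)             # het in i among j's non-missing
  e0 <- tcrossprod(sweep(M, 2L, sqrt(w0), `*`))
  n_inf <- tcrossprod(M)

  ut <- which(upper.tri(both_het), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  denom <- het_i_shared[cbind(i, j)] + het_i_shared[cbind(j, i)]
  undefined <- denom == 0
  kin <- ifelse(undefined, NA_real_,
                (both_het[cbind(i, j)] - 2 * opp[cbind(i, j)]) / denom)
  k0 <- ifelse(e0[cbind(i, j)] > 0, opp[cbind(i, j)] / e0[cbind(i, j)],
               NA_real_)
  res <- data.frame(id1 = ds$samples$sample_id[i],
                    id2 = ds$samples$sample_id[j],
                    kin = kin, k0 = k0, n_informative = n_inf[cbind(i, j)],
                    undefined = undefined, stringsAsFactors = FALSE)
  if (classify)
    res$label <- classify_relationship(res$kin, res$k0)
  class(res) <- c("kinship_result", "data.frame")
  res
}

#' Classify a relative pair from its kin/k0 estimates
#'
#' The rule cascade is applied in order, first match wins: monozygotic
#' twins (kin > 0.45, k0 < 0.2); parent-offspring (0.24 < kin < 0.26,
#' k0 < 0.01); full siblings (0.2 < kin < 0.3, 0.1 < k0 < 0.4);
#' second-degree relatives (2^(-9/2) < kin < 0.2, k0 > 0.23); otherwise
#' unrelated. Non-finite inputs classify as unrelated.
#'
#' @param kin,k0 numeric vectors of kinship and zero-IBD estimates.
#' @return character vector of labels.
#' @export
classify_relationship <- function(kin, k0) {
  lab <- rep("unrelated", length(kin))
  ok <- is.finite(kin) & is.finite(k0)
  mz <- ok & kin > 0.45 & k0 < 0.2
  po <- ok & !mz & kin > 0.24 & kin < 0.26 & k0 < 0.01
  fs <- ok & !mz & !po & kin > 0.2 & kin < 0.3 & k0 > 0.1 & k0 < 0.4
  sd2 <- ok & !mz & !po & !fs & kin > 2^(-9 / 2) & kin < 0.2 & k0 > 0.23
  lab[mz] <- "MZ"
  lab[po] <- "parent-offspring"
  lab[fs] <- "full-sibling"
  lab[sd2] <- "second-degree"
  lab
}

#' Samples to remove due to relatedness
#'
#' Every sample participating in any pair classified second-degree or
#' closer is removed -- both members of each flagged pair, and therefore
#' the closure over chains of flagged pairs. A greedy alternative that
#' keeps a maximal set of mutually unrelated samples is available via
#' `keep_one = TRUE`.
#'
#' @param kinship a `kinship_result` with labels.
#' @param keep_one logical; if TRUE, greedily retain one member per
#'   related cluster (removing the sample involved in the most flagged
#'   pairs first) instead of removing both members.
#' @return character vector of sample ids to remove.
#' @export
prune_related <- function(kinship, keep_one = FALSE) {
  rel <- kinship[kinship$label != "unrelated", , drop = FALSE]
  if (nrow(rel) == 0) return(character(0))
  if (!keep_one) return(sort(unique(c(rel$id1, rel$id2))))
  removed <- character(0)
  repeat {
    act <- rel[!(rel$id1 %in% removed) & !(rel$id2 %in% removed), ,
               drop = FALSE]
    if (nrow(act) == 0) break
    cnt <- sort(table(c(act$id1, act$id2)), decreasing = TRUE)
    removed <- c(removed, names(cnt)[1])
  }
  sort(removed)
}
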