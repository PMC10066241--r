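# Summary-statistic harmonization to the target allele coding, greedy
# p-value-aware LD clumping, and pruning-and-thresholding polygenic scores.

#' Default p-value threshold grid
#'
#' Thirteen thresholds from genome-wide significance to all variants.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1.0)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary statistics to the target allele coding
#'
#' Each summary-statistics row is matched to a target variant by id (with
#' a chrom:pos fallback for ids absent from the target) and its effect is
#' re-expressed per copy of the target's `allele_1`. Strand-ambiguous
#' rows (A/T, C/G) are dropped before any matching since their strand
#' cannot be resolved. If the allele pair matches directly the action is
#' `match` (effect allele = allele_1) or `sign-flip` (effect allele =
#' allele_2, beta negated); otherwise both alleles are strand-complemented
#' and re-tried (`strand-flip`, `strand-flip+sign-flip`); irreconcilable
#' pairs are `drop-mismatch` and unmatched rows `drop-absent`.
#'
#' @param sumstats summary-statistics data.frame (as from
#'   [read_sumstats()] or [simulate_sumstats()]).
#' @param ds target [genotype_dataset].
#' @return list of class `harmonization_result`: `table` (data.frame:
#'   `id`, `action`, `target_id`, `aligned_beta`, `pvalue`) and
#'   `action_counts` (named table of actions).
#' @export
harmonize <- function(sumstats, ds) {
  ss <- as.data.frame(sumstats, stringsAsFactors = FALSE)
  tv <- ds$variants
  if (anyDuplicated(ss$id))
    stop("duplicate ids in summary statistics: ",
         paste(utils::head(unique(ss$id[duplicated(ss$id)]), 5), collapse = ", "))
  if (anyDuplicated(tv$id))
    stop("duplicate ids in target variants: ",
         paste(utils::head(unique(tv$id[duplicated(tv$id)]), 5), collapse = ", "))

  ti <- match(ss$id, tv$id)
  if ("chrom" %in% names(ss) && "pos" %in% names(ss)) {
    key_t <- paste(tv$chrom, tv$pos)
    fallback <- is.na(ti) & !is.na(ss$chrom) & !is.na(ss$pos)
    ti[fallback] <- match(paste(ss$chrom, ss$pos)[fallback], key_t)
  }

  action <- rep("drop-absent", nrow(ss))
  beta <- rep(NA_real_, nrow(ss))
  amb <- strand_ambiguous(ss$effect_allele, ss$other_allele)
  action[amb] <- "drop-ambiguous"

  ok <- !amb & !is.na(ti)
  a1 <- tv$allele_1[ti]; a2 <- tv$allele_2[ti]
  e <- ss$effect_allele; o <- ss$other_allele
  ce <- unname(.complement[e]); co <- unname(.complement[o])

  m_dir <- ok & e == a1 & o == a2
  m_swp <- ok & e == a2 & o == a1
  m_str <- ok & !m_dir & !m_swp & ce == a1 & co == a2
  m_sts <- ok & !m_dir & !m_swp & ce == a2 & co == a1
  m_bad <- ok & !m_dir & !m_swp & !m_str & !m_sts

  action[m_dir] <- "match"
  action[m_swp] <- "sign-flip"
  action[m_str] <- "strand-flip"
  action[m_sts] <- "strand-flip+sign-flip"
  action[m_bad] <- "drop-mismatch"
  beta[m_dir | m_str] <- ss$beta[m_dir | m_str]
  beta[m_swp | m_sts] <- -ss$beta[m_swp | m_sts]

  tab <- data.frame(id = ss$id, action = action,
                    target_id = ifelse(action %in% c("drop-absent",
                                                     "drop-ambiguous"),
                                       NA_character_, tv$id[ti]),
                    aligned_beta = beta, pvalue = ss$pvalue,
                    stringsAsFactors = FALSE)
  tab$target_id[tab$action %in% c("drop-mismatch")] <- tv$id[ti][
    tab$action %in% c("drop-mismatch")]
  structure(list(table = tab,
                 action_counts = table(factor(action, levels = c(
                   "match", "sign-flip", "strand-flip",
                   "strand-flip+sign-flip", "drop-ambiguous",
                   "drop-mismatch", "drop-absent")))),
            class = "harmonization_result")
}

# rows of the harmonization table that carry usable aligned effects
harmonized_usable <- function(harmonized) {
  tab <- harmonized$table
  tab[!startsWith(tab$action, "drop"), , drop = FALSE]
}

#' Greedy p-value-aware LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value as
#' an index and removes all unselected variants within `window_bp` of it
#' (same chromosome) whose squared dosage correlation with the index
#' exceeds `r2_max`.
#'
#' @param ds target [genotype_dataset].
#' @param harmonized a `harmonization_result` from [harmonize()].
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_bp clumping window in base pairs (default 5e5).
#' @return character vector of retained target variant ids.
#' @export
clump <- function(ds, harmonized, r2_max = 0.1, window_bp = 5e5) {
  use <- harmonized_usable(harmonized)
  vi <- match(use$target_id, ds$variants$id)
  ord <- order(use$pvalue)
  x <- mean_impute(ds$dosage[, vi, drop = FALSE])
  chrom <- ds$variants$chrom[vi]
  pos <- ds$variants$pos[vi]
  state <- rep("free", length(vi))  # free / index / removed
  for (k in ord) {
    if (state[k] != "free") next
    state[k] <- "index"
    near <- which(state == "free" & chrom == chrom[k] &
                    abs(pos - pos[k]) <= window_bp)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(x[, k], x[, near, drop = FALSE]))
      r[is.na(r)] <- 0
      state[near[r^2 > r2_max]] <- "removed"
    }
  }
  use$target_id[state == "index"]
}

#' Pruning-and-thresholding polygenic scores
#'
#' For each threshold p_T the score of sample s is the sum over clumped,
#' harmonized variants with p < p_T (p <= p_T for p_T = 1) of the aligned
#' effect times the sample's allele_1 dosage; missing dosages are replaced
#' by twice the target allele frequency. Raw sums are returned;
#' `standardize = TRUE` z-scores each column (optionally within a declared
#' sample subset).
#'
#' @param ds target [genotype_dataset].
#' @param harmonized a `harmonization_result`.
#' @param clumped_ids variant ids retained by [clump()] (default: all
#'   usable harmonized variants).
#' @param thresholds p-value threshold grid (default
#'   [default_thresholds()]).
#' @param standardize z-score the columns (default FALSE).
#' @param subset optional sample ids defining the standardization subset.
#' @return list of class `score_matrix`: `scores` (samples x thresholds),
#'   `n_variants` (per threshold), `thresholds`, `sample_id`.
#' @export
compute_prs <- function(ds, harmonized, clumped_ids = NULL,
                        thresholds = default_thresholds(),
                        standardize = FALSE, subset = NULL) {
  use <- harmonized_usable(harmonized)
  if (!is.null(clumped_ids))
    use <- use[use$target_id %in% clumped_ids, , drop = FALSE]
  vi <- match(use$target_id, ds$variants$id)
  x <- ds$dosage[, vi, drop = FALSE]
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    p <- colMeans(x, na.rm = TRUE) / 2
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- 2 * p[idx[, 2]]
    x[is.na(x)] <- 0
  }
  thresholds <- sort(thresholds)
  mask <- outer(use$pvalue, thresholds, `<`)
  if (any(thresholds == 1))
    mask[, thresholds == 1] <- use$pvalue <= 1
  n_var <- as.integer(colSums(mask))
  names(n_var) <- paste0("pT_", vapply(thresholds, as.character, ""))
  if (any(n_var == 0))
    warning("no variants pass threshold(s): ",
            paste(thresholds[n_var == 0], collapse = ", "))
  wmat <- mask * use$aligned_beta
  scores <- x %*% wmat
  colnames(scores) <- paste0("pT_", vapply(thresholds, as.character, ""))
  if (standardize) {
    rows <- if (is.null(subset)) seq_len(nrow(scores)) else
      match(subset, ds$samples$sample_id)
    mu <- colMeans(scores[rows, , drop = FALSE])
    sdv <- apply(scores[rows, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    scores <- sweep(sweep(scores, 2L, mu, `-`), 2L, sdv, `/`)
  }
  structure(list(scores = scores, n_variants = n_var,
                 thresholds = thresholds,
                 sample_id = ds$samples$sample_id),
            class = "score_matrix")
}
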