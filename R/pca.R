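# Principal components against a labelled reference panel, broad ancestry
# assignment by nearest reference centroid, and within-ancestry PCs.

#' Principal components of standardized dosages
#'
#' Dosages are mean-imputed at missing calls, centered, and scaled by
#' sqrt(2 p (1 - p)) -- the conventional GWAS standardization -- then the
#' sample-sample covariance is eigendecomposed. When a labelled reference
#' panel is supplied, the decomposition runs on the combined target +
#' reference matrix over the variant intersection, so both cohorts receive
#' scores on common axes.
#'
#' @param ds target [genotype_dataset].
#' @param reference optional reference [genotype_dataset]; its samples
#'   should carry a `population` column for downstream
#'   [assign_ancestry()].
#' @param n_pcs number of components (default 20; truncated with a warning
#'   when fewer samples are available).
#' @param variant_ids optional subset of variant ids (e.g. an LD-pruned
#'   set) to use.
#' @return list of class `pca_result`: `scores` (samples x PCs, zero
#'   column means), `loadings` (variants x PCs), `eigenvalues`,
#'   `sample_id`, `is_reference`, `ref_labels` (populations of reference
#'   samples, or NULL), `variant_ids`.
#' @export
run_pca <- function(ds, reference = NULL, n_pcs = 20, variant_ids = NULL) {
  if (!is.null(variant_ids)) {
    ds <- subset_dataset(ds, variants = intersect(variant_ids, ds$variants$id))
  }
  if (!is.null(reference)) {
    common <- intersect(ds$variants$id, reference$variants$id)
    if (!length(common)) stop("no variants shared with the reference panel")
    ds <- subset_dataset(ds, variants = common)
    reference <- subset_dataset(reference, variants = common)
    x <- rbind(ds$dosage, reference$dosage)
    sample_id <- c(ds$samples$sample_id, reference$samples$sample_id)
    is_ref <- rep(c(FALSE, TRUE), c(nrow(ds$samples), nrow(reference$samples)))
    ref_labels <- reference$samples$population
  } else {
    x <- ds$dosage
    sample_id <- ds$samples$sample_id
    is_ref <- rep(FALSE, nrow(x))
    ref_labels <- NULL
  }
  n <- nrow(x)
  if (n < 2) stop("need >= 2 samples for PCA")
  if (n_pcs > n - 1) {
    warning("only ", n - 1, " PCs available for ", n, " samples")
    n_pcs <- n - 1
  }
  z <- standardize_dosage(x)
  k <- tcrossprod(z) / ncol(z)
  e <- eigen(k, symmetric = TRUE)
  lambda <- pmax(e$values[seq_len(n_pcs)], 0)
  u <- e$vectors[, seq_len(n_pcs), drop = FALSE]
  scores <- u %*% diag(sqrt(lambda * ncol(z)), n_pcs, n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  pos <- lambda > 0
  loadings <- matrix(0, ncol(z), n_pcs,
                     dimnames = list(ds$variants$id, colnames(scores)))
  if (any(pos))
    loadings[, pos] <- crossprod(z, scores[, pos, drop = FALSE]) %*%
      diag(1 / (lambda[pos] * ncol(z)), sum(pos), sum(pos))
  structure(list(scores = scores, loadings = loadings, eigenvalues = lambda,
                 sample_id = sample_id, is_reference = is_ref,
                 ref_labels = ref_labels, variant_ids = ds$variants$id),
            class = "pca_result")
}

# mean-impute, center, scale by sqrt(2 p (1-p)); monomorphic columns -> 0
standardize_dosage <- function(x) {
  x <- mean_impute(x)
  p <- colMeans(x) / 2
  s <- sqrt(2 * p * (1 - p))
  z <- sweep(x, 2L, 2 * p, `-`)
  ok <- s > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, s[ok], `/`)
  z[, !ok] <- 0
  z
}

#' Assign broad ancestry by nearest reference centroid
#'
#' Reference samples (grouped by their population labels) define per-group
#' centroids and a pooled within-group standard deviation per PC. Each
#' target sample is assigned the label of the nearest centroid by
#' standardized Euclidean distance over the first `n_pcs_used` PCs, or
#' `"not-assigned"` when even the nearest centroid is farther than
#' `max_dist_sd`.
#'
#' @param pca a `pca_result` from [run_pca()] with a reference panel.
#' @param n_pcs_used number of leading PCs for the distance (default 4).
#' @param max_dist_sd assignment radius in pooled-SD units (default 6).
#' @return data.frame: `sample_id`, `ancestry_label`, `distance` (to the
#'   nearest centroid), for target (non-reference) samples.
#' @export
assign_ancestry <- function(pca, n_pcs_used = 4, max_dist_sd = 6) {
  if (is.null(pca$ref_labels)) stop("pca_result lacks reference labels")
  k <- min(n_pcs_used, ncol(pca$scores))
  ref <- pca$scores[pca$is_reference, seq_len(k), drop = FALSE]
  lab <- pca$ref_labels
  groups <- unique(lab)
  if (length(groups) < 2) stop("reference must carry >= 2 labelled groups")
  centroids <- t(sapply(groups, function(g)
    colMeans(ref[lab == g, , drop = FALSE])))
  within <- ref - centroids[match(lab, groups), , drop = FALSE]
  pooled_sd <- sqrt(colSums(within^2) / (nrow(ref) - length(groups)))
  pooled_sd[pooled_sd == 0] <- 1

  tgt <- pca$scores[!pca$is_reference, seq_len(k), drop = FALSE]
  dist <- sapply(seq_along(groups), function(gi) {
    d <- sweep(tgt, 2L, centroids[gi, ], `-`)
    sqrt(rowSums(sweep(d, 2L, pooled_sd, `/`)^2))
  })
  dist <- matrix(dist, nrow = nrow(tgt))
  nearest <- max.col(-dist)
  dmin <- dist[cbind(seq_len(nrow(tgt)), nearest)]
  label <- ifelse(dmin > max_dist_sd, "not-assigned", groups[nearest])
  data.frame(sample_id = pca$sample_id[!pca$is_reference],
             ancestry_label = label, distance = dmin,
             stringsAsFactors = FALSE)
}

#' Ancestry-specific principal components
#'
#' Re-runs [run_pca()] restricted to the samples assigned to one ancestry
#' group, with no reference panel -- the within-ancestry axes used to
#' adjust polygenic-score regressions.
#'
#' @param ds a [genotype_dataset].
#' @param assignment data.frame from [assign_ancestry()] (or any frame
#'   with `sample_id` and `ancestry_label`).
#' @param group ancestry label to keep.
#' @param n_pcs number of components (default 20).
#' @param variant_ids optional variant subset.
#' @return a `pca_result` for the group's samples.
#' @export
ancestry_specific_pcs <- function(ds, assignment, group, n_pcs = 20,
                                  variant_ids = NULL) {
  ids <- assignment$sample_id[assignment$ancestry_label == group]
  ids <- intersect(ids, ds$samples$sample_id)
  if (length(ids) < 2) stop("fewer than 2 samples in group ", group)
  run_pca(subset_dataset(ds, samples = ids), n_pcs = n_pcs,
          variant_ids = variant_ids)
}
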