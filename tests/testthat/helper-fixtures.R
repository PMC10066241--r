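# Small fixture builders shared across the suite. Everything is generated
# in code; no stored binary data.

# a minimal genotype dataset from an explicit dosage matrix
make_ds <- function(dosage, alleles = NULL, chrom = NULL, pos = NULL,
                    r2 = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  n <- nrow(dosage)
  if (is.null(alleles)) alleles <- matrix(rep(c("A", "G"), m), ncol = 2,
                                          byrow = TRUE)
  variants <- data.frame(
    id = paste0("v", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    pos = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
    allele_1 = alleles[, 1], allele_2 = alleles[, 2],
    stringsAsFactors = FALSE)
  if (!is.null(r2)) variants$imputation_r2 <- r2
  samples <- data.frame(sample_id = paste0("s", seq_len(n)),
                        stringsAsFactors = FALSE)
  genotype_dataset(dosage, variants, samples)
}

# random dataset for round-trip and property tests
random_ds <- function(n, m, miss_rate = 0, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2L, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                       each = n)]),
              nrow = n)
  if (miss_rate > 0)
    d[runif(n * m) < miss_rate] <- NA_integer_
  make_ds(d)
}

# a dataset holding a single simulated relative pair plus the pedigree
# truth; founders drawn at `freqs`, pair construction via the package's
# Mendelian-transmission generator
simulate_pair <- function(relationship, freqs, seed) {
  m <- length(freqs)
  empty <- genotype_dataset(
    matrix(integer(0), nrow = 0, ncol = m),
    data.frame(id = paste0("v", seq_len(m)), chrom = "1",
               pos = seq_len(m) * 1000L, allele_1 = "A", allele_2 = "G",
               stringsAsFactors = FALSE),
    data.frame(sample_id = character(0), stringsAsFactors = FALSE))
  truth <- list(p_pop = rbind(pop1 = freqs, pop2 = freqs))
  simulate_relatives(empty, truth,
                     data.frame(relationship = relationship,
                                population = "pop1"), seed = seed)
}

# brute-force masked matrix-product polygenic score oracle
prs_oracle <- function(ds, harmonized, clumped_ids, thresholds) {
  tab <- harmonized$table
  tab <- tab[!startsWith(tab$action, "drop"), , drop = FALSE]
  if (!is.null(clumped_ids)) tab <- tab[tab$target_id %in% clumped_ids, ]
  x <- ds$dosage
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    p <- colMeans(x, na.rm = TRUE) / 2
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- 2 * p[idx[, 2]]
  }
  sapply(thresholds, function(t) {
    inc <- if (t == 1) tab$pvalue <= 1 else tab$pvalue < t
    rows <- tab[inc, , drop = FALSE]
    if (nrow(rows) == 0) return(numeric(nrow(x)))
    vi <- match(rows$target_id, ds$variants$id)
    as.numeric(x[, vi, drop = FALSE] %*% rows$aligned_beta)
  })
}

# exhaustive greedy LD-pruning oracle (quadratic scan, no shortcuts)
ld_prune_oracle <- function(ds, window_bp, r2_max) {
  x <- ds$dosage
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  keep <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) next
    ok <- TRUE
    for (k in keep) {
      if (ds$variants$chrom[k] == ds$variants$chrom[j] &&
          ds$variants$pos[j] - ds$variants$pos[k] <= window_bp &&
          stats::cor(x[, j], x[, k])^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, j)
  }
  ds$variants$id[keep]
}

# exhaustive greedy clumping oracle
clump_oracle <- function(ds, harmonized, r2_max, window_bp) {
  tab <- harmonized$table
  tab <- tab[!startsWith(tab$action, "drop"), , drop = FALSE]
  x <- ds$dosage
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  vi <- match(tab$target_id, ds$variants$id)
  remaining <- order(tab$pvalue)
  removed <- rep(FALSE, nrow(tab))
  index <- logical(nrow(tab))
  for (k in remaining) {
    if (removed[k] || index[k]) next
    index[k] <- TRUE
    for (j in seq_len(nrow(tab))) {
      if (j == k || removed[j] || index[j]) next
      same_chr <- ds$variants$chrom[vi[j]] == ds$variants$chrom[vi[k]]
      close <- abs(ds$variants$pos[vi[j]] - ds$variants$pos[vi[k]]) <= window_bp
      if (same_chr && close &&
          stats::cor(x[, vi[j]], x[, vi[k]])^2 > r2_max)
        removed[j] <- TRUE
    }
  }
  tab$target_id[index]
}

# aggregate score without the zero-gene warning (used in permutation loops
# where some permutations may flag nothing)
aggregate_score_quiet <- function(residuals, de) {
  suppressWarnings(aggregate_score(residuals, de))$score
}
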