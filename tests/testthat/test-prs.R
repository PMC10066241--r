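# harmonization, clumping, pruning-and-thresholding scores

test_that("harmonization resolves allele order and strand", {
  ds <- make_ds(matrix(rbinom(40, 2, 0.5), nrow = 10),
                alleles = matrix(c("A", "G",
                                   "C", "T",
                                   "C", "T",
                                   "G", "A"), ncol = 2, byrow = TRUE))
  ss <- data.frame(id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "T", "G", "A"),
                   other_allele = c("G", "C", "A", "T"),
                   beta = c(0.1, 0.3, 0.2, 0.4),
                   pvalue = c(0.01, 0.02, 0.03, 0.04),
                   stringsAsFactors = FALSE)
  h <- harmonize(ss, ds)
  tab <- h$table
  expect_identical(tab$action,
                   c("match", "sign-flip", "strand-flip", "drop-ambiguous"))
  expect_equal(tab$aligned_beta, c(0.1, -0.3, 0.2, NA))

  # strand-flip + sign-flip: effect G / other A against target C/T
  ds2 <- make_ds(matrix(rbinom(10, 2, 0.5), nrow = 10),
                 alleles = matrix(c("C", "T"), ncol = 2))
  ss2 <- data.frame(id = "v1", effect_allele = "A", other_allele = "G",
                    beta = 0.5, pvalue = 0.1, stringsAsFactors = FALSE)
  h2 <- harmonize(ss2, ds2)
  expect_identical(h2$table$action, "strand-flip+sign-flip")
  expect_equal(h2$table$aligned_beta, -0.5)
})

test_that("harmonization recovers every scrambled simulated row", {
  cfg <- sim_config(seed = 91, n_variants = 400, n_samples = c(60, 60),
                    n_causal = 50, scramble_frac = 0.5)
  sim <- simulate_genotypes(cfg)
  ss <- simulate_sumstats(sim$truth, cfg)
  h <- harmonize(ss$table, sim$ds)
  expect_identical(nrow(ss$scramble), 200L)
  # every row is usable and flip/complement actions land exactly on the
  # scrambled rows
  expect_identical(sum(startsWith(h$table$action, "drop")), 0L)
  flipped <- which(h$table$action != "match")
  expect_identical(flipped, ss$scramble$row)
  # aligned effects equal the truth-scale estimates before scrambling
  cfg0 <- sim_config(seed = 91, n_variants = 400, n_samples = c(60, 60),
                     n_causal = 50, scramble_frac = 0)
  sim0 <- simulate_genotypes(cfg0)
  ss0 <- simulate_sumstats(sim0$truth, cfg0)
  expect_equal(h$table$aligned_beta, ss0$table$beta, tolerance = 1e-12)
})

test_that("unmatched, mismatched and duplicate inputs are handled", {
  ds <- make_ds(matrix(rbinom(20, 2, 0.5), nrow = 10),
                alleles = matrix(c("A", "G", "C", "T"), ncol = 2,
                                 byrow = TRUE))
  ss <- data.frame(id = c("v1", "nope", "v2"),
                   effect_allele = c("A", "A", "A"),
                   other_allele = c("C", "G", "C"),
                   beta = 0.1, pvalue = 0.5, stringsAsFactors = FALSE)
  h <- harmonize(ss, ds)
  expect_identical(h$table$action, c("drop-mismatch", "drop-absent",
                                     "drop-mismatch"))
  ss_dup <- rbind(ss, ss[1, ])
  expect_error(harmonize(ss_dup, ds), "duplicate ids")
})

test_that("chrom:pos fallback matches rows whose ids differ", {
  ds <- make_ds(matrix(rbinom(20, 2, 0.5), nrow = 10), chrom = c(3, 3),
                pos = c(100L, 200L))
  ss <- data.frame(id = c("rsX", "v2"), chrom = c("3", "3"),
                   pos = c(100L, 200L), effect_allele = "A",
                   other_allele = "G", beta = c(0.2, 0.1), pvalue = 0.5,
                   stringsAsFactors = FALSE)
  h <- harmonize(ss, ds)
  expect_identical(h$table$action, c("match", "match"))
  expect_identical(h$table$target_id, c("v1", "v2"))
})

test_that("clumping keeps the best-p index of each correlated block", {
  set.seed(92)
  n <- 150
  a <- rbinom(n, 2, 0.5)
  ds <- make_ds(cbind(a, a), pos = c(1000L, 11000L))
  ss <- data.frame(id = c("v1", "v2"), effect_allele = "A",
                   other_allele = "G", beta = 0.1,
                   pvalue = c(1e-4, 1e-9), stringsAsFactors = FALSE)
  h <- harmonize(ss, ds)
  expect_identical(clump(ds, h), "v2")

  # six-variant constructed block against the exhaustive oracle
  for (s in 1:3) {
    set.seed(100 + s)
    block <- rbinom(n, 2, 0.5)
    d6 <- sapply(1:6, function(k) {
      out <- block
      swap <- sample(n, 15 * k)
      out[swap] <- rbinom(length(swap), 2, 0.5)
      out
    })
    ds6 <- make_ds(d6, pos = as.integer(seq(1e4, 6e4, by = 1e4)))
    ss6 <- data.frame(id = paste0("v", 1:6), effect_allele = "A",
                      other_allele = "G", beta = 0.1,
                      pvalue = runif(6), stringsAsFactors = FALSE)
    h6 <- harmonize(ss6, ds6)
    expect_identical(sort(clump(ds6, h6)),
                     sort(clump_oracle(ds6, h6, 0.1, 5e5)))
  }
})

test_that("scores match the masked matrix-product oracle exactly", {
  cfg <- sim_config(seed = 93, n_variants = 50, n_samples = c(40, 40),
                    n_causal = 10, scramble_frac = 0.3)
  sim <- simulate_genotypes(cfg)
  sim$ds$dosage[sample(length(sim$ds$dosage), 60)] <- NA_integer_
  ss <- simulate_sumstats(sim$truth, cfg)
  h <- harmonize(ss$table, sim$ds)
  cl <- clump(sim$ds, h)
  prs <- suppressWarnings(compute_prs(sim$ds, h, cl))
  oracle <- prs_oracle(sim$ds, h, cl, prs$thresholds)
  expect_lt(max(abs(prs$scores - oracle)), 1e-12)
  # single-variant linearity: beta 0.5 on dosages 0/1/2
  ds1 <- make_ds(matrix(c(0L, 1L, 2L), ncol = 1))
  ss1 <- data.frame(id = "v1", effect_allele = "A", other_allele = "G",
                    beta = 0.5, pvalue = 0.01, stringsAsFactors = FALSE)
  p1 <- compute_prs(ds1, harmonize(ss1, ds1), thresholds = 0.05)
  expect_equal(as.numeric(p1$scores), c(0, 0.5, 1.0))
})

test_that("threshold semantics: strict below 1, inclusive at 1, monotone counts", {
  ds <- make_ds(matrix(rbinom(30, 2, 0.5), nrow = 10))
  ss <- data.frame(id = paste0("v", 1:3), effect_allele = "A",
                   other_allele = "G", beta = c(0.1, 0.2, 0.3),
                   pvalue = c(0.05, 0.5, 1.0), stringsAsFactors = FALSE)
  h <- harmonize(ss, ds)
  prs <- suppressWarnings(compute_prs(ds, h))
  # p = 0.05 excluded at p_T = 0.05 (strict), p = 1 included at p_T = 1
  expect_identical(unname(prs$n_variants[prs$thresholds == 0.05]), 0L)
  expect_identical(unname(prs$n_variants[prs$thresholds == 1]), 3L)
  expect_true(all(diff(prs$n_variants) >= 0))
  expect_identical(length(prs$thresholds), 13L)
})

test_that("allele-coding flips leave standardized scores unchanged", {
  cfg <- sim_config(seed = 94, n_variants = 80, n_samples = c(50, 50),
                    n_causal = 20, scramble_frac = 0)
  sim <- simulate_genotypes(cfg)
  ss <- simulate_sumstats(sim$truth, cfg)
  h1 <- harmonize(ss$table, sim$ds)
  s1 <- suppressWarnings(compute_prs(sim$ds, h1, standardize = TRUE))

  flip <- sample(80, 30)
  ds2 <- sim$ds
  tmp <- ds2$variants$allele_1[flip]
  ds2$variants$allele_1[flip] <- ds2$variants$allele_2[flip]
  ds2$variants$allele_2[flip] <- tmp
  ds2$dosage[, flip] <- 2L - ds2$dosage[, flip]
  h2 <- harmonize(ss$table, ds2)
  s2 <- suppressWarnings(compute_prs(ds2, h2, standardize = TRUE))
  expect_lt(max(abs(s1$scores - s2$scores)), 1e-10)
})
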