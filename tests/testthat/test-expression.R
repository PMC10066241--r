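# logCPM, precision weights, covariate selection/regression, DE weights,
# aggregate expression score, cross-modal correlation

make_expr <- function(seed, n = 120, n_genes = 250, ...) {
  samp <- data.frame(sample_id = sprintf("e%03d", seq_len(n)),
                     diagnosis = rep(c("case", "control"), length.out = n))
  cfg <- sim_config(seed = seed, expression = list(n_genes = n_genes, ...))
  simulate_expression(samp, cfg)
}

covar_cols <- c("batch", "sex", "age", "RIN", "PMI", "pH",
                "mapping_rate", "intergenic_rate")

test_that("logCPM matches its closed form and is scale invariant", {
  cts <- matrix(c(20, 10, 100, 5, 50, 500), nrow = 3)
  expect_equal(compute_logcpm(matrix(0, 1, 1), lib_size = 1e6 - 1)[1, 1], -1)
  lc <- compute_logcpm(cts)
  # independent elementwise computation
  want <- log2((cts + 0.5) / (rep(colSums(cts), each = 3) + 1) * 1e6)
  expect_equal(lc, want, tolerance = 1e-10)
  # doubling counts and library sizes is a near no-op away from the offsets
  lc2 <- compute_logcpm(2 * cts)
  expect_lt(max(abs(lc2 - lc)), 0.15)
  expect_error(compute_logcpm(cts, lib_size = c(0, 1)), "positive")
})

test_that("precision weights track the mean-variance trend", {
  ex <- make_expr(111, n_genes = 400)
  lc <- compute_logcpm(ex$eds$counts)
  design <- model.matrix(~ diagnosis, ex$eds$samples)
  w <- voom_weights(lc, design, ex$eds$lib_size)
  # low-count genes are noisier on the log scale: their weights are lower
  mean_count <- rowMeans(ex$eds$counts)
  lo <- mean_count < quantile(mean_count, 0.2)
  hi <- mean_count > quantile(mean_count, 0.8)
  expect_gt(median(w[hi, ]), median(w[lo, ]))

  # homoscedastic Gaussian surrogate: weights approximately constant
  flat <- matrix(rnorm(400 * 120, mean = 8, sd = 0.5), nrow = 400)
  wf <- voom_weights(flat, design, rep(1e6, 120))
  expect_lt(sd(wf) / mean(wf), 0.2)

  # too few genes for a trend: unit-weight fallback
  expect_warning(w10 <- voom_weights(lc[1:10, ], design, ex$eds$lib_size),
                 "unit weights")
  expect_true(all(w10 == 1))
})

test_that("agreement with the reference voom implementation", {
  skip_if_not_installed("limma")
  ex <- make_expr(112, n_genes = 300)
  design <- model.matrix(~ diagnosis, ex$eds$samples)
  v <- limma::voom(ex$eds$counts, design, span = 0.5)
  w <- voom_weights(compute_logcpm(ex$eds$counts), design, ex$eds$lib_size)
  expect_gt(cor(log(as.vector(v$weights)), log(as.vector(w))), 0.95)
})

test_that("covariate selection keeps signal and rejects noise", {
  ex <- make_expr(113, n_genes = 300, covar_effect_sd = 0.4)
  lc <- compute_logcpm(ex$eds$counts)
  cands <- ex$eds$samples[, covar_cols]
  cands$noise <- rnorm(ncol(lc))
  sel <- select_covariates(lc, cands)
  expect_true("batch" %in% sel || "age" %in% sel || "RIN" %in% sel)

  # a candidate equal to expression PC1 is always included
  z <- t(scale(t(lc))); z[!is.finite(z)] <- 0
  pc1 <- prcomp(t(z))$x[, 1]
  cands$pc1copy <- pc1
  expect_true("pc1copy" %in% select_covariates(lc, cands))

  # duplicated covariates tied to the same PC: exactly one survives
  cands2 <- data.frame(a = pc1, b = pc1 + rnorm(length(pc1), 0, 1e-6))
  sel2 <- select_covariates(lc, cands2)
  expect_identical(length(sel2), 1L)

  # pure-noise candidates are excluded at roughly the test size
  hits <- mean(replicate(20, {
    nc <- data.frame(x = rnorm(ncol(lc)))
    length(select_covariates(lc, nc)) > 0
  }))
  expect_lt(hits, 0.8)  # any-of-20-PCs inclusion, far below certainty
})

test_that("covariate regression removes exactly the modelled structure", {
  ex <- make_expr(114, n_genes = 100)
  lc <- compute_logcpm(ex$eds$counts)
  cov <- ex$eds$samples[, covar_cols]

  # constant covariates leave centered rows
  resid_const <- regress_covariates(lc, data.frame(z = rep(1, ncol(lc))))
  expect_equal(resid_const, lc - rowMeans(lc), tolerance = 1e-10,
               ignore_attr = TRUE)

  # an exact linear function of covariates residualizes to ~0
  design <- model.matrix(~ ., cov)
  fake <- matrix(rnorm(5 * ncol(design)), nrow = 5) %*% t(design)
  expect_lt(max(abs(regress_covariates(fake, cov))), 1e-8)

  # weighted single-gene fit matches the closed-form WLS solution
  y <- lc[1, ]
  w1 <- runif(ncol(lc), 0.5, 2)
  wm <- matrix(w1, 1)
  r_pkg <- regress_covariates(lc[1, , drop = FALSE], cov, wm)
  xtx <- t(design) %*% (w1 * design)
  beta <- solve(xtx, t(design) %*% (w1 * y))
  expect_equal(as.numeric(r_pkg), as.numeric(y - design %*% beta),
               tolerance = 1e-10)

  # aliased columns are named
  cov_bad <- cbind(cov, dup_age = cov$age)
  expect_error(regress_covariates(lc, cov_bad), "dup_age")
})

test_that("DE weights recover planted shifts with the right sign convention", {
  ex <- make_expr(115, n_genes = 200, de_fraction = 0)
  lc <- compute_logcpm(ex$eds$counts)
  resid <- regress_covariates(lc, ex$eds$samples[, covar_cols])
  case <- as.integer(ex$eds$samples$diagnosis == "case")

  shifted <- resid
  shifted[7, case == 1] <- shifted[7, case == 1] + 1
  de <- de_weights(shifted, ex$eds$samples$diagnosis)
  expect_lt(abs(de$coef[7] - 1), 0.2)
  expect_gt(de$coef[7], 0)            # cases higher -> positive

  # matches lm() per gene
  for (g in c(1, 7, 50)) {
    fit <- lm(shifted[g, ] ~ case)
    sm <- summary(fit)$coefficients
    expect_equal(de$coef[g], sm[2, 1], tolerance = 1e-10)
    expect_equal(de$se[g], sm[2, 2], tolerance = 1e-10)
    expect_equal(de$p_value[g], sm[2, 4], tolerance = 1e-10)
  }

  # null calibration of the nominal flag
  de0 <- de_weights(resid, ex$eds$samples$diagnosis)
  expect_lt(abs(mean(de0$significant) - 0.05),
            3 * sqrt(0.05 * 0.95 / 200) + 0.02)
  expect_error(de_weights(resid, rep("case", ncol(resid))), "both")
})

test_that("aggregate score is the weighted residual sum with case-ward sign", {
  # single flagged gene, coefficient 2, residuals (-1, 0, 1)
  resid <- matrix(c(-1, 0, 1), nrow = 1,
                  dimnames = list("g1", paste0("s", 1:3)))
  de <- data.frame(gene = "g1", coef = 2, se = 0.1, p_value = 0.01,
                   significant = TRUE)
  agg <- aggregate_score(resid, de)
  expect_equal(unname(agg$score), c(-2, 0, 2))
  expect_identical(agg$n_genes, 1L)

  # zero flagged genes: all-zero scores with a warning
  de0 <- transform(de, significant = FALSE)
  expect_warning(agg0 <- aggregate_score(resid, de0), "no nominally")
  expect_true(all(agg0$score == 0))

  # linearity in residuals and coefficients
  ex <- make_expr(116, n_genes = 150)
  lc <- compute_logcpm(ex$eds$counts)
  resid2 <- regress_covariates(lc, ex$eds$samples[, covar_cols])
  de2 <- de_weights(resid2, ex$eds$samples$diagnosis)
  a1 <- aggregate_score(resid2, de2)$score
  expect_equal(aggregate_score(2 * resid2, de2)$score, 2 * a1)
  de2_scaled <- de2; de2_scaled$coef <- 3 * de2_scaled$coef
  expect_equal(aggregate_score(resid2, de2_scaled)$score, 3 * a1)

  # in-sample identity: case-minus-control mean equals sum of squared
  # flagged coefficients (unweighted fit), hence cases sit higher
  case <- as.integer(ex$eds$samples$diagnosis == "case")
  diffs <- mean(a1[case == 1]) - mean(a1[case == 0])
  expect_equal(diffs, sum(de2$coef[de2$significant]^2), tolerance = 1e-10)
  expect_gte(diffs, 0)
})

test_that("PRS-expression correlation is anchored at its extremes", {
  set.seed(117)
  prs <- rnorm(60)
  pcs <- matrix(rnorm(60 * 3), ncol = 3)
  resid_prs <- lm(prs ~ pcs)$residuals
  r1 <- correlate_prs_expression(prs, resid_prs, pcs)
  expect_equal(r1$r, 1, tolerance = 1e-10)
  # independent modalities: near-zero correlation over replicates
  rs <- replicate(30, correlate_prs_expression(rnorm(60), rnorm(60), pcs)$r)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(correlate_prs_expression(rnorm(3), rnorm(3)), ">= 4")
  expect_error(correlate_prs_expression(rnorm(5), rnorm(6)), "matched")
})
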