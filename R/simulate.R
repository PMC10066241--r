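# Synthetic-data generators: Balding-Nichols population structure,
# liability-threshold phenotypes, analytic training-GWAS summary statistics,
# Mendelian relative pairs, and negative-binomial expression counts.
# Every generator is a deterministic function of (config, seed).

#' Simulation configuration
#'
#' Collects the parameters of all synthetic-data generators. Defaults
#' describe a two-population target cohort genotyped at independent common
#' variants, a liability-threshold disease of moderate heritability and
#' high sampled prevalence (case/control cohorts are case-enriched relative
#' to population prevalence), and a large external training GWAS.
#'
#' @param seed integer seed; mandatory, drives every generator.
#' @param n_variants number of biallelic variants.
#' @param n_samples samples per population (length-2 vector or scalar
#'   recycled to both populations).
#' @param fst Balding-Nichols divergence between the two populations,
#'   in (0, 1); 0 is accepted and collapses both populations onto the
#'   ancestral frequency.
#' @param maf_range ancestral minor-allele-frequency interval within
#'   (0, 0.5].
#' @param n_causal number of causal variants.
#' @param h2_liability heritability of liability in `[0, 1]`.
#' @param prevalence disease prevalence in (0, 1).
#' @param n_train training-GWAS sample size (summary statistics are drawn
#'   analytically around the true effects with the corresponding standard
#'   errors).
#' @param scramble_frac fraction of summary-statistic rows whose allele
#'   representation is scrambled (allele-order swap and/or strand
#'   complement) to exercise harmonization.
#' @param expression list of expression-generator parameters: `n_genes`,
#'   `de_fraction`, `de_logfc_sd` (log2 scale), `dispersion` (NB dispersion;
#'   variance = mu + dispersion * mu^2), `covar_effect_sd` (per-gene log2
#'   effect SD of each covariate), `lib_size_mu` and `lib_size_sd`
#'   (log-normal library sizes, natural-log scale).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_variants = 10000L,
                       n_samples = c(1000L, 1000L),
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       n_causal = 1000L,
                       h2_liability = 0.5,
                       prevalence = 0.3,
                       n_train = 50000L,
                       scramble_frac = 0.2,
                       expression = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, 2L)
  expr_defaults <- list(n_genes = 1000L, de_fraction = 0.1,
                        de_logfc_sd = 0.5, dispersion = 0.1,
                        covar_effect_sd = 0.1,
                        lib_size_mu = log(5e6), lib_size_sd = 0.3)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_samples = as.integer(n_samples), fst = fst,
              maf_range = maf_range, n_causal = as.integer(n_causal),
              h2_liability = h2_liability, prevalence = prevalence,
              n_train = n_train, scramble_frac = scramble_frac,
              expression = expression)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must be an interval within (0, 0.5]")
    if (h2_liability < 0 || h2_liability > 1)
      stop("h2_liability must lie in [0, 1]")
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must lie in (0, 1)")
    if (n_causal > n_variants) stop("n_causal exceeds n_variants")
    if (n_train <= 0) stop("n_train must be positive")
    if (scramble_frac < 0 || scramble_frac > 1)
      stop("scramble_frac must lie in [0, 1]")
  })
  invisible(cfg)
}

# non-ambiguous allele pairs used for simulated variants; strand-ambiguous
# (A/T, C/G) variants are planted explicitly by QC fixtures instead
.sim_allele_pairs <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G"),
                            ncol = 2, byrow = TRUE)

#' Simulate two-population genotypes under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn uniformly from `maf_range`; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `fst`
#' (exactly the ancestral frequency when `fst = 0`); genotypes are
#' Binomial(2, population frequency), independent across variants.
#' Variants are laid out 10 kb apart along chromosomes 1-22.
#'
#' Causal variants and their liability-scale effect sizes are chosen here
#' so that phenotype and summary-statistic generators share one truth:
#' effects are Gaussian on causal variants and scaled so that the genetic
#' variance at ancestral frequencies equals `h2_liability`.
#'
#' @param config a [sim_config()].
#' @return list with `ds` (a [genotype_dataset], samples carry a
#'   `population` column) and `truth` (ancestral/population frequencies,
#'   causal flags, true effects, variant table, population labels).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_variants
  n <- config$n_samples
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  f <- config$fst
  if (f > 0) {
    shape_scale <- (1 - f) / f
    p_pop <- rbind(stats::rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale),
                   stats::rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale))
  } else {
    p_pop <- rbind(p_anc, p_anc)
  }
  rownames(p_pop) <- c("pop1", "pop2")

  dosage <- rbind(
    matrix(stats::rbinom(n[1] * m, 2L, rep(p_pop[1, ], each = n[1])),
           nrow = n[1], ncol = m),
    matrix(stats::rbinom(n[2] * m, 2L, rep(p_pop[2, ], each = n[2])),
           nrow = n[2], ncol = m)
  )
  population <- rep(c("pop1", "pop2"), n)

  chrom <- sort(rep(1:22, length.out = m))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 10000L
  pair <- .sim_allele_pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
  variants <- data.frame(id = sprintf("var%06d", seq_len(m)),
                         chrom = as.character(chrom), pos = as.integer(pos),
                         allele_1 = pair[, 1], allele_2 = pair[, 2],
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(sum(n))),
    sex = sample(c("male", "female"), sum(n), replace = TRUE),
    age = round(stats::runif(sum(n), 20, 80)),
    population = population, stringsAsFactors = FALSE)

  causal <- logical(m)
  causal[sample.int(m, config$n_causal)] <- TRUE
  beta <- numeric(m)
  if (config$n_causal > 0 && config$h2_liability > 0) {
    b <- stats::rnorm(config$n_causal)
    var_raw <- sum(b^2 * 2 * p_anc[causal] * (1 - p_anc[causal]))
    beta[causal] <- b * sqrt(config$h2_liability / var_raw)
  }

  ds <- genotype_dataset(dosage, variants, samples)
  truth <- list(p_anc = p_anc, p_pop = p_pop, causal = causal, beta = beta,
                variants = variants, population = population)
  list(ds = ds, truth = truth)
}

#' Simulate a liability-threshold phenotype
#'
#' Liability is the standardized genetic score over causal variants, scaled
#' to variance `h2_liability`, plus independent Gaussian noise of variance
#' `1 - h2_liability`. A sample is a case when liability exceeds the
#' threshold `qnorm(1 - prevalence)`; the liability itself serves as the
#' continuous trait.
#'
#' @param ds a [genotype_dataset].
#' @param truth truth record from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return list: `status` (integer 0/1), `diagnosis`
#'   (`"case"`/`"control"`), `liability`, `genetic_score` (standardized),
#'   `threshold`.
#' @export
simulate_phenotype <- function(ds, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  h2 <- config$h2_liability
  n <- nrow(ds$samples)
  if (h2 > 0) {
    x <- ds$dosage[, truth$causal, drop = FALSE]
    g_raw <- as.numeric(x %*% truth$beta[truth$causal])
    g <- as.numeric(scale(g_raw))
  } else {
    g <- numeric(n)
  }
  liability <- sqrt(h2) * g +
    if (h2 < 1) sqrt(1 - h2) * stats::rnorm(n) else 0
  thr <- stats::qnorm(1 - config$prevalence)
  status <- as.integer(liability > thr)
  list(status = status,
       diagnosis = ifelse(status == 1L, "case", "control"),
       liability = liability, genetic_score = g, threshold = thr)
}

#' Simulate training-GWAS summary statistics analytically
#'
#' For each variant the estimated effect is Normal(true effect, se^2) with
#' se = 1/sqrt(2 p (1 - p) n_train) at the training population's allele
#' frequency, and the p-value is the two-sided Wald test. This reproduces
#' the sampling distribution of a large single-population GWAS of the
#' liability trait without simulating the training cohort itself. The
#' training population is population 1 (mirroring a score trained in one
#' ancestry and applied across ancestries).
#'
#' A `scramble_frac` fraction of rows has its allele representation
#' scrambled -- allele-order swap (with the compensating sign change),
#' strand complement, or both -- so harmonization is exercised against
#' recorded truth.
#'
#' @param truth truth record from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return list: `table` (summary-statistics data.frame), `scramble`
#'   (data.frame of row index and applied action).
#' @export
simulate_sumstats <- function(truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  p_train <- truth$p_pop[1, ]
  se <- 1 / sqrt(2 * p_train * (1 - p_train) * config$n_train)
  beta_hat <- stats::rnorm(length(se), truth$beta, se)
  z <- beta_hat / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue <- pmax(pvalue, .Machine$double.xmin)  # keep within (0, 1]
  tab <- data.frame(id = truth$variants$id, chrom = truth$variants$chrom,
                    pos = truth$variants$pos,
                    effect_allele = truth$variants$allele_1,
                    other_allele = truth$variants$allele_2,
                    beta = beta_hat, pvalue = pvalue,
                    stringsAsFactors = FALSE)

  m <- nrow(tab)
  n_scramble <- round(config$scramble_frac * m)
  scramble <- data.frame(row = integer(0), action = character(0))
  if (n_scramble > 0) {
    rows <- sort(sample.int(m, n_scramble))
    action <- sample(c("swap", "complement", "swap+complement"),
                     n_scramble, replace = TRUE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    do_swap <- action %in% c("swap", "swap+complement")
    do_comp <- action %in% c("complement", "swap+complement")
    sw <- rows[do_swap]
    tmp <- tab$effect_allele[sw]
    tab$effect_allele[sw] <- tab$other_allele[sw]
    tab$other_allele[sw] <- tmp
    tab$beta[sw] <- -tab$beta[sw]
    cm <- rows[do_comp]
    tab$effect_allele[cm] <- comp[tab$effect_allele[cm]]
    tab$other_allele[cm] <- comp[tab$other_allele[cm]]
    scramble <- data.frame(row = rows, action = action,
                           stringsAsFactors = FALSE)
  }
  list(table = tab, scramble = scramble)
}

# one diploid founder as two haplotypes at frequency vector f
.founder_haps <- function(f) {
  cbind(stats::rbinom(length(f), 1L, f), stats::rbinom(length(f), 1L, f))
}

# Mendelian transmission: returns the transmitted haplotype and the
# chromosome indicator (1 or 2) per locus
.transmit <- function(haps) {
  pick <- stats::rbinom(nrow(haps), 1L, 0.5) + 1L
  list(hap = haps[cbind(seq_len(nrow(haps)), pick)], pick = pick)
}

#' Simulate relative pairs by Mendelian transmission
#'
#' Appends pairs of relatives of the requested degree to a dataset.
#' Founders are drawn as phased haplotypes at the requested population's
#' frequencies; offspring receive one haplotype from each parent by
#' independent per-locus transmission. Monozygotic (MZ) twins duplicate one
#' genotype vector; second-degree pairs are grandparent-grandchild.
#' Transmission indicators are retained so the pedigree records both the
#' expected kinship (0.5, 0.25, 0.25, 0.125, 0) and the realized
#' (identity-by-descent) kinship of each pair.
#'
#' @param ds a [genotype_dataset] to augment.
#' @param truth truth record from [simulate_genotypes()] (source of
#'   population frequencies).
#' @param pairs data.frame with columns `relationship` (one of `"MZ"`,
#'   `"parent-offspring"`, `"full-sibling"`, `"second-degree"`,
#'   `"unrelated"`) and `population` (`"pop1"`/`"pop2"`).
#' @param seed integer seed.
#' @return list: `ds` (augmented dataset), `pedigree` (data.frame: pair
#'   member ids, relationship, `kinship_true`, `kinship_realized`).
#' @export
simulate_relatives <- function(ds, truth, pairs, seed) {
  set.seed(seed)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  known <- c("MZ", "parent-offspring", "full-sibling", "second-degree",
             "unrelated")
  bad <- setdiff(pairs$relationship, known)
  if (length(bad)) stop("unknown relationship label: ",
                        paste(unique(bad), collapse = ", "))
  m <- nrow(ds$variants)
  new_dos <- list(); ped <- list(); new_meta <- list()
  idx0 <- nrow(ds$samples)
  for (k in seq_len(nrow(pairs))) {
    popn <- pairs$population[k]
    f <- truth$p_pop[popn, ]
    rel <- pairs$relationship[k]
    if (rel == "MZ") {
      a <- .founder_haps(f); ga <- rowSums(a)
      g1 <- ga; g2 <- ga
      kin_real <- 0.5
    } else if (rel == "parent-offspring") {
      pa <- .founder_haps(f); pb <- .founder_haps(f)
      ta <- .transmit(pa); tb <- .transmit(pb)
      g1 <- rowSums(pa); g2 <- ta$hap + tb$hap
      kin_real <- 0.25  # child carries exactly one allele IBD with parent
    } else if (rel == "full-sibling") {
      pa <- .founder_haps(f); pb <- .founder_haps(f)
      ta1 <- .transmit(pa); tb1 <- .transmit(pb)
      ta2 <- .transmit(pa); tb2 <- .transmit(pb)
      g1 <- ta1$hap + tb1$hap; g2 <- ta2$hap + tb2$hap
      kin_real <- mean((ta1$pick == ta2$pick) + (tb1$pick == tb2$pick)) / 4
    } else if (rel == "second-degree") {
      g1h <- .founder_haps(f); g2h <- .founder_haps(f)  # grandparents
      tp1 <- .transmit(g1h); tp2 <- .transmit(g2h)
      parent <- cbind(tp1$hap, tp2$hap)  # col 1 descends from grandparent 1
      spouse <- .founder_haps(f)
      tc <- .transmit(parent); ts <- .transmit(spouse)
      g1 <- rowSums(g1h); g2 <- tc$hap + ts$hap
      kin_real <- mean(tc$pick == 1L) / 4
    } else {
      g1 <- rowSums(.founder_haps(f)); g2 <- rowSums(.founder_haps(f))
      kin_real <- 0
    }
    kin_true <- c(MZ = 0.5, `parent-offspring` = 0.25,
                  `full-sibling` = 0.25, `second-degree` = 0.125,
                  unrelated = 0)[[rel]]
    id1 <- sprintf("REL%04d_a", k); id2 <- sprintf("REL%04d_b", k)
    new_dos[[k]] <- rbind(g1, g2)
    new_meta[[k]] <- data.frame(sample_id = c(id1, id2), sex = "unknown",
                                age = NA_real_, population = popn,
                                stringsAsFactors = FALSE)
    ped[[k]] <- data.frame(id1 = id1, id2 = id2, relationship = rel,
                           kinship_true = kin_true,
                           kinship_realized = kin_real,
                           stringsAsFactors = FALSE)
  }
  add <- do.call(rbind, new_dos)
  meta <- do.call(rbind, new_meta)
  samples <- merge_sample_frames(ds$samples, meta)
  aug <- genotype_dataset(rbind(ds$dosage, add), ds$variants, samples)
  list(ds = aug, pedigree = do.call(rbind, ped))
}

merge_sample_frames <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- rep(NA, nrow(a))
  for (cc in setdiff(cols, names(b))) b[[cc]] <- rep(NA, nrow(b))
  rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
}

#' Simulate negative-binomial RNA-seq counts with planted differential
#' expression
#'
#' Per-gene relative abundances on the log2 scale combine a Gaussian
#' baseline, per-gene covariate effects on standardized covariates (library
#' batch, sex, age, RIN, PMI, pH, mapping rates -- generated here when the
#' sample table lacks them), and a planted case/control log2-fold-change on
#' a `de_fraction` of genes. Counts are negative binomial around the
#' library-size-scaled means; library sizes are log-normal.
#'
#' @param samples data.frame with `sample_id` and `diagnosis`
#'   (`"case"`/`"control"` or `"schizophrenia"`/`"control"`); covariate
#'   columns are reused when present.
#' @param config a [sim_config()]; the `expression` sublist parameterizes
#'   this generator.
#' @param seed optional seed override (default `config$seed + 3`).
#' @return list: `eds` (an [expression_dataset()]), `truth` (per-gene DE
#'   flags and log2-fold-changes, covariate effect matrix).
#' @export
simulate_expression <- function(samples, config, seed = NULL) {
  validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed + 3L else seed)
  ex <- config$expression
  n <- nrow(samples)
  g <- ex$n_genes
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$diagnosis)) stop("samples must carry diagnosis labels")
  case <- as.integer(samples$diagnosis %in% c("case", "schizophrenia"))
  if (is.null(samples$batch))
    samples$batch <- sample(paste0("b", 1:3), n, replace = TRUE)
  if (is.null(samples$sex))
    samples$sex <- sample(c("male", "female"), n, replace = TRUE)
  if (is.null(samples$age) || anyNA(samples$age))
    samples$age <- round(stats::runif(n, 20, 80))
  defaults <- list(RIN = c(7.5, 1), PMI = c(30, 10), pH = c(6.5, 0.3),
                   mapping_rate = c(0.85, 0.03), intergenic_rate = c(0.08, 0.02))
  for (nm in names(defaults))
    if (is.null(samples[[nm]]))
      samples[[nm]] <- stats::rnorm(n, defaults[[nm]][1], defaults[[nm]][2])

  # standardized numeric covariates + indicator-coded categoricals
  num_cov <- scale(cbind(age = samples$age, RIN = samples$RIN,
                         PMI = samples$PMI, pH = samples$pH,
                         mapping_rate = samples$mapping_rate,
                         intergenic_rate = samples$intergenic_rate))
  cat_cov <- cbind(sex = as.integer(samples$sex == "female"),
                   stats::model.matrix(~ batch, samples)[, -1, drop = FALSE])
  covmat <- cbind(num_cov, cat_cov)

  baseline <- stats::rnorm(g, 0, 2)            # log2 relative abundance
  cov_eff <- matrix(stats::rnorm(g * ncol(covmat), 0, ex$covar_effect_sd),
                    nrow = g)
  de <- logical(g)
  de[sample.int(g, round(ex$de_fraction * g))] <- TRUE
  lfc <- numeric(g)
  lfc[de] <- stats::rnorm(sum(de), 0, ex$de_logfc_sd)

  log2rel <- baseline + cov_eff %*% t(covmat) + outer(lfc, case)
  rel <- 2^log2rel
  lib <- stats::rlnorm(n, ex$lib_size_mu, ex$lib_size_sd)
  mu <- sweep(rel, 2L, lib / colSums(rel), `*`)
  counts <- matrix(
    if (ex$dispersion > 0)
      stats::rnbinom(g * n, mu = mu, size = 1 / ex$dispersion)
    else stats::rpois(g * n, mu),
    nrow = g)
  rownames(counts) <- sprintf("gene%05d", seq_len(g))
  colnames(counts) <- samples$sample_id
  eds <- expression_dataset(counts, samples)
  truth <- list(de = de, lfc = lfc, baseline = baseline, cov_eff = cov_eff,
                case = case)
  list(eds = eds, truth = truth)
}
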