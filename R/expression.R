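# Covariate-adjusted expression residuals with mean-variance precision
# weights, per-gene case/control weights, the aggregate gene expression
# score, and its correlation with polygenic scores.

#' Log2 counts per million
#'
#' logCPM = log2((count + 0.5) / (library size + 1) * 1e6), the working
#' scale of the weighted-regression expression pipeline.
#'
#' @param counts gene-by-sample count matrix.
#' @param lib_size per-sample library sizes (default column sums).
#' @return numeric matrix of the same shape.
#' @export
compute_logcpm <- function(counts, lib_size = colSums(counts)) {
  if (any(lib_size <= 0)) stop("library sizes must be positive")
  log2(sweep(counts + 0.5, 2L, (lib_size + 1) / 1e6, `/`))
}

#' Mean-variance precision weights for log-counts
#'
#' The voom-style procedure: each gene is fitted by unweighted least
#' squares on the design; the square roots of the residual standard
#' deviations are smoothed by lowess (span 0.5) against average log2
#' count; each observation's predicted standard deviation is read off the
#' trend at its fitted log2 count, and its weight is the predicted SD to
#' the power -4 (an inverse-variance weight on the logCPM scale). With
#' fewer than `min_genes` genes the trend is unreliable and unit weights
#' are returned with a warning.
#'
#' @param logcpm gene-by-sample logCPM matrix.
#' @param design model matrix (samples x coefficients), full rank.
#' @param lib_size per-sample library sizes used to convert logCPM to
#'   log-counts.
#' @param span lowess span (default 0.5).
#' @param min_genes minimum gene count for trend fitting (default 50).
#' @return gene-by-sample matrix of observation weights.
#' @export
voom_weights <- function(logcpm, design, lib_size, span = 0.5,
                         min_genes = 50) {
  g <- nrow(logcpm); n <- ncol(logcpm)
  if (g < min_genes) {
    warning("fewer than ", min_genes,
            " genes; mean-variance trend unreliable, using unit weights")
    return(matrix(1, g, n, dimnames = dimnames(logcpm)))
  }
  design <- as.matrix(design)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("design is rank deficient")
  coef <- t(qr.coef(qrd, t(logcpm)))
  fitted <- coef %*% t(design)
  resid <- logcpm - fitted
  sigma <- sqrt(rowSums(resid^2) / (n - ncol(design)))

  # average log2 count per gene, and the trend of sqrt(SD) against it
  sx <- rowMeans(logcpm) + mean(log2(lib_size + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  keep <- is.finite(sx) & is.finite(sy) & sigma > 0
  lo <- stats::lowess(sx[keep], sy[keep], f = span)

  fitted_count <- fitted + outer(rep(1, g), log2(lib_size + 1) - log2(1e6))
  pred_sqrt_sd <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_count),
                                rule = 2)$y
  w <- matrix(pred_sqrt_sd, g, n)^-4
  dimnames(w) <- dimnames(logcpm)
  w
}

#' Select covariates associated with expression principal components
#'
#' Computes the top `n_pcs` principal components of the gene-standardized
#' logCPM matrix (so high-abundance genes do not dominate), flags every
#' candidate covariate significantly associated with any PC (Pearson test
#' for continuous candidates, one-way ANOVA for categorical ones), and
#' then resolves collinearity: among flagged candidates whose best PC
#' coincides and whose mutual correlation exceeds `collinearity_r`
#' (Cramer's V for categorical pairs), only the more strongly associated
#' one is kept; the remainder are re-tested until no change.
#'
#' @param logcpm gene-by-sample logCPM matrix.
#' @param candidates data.frame of candidate covariates (rows = samples).
#' @param n_pcs number of expression PCs (default 20, capped at n - 1).
#' @param alpha association test level (default 0.05).
#' @param collinearity_r collinearity threshold (default 0.6).
#' @return character vector of selected covariate names.
#' @export
select_covariates <- function(logcpm, candidates, n_pcs = 20, alpha = 0.05,
                              collinearity_r = 0.6) {
  n <- ncol(logcpm)
  if (n < n_pcs + 1) n_pcs <- n - 1
  z <- t(scale(t(logcpm)))
  z[!is.finite(z)] <- 0
  pcs <- stats::prcomp(t(z), center = TRUE)$x[, seq_len(n_pcs), drop = FALSE]

  assoc_p <- function(v, pc) {
    if (is.numeric(v)) stats::cor.test(v, pc)$p.value
    else summary(stats::aov(pc ~ factor(v)))[[1]][["Pr(>F)"]][1]
  }
  test_all <- function(nms) {
    t(sapply(nms, function(nm) {
      p <- vapply(seq_len(n_pcs), function(k) assoc_p(candidates[[nm]],
                                                      pcs[, k]), 0)
      c(best_pc = which.min(p), min_p = min(p))
    }))
  }
  pair_r <- function(a, b) {
    if (is.numeric(a) && is.numeric(b)) return(abs(stats::cor(a, b)))
    if (!is.numeric(a) && !is.numeric(b)) {
      tb <- table(a, b)
      chi <- suppressWarnings(stats::chisq.test(tb, correct = FALSE)$statistic)
      return(sqrt(chi / (sum(tb) * (min(dim(tb)) - 1))))
    }
    num <- if (is.numeric(a)) a else b
    cat_ <- if (is.numeric(a)) b else a
    sqrt(summary(stats::lm(num ~ factor(cat_)))$r.squared)
  }

  active <- names(candidates)
  repeat {
    stats_tab <- test_all(active)
    flagged <- active[stats_tab[, "min_p"] < alpha]
    if (length(flagged) < 2) return(flagged)
    ft <- stats_tab[match(flagged, active), , drop = FALSE]
    dropped <- NULL
    for (i in seq_along(flagged)) {
      for (j in seq_len(i - 1)) {
        if (ft[i, "best_pc"] != ft[j, "best_pc"]) next
        r <- pair_r(candidates[[flagged[i]]], candidates[[flagged[j]]])
        if (is.finite(r) && r > collinearity_r) {
          dropped <- if (ft[i, "min_p"] < ft[j, "min_p"]) flagged[j]
          else flagged[i]
          break
        }
      }
      if (!is.null(dropped)) break
    }
    if (is.null(dropped)) return(flagged)
    active <- setdiff(active, dropped)
  }
}

#' Regress covariates out of expression, gene by gene
#'
#' Weighted least squares of each gene's logCPM on the covariate-only
#' design (categorical covariates one-hot encoded against a reference
#' level); returns the residual matrix consumed by [de_weights()] and
#' [aggregate_score()].
#'
#' @param logcpm gene-by-sample logCPM matrix.
#' @param covariates data.frame of covariates (rows = samples).
#' @param weights optional gene-by-sample observation weights (e.g. from
#'   [voom_weights()]); unit weights when NULL.
#' @return residual matrix, genes x samples.
#' @export
regress_covariates <- function(logcpm, covariates, weights = NULL) {
  covariates <- as.data.frame(covariates)
  constant <- vapply(covariates, function(v) length(unique(v)) < 2,
                     logical(1))
  covariates <- covariates[, !constant, drop = FALSE]
  design <- if (ncol(covariates) == 0)
    matrix(1, ncol(logcpm), 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~ ., data = covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- setdiff(colnames(design),
                       colnames(design)[qrd$pivot[seq_len(qrd$rank)]])
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  g <- nrow(logcpm)
  if (is.null(weights)) {
    coef <- t(qr.coef(qrd, t(logcpm)))
    return(logcpm - coef %*% t(design))
  }
  res <- matrix(NA_real_, g, ncol(logcpm), dimnames = dimnames(logcpm))
  for (k in seq_len(g)) {
    fit <- stats::lm.wfit(design, logcpm[k, ], weights[k, ])
    res[k, ] <- fit$residuals
  }
  res
}

#' Per-gene case/control differential-expression weights
#'
#' Weighted least squares of each gene's covariate-adjusted residual on a
#' case indicator (cases coded 1, so positive coefficients mean higher
#' expression in cases). Coefficients are on the log2-fold-change scale of
#' the logCPM residuals. Genes with two-sided p < `alpha` are flagged
#' nominally significant.
#'
#' @param residuals gene-by-sample residual matrix from
#'   [regress_covariates()].
#' @param diagnosis case/control labels (`"case"`/`"schizophrenia"` = 1)
#'   or a 0/1 vector.
#' @param weights optional gene-by-sample observation weights.
#' @param alpha nominal significance level (default 0.05).
#' @return data.frame of class `de_result`: `gene`, `coef`, `se`,
#'   `p_value`, `significant`.
#' @export
de_weights <- function(residuals, diagnosis, weights = NULL, alpha = 0.05) {
  x <- if (is.numeric(diagnosis)) as.numeric(diagnosis)
  else as.numeric(diagnosis %in% c("case", "schizophrenia"))
  if (length(unique(x)) < 2) stop("both diagnostic classes must be present")
  n <- ncol(residuals)
  g <- nrow(residuals)
  w <- if (is.null(weights)) matrix(1, g, n) else weights
  sw <- rowSums(w)
  xbar <- (w %*% x) / sw
  ybar <- rowSums(w * residuals) / sw
  xc <- sweep(matrix(x, g, n, byrow = TRUE), 1L, xbar, `-`)
  yc <- residuals - ybar
  sxx <- rowSums(w * xc^2)
  sxy <- rowSums(w * xc * yc)
  slope <- sxy / sxx
  e <- yc - slope * xc
  sigma2 <- rowSums(w * e^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  out <- data.frame(gene = rownames(residuals) %||% paste0("g", seq_len(g)),
                    coef = slope, se = se, p_value = p,
                    significant = p < alpha, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate gene expression score
#'
#' Per sample, the sum over nominally significant genes of the gene's
#' covariate-adjusted residual times its case/control coefficient, with no
#' normalization. A positive score indicates expression deviating from
#' the cohort mean in the direction of cases. Because the weights are the
#' in-sample coefficients, the case-minus-control mean of the score equals
#' the sum of squared flagged coefficients and is therefore nonnegative by
#' construction.
#'
#' @param residuals gene-by-sample residual matrix (the same one
#'   `de` was computed on).
#' @param de a `de_result` from [de_weights()].
#' @return list of class `aggregate_score_result`: `score` (named
#'   per-sample vector), `n_genes` (flagged gene count), `genes`.
#' @export
aggregate_score <- function(residuals, de) {
  flagged <- which(de$significant)
  if (length(flagged) == 0) {
    warning("no nominally significant genes; aggregate scores are all zero")
    score <- stats::setNames(numeric(ncol(residuals)), colnames(residuals))
  } else {
    score <- as.numeric(crossprod(residuals[flagged, , drop = FALSE],
                                  de$coef[flagged]))
    names(score) <- colnames(residuals)
  }
  structure(list(score = score, n_genes = length(flagged),
                 genes = de$gene[flagged]),
            class = "aggregate_score_result")
}

#' Correlate polygenic scores with aggregate expression scores
#'
#' The polygenic score is residualized on the ancestry-specific principal
#' components by ordinary least squares, then Pearson-correlated with the
#' aggregate gene expression score; the two-sided p-value comes from the
#' correlation t-test.
#'
#' @param prs numeric polygenic scores (one threshold column), aligned to
#'   samples.
#' @param agg aggregate scores: an `aggregate_score_result` or a numeric
#'   vector, aligned to the same samples.
#' @param pcs matrix/data.frame of ancestry-specific PCs (NULL to skip
#'   residualization).
#' @return list: `r`, `p_value`, `n`.
#' @export
correlate_prs_expression <- function(prs, agg, pcs = NULL) {
  a <- if (inherits(agg, "aggregate_score_result")) agg$score else agg
  if (length(prs) != length(a)) stop("samples not matched across modalities")
  if (length(prs) < 4) stop("need >= 4 matched samples")
  resid_prs <- if (is.null(pcs)) prs - mean(prs)
  else stats::lm(prs ~ ., data = as.data.frame(pcs))$residuals
  ct <- stats::cor.test(resid_prs, a)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(prs))
}
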