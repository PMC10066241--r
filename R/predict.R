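# Variance explained by polygenic scores: incremental Nagelkerke pseudo-R2
# for binary phenotypes, incremental R2 for quantitative phenotypes, both
# adjusted for ancestry-specific principal components; plus the 2x2
# continuity-corrected contingency test used for ancestry-by-diagnosis
# composition.

#' Nagelkerke pseudo-R-squared of a logistic model
#'
#' R2_N = (1 - exp(-2 (LL_model - LL_intercept) / n)) /
#'        (1 - exp(2 LL_intercept / n)),
#' where LL_intercept is the intercept-only log-likelihood. The null model
#' evaluated against itself gives 0; a saturated model approaches 1.
#'
#' @param ll_model log-likelihood of the model.
#' @param ll_intercept log-likelihood of the intercept-only model.
#' @param n sample size.
#' @return numeric scalar.
#' @export
nagelkerke_r2 <- function(ll_model, ll_intercept, n) {
  (1 - exp(-2 * (ll_model - ll_intercept) / n)) /
    (1 - exp(2 * ll_intercept / n))
}

#' Incremental variance explained by a polygenic score (binary phenotype)
#'
#' Fits the covariates-only (intercept + PCs) and full (+ standardized
#' score) logistic models by maximum likelihood and reports the
#' incremental Nagelkerke pseudo-R-squared -- full minus covariates-only,
#' the convention of the polygenic-score prediction literature -- with the
#' Wald p-value and direction of the score coefficient. Perfect or
#' quasi-perfect separation is flagged as unstable.
#'
#' @param score numeric polygenic score (one threshold column); it is
#'   z-standardized within the analysis subset before fitting.
#' @param status binary phenotype (0/1 or logical).
#' @param pcs matrix/data.frame of ancestry-adjustment covariates (the
#'   first 10 ancestry-specific PCs in the standard analysis); NULL for
#'   none.
#' @return list of class `prediction_result`: `n`, `n_cases`,
#'   `n_controls`, `variance_explained`, `p_value`, `direction`,
#'   `unstable`.
#' @export
predict_binary <- function(score, status, pcs = NULL) {
  status <- as.integer(status)
  if (anyNA(score) || anyNA(status)) stop("missing values not allowed")
  if (!all(status %in% 0:1)) stop("status must be binary 0/1")
  n <- length(status)
  score_z <- as.numeric(scale(score))
  dat <- data.frame(status = status, score = score_z)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    dat <- cbind(dat, pcs)
  }
  rhs_null <- if (is.null(pcs)) "1" else paste(colnames(pcs), collapse = " + ")
  f_null <- stats::as.formula(paste("status ~", rhs_null))
  f_full <- stats::as.formula(paste("status ~ score +", rhs_null))

  unstable <- FALSE
  h <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1|did not converge",
              conditionMessage(w))) {
      unstable <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  fit0 <- withCallingHandlers(
    stats::glm(f_null, family = stats::binomial(), data = dat), warning = h)
  fit1 <- withCallingHandlers(
    stats::glm(f_full, family = stats::binomial(), data = dat), warning = h)
  fit_int <- stats::glm(status ~ 1, family = stats::binomial(), data = dat)

  ll0 <- as.numeric(stats::logLik(fit0))
  ll1 <- as.numeric(stats::logLik(fit1))
  lli <- as.numeric(stats::logLik(fit_int))
  r2 <- nagelkerke_r2(ll1, lli, n) - nagelkerke_r2(ll0, lli, n)
  cf <- summary(fit1)$coefficients["score", ]
  structure(list(n = n, n_cases = sum(status), n_controls = sum(1 - status),
                 variance_explained = r2, p_value = unname(cf[4]),
                 direction = sign(unname(cf[1])), unstable = unstable),
            class = "prediction_result")
}

#' Incremental variance explained by a polygenic score (quantitative
#' phenotype)
#'
#' Ordinary least squares: incremental R-squared of the full model
#' (score + PCs) over the PCs-only model, with the t-test p-value of the
#' score coefficient.
#'
#' @inheritParams predict_binary
#' @param phenotype numeric continuous phenotype.
#' @return list of class `prediction_result`: `n`, `variance_explained`,
#'   `p_value`, `direction`.
#' @export
predict_quantitative <- function(score, phenotype, pcs = NULL) {
  if (anyNA(score) || anyNA(phenotype)) stop("missing values not allowed")
  if (stats::sd(phenotype) == 0) stop("zero-variance phenotype")
  n <- length(phenotype)
  score_z <- as.numeric(scale(score))
  dat <- data.frame(y = phenotype, score = score_z)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    dat <- cbind(dat, pcs)
  }
  rhs_null <- if (is.null(pcs)) "1" else paste(colnames(pcs), collapse = " + ")
  fit0 <- stats::lm(stats::as.formula(paste("y ~", rhs_null)), data = dat)
  fit1 <- stats::lm(stats::as.formula(paste("y ~ score +", rhs_null)),
                    data = dat)
  r2 <- summary(fit1)$r.squared - summary(fit0)$r.squared
  cf <- summary(fit1)$coefficients["score", ]
  structure(list(n = n, variance_explained = r2, p_value = unname(cf[4]),
                 direction = sign(unname(cf[1]))),
            class = "prediction_result")
}

#' Variance explained across all score thresholds
#'
#' Convenience wrapper applying [predict_binary()] or
#' [predict_quantitative()] to every column of a score matrix. A
#' Bonferroni flag marks thresholds significant at 0.05 divided by the
#' number of thresholds.
#'
#' @param scores a `score_matrix` from [compute_prs()].
#' @param phenotype binary status or continuous phenotype.
#' @param pcs ancestry-adjustment covariates.
#' @param binary logical; choose the logistic or linear analysis.
#' @return data.frame: one row per threshold with `p_T`, `n_variants`,
#'   `variance_explained`, `p_value`, `direction`,
#'   `significant_bonferroni`.
#' @export
predict_thresholds <- function(scores, phenotype, pcs = NULL,
                               binary = TRUE) {
  res <- lapply(seq_along(scores$thresholds), function(k) {
    s <- scores$scores[, k]
    if (stats::sd(s) == 0)
      return(data.frame(variance_explained = 0, p_value = NA_real_,
                        direction = 0))
    r <- if (binary) predict_binary(s, phenotype, pcs)
    else predict_quantitative(s, phenotype, pcs)
    data.frame(variance_explained = r$variance_explained,
               p_value = r$p_value, direction = r$direction)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(p_T = scores$thresholds,
                          n_variants = as.integer(scores$n_variants)), out)
  out$significant_bonferroni <- !is.na(out$p_value) &
    out$p_value < 0.05 / length(scores$thresholds)
  out
}

#' Continuity-corrected chi-square test on a 2x2 table
#'
#' Yates correction: the statistic is the sum over cells of
#' (max(|O - E| - 0.5, 0))^2 / E with expectations from the row/column
#' margins, referred to a chi-square distribution with one degree of
#' freedom.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list of class `contingency_result`: `table`, `statistic`,
#'   `df`, `n`, `p_value`.
#' @export
contingency_test <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2)) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in contingency table")
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  stat <- sum(pmax(abs(m - e) - 0.5, 0)^2 / e)
  structure(list(table = m, statistic = stat, df = 1L, n = n,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Row-wise first-column proportions of a contingency table
#'
#' @param table matrix of counts.
#' @return data.frame: per row, the first column's share of the row total
#'   (`proportion`) and the same in percent rounded to 1 decimal
#'   (`percent`); empty rows are NA and flagged.
#' @export
proportion_report <- function(table) {
  m <- as.matrix(table)
  tot <- rowSums(m)
  prop <- ifelse(tot > 0, m[, 1] / tot, NA_real_)
  data.frame(row = seq_len(nrow(m)), proportion = prop,
             percent = round(100 * prop, 1), empty_row = tot == 0)
}
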