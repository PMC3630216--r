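# Per-variant, per-outcome covariate-adjusted logistic screening.
#
# Genotype enters as an ordinal dosage (0/1/2 copies of the minor allele;
# 0/1 for the binary pseudo-variants), so exp(beta) is a per-allele odds
# ratio and the 1-df Wald test on beta is the trend test.  Fits are
# complete-case per variant; quasi-complete separation is detected and
# flagged rather than silently estimated.

covariate_design <- function(covariates) {
  data.frame(race_white = as.integer(covariates$race == "white"),
             sex_male = as.integer(covariates$sex == "male"),
             age = covariates$age)
}

#' Fit the per-allele logistic model for one variant and one outcome
#'
#' Maximum-likelihood logistic regression of a case-only dichotomy on
#' ordinal dosage plus race (white vs other), sex and age in years.
#' Convergence uses a relative log-likelihood tolerance of 1e-8 with an
#' iteration cap of 100.
#'
#' @param dosage Numeric vector of minor-allele dosages (`NA` = missing;
#'   subjects with missing dosage are dropped for this variant only).
#' @param y Binary outcome vector (0/1), same length.
#' @param covariates Covariate data frame (`age`, `sex`, `race`) aligned
#'   with `dosage`, or `NULL` for an unadjusted fit.
#' @return One-row data frame: `or`, `ci_low`, `ci_high` (Wald 95% CI),
#'   `p` (1-df Wald trend test), `beta`, `se`, `status`
#'   (`converged`/`separated`/`degenerate`/`not_converged`), `n_used`.
#' @export
fit_variant_model <- function(dosage, y, covariates = NULL) {
  df <- data.frame(y = y, dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, covariate_design(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  empty <- function(status) data.frame(
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    beta = NA_real_, se = NA_real_, status = status, n_used = nrow(df))
  if (nrow(df) == 0L || length(unique(df$y)) < 2L ||
      length(unique(df$dosage)) < 2L)
    return(empty("degenerate"))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-10
  if (separated || any(fit$fitted.values < eps | fit$fitted.values > 1 - eps))
    return(empty("separated"))
  if (!fit$converged) return(empty("not_converged"))
  beta <- coef(fit)[["dosage"]]
  se <- sqrt(diag(vcov(fit))[["dosage"]])
  z <- qnorm(0.975)
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se),
             p = 2 * pnorm(-abs(beta / se)),
             beta = beta, se = se, status = "converged", n_used = nrow(df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values (`NA` entries are passed through
#'   unadjusted and never rejected).
#' @param q Target false discovery rate.
#' @return List with `adjusted` (monotone BH-adjusted p-values) and
#'   `reject` (logical, `adjusted <= q`).
#' @export
bh_adjust <- function(p, q = 0.25) {
  adjusted <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adjusted[ok] <- p.adjust(p[ok], method = "BH")
  reject <- !is.na(adjusted) & adjusted <= q
  list(adjusted = adjusted, reject = reject)
}

align_outcomes <- function(panel, outcomes) {
  m <- match(panel$subjects, rownames(outcomes$indicator))
  if (anyNA(m)) stopf("outcome set missing panel subject(s)")
  outcomes$indicator[m, , drop = FALSE]
}

align_covariates <- function(panel, covariates) {
  m <- match(panel$subjects, covariates$subject)
  if (anyNA(m)) stopf("covariate table missing panel subject(s)")
  covariates[m, , drop = FALSE]
}

#' Scan all variants against all seven outcomes
#'
#' One covariate-adjusted per-allele fit per retained variant x outcome,
#' with BH false-discovery-rate control applied within each outcome family
#' (default) or pooled across all tests.  A failing fit is flagged in its
#' row; the scan never aborts on a single bad variant.
#'
#' @param panel QC-filtered, oriented [genotype_panel()].
#' @param outcomes `outcome_set` covering the panel subjects.
#' @param covariates Covariate table covering the panel subjects.
#' @param q FDR level (default 0.25).
#' @param family `"per-outcome"` (7 families across variants) or
#'   `"pooled"` (one family).
#' @return Data frame ordered by (gene, variant, outcome): association
#'   results with `p_adj` and `reject` columns.
#' @export
snp_scan <- function(panel, outcomes, covariates, q = 0.25,
                 family = c("per-outcome", "pooled")) {
  family <- match.arg(family)
  ind <- align_outcomes(panel, outcomes)
  cov <- align_covariates(panel, covariates)
  v <- panel$variants
  ord <- order(v$gene, v$variant)
  cats <- mutation_categories()
  rows <- vector("list", length(ord) * length(cats))
  i <- 0L
  for (j in ord) {
    for (k in seq_along(cats)) {
      i <- i + 1L
      fit <- fit_variant_model(panel$dosage[, j], ind[, k], cov)
      rows[[i]] <- cbind(
        data.frame(variant = v$variant[j], gene = v$gene[j],
                   outcome = cats[k]), fit)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  res$reject <- FALSE
  if (family == "pooled") {
    adj <- bh_adjust(res$p, q)
    res$p_adj <- adj$adjusted
    res$reject <- adj$reject
  } else {
    for (k in cats) {
      sel <- res$outcome == k
      adj <- bh_adjust(res$p[sel], q)
      res$p_adj[sel] <- adj$adjusted
      res$reject[sel] <- adj$reject
    }
  }
  rownames(res) <- NULL
  res
}

subset_outcomes <- function(outcomes, subjects) {
  keep <- outcomes$subject %in% subjects
  structure(list(subject = outcomes$subject[keep],
                 category = outcomes$category[keep],
                 indicator = outcomes$indicator[keep, , drop = FALSE]),
            class = "outcome_set")
}

#' Site-restricted subanalysis
#'
#' Reruns [snp_scan()] on the subjects whose tumor site matches `sites`
#' (e.g. small-intestinal tumors only).
#'
#' @inheritParams snp_scan
#' @param sites Character vector of tumor-site labels to keep.
#' @return As [snp_scan()], with the subset size as attribute `"n_subset"`.
#' @export
subset_scan <- function(panel, outcomes, covariates, sites, q = 0.25,
                        family = c("per-outcome", "pooled")) {
  cov <- align_covariates(panel, covariates)
  keep <- panel$subjects[!is.na(cov$site) & cov$site %in% sites]
  if (!length(keep)) stopf("site filter leaves no subjects")
  sub <- subset_panel(panel, subjects = keep)
  res <- snp_scan(sub, subset_outcomes(outcomes, keep),
              covariates[covariates$subject %in% keep, , drop = FALSE],
              q = q, family = family)
  attr(res, "n_subset") <- length(keep)
  res
}
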