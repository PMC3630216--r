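# Gene-level logistic kernel-machine variance-component score test.
#
# Model: logit P(y_i = 1) = alpha_0 + alpha' x_i + h(z_i), with h defined
# by a positive semi-definite kernel K and random-effect variance tau.
# H0: tau = 0 is tested with the score statistic Q = (y - mu)' K (y - mu),
# where mu are the fitted probabilities of the covariate-only null model.
# Under H0, Q is approximately a mixture of chi-squares; the default
# p-value matches the first two moments of the mixture to a scaled
# chi-square (Satterthwaite): with P0 = V - V X (X'VX)^-1 X'V,
#   E[Q] = tr(P0 K),  Var[Q] = 2 tr(P0 K P0 K),
#   kappa = Var / (2 E),  nu = 2 E^2 / Var,  p = P(chisq_nu > Q / kappa).
# An exact mode evaluates the tail of the eigenvalue mixture by Imhof's
# numerical inversion, and a permutation oracle is available for
# validation.

#' Fit the covariate-only null model for the kernel test
#'
#' Logistic ML fit of one outcome dichotomy on the adjustment covariates
#' only (no genotypes), returning the fitted probabilities, the weight
#' matrix V = diag(mu (1 - mu)) and the projection kernel
#' P0 = V - V X (X'VX)^-1 X'V used for moment matching.
#'
#' @param y Binary outcome vector with both levels present.
#' @param covariates Covariate data frame (`age`, `sex`, `race`), or
#'   `NULL` for an intercept-only null model.
#' @return An object of class `skat_null`: list with `X`, `alpha`, `mu`,
#'   `v` (diagonal of V), `P0`, `y`.
#' @export
fit_null <- function(y, covariates = NULL) {
  if (length(unique(y)) < 2L) stopf("outcome has a single level")
  df <- data.frame(y = y)
  if (!is.null(covariates)) df <- cbind(df, covariate_design(covariates))
  if (anyNA(df)) stopf("null-model covariates must be complete")
  fit <- glm(y ~ ., data = df, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  mu <- fit$fitted.values
  eps <- 1e-10
  if (any(mu < eps | mu > 1 - eps))
    stopf("null model separated or degenerate for this outcome")
  X <- model.matrix(fit)
  v <- mu * (1 - mu)
  VX <- v * X
  P0 <- diag(v) - VX %*% solve(crossprod(X, VX), t(VX))
  P0 <- (P0 + t(P0)) / 2
  if (max(abs(P0 %*% X)) > 1e-6)
    stopf("projection failed to annihilate the design columns")
  structure(list(X = X, alpha = coef(fit), mu = mu, v = v, P0 = P0, y = y),
            class = "skat_null")
}

#' Build the identity-by-state kernel for a gene
#'
#' K_ij = sum over the gene's variants of IBS(g_is, g_js) / (2p), with
#' IBS(a, b) = 2 - |a - b| on minor-allele dosages, so K_ii = 1 without
#' missingness.  Missing dosages are mean-imputed per variant before
#' kernel construction (keeps K positive semi-definite and the subject
#' count fixed).  Binary pseudo-variants use the same formula on {0, 1}
#' dosages.
#'
#' @param G Numeric matrix of dosages, subjects x variants (>= 1 variant).
#' @param check Verify symmetry and positive semi-definiteness (smallest
#'   eigenvalue >= -1e-8); on by default.
#' @return An object of class `gene_kernel`: list with `K`, `p`
#'   (variant count) and `subjects`.
#' @export
build_ibs_kernel <- function(G, check = TRUE) {
  G <- as.matrix(G)
  if (ncol(G) < 1L) stopf("gene has zero variants")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (anyNA(g)) {
      m <- mean(g, na.rm = TRUE)
      if (is.nan(m)) stopf("variant %d has no non-missing calls", j)
      g[is.na(g)] <- m
      G[, j] <- g
    }
  }
  n <- nrow(G)
  p <- ncol(G)
  K <- matrix(0, n, n)
  for (j in seq_len(p))
    K <- K + 2 - abs(outer(G[, j], G[, j], "-"))
  K <- K / (2 * p)
  if (check) {
    if (max(abs(K - t(K))) > 1e-10) stopf("kernel not symmetric")
    lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) < -1e-8) stopf("kernel not positive semi-definite")
  }
  structure(list(K = K, p = p, subjects = rownames(G)),
            class = "gene_kernel")
}

as_kernel_matrix <- function(kernel) {
  if (inherits(kernel, "gene_kernel")) kernel$K else as.matrix(kernel)
}

#' Variance-component score statistic
#'
#' Q = (y - mu)' K (y - mu), with mu from the covariate-only null model;
#' nonnegative for a positive semi-definite kernel.
#'
#' @param kernel A `gene_kernel` (or plain kernel matrix).
#' @param null A [fit_null()] object.
#' @param y Outcome vector; defaults to the one stored in the null model.
#' @return The scalar score statistic Q.
#' @export
q_statistic <- function(kernel, null, y = null$y) {
  K <- as_kernel_matrix(kernel)
  r <- y - null$mu
  drop(crossprod(r, K %*% r))
}

# Imhof (1961) numerical inversion for P(sum_i lambda_i chisq_1 > q).
imhof_tail <- function(q, lambda) {
  lambda <- lambda[abs(lambda) > 1e-12]
  if (!length(lambda)) return(NA_real_)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                   subdivisions = 2000L, stop.on.error = FALSE)$value
  min(max(0.5 + val / pi, 1e-12), 1)
}

#' Moment-matched (and exact) p-value for the score statistic
#'
#' Default: Satterthwaite scaled chi-square with kappa and nu from the
#' exact first two moments of Q under the null, which absorb the
#' correlation between variants of the same gene.  `method = "exact"`
#' computes the tail of the chi-square mixture whose weights are the
#' eigenvalues of P0-whitened K, by Imhof's numerical inversion.
#'
#' @param Q Score statistic from [q_statistic()].
#' @param kernel The same kernel.
#' @param null The same null model.
#' @param method `"moments"` (default) or `"exact"`.
#' @return List with `kappa`, `nu`, `p` (and `lambda` for `"exact"`);
#'   degenerate kernels (nonpositive moments) yield `p = NA` with a note.
#' @export
moment_matched_p <- function(Q, kernel, null,
                             method = c("moments", "exact")) {
  method <- match.arg(method)
  K <- as_kernel_matrix(kernel)
  P0K <- null$P0 %*% K
  e <- sum(diag(P0K))
  vq <- 2 * sum(P0K * t(P0K))
  if (e <= 0 || vq <= 0)
    return(list(kappa = NA_real_, nu = NA_real_, p = NA_real_,
                note = "degenerate kernel"))
  if (method == "moments") {
    kappa <- vq / (2 * e)
    nu <- 2 * e^2 / vq
    return(list(kappa = kappa, nu = nu,
                p = pchisq(Q / kappa, df = nu, lower.tail = FALSE)))
  }
  # exact mixture: eigenvalues of P0^(1/2) K P0^(1/2)
  ep <- eigen(null$P0, symmetric = TRUE)
  pos <- pmax(ep$values, 0)
  S <- ep$vectors %*% (sqrt(pos) * t(ep$vectors))
  lambda <- eigen(S %*% K %*% S, symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(abs(lambda))]
  p <- if (Q <= 0) 1 else imhof_tail(Q, lambda)
  list(kappa = vq / (2 * e), nu = 2 * e^2 / vq, p = p, lambda = lambda)
}

#' Permutation p-value for the score statistic
#'
#' Permutes the outcome labels within strata of the fitted null
#' probabilities binned to deciles (so covariate structure is respected
#' approximately), recomputes Q for each permutation, and applies the
#' add-one rule p = (1 + #\{Q_perm >= Q_obs\}) / (1 + n_perm).
#'
#' @param kernel A `gene_kernel` (or matrix).
#' @param null A [fit_null()] object.
#' @param y Outcome vector (defaults to the null model's).
#' @param n_perm Number of permutations (>= 1000).
#' @param seed Integer seed.
#' @return The permutation p-value, with the observed Q as attribute
#'   `"Q"`.
#' @export
permutation_p <- function(kernel, null, y = null$y, n_perm = 10000L,
                          seed = 1L) {
  if (n_perm < 1000L) stopf("n_perm must be at least 1000")
  K <- as_kernel_matrix(kernel)
  n <- length(y)
  Q_obs <- q_statistic(K, null, y)
  breaks <- unique(quantile(null$mu, probs = seq(0, 1, 0.1)))
  bins <- if (length(breaks) > 1L)
    cut(null$mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  idx <- with_seed(seed, {
    m <- matrix(seq_len(n), n, n_perm)
    for (b in unique(bins)) {
      rows <- which(bins == b)
      if (length(rows) > 1L)
        m[rows, ] <- apply(m[rows, , drop = FALSE], 2L, sample)
    }
    m
  })
  R <- matrix(y[idx], n, n_perm) - null$mu
  Q_perm <- colSums(R * (K %*% R))
  p <- (1 + sum(Q_perm >= Q_obs)) / (1 + n_perm)
  attr(p, "Q") <- Q_obs
  p
}

#' Gene-level kernel association scan
#'
#' One kernel test per gene x outcome: the null model is fitted once per
#' outcome, each gene's IBS kernel once overall, and failures (degenerate
#' outcomes or kernels) are isolated per gene rather than aborting the
#' scan.
#'
#' @param panel QC-filtered, oriented [genotype_panel()].
#' @param outcomes `outcome_set` covering the panel subjects.
#' @param covariates Covariate table covering the panel subjects.
#' @param method P-value mode: `"moments"`, `"exact"` or `"permutation"`.
#' @param n_perm,seed Permutation settings (permutation mode only).
#' @return Data frame ordered by (gene, outcome): `gene`, `outcome`,
#'   `n_variants`, `Q`, `kappa`, `nu`, `p`, `status`.
#' @export
gene_scan <- function(panel, outcomes, covariates,
                      method = c("moments", "exact", "permutation"),
                      n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  ind <- align_outcomes(panel, outcomes)
  cov <- align_covariates(panel, covariates)
  genes <- sort(unique(panel$variants$gene))
  cats <- mutation_categories()
  kernels <- list()
  for (g in genes) {
    cols <- panel$variants$variant[panel$variants$gene == g]
    kernels[[g]] <- tryCatch(
      build_ibs_kernel(panel$dosage[, cols, drop = FALSE]),
      error = function(e) NULL)
  }
  rows <- list()
  i <- 0L
  for (k in seq_along(cats)) {
    null <- tryCatch(fit_null(ind[, k], cov), error = function(e) NULL)
    for (g in genes) {
      i <- i + 1L
      row <- data.frame(gene = g, outcome = cats[k],
                        n_variants = sum(panel$variants$gene == g),
                        Q = NA_real_, kappa = NA_real_, nu = NA_real_,
                        p = NA_real_, status = "failed")
      if (!is.null(null) && !is.null(kernels[[g]])) {
        Q <- q_statistic(kernels[[g]], null)
        row$Q <- Q
        if (method == "permutation") {
          row$p <- as.numeric(permutation_p(kernels[[g]], null,
                                            n_perm = n_perm,
                                            seed = sub_seed(seed, i)))
          row$status <- "ok"
        } else {
          mm <- moment_matched_p(Q, kernels[[g]], null, method = method)
          row$kappa <- mm$kappa
          row$nu <- mm$nu
          row$p <- mm$p
          row$status <- if (is.na(mm$p)) "degenerate" else "ok"
        }
      }
      rows[[i]] <- row
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene, match(res$outcome, cats)), ]
  rownames(res) <- NULL
  res
}
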