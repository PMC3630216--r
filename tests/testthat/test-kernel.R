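# Logistic kernel-machine score test: null model projection, IBS kernel,
# Q statistic, moment matching, exact mixture, permutation oracle.

test_that("intercept-only null model fits the case fraction", {
  y <- rep(c(1, 0), c(6, 14))
  null <- fit_null(y)
  expect_equal(unname(null$mu), rep(0.3, 20))
  expect_lt(max(abs(null$P0 %*% null$X)), 1e-8)
})

test_that("the projection annihilates covariate columns", {
  withr::with_seed(2, {
    cov <- random_covariates(100)
    y <- rbinom(100, 1, 0.4)
    null <- fit_null(y, cov)
    expect_lt(max(abs(null$P0 %*% null$X)), 1e-8)
    expect_true(all(null$mu > 0 & null$mu < 1))
    expect_equal(null$P0, t(null$P0))
  })
})

test_that("null model recovers generating coefficients within 2 SE", {
  withr::with_seed(4, {
    n <- 4000
    cov <- random_covariates(n)
    eta <- -1 + 0.6 * (cov$race == "white") - 0.4 * (cov$sex == "male") +
      0.02 * cov$age
    y <- rbinom(n, 1, plogis(eta))
    null <- fit_null(y, cov)
    se <- sqrt(diag(solve(crossprod(null$X, null$v * null$X))))
    truth <- c(-1, 0.6, -0.4, 0.02)
    expect_true(all(abs(null$alpha - truth) < 2 * se))
  })
})

test_that("IBS kernel entries follow the allele-sharing definition", {
  # single variant: IBS(a, b) = 2 - |a - b|, normalized by 2p
  k <- build_ibs_kernel(cbind(c(0, 2, 1)))
  expect_equal(k$K[1, 2], 0)    # opposite homozygotes share nothing
  expect_equal(k$K[2, 3], 0.5)  # het vs hom shares one allele
  expect_equal(unname(diag(k$K)), rep(1, 3))
  # identical genotype vectors across several variants
  G <- rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0))
  k2 <- build_ibs_kernel(G)
  expect_equal(k2$K[1, 2], 1)
  # opposite homozygotes at every variant
  G3 <- rbind(c(0, 0, 0), c(2, 2, 2))
  expect_equal(build_ibs_kernel(G3)$K[1, 2], 0)
})

test_that("IBS kernel is symmetric PSD on random dosage matrices", {
  withr::with_seed(15, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      p <- sample(1:8, 1)
      G <- matrix(rbinom(n * p, 2, runif(1, 0.1, 0.5)), n, p)
      if (i %% 3 == 0) G[sample(length(G), n %/% 4)] <- NA  # mean-imputed
      k <- build_ibs_kernel(G)  # internal check errors if not PSD
      expect_equal(k$K, t(k$K))
      expect_true(all(k$K >= -1e-12 & k$K <= 1 + 1e-12))
      lam <- eigen(k$K, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(lam), -1e-8)
    }
  })
})

test_that("Q is the residual quadratic form and is invariant and nonnegative", {
  y <- c(1, 0, 0, 1, 0, 1)
  null <- fit_null(y)
  # identity kernel: Q is the residual sum of squares, by direct arithmetic
  K <- diag(6)
  expect_equal(q_statistic(K, null), sum((y - 0.5)^2))
  # zero residual gives exactly zero
  expect_equal(q_statistic(K, null, y = null$mu), 0)
  # joint subject permutation leaves Q unchanged
  G <- cbind(c(0, 1, 2, 0, 1, 2), c(2, 2, 0, 1, 0, 1))
  k <- build_ibs_kernel(G)
  Q1 <- q_statistic(k, null)
  perm <- c(3, 1, 6, 2, 5, 4)
  nullp <- fit_null(y[perm])
  Qp <- q_statistic(k$K[perm, perm], nullp)
  expect_equal(Qp, Q1)
  # PSD kernel keeps Q nonnegative for arbitrary outcomes
  withr::with_seed(8, {
    for (i in 1:20) {
      yy <- rbinom(30, 1, 0.5)
      if (length(unique(yy)) < 2) next
      GG <- matrix(rbinom(90, 2, 0.3), 30, 3)
      expect_gte(q_statistic(build_ibs_kernel(GG), fit_null(yy)), 0)
    }
  })
})

test_that("moment p is 1 at Q = 0 and decreases in Q", {
  withr::with_seed(21, {
    y <- rbinom(40, 1, 0.4)
    null <- fit_null(y)
    k <- build_ibs_kernel(matrix(rbinom(120, 2, 0.3), 40, 3))
    mm0 <- moment_matched_p(0, k, null)
    expect_equal(mm0$p, 1)
    qs <- seq(0.5, 20, length.out = 20)
    ps <- vapply(qs, function(q) moment_matched_p(q, k, null)$p, 0)
    expect_true(all(diff(ps) < 0))
  })
})

test_that("moment formulas match the parametric null distribution of Q", {
  withr::with_seed(33, {
    n <- 100
    y <- rbinom(n, 1, 0.35)
    null <- fit_null(y)
    k <- build_ibs_kernel(matrix(rbinom(n * 4, 2, 0.3), n, 4))
    e_theory <- sum(diag(null$P0 %*% k$K))
    v_theory <- 2 * sum((null$P0 %*% k$K) * t(null$P0 %*% k$K))
    B <- 4000
    Qb <- numeric(B)
    for (b in seq_len(B)) {
      yb <- rbinom(n, 1, null$mu)
      if (length(unique(yb)) < 2) { Qb[b] <- NA; next }
      Qb[b] <- q_statistic(k, fit_null(yb))
    }
    Qb <- Qb[!is.na(Qb)]
    expect_lt(abs(mean(Qb) - e_theory) / e_theory, 0.08)
    expect_lt(abs(var(Qb) - v_theory) / v_theory, 0.25)
  })
})

test_that("rank-1 linear kernel reproduces the covariate-adjusted score test", {
  withr::with_seed(44, {
    n <- 120
    cov <- random_covariates(n)
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.8 + 0.3 * (cov$race == "white")))
    null <- fit_null(y, cov)
    K <- tcrossprod(g)
    Q <- q_statistic(K, null)
    S <- sum(g * (y - null$mu))
    expect_equal(Q, S^2, tolerance = 1e-10)
    mm <- moment_matched_p(Q, K, null)
    v <- drop(crossprod(g, null$P0 %*% g))
    expect_equal(mm$nu, 1, tolerance = 1e-10)
    expect_equal(mm$p, pchisq(S^2 / v, df = 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  })
})

test_that("the moment-matched p is invariant to positive kernel rescaling", {
  withr::with_seed(55, {
    y <- rbinom(60, 1, 0.4)
    null <- fit_null(y)
    k <- build_ibs_kernel(matrix(rbinom(300, 2, 0.25), 60, 5))
    Q <- q_statistic(k, null)
    p1 <- moment_matched_p(Q, k, null)$p
    c <- 7.3
    p2 <- moment_matched_p(c * Q, c * k$K, null)$p
    expect_equal(p2, p1, tolerance = 1e-12)
  })
})

test_that("exact mixture mode agrees closely with the moment approximation", {
  withr::with_seed(60, {
    n <- 150
    y <- rbinom(n, 1, 0.4)
    null <- fit_null(y)
    k <- build_ibs_kernel(matrix(rbinom(n * 5, 2, 0.3), n, 5))
    Q <- q_statistic(k, null)
    mm <- moment_matched_p(Q, k, null)$p
    ex <- moment_matched_p(Q, k, null, method = "exact")$p
    expect_lt(abs(mm - ex), 0.03)
    # the mixture tail is exact for a single chi-square: check against pchisq
    lam <- 2.5
    expect_equal(mutsigscan:::imhof_tail(5, lam),
                 pchisq(5 / lam, 1, lower.tail = FALSE), tolerance = 1e-3)
  })
})

test_that("permutation p obeys the add-one bound and is seed-deterministic", {
  withr::with_seed(70, {
    y <- rbinom(30, 1, 0.5)
    null <- fit_null(y)
    k <- build_ibs_kernel(matrix(rbinom(90, 2, 0.4), 30, 3))
    p1 <- permutation_p(k, null, n_perm = 2000, seed = 5)
    p2 <- permutation_p(k, null, n_perm = 2000, seed = 5)
    expect_identical(as.numeric(p1), as.numeric(p2))
    expect_gte(as.numeric(p1), 1 / 2001)
    expect_error(permutation_p(k, null, n_perm = 10), "at least 1000")
  })
})

test_that("permutation p is approximately uniform under the null", {
  ps <- numeric(0)
  for (s in 1:300) {
    ps <- c(ps, withr::with_seed(s, {
      n <- 50
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) return(NA_real_)
      null <- fit_null(y)
      G <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
      as.numeric(permutation_p(build_ibs_kernel(G, check = FALSE), null,
                               n_perm = 2000, seed = s))
    }))
  }
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("moment and permutation p-values agree in rank across toys", {
  mm <- pp <- numeric(0)
  for (s in 1:100) {
    r <- withr::with_seed(1000 + s, {
      n <- 50
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) return(NULL)
      null <- fit_null(y)
      k <- build_ibs_kernel(matrix(rbinom(n * 4, 2, 0.3), n, 4),
                            check = FALSE)
      Q <- q_statistic(k, null)
      c(moment_matched_p(Q, k, null)$p,
        as.numeric(permutation_p(k, null, n_perm = 2000, seed = s)))
    })
    if (!is.null(r)) { mm <- c(mm, r[1]); pp <- c(pp, r[2]) }
  }
  expect_gt(cor(mm, pp, method = "spearman"), 0.95)
})

test_that("gene scan ranks a gene holding a planted causal variant first", {
  hits <- 0L
  n_seeds <- 3L
  for (s in seq_len(n_seeds)) {
    spec <- tiny_spec(seed = 500 + s, n = 800L,
                      genes = c(A = 3L, B = 3L, C = 3L, D = 3L,
                                E = 3L, F = 3L),
                      maf = 0.3, rho = 0.3,
                      effects = data.frame(variant = "C_v2",
                                           category = "kit_ex11_del557_558",
                                           log_or = log(2.5)))
    co <- simulate_cohort(spec)
    oc <- build_outcome_matrix(co$mutations)
    res <- gene_scan(co$panel, oc, co$covariates)
    tgt <- res[res$outcome == "kit_ex11_del557_558", ]
    if (tgt$gene[which.min(tgt$p)] == "C") hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("gene scan emits one row per gene and outcome, failures isolated", {
  co <- simulate_cohort(tiny_spec(seed = 61L, n = 250L,
                                  genes = c(A = 2L, B = 3L)))
  oc <- build_outcome_matrix(co$mutations)
  res <- gene_scan(co$panel, oc, co$covariates)
  expect_identical(nrow(res), 14L)
  expect_identical(res$n_variants, rep(c(2L, 3L), each = 7L))
  expect_true(all(res$Q[res$status == "ok"] >= 0))
})
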