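# Synthetic cohort generator.
#
# Genotypes are drawn per race stratum under Hardy-Weinberg equilibrium at
# the stratum allele frequency; within-gene LD is induced by a latent
# Gaussian copula with AR(1) correlation rho between adjacent variants,
# thresholded at the HWE genotype-class quantiles so the marginal genotype
# distribution is exactly HWE.  Somatic outcomes follow a multinomial-logit
# model: baseline log-odds from the category probabilities plus planted
# per-allele contributions for causal variants.

assign_strata <- function(spec) {
  with_seed(sub_seed(spec$seed, 1L),
            sample(spec$strata$label, spec$n_subjects, replace = TRUE,
                   prob = spec$strata$proportion))
}

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

ar1_chol <- function(p, rho) {
  if (p == 1L) return(matrix(1, 1, 1))
  chol(rho ^ abs(outer(seq_len(p), seq_len(p), "-")))
}

#' Simulate a stratified genotype panel
#'
#' Draws the samples x variants dosage matrix described by a
#' [cohort_spec()]: per stratum, each SNP is in Hardy-Weinberg proportions
#' at its stratum allele frequency; binary pseudo-variants are Bernoulli at
#' their null-genotype frequency; within-gene LD comes from a latent
#' Gaussian AR(1) copula; missing calls are set completely at random at the
#' spec's rate.  Fully reproducible from the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A [genotype_panel()] with the stratum assignment attached as
#'   attribute `"stratum"`.
#' @export
simulate_genotypes <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  stratum <- assign_strata(spec)
  vdf <- spec$variants
  V <- nrow(vdf)
  dosage <- matrix(NA_integer_, n, V,
                   dimnames = list(subject_ids(n), vdf$variant))
  with_seed(sub_seed(spec$seed, 2L), {
    for (g in unique(vdf$gene)) {
      cols <- which(vdf$gene == g)
      p <- length(cols)
      R <- ar1_chol(p, spec$ld_rho[[g]])
      for (s in seq_len(nrow(spec$strata))) {
        rows <- which(stratum == spec$strata$label[s])
        if (!length(rows)) next
        z <- matrix(rnorm(length(rows) * p), length(rows), p) %*% R
        for (j in seq_len(p)) {
          f <- spec$maf[cols[j], s]
          if (vdf$is_binary[cols[j]]) {
            dosage[rows, cols[j]] <- as.integer(z[, j] > qnorm(1 - f))
          } else {
            q1 <- qnorm((1 - f)^2)
            q2 <- qnorm((1 - f)^2 + 2 * f * (1 - f))
            dosage[rows, cols[j]] <-
              as.integer(z[, j] > q1) + as.integer(z[, j] > q2)
          }
        }
      }
    }
  })
  if (spec$missing_rate > 0) {
    with_seed(sub_seed(spec$seed, 3L), {
      dosage[runif(length(dosage)) < spec$missing_rate] <- NA_integer_
    })
  }
  alleles <- with_seed(sub_seed(spec$seed, 4L), {
    t(replicate(V, sample(c("A", "C", "G", "T"), 2L)))
  })
  variants <- data.frame(
    variant = vdf$variant, gene = vdf$gene,
    ref = alleles[, 1], alt = alleles[, 2],
    is_binary = vdf$is_binary %||% FALSE,
    cluster_pass = TRUE,
    class = ifelse(vdf$is_binary, "gene_deletion", "snp"))
  out <- genotype_panel(dosage, variants)
  attr(out, "stratum") <- stratum
  out
}

#' Simulate subject covariates
#'
#' Age is drawn from a normal distribution truncated to the spec bounds
#' (inverse-CDF method), sex is Bernoulli, race is the same stratum
#' assignment used by [simulate_genotypes()] (shared sub-seed), and tumor
#' site is multinomial and independent of genotype.
#'
#' @param spec A [cohort_spec()].
#' @return A covariate data frame with columns `subject`, `age`, `sex`,
#'   `race`, `site`.
#' @export
simulate_covariates <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  race <- assign_strata(spec)
  age <- with_seed(sub_seed(spec$seed, 5L), {
    lo <- pnorm(spec$age$min, spec$age$mean, spec$age$sd)
    hi <- pnorm(spec$age$max, spec$age$mean, spec$age$sd)
    round(qnorm(runif(n, lo, hi), spec$age$mean, spec$age$sd))
  })
  sex <- with_seed(sub_seed(spec$seed, 6L),
    ifelse(runif(n) < spec$sex_prop_male, "male", "female"))
  site_levels <- c(stomach = "stomach", small_intestine = "small_intestine",
                   rectum = "rectum", other = "other")
  site <- with_seed(sub_seed(spec$seed, 7L),
    sample(site_levels[names(spec$site_probs)], n, replace = TRUE,
           prob = spec$site_probs))
  data.frame(subject = subject_ids(n), age = age, sex = sex,
             race = race, site = unname(site))
}

# Emit a somatic mutation record consistent with a signature category.
# Spans are 1-based inclusive codon coordinates.  `u` is a vector of
# uniforms, one per subject, driving within-category detail choices.
category_record <- function(category, u) {
  n <- length(u)
  rec <- data.frame(gene = rep("none", n), exon = NA_integer_,
                    type = NA_character_,
                    codon_start = NA_integer_, codon_end = NA_integer_)
  if (category == "kit_ex11_del557_558") {
    rec$gene <- "KIT"; rec$exon <- 11L; rec$type <- "deletion"
    wide <- u < 0.2  # some deletions extend beyond the 557-558 core
    rec$codon_start <- ifelse(wide, 556L, 557L)
    rec$codon_end <- ifelse(wide, 560L, 558L)
  } else if (category == "kit_ex11_del_other") {
    rec$gene <- "KIT"; rec$exon <- 11L; rec$type <- "deletion"
    start <- ifelse(u < 0.5, 559L + as.integer(u * 20),
                    550L + as.integer(u * 12))
    rec$codon_start <- start
    rec$codon_end <- start + ifelse(u < 0.8, 2L, 0L)
    # spans covering both 557 and 558 belong to the first category
    hit <- rec$codon_start <= 557L & rec$codon_end >= 558L
    rec$codon_end[hit] <- 557L
  } else if (category == "kit_ex11_ins") {
    rec$gene <- "KIT"; rec$exon <- 11L; rec$type <- "insertion"
    rec$codon_start <- 570L + as.integer(u * 9)
    rec$codon_end <- rec$codon_start + 1L
  } else if (category == "kit_ex11_point") {
    rec$gene <- "KIT"; rec$exon <- 11L; rec$type <- "point"
    rec$codon_start <- 550L + as.integer(u * 30)
    rec$codon_end <- rec$codon_start
  } else if (category == "kit_other_exon") {
    rec$gene <- "KIT"
    exon <- ifelse(u < 15 / 19, 9L, ifelse(u < 18 / 19, 13L, 14L))
    rec$exon <- exon
    rec$type <- ifelse(exon == 9L, "insertion", "point")
    rec$codon_start <- ifelse(exon == 9L, 502L,
                              ifelse(exon == 13L, 642L, 670L))
    rec$codon_end <- ifelse(exon == 9L, 503L, rec$codon_start)
  } else if (category == "pdgfra") {
    rec$gene <- "PDGFRA"
    ex18 <- u < 0.75
    rec$exon <- ifelse(ex18, 18L, 12L)
    pt <- (u * 7) %% 1 < 0.6
    rec$type <- ifelse(pt, "point", "deletion")
    rec$codon_start <- ifelse(ex18, 842L, 561L)
    rec$codon_end <- ifelse(pt, rec$codon_start, rec$codon_start + 3L)
  }
  rec
}

#' Simulate somatic mutation outcomes
#'
#' Assigns each subject exactly one of the seven signature categories by a
#' multinomial-logit model (baseline log-odds from the spec's category
#' probabilities plus dosage x log-odds for each planted effect), then
#' emits a somatic mutation record consistent with the category, at the
#' level the classifier consumes (gene / exon / type / codon span).
#' Missing dosages contribute the variant's observed mean dosage.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param covariates Covariate table for the same subjects.
#' @param spec The generating [cohort_spec()].
#' @return A mutation table (one row per subject) with attribute
#'   `"category"`: the true category labels.
#' @export
simulate_outcomes <- function(panel, covariates, spec) {
  validate_cohort_spec(spec)
  n <- nrow(panel$dosage)
  if (n != nrow(covariates))
    stopf("panel and covariates disagree on subject count")
  cats <- mutation_categories()
  eta <- matrix(log(spec$baseline_probs[cats]), n, 7L, byrow = TRUE,
                dimnames = list(NULL, cats))
  if (nrow(spec$effects)) {
    for (k in seq_len(nrow(spec$effects))) {
      v <- spec$effects$variant[k]
      if (!v %in% colnames(panel$dosage))
        stopf("planted effect references unknown variant: %s", v)
      g <- panel$dosage[, v]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      eta[, spec$effects$category[k]] <-
        eta[, spec$effects$category[k]] + spec$effects$log_or[k] * g
    }
  }
  prob <- softmax_rows(eta)
  cum <- t(apply(prob, 1L, cumsum))
  with_seed(sub_seed(spec$seed, 8L), {
    u <- runif(n)
    category <- cats[rowSums(u > cum) + 1L]
    detail <- runif(n)
  })
  rec <- data.frame(subject = panel$subjects, gene = "none",
                    exon = NA_integer_, type = NA_character_,
                    codon_start = NA_integer_, codon_end = NA_integer_)
  for (cat in cats) {
    rows <- which(category == cat)
    if (length(rows))
      rec[rows, -1L] <- category_record(cat, detail[rows])
  }
  attr(rec, "category") <- category
  rec
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_covariates()] and
#' [simulate_outcomes()] under one spec and bundles the results with a
#' truth record of the planted effects.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `panel`,
#'   `covariates`, `mutations`, `truth` (planted effects and causal
#'   variant ids) and the generating `spec`.
#' @export
simulate_cohort <- function(spec) {
  panel <- simulate_genotypes(spec)
  covariates <- simulate_covariates(spec)
  mutations <- simulate_outcomes(panel, covariates, spec)
  structure(
    list(panel = panel, covariates = covariates, mutations = mutations,
         truth = list(effects = spec$effects,
                      causal_variants = unique(spec$effects$variant)),
         spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d variants, seed %d\n",
              nrow(x$panel$dosage), ncol(x$panel$dosage), x$spec$seed))
  print(table(attr(x$mutations, "category")))
  invisible(x)
}
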