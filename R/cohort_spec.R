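#' Specify a synthetic cohort
#'
#' A `cohort_spec` fully parameterizes the synthetic cohort generator:
#' race strata with per-stratum coded-allele frequencies, within-gene
#' linkage disequilibrium (LD), the covariate model, the multinomial
#' somatic-outcome model with optional planted per-allele effects, the
#' per-call missingness rate, and a single integer seed from which all
#' randomness flows.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param strata Data frame with columns `label` and `proportion`
#'   (proportions must sum to 1).  The first stratum is taken as the
#'   "white" reference level downstream.
#' @param variants Data frame with columns `variant`, `gene` and optionally
#'   `is_binary` (binary pseudo-variants such as gene-deletion assays,
#'   dosage 0/1).
#' @param maf Numeric matrix, variants x strata, of per-stratum coded-allele
#'   frequencies in (0, 1); rows follow `variants`, columns follow `strata`.
#' @param ld_rho Named numeric vector, one entry per gene, giving the AR(1)
#'   latent correlation between adjacent variants of that gene; each in
#'   \[0, 1).
#' @param age List with `mean`, `sd`, `min`, `max` (years); ages are drawn
#'   from a normal truncated to \[`min`, `max`\].
#' @param sex_prop_male Probability a subject is male.
#' @param site_probs Named probabilities over tumor sites
#'   (`stomach`, `small_intestine`, `rectum`, `other`); must sum to 1.
#' @param baseline_probs Named probabilities over the seven
#'   [mutation_categories()]; must sum to 1.
#' @param effects Data frame of planted per-allele effects with columns
#'   `variant`, `category`, `log_or`; may have zero rows.
#' @param missing_rate Per-call genotype missingness probability.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects, strata, variants, maf, ld_rho,
                        age = list(mean = 57, sd = 13, min = 18, max = 85),
                        sex_prop_male = 0.51,
                        site_probs = c(stomach = 0.66, small_intestine = 0.31,
                                       rectum = 0.01, other = 0.02),
                        baseline_probs = NULL,
                        effects = data.frame(variant = character(),
                                             category = character(),
                                             log_or = numeric()),
                        missing_rate = 0, seed = 1L) {
  if (is.null(baseline_probs)) {
    # default category mix of the reference trial cohort
    baseline_probs <- setNames(
      c(66, 45, 28, 56, 19, 29, 36) / 279, mutation_categories())
  }
  spec <- structure(
    list(n_subjects = as.integer(n_subjects), strata = strata,
         variants = variants, maf = as.matrix(maf), ld_rho = ld_rho,
         age = age, sex_prop_male = sex_prop_male,
         site_probs = site_probs, baseline_probs = baseline_probs,
         effects = effects, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants of a [cohort_spec()]; called by the
#' constructor and by every simulator entry point.
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("not a cohort_spec")
  if (spec$n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (abs(sum(spec$strata$proportion) - 1) > 1e-8)
    stopf("stratum proportions must sum to 1")
  if (abs(sum(spec$baseline_probs) - 1) > 1e-8)
    stopf("baseline category probabilities must sum to 1")
  if (!identical(sort(names(spec$baseline_probs)),
                 sort(mutation_categories())))
    stopf("baseline_probs must be named by the seven mutation categories")
  if (nrow(spec$maf) != nrow(spec$variants) ||
      ncol(spec$maf) != nrow(spec$strata))
    stopf("maf must be variants x strata")
  if (any(spec$maf <= 0 | spec$maf >= 1))
    stopf("allele frequencies must lie strictly in (0, 1)")
  genes <- unique(spec$variants$gene)
  if (!all(genes %in% names(spec$ld_rho)))
    stopf("ld_rho must name every gene")
  if (any(spec$ld_rho < 0 | spec$ld_rho >= 1))
    stopf("LD parameter rho must lie in [0, 1)")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stopf("missing_rate must lie in [0, 1)")
  if (nrow(spec$effects)) {
    bad <- setdiff(spec$effects$variant, spec$variants$variant)
    if (length(bad))
      stopf("planted effect references unknown variant(s): %s",
            paste(bad, collapse = ", "))
    badc <- setdiff(spec$effects$category, mutation_categories())
    if (length(badc))
      stopf("planted effect references unknown category: %s",
            paste(badc, collapse = ", "))
  }
  if (abs(sum(spec$site_probs) - 1) > 1e-8)
    stopf("site probabilities must sum to 1")
  with(spec$age, if (min >= max || sd <= 0) stopf("invalid age model"))
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d subjects, %d variants in %d genes, %d strata, seed %d\n",
    x$n_subjects, nrow(x$variants), length(unique(x$variants$gene)),
    nrow(x$strata), x$seed))
  if (nrow(x$effects))
    cat(sprintf("  planted effects: %d\n", nrow(x$effects)))
  invisible(x)
}

# 39 candidate genes of the dioxin-response / xenobiotic-metabolism / DNA
# repair panel; sizes chosen to total 225 variants (223 SNPs plus the two
# binary gene-deletion pseudo-variants in GSTM1 and GSTT1).
panel_genes <- function() {
  genes <- c("AHR", "MDM2", "ERCC5", "CYP1A2", "CYP1B1", "HIF1A", "NQO1",
             "G6PC", "ADH1A", "ADH1B", "ADH1C", "ALDH18A1", "ALDH1A1",
             "ALDH1A2", "ALDH1A3", "ALDH1B1", "ALDH1L1", "ALDH1L2",
             "ALDH2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2D6", "CYP2E1",
             "CYP3A4", "GSTM1", "GSTT1", "GSTP1", "HNF4A", "NAT2",
             "NFE2L2", "NOS2A", "PTGS2", "SULT1A1", "TP53", "ERCC2",
             "RAD23B", "XPA", "XPC")
  n <- c(rep(6L, 30), rep(5L, 9))
  names(n) <- genes
  n
}

#' Default synthetic cohort specification
#'
#' Builds a `cohort_spec` that emulates the study conditions of the
#' reference GIST trial cohort: 279 subjects in two race strata
#' (white 82%, other 18%), a 39-gene candidate panel of 225 variants
#' (223 SNPs plus the GSTM1/GSTT1 deletion pseudo-variants), stratum
#' allele frequencies of at least 10% in the reference (white) stratum,
#' within-gene AR(1) LD, an age model with median near 58 truncated to
#' 18-85 years, and the seven-category somatic outcome mix
#' (66, 45, 28, 56, 19, 29, 36)/279.
#'
#' @param seed Integer master seed.
#' @param n_subjects Number of subjects (default 279).
#' @param effects Optional planted-effect data frame (see [cohort_spec()]).
#' @param missing_rate Per-call missingness (default 0.005).
#' @param ld_rho_default AR(1) latent LD within genes (default 0.5).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L, n_subjects = 279L,
                                effects = NULL, missing_rate = 0.005,
                                ld_rho_default = 0.5) {
  sizes <- panel_genes()
  gene <- rep(names(sizes), sizes)
  idx <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  variant <- sprintf("%s_s%02d", gene, idx)
  is_binary <- rep(FALSE, length(variant))
  # last slot of GSTM1 and GSTT1 is the copy-deletion (null genotype) assay
  for (g in c("GSTM1", "GSTT1")) {
    slot <- which(gene == g)[sizes[[g]]]
    variant[slot] <- paste0(g, "_del")
    is_binary[slot] <- TRUE
  }
  variants <- data.frame(variant = variant, gene = gene,
                         is_binary = is_binary)
  maf <- with_seed(sub_seed(seed, 101L), {
    white <- runif(length(variant), 0.10, 0.50)
    other <- pmin(pmax(white + rnorm(length(variant), 0, 0.08), 0.02), 0.6)
    cbind(white = white, other = other)
  })
  # null-genotype frequencies for the deletion assays sit near 0.5 / 0.2
  maf[is_binary, ] <- c(0.50, 0.20)[match(gene[is_binary],
                                          c("GSTM1", "GSTT1"))]
  cohort_spec(
    n_subjects = n_subjects,
    strata = data.frame(label = c("white", "other"),
                        proportion = c(0.82, 0.18)),
    variants = variants, maf = maf,
    ld_rho = setNames(rep(ld_rho_default, length(sizes)), names(sizes)),
    effects = effects %||% data.frame(variant = character(),
                                      category = character(),
                                      log_or = numeric()),
    missing_rate = missing_rate, seed = seed)
}
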