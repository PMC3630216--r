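# Small builders shared across test files.

# Minimal spec: `genes` is a named integer vector of variant counts.
tiny_spec <- function(seed = 1L, n = 200L, genes = c(GENE1 = 2L),
                      maf = 0.3, rho = 0, missing_rate = 0,
                      effects = NULL, strata_props = c(0.82, 0.18)) {
  gene <- rep(names(genes), genes)
  variant <- sprintf("%s_v%d", gene, unlist(lapply(genes, seq_len)))
  nv <- length(variant)
  maf <- if (length(maf) == 1L) rep(maf, nv) else maf
  cohort_spec(
    n_subjects = n,
    strata = data.frame(label = c("white", "other"),
                        proportion = strata_props),
    variants = data.frame(variant = variant, gene = gene,
                          is_binary = FALSE),
    maf = cbind(white = maf, other = maf),
    ld_rho = setNames(rep(rho, length(genes)), names(genes)),
    effects = effects %||% data.frame(variant = character(),
                                      category = character(),
                                      log_or = numeric()),
    missing_rate = missing_rate, seed = seed)
}

# A panel built directly from a dosage matrix (one gene, arbitrary alleles).
panel_from_dosage <- function(d, ref = NULL, alt = NULL, gene = "G1",
                              is_binary = FALSE, cluster_pass = TRUE) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("v%d", seq_len(ncol(d)))
  nv <- ncol(d)
  genotype_panel(d, data.frame(
    variant = colnames(d), gene = rep_len(gene, nv),
    ref = ref %||% rep("A", nv), alt = alt %||% rep("C", nv),
    is_binary = rep_len(is_binary, nv),
    cluster_pass = rep_len(cluster_pass, nv)))
}

random_covariates <- function(n, seed = 1L) {
  withr::with_seed(seed, data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    age = round(runif(n, 20, 80)),
    sex = sample(c("male", "female"), n, TRUE),
    race = sample(c("white", "other"), n, TRUE, prob = c(0.82, 0.18)),
    site = sample(c("stomach", "small_intestine", "rectum", "other"),
                  n, TRUE, prob = c(0.66, 0.31, 0.01, 0.02))))
}

# Outcome set built directly from a category assignment.
outcomes_from_categories <- function(subjects, category) {
  cats <- mutation_categories()
  ind <- matrix(0L, length(subjects), 7L,
                dimnames = list(subjects, cats))
  ind[cbind(seq_along(subjects), match(category, cats))] <- 1L
  structure(list(subject = subjects,
                 category = factor(category, levels = cats),
                 indicator = ind),
            class = "outcome_set")
}
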