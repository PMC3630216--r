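# Engineered QC fixture.
#
# A deterministic cohort built to exercise the full filter cascade with
# known counts: 333 subjects of whom 52 lack a somatic mutation record and
# 2 exceed 10% genotype missingness (279 analyzable), and a 225-variant
# panel containing exactly 3 mono-allelic variants, 6 with MAF below 5%,
# 7 flagged for poor array clustering and 1 violating the minor-allele
# homozygote rule (208 retained).  The analyzable subjects carry the
# seven-category somatic outcome mix (66, 45, 28, 56, 19, 29, 36).

#' Engineered QC reference cohort
#'
#' @param seed Integer seed for the stochastic filling of the fixture;
#'   the engineered QC structure itself (which variants fail which rule,
#'   the category counts) is identical for every seed.
#' @return List with `panel` (333 x 225 [genotype_panel()]), `covariates`
#'   (333 rows), `mutations` (281 rows; 52 subjects absent) and
#'   `category` (named category assignment of the 279 analyzable
#'   subjects).
#' @export
qc_reference_cohort <- function(seed = 1L) {
  sizes <- panel_genes()
  gene <- rep(names(sizes), sizes)
  idx <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  variant <- sprintf("%s_s%02d", gene, idx)
  is_binary <- rep(FALSE, length(variant))
  for (g in c("GSTM1", "GSTT1")) {
    slot <- which(gene == g)[sizes[[g]]]
    variant[slot] <- paste0(g, "_del")
    is_binary[slot] <- TRUE
  }
  nv <- length(variant)
  n <- 333L
  ids <- subject_ids(n)
  analysis <- ids[1:279]
  high_missing <- ids[280:281]
  no_mutation <- ids[282:333]

  # first slot of genes 1..17 carries the engineered exclusions
  first_slot <- vapply(names(sizes), function(g) which(gene == g)[1], 0L)
  mono_idx <- first_slot[1:3]
  lowmaf_idx <- first_slot[4:9]
  cluster_idx <- first_slot[10:16]
  homrule_idx <- first_slot[17]

  counts <- c(66L, 45L, 28L, 56L, 19L, 29L, 36L)
  cats <- mutation_categories()
  category <- with_seed(sub_seed(seed, 11L),
                        sample(rep(cats, counts)))
  names(category) <- analysis

  dosage <- with_seed(sub_seed(seed, 12L), {
    f <- runif(nv, 0.15, 0.35)
    f[is_binary] <- 0.35
    d <- vapply(seq_len(nv), function(j)
      rbinom(n, size = if (is_binary[j]) 1L else 2L, prob = f[j]),
      integer(n))
    dimnames(d) <- list(ids, variant)
    d
  })
  # sparse random missingness plus two heavily missing subjects
  dosage <- with_seed(sub_seed(seed, 13L), {
    d <- dosage
    d[matrix(runif(length(d)) < 0.005, n, nv)] <- NA_integer_
    for (s in high_missing)
      d[s, sample(nv, ceiling(0.15 * nv))] <- NA_integer_
    d
  })
  dosage[, mono_idx] <- 0L
  for (j in lowmaf_idx) {
    dosage[, j] <- 0L
    dosage[analysis[1:8], j] <- 1L  # 8 hets: MAF 8/558 < 0.05, not mono
  }
  # every retained variant gets a minor-allele homozygote in each category
  retained <- setdiff(seq_len(nv),
                      c(mono_idx, lowmaf_idx, cluster_idx))
  for (j in retained) {
    top <- hom_dosage(is_binary[j])
    for (k in seq_along(cats)) {
      if (j == homrule_idx && cats[k] == "kit_other_exon") next
      members <- analysis[category[analysis] == cats[k]]
      pick <- members[(j %% length(members)) + 1L]
      dosage[pick, j] <- top
    }
  }
  # the homozygote-rule violator: no minor homozygote among category-v cases
  vcases <- analysis[category[analysis] == "kit_other_exon"]
  dosage[vcases, homrule_idx] <- pmin(dosage[vcases, homrule_idx], 1L,
                                      na.rm = FALSE)

  alleles <- with_seed(sub_seed(seed, 14L),
                       t(replicate(nv, sample(c("A", "C", "G", "T"), 2L))))
  variants <- data.frame(
    variant = variant, gene = gene, ref = alleles[, 1], alt = alleles[, 2],
    is_binary = is_binary,
    cluster_pass = !(seq_len(nv) %in% cluster_idx),
    class = ifelse(is_binary, "gene_deletion", "snp"))
  panel <- genotype_panel(dosage, variants)

  covariates <- with_seed(sub_seed(seed, 15L), {
    lo <- pnorm(18, 57, 13); hi <- pnorm(85, 57, 13)
    data.frame(
      subject = ids,
      age = round(qnorm(runif(n, lo, hi), 57, 13)),
      sex = ifelse(runif(n) < 0.51, "male", "female"),
      race = sample(c("white", "other"), n, TRUE, prob = c(0.82, 0.18)),
      site = sample(c("stomach", "small_intestine", "rectum", "other"),
                    n, TRUE, prob = c(0.66, 0.31, 0.01, 0.02)))
  })

  mut_subjects <- c(analysis, high_missing)
  mut_category <- c(category[analysis],
                    setNames(rep("kit_ex11_point", 2L), high_missing))
  detail <- with_seed(sub_seed(seed, 16L), runif(length(mut_subjects)))
  mutations <- data.frame(subject = mut_subjects, gene = "none",
                          exon = NA_integer_, type = NA_character_,
                          codon_start = NA_integer_,
                          codon_end = NA_integer_)
  for (cat in cats) {
    rows <- which(mut_category == cat)
    if (length(rows))
      mutations[rows, -1L] <- category_record(cat, detail[rows])
  }
  list(panel = panel, covariates = covariates, mutations = mutations,
       category = category, no_mutation_subjects = no_mutation)
}
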