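# Sample- and variant-level QC cascade.
#
# Sample rules, in order: (1) drop subjects with no somatic mutation
# record; (2) drop subjects with strictly more than `missingness_threshold`
# of genotype calls missing.  Variant rules, applied after orientation and
# in order with each exclusion attributed to the first violated rule:
# (1) mono-allelic; (2) MAF strictly below the minimum; (3) array
# clustering failure (carried as a boolean flag -- an intensity-level
# property that cannot be recomputed from dosages); (4) no minor-allele
# homozygote on one side of at least one outcome dichotomy.

#' Exclude samples failing QC
#'
#' @param panel A [genotype_panel()].
#' @param mutations Mutation table; subjects absent from it are treated as
#'   missing mutation data (an explicit wild-type row is *not* missing).
#' @param missingness_threshold Maximum tolerated fraction of missing
#'   genotype calls; exclusion requires strictly more than this.
#' @return List with the filtered `panel` and a `report` data frame of
#'   counts per rule.
#' @export
exclude_samples <- function(panel, mutations, missingness_threshold = 0.10) {
  if (missingness_threshold <= 0 || missingness_threshold > 1)
    stopf("missingness_threshold must lie in (0, 1]")
  n0 <- length(panel$subjects)
  has_mut <- panel$subjects %in% mutations$subject
  p1 <- subset_panel(panel, subjects = panel$subjects[has_mut])
  miss_frac <- rowMeans(is.na(p1$dosage))
  keep <- miss_frac <= missingness_threshold
  p2 <- subset_panel(p1, subjects = p1$subjects[keep])
  report <- data.frame(
    stage = "sample",
    rule = c("input", "missing_mutation_data", "genotype_missingness",
             "retained"),
    n = c(n0, sum(!has_mut), sum(!keep), length(p2$subjects)))
  list(panel = p2, report = report)
}

# Coded-allele frequency over non-missing calls; for binary pseudo-variants
# the "allele frequency" is the null-genotype carrier frequency.
coded_freq <- function(d, binary) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  if (binary) mean(d) else sum(d) / (2 * length(d))
}

#' Compute MAFs and fix the minor-allele orientation
#'
#' Computes each variant's coded-allele frequency over the non-missing
#' calls of the current cohort and flips the dosage coding (d -> 2 - d, or
#' 1 - d for binary pseudo-variants) wherever the coded allele is the more
#' frequent one, so that after orientation every MAF is at most 0.5.  An
#' exact tie at 0.5 is broken lexicographically: the alphabetically first
#' allele is kept as minor.  Variants with all calls missing are flagged
#' and left unoriented.
#'
#' @param panel A [genotype_panel()].
#' @return The panel with dosages re-oriented and the `orientation` table
#'   (columns `variant`, `minor_allele`, `flipped`, `maf`, `all_missing`)
#'   filled in.
#' @export
compute_maf_and_orient <- function(panel) {
  v <- panel$variants
  d <- panel$dosage
  nv <- ncol(d)
  flipped <- logical(nv)
  minor <- character(nv)
  maf <- numeric(nv)
  all_missing <- logical(nv)
  prior <- panel$orientation
  for (j in seq_len(nv)) {
    f <- coded_freq(d[, j], v$is_binary[j])
    if (is.na(f)) {
      all_missing[j] <- TRUE
      minor[j] <- NA_character_
      maf[j] <- NA_real_
      next
    }
    # allele currently counted by the dosage coding (alt unless a previous
    # orientation pass flipped it)
    pre_flipped <- !is.null(prior) && isTRUE(prior$flipped[j])
    coded <- if (pre_flipped) v$ref[j] else v$alt[j]
    other <- if (pre_flipped) v$alt[j] else v$ref[j]
    flip <- if (f > 0.5) TRUE
      else if (f == 0.5) other < coded  # tie: alphabetically first allele
      else FALSE
    if (flip) {
      top <- if (v$is_binary[j]) 1L else 2L
      d[, j] <- top - d[, j]
      f <- 1 - f
    }
    flipped[j] <- xor(pre_flipped, flip)
    minor[j] <- if (flip) other else coded
    maf[j] <- f
  }
  panel$dosage <- d
  panel$orientation <- data.frame(
    variant = v$variant, minor_allele = minor, flipped = flipped,
    maf = maf, all_missing = all_missing)
  panel
}

hom_dosage <- function(binary) ifelse(binary, 1L, 2L)

#' Apply the variant QC filter cascade
#'
#' @param panel An oriented [genotype_panel()] (see
#'   [compute_maf_and_orient()]).
#' @param outcomes An `outcome_set` for the panel's subjects, used by the
#'   homozygote rule.
#' @param maf_min Minimum MAF; exclusion is strict (`maf < maf_min`).
#' @param homozygote_rule `"any_level"` (default) excludes a variant when,
#'   for at least one of the seven dichotomies, either the case or the
#'   referent side contains zero minor-allele homozygotes; `"none"`
#'   disables the rule.  This operationalization is a documented
#'   convention and is recorded in the report.
#' @return List with the filtered `panel`, a `report` count table, and
#'   `attribution`: per excluded variant, the first rule it violated.
#' @export
apply_variant_filters <- function(panel, outcomes, maf_min = 0.05,
                                  homozygote_rule = c("any_level", "none")) {
  homozygote_rule <- match.arg(homozygote_rule)
  if (is.null(panel$orientation))
    stopf("panel must be oriented before variant filtering")
  v <- panel$variants
  maf <- panel$orientation$maf
  nv <- ncol(panel$dosage)
  rule <- rep(NA_character_, nv)
  ind <- NULL
  if (homozygote_rule == "any_level") {
    if (is.null(outcomes)) stopf("homozygote rule requires outcomes")
    ind <- outcomes$indicator[match(panel$subjects,
                                    rownames(outcomes$indicator)), ,
                              drop = FALSE]
    if (anyNA(ind)) stopf("outcomes missing for some panel subjects")
  }
  for (j in seq_len(nv)) {
    if (is.na(maf[j]) || maf[j] == 0) { rule[j] <- "mono_allelic"; next }
    if (maf[j] < maf_min) { rule[j] <- "low_maf"; next }
    if (!v$cluster_pass[j]) { rule[j] <- "poor_clustering"; next }
    if (homozygote_rule == "any_level") {
      hom <- panel$dosage[, j] == hom_dosage(v$is_binary[j])
      hom[is.na(hom)] <- FALSE
      bad <- FALSE
      for (k in seq_len(ncol(ind))) {
        cases <- ind[, k] == 1L
        if (!any(hom[cases]) || !any(hom[!cases])) { bad <- TRUE; break }
      }
      if (bad) rule[j] <- "no_minor_homozygote_at_outcome_level"
    }
  }
  keep <- is.na(rule)
  rules <- c("mono_allelic", "low_maf", "poor_clustering",
             "no_minor_homozygote_at_outcome_level")
  report <- data.frame(
    stage = "variant",
    rule = c("input", rules, "retained"),
    n = c(nv, vapply(rules, function(r) sum(rule == r, na.rm = TRUE), 0L),
          sum(keep)))
  attribution <- data.frame(variant = v$variant[!keep],
                            rule = rule[!keep])
  list(panel = subset_panel(panel, variants = v$variant[keep]),
       report = report, attribution = attribution)
}

#' Concordance between duplicate genotyping runs
#'
#' @param panel A [genotype_panel()].
#' @param pairs Data frame with columns `id1`, `id2` naming duplicate
#'   subject pairs.
#' @return Data frame per pair (`id1`, `id2`, `n_compared`, `concordance`;
#'   `NA` with zero jointly non-missing calls) with the pooled concordance
#'   as attribute `"pooled"`.
#' @export
duplicate_concordance <- function(panel, pairs) {
  bad <- setdiff(c(pairs$id1, pairs$id2), panel$subjects)
  if (length(bad))
    stopf("duplicate pair references unknown subject(s): %s",
          paste(bad, collapse = ", "))
  res <- data.frame(pairs, n_compared = 0L, concordance = NA_real_)
  tot_n <- 0L; tot_match <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- panel$dosage[pairs$id1[i], ]
    b <- panel$dosage[pairs$id2[i], ]
    ok <- !is.na(a) & !is.na(b)
    res$n_compared[i] <- sum(ok)
    if (any(ok)) {
      m <- sum(a[ok] == b[ok])
      res$concordance[i] <- m / sum(ok)
      tot_n <- tot_n + sum(ok); tot_match <- tot_match + m
    }
  }
  attr(res, "pooled") <- if (tot_n) tot_match / tot_n else NA_real_
  res
}

# Pearson chi-square with Fisher's exact fallback when any observed cell
# is below 5; the dispatch is a pure function of the count table.
count_table_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = NA_real_, p = NA_real_, test = "degenerate"))
  if (any(tab < 5)) {
    ft <- fisher.test(tab, workspace = 2e7)
    list(statistic = NA_real_, p = ft$p.value, test = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value, test = "chisq")
  }
}

genotype_class_counts <- function(d, binary) {
  d <- d[!is.na(d)]
  if (binary) c(`0` = sum(d == 0L), `1` = sum(d == 1L))
  else c(`0` = sum(d == 0L), `1` = sum(d == 1L), `2` = sum(d == 2L))
}

#' Per-variant genotype-frequency comparison across groups
#'
#' Builds, per variant, the group x genotype-class contingency table
#' (three classes, or two for binary pseudo-variants) and tests
#' homogeneity with Pearson's chi-square, switching to Fisher's exact test
#' whenever any observed cell count is below 5.
#'
#' @param panel A [genotype_panel()].
#' @param race Character vector of race labels aligned with the panel's
#'   subjects (used when `reference` is `NULL`).
#' @param reference Optional reference-frequency table (columns `variant`,
#'   `n0`, `n1`, `n2`); when given, the panel's counts are contrasted with
#'   the reference genotype counts instead of across race strata.
#' @return Data frame: `variant`, `statistic` (`NA` for Fisher), `p`,
#'   `test` (chisq / fisher / degenerate).
#' @export
stratified_frequency_test <- function(panel, race = NULL, reference = NULL) {
  v <- panel$variants
  out <- data.frame(variant = v$variant, statistic = NA_real_,
                    p = NA_real_, test = "degenerate")
  for (j in seq_len(nrow(v))) {
    if (is.null(reference)) {
      if (is.null(race)) stopf("race labels required without a reference")
      groups <- unique(race)
      tab <- t(vapply(groups, function(g)
        genotype_class_counts(panel$dosage[race == g, j],
                              v$is_binary[j]),
        numeric(if (v$is_binary[j]) 2L else 3L)))
    } else {
      m <- match(v$variant[j], reference$variant)
      if (is.na(m)) next
      study <- genotype_class_counts(panel$dosage[, j], v$is_binary[j])
      refc <- if (v$is_binary[j])
        c(reference$n0[m], reference$n1[m] + reference$n2[m])
      else c(reference$n0[m], reference$n1[m], reference$n2[m])
      tab <- rbind(study = study, reference = refc)
    }
    r <- count_table_test(tab)
    out$statistic[j] <- r$statistic
    out$p[j] <- r$p
    out$test[j] <- r$test
  }
  out
}
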