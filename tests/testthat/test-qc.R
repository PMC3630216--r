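# QC cascade: sample exclusions, orientation, variant filters,
# duplicate concordance, stratified frequency tests.

test_that("sample exclusion applies the two rules in order, strictly", {
  fx <- qc_reference_cohort(2)
  s <- exclude_samples(fx$panel, fx$mutations)
  r <- setNames(s$report$n, s$report$rule)
  expect_identical(r[["input"]], 333L)
  expect_identical(r[["missing_mutation_data"]], 52L)
  expect_identical(r[["genotype_missingness"]], 2L)
  expect_identical(r[["retained"]], 279L)
  # counts conserve at the stage boundary
  expect_identical(r[["input"]] - r[["missing_mutation_data"]] -
                     r[["genotype_missingness"]], r[["retained"]])
})

test_that("a subject with exactly 10% missing calls is retained", {
  d <- matrix(0L, 2, 10,
              dimnames = list(c("S1", "S2"), sprintf("v%d", 1:10)))
  d[1, 1] <- NA  # exactly 10% missing
  d[2, 1:2] <- NA  # 20%: strictly more than the threshold
  d[, 10] <- c(1L, 1L)
  panel <- panel_from_dosage(d)
  mut <- data.frame(subject = c("S1", "S2"), gene = "none",
                    exon = NA, type = NA, codon_start = NA, codon_end = NA)
  out <- exclude_samples(panel, mut, missingness_threshold = 0.10)
  expect_identical(out$panel$subjects, "S1")
})

test_that("no-op exclusion is the identity", {
  co <- simulate_cohort(tiny_spec(seed = 3L, n = 30L))
  out <- exclude_samples(co$panel, co$mutations)
  expect_identical(out$panel$dosage, co$panel$dosage)
})

test_that("orientation flips the more frequent coded allele to major", {
  # coded frequency 7/8 -> flipped, MAF 1/8
  p <- compute_maf_and_orient(panel_from_dosage(cbind(c(2L, 2L, 2L, 1L))))
  expect_equal(p$orientation$maf, 1 / 8)
  expect_true(p$orientation$flipped)
  expect_identical(unname(p$dosage[, 1]), c(0L, 0L, 0L, 1L))

  # mono-allelic: MAF 0, no flip
  p0 <- compute_maf_and_orient(panel_from_dosage(cbind(rep(0L, 4))))
  expect_equal(p0$orientation$maf, 0)
})

test_that("a 0.5 tie is broken by lexicographic allele order", {
  # frequency (0+1+1+2)/8 = 0.5; coded (alt) allele is "C", ref "A":
  # the alphabetically first allele A becomes minor, so coding flips
  p <- compute_maf_and_orient(
    panel_from_dosage(cbind(c(0L, 1L, 1L, 2L)), ref = "A", alt = "C"))
  expect_true(p$orientation$flipped)
  expect_identical(p$orientation$minor_allele, "A")
  # with ref "T", the coded allele "C" is already alphabetically first
  p2 <- compute_maf_and_orient(
    panel_from_dosage(cbind(c(0L, 1L, 1L, 2L)), ref = "T", alt = "C"))
  expect_false(p2$orientation$flipped)
  expect_identical(p2$orientation$minor_allele, "C")
  # the tie-broken orientation is stable under re-orientation
  again <- compute_maf_and_orient(p)
  expect_identical(again$dosage, p$dosage)
  expect_identical(again$orientation$minor_allele, p$orientation$minor_allele)
})

test_that("orientation is idempotent", {
  co <- simulate_cohort(tiny_spec(seed = 10L, n = 80L,
                                  genes = c(A = 4L), maf = 0.45,
                                  missing_rate = 0.05))
  once <- compute_maf_and_orient(co$panel)
  twice <- compute_maf_and_orient(once)
  expect_identical(twice$dosage, once$dosage)
  expect_identical(twice$orientation$maf, once$orientation$maf)
  expect_identical(twice$orientation$flipped, once$orientation$flipped)
  expect_true(all(once$orientation$maf <= 0.5))
})

test_that("an all-missing variant is flagged, not oriented", {
  d <- cbind(a = c(NA_integer_, NA_integer_), b = c(0L, 1L))
  p <- compute_maf_and_orient(panel_from_dosage(d))
  expect_true(p$orientation$all_missing[1])
  expect_true(is.na(p$orientation$maf[1]))
})

test_that("variant filter cascade reproduces engineered counts in order", {
  fx <- qc_reference_cohort(3)
  s <- exclude_samples(fx$panel, fx$mutations)
  p <- compute_maf_and_orient(s$panel)
  oc <- outcomes_from_categories(names(fx$category), fx$category)
  vf <- apply_variant_filters(p, oc)
  r <- setNames(vf$report$n, vf$report$rule)
  expect_identical(r[["input"]], 225L)
  expect_identical(r[["mono_allelic"]], 3L)
  expect_identical(r[["low_maf"]], 6L)
  expect_identical(r[["poor_clustering"]], 7L)
  expect_identical(r[["no_minor_homozygote_at_outcome_level"]], 1L)
  expect_identical(r[["retained"]], 208L)
  expect_identical(sum(r[c("mono_allelic", "low_maf", "poor_clustering",
                           "no_minor_homozygote_at_outcome_level",
                           "retained")]), r[["input"]])
})

test_that("MAF exactly at the threshold is retained (strict rule)", {
  # 10 subjects, one hom + ... frequency exactly 0.05: 1 het in 10 subjects
  d <- cbind(v1 = c(1L, rep(0L, 9L)),   # MAF 0.05 exactly
             v2 = c(rep(1L, 5L), rep(0L, 5L)))
  panel <- compute_maf_and_orient(panel_from_dosage(d))
  expect_equal(panel$orientation$maf, c(0.05, 0.25))
  vf <- apply_variant_filters(panel, NULL, homozygote_rule = "none")
  expect_identical(colnames(vf$panel$dosage), c("v1", "v2"))
})

test_that("filters are the identity when everything passes", {
  co <- simulate_cohort(tiny_spec(seed = 20L, n = 400L,
                                  genes = c(A = 3L), maf = 0.4))
  p <- compute_maf_and_orient(co$panel)
  vf <- apply_variant_filters(p, NULL, homozygote_rule = "none")
  expect_identical(vf$panel$dosage, p$dosage)
  expect_identical(nrow(vf$attribution), 0L)
})

test_that("duplicate concordance counts jointly non-missing calls only", {
  nv <- 1000L
  d <- matrix(0L, 3, nv, dimnames = list(c("A", "B", "C"),
                                         sprintf("v%d", 1:nv)))
  d[2, 1] <- 1L           # one discordant call between A and B
  d[3, 1:10] <- NA        # missing in one member: out of the denominator
  panel <- panel_from_dosage(d)
  res <- duplicate_concordance(
    panel, data.frame(id1 = c("A", "A", "A"), id2 = c("B", "C", "A")))
  expect_equal(res$concordance[1], 0.999)
  expect_identical(res$n_compared[2], nv - 10L)
  expect_equal(res$concordance[3], 1)  # self-concordance
  expect_error(duplicate_concordance(panel,
                                     data.frame(id1 = "A", id2 = "Z")),
               "unknown subject")
})

test_that("a pair with zero jointly non-missing calls is flagged", {
  d <- rbind(A = c(NA_integer_, 1L), B = c(0L, NA_integer_))
  colnames(d) <- c("v1", "v2")
  res <- duplicate_concordance(panel_from_dosage(d),
                               data.frame(id1 = "A", id2 = "B"))
  expect_true(is.na(res$concordance))
  expect_identical(res$n_compared, 0L)
})

test_that("chi-square statistic equals the textbook formula", {
  tab <- rbind(c(50, 40, 10), c(45, 44, 11))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  # drive it through a panel: one variant with these genotype counts by race
  d <- c(rep(0L, 50), rep(1L, 40), rep(2L, 10),
         rep(0L, 45), rep(1L, 44), rep(2L, 11))
  race <- rep(c("white", "other"), c(100, 100))
  res <- stratified_frequency_test(panel_from_dosage(cbind(d)), race = race)
  expect_identical(res$test, "chisq")
  expect_equal(res$statistic, hand, tolerance = 1e-12)
})

test_that("proportional rows give statistic 0 and p 1", {
  d <- c(rep(0L, 20), rep(1L, 20), rep(2L, 10),
         rep(0L, 40), rep(1L, 40), rep(2L, 20))
  race <- rep(c("white", "other"), c(50, 100))
  res <- stratified_frequency_test(panel_from_dosage(cbind(d)), race = race)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("Fisher's exact test is dispatched iff any cell is below 5", {
  d <- c(rep(0L, 3), rep(1L, 10), rep(2L, 8),
         rep(0L, 7), rep(1L, 9), rep(2L, 6))
  race <- rep(c("white", "other"), c(21, 22))
  res <- stratified_frequency_test(panel_from_dosage(cbind(d)), race = race)
  expect_identical(res$test, "fisher")
  expect_true(is.na(res$statistic))

  # property: dispatch is a pure function of the count table
  withr::with_seed(99, {
    for (i in 1:25) {
      counts <- matrix(sample(0:30, 6, TRUE), 2)
      if (any(rowSums(counts) == 0)) next
      d <- unlist(lapply(1:2, function(r)
        rep(0:2, counts[r, ])))
      race <- rep(c("white", "other"), rowSums(counts))
      res <- stratified_frequency_test(panel_from_dosage(cbind(as.integer(d))),
                                       race = race)
      cc <- table(factor(race, c("white", "other")), factor(d, 0:2))
      expect_identical(res$test,
                       if (any(cc < 5)) "fisher" else "chisq")
    }
  })
})

test_that("reference-population comparison contrasts study vs reference counts", {
  d <- c(rep(0L, 40), rep(1L, 40), rep(2L, 20))
  ref <- data.frame(variant = "v1", ref_maf = 0.4, n0 = 36, n1 = 48, n2 = 16)
  panel <- panel_from_dosage(cbind(v1 = d))
  res <- stratified_frequency_test(panel, reference = ref)
  expect_identical(res$test, "chisq")
  expect_gt(res$p, 0.5)  # nearly identical distributions
  # degenerate: variant missing from the reference stays flagged
  ref2 <- data.frame(variant = "other", ref_maf = 0.4, n0 = 1, n1 = 1, n2 = 1)
  res2 <- stratified_frequency_test(panel, reference = ref2)
  expect_identical(res2$test, "degenerate")
  expect_true(is.na(res2$p))
})
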