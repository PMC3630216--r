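# Seven-way somatic signature classification.
#
# Each tumor record (gene / exon / mutation type / codon span) maps to
# exactly one category: (i) KIT exon 11 deletions whose codon span covers
# both 557 and 558, (ii) other KIT exon 11 deletions, (iii) KIT exon 11
# insertions, (iv) KIT exon 11 point mutations, (v) KIT exon 9/13/14/17
# mutations of any type, (vi) PDGFRA exon 12/18 mutations, (vii) wild type.
# Case-only dichotomy k contrasts category k against all other categories.

#' Classify a somatic mutation record
#'
#' @param gene `"KIT"`, `"PDGFRA"` or `"none"` (wild type).
#' @param exon Integer exon number, or `NA` for wild type.
#' @param type `"deletion"`, `"insertion"` or `"point"`, or `NA`.
#' @param codon_start,codon_end 1-based inclusive codon span (deletions and
#'   insertions); `NA` allowed for point mutations and wild type.
#' @return One of [mutation_categories()].  A deletion spanning codons
#'   557-558 plus additional codons still counts as the 557-558 deletion
#'   category (span-covers rule).
#' @export
classify_mutation <- function(gene, exon, type, codon_start, codon_end) {
  if (is.na(gene) || gene == "none") return("wild_type")
  if (gene == "KIT") {
    if (is.na(exon)) stopf("KIT record without exon")
    if (exon == 11L) {
      if (is.na(type)) stopf("KIT exon 11 record without mutation type")
      if (type == "deletion") {
        if (is.na(codon_start) || is.na(codon_end))
          stopf("deletion record without codon span")
        if (codon_start <= 557L && codon_end >= 558L)
          return("kit_ex11_del557_558")
        return("kit_ex11_del_other")
      }
      if (type == "insertion") return("kit_ex11_ins")
      if (type == "point") return("kit_ex11_point")
      stopf("unrecognized mutation type '%s'", type)
    }
    if (exon %in% c(9L, 13L, 14L, 17L)) return("kit_other_exon")
    stopf("unrecognized KIT exon %s", exon)
  }
  if (gene == "PDGFRA") {
    if (is.na(exon) || !exon %in% c(12L, 18L))
      stopf("unrecognized PDGFRA exon %s", exon)
    return("pdgfra")
  }
  stopf("unrecognized gene '%s'", gene)
}

#' Build the seven case-only outcome dichotomies
#'
#' Classifies every subject's mutation record and derives seven mutually
#' exclusive, exhaustive binary indicator columns; for dichotomy k the
#' cases are subjects in category k and the referents are all other
#' subjects.
#'
#' @param mutations Mutation table with columns `subject`, `gene`, `exon`,
#'   `type`, `codon_start`, `codon_end` (one row per subject).
#' @return An object of class `outcome_set`: list with `subject`,
#'   `category` (factor over [mutation_categories()]) and `indicator`
#'   (subjects x 7 binary matrix).
#' @export
build_outcome_matrix <- function(mutations) {
  if (anyDuplicated(mutations$subject))
    stopf("duplicate subject in mutation table")
  n <- nrow(mutations)
  category <- character(n)
  for (i in seq_len(n)) {
    category[i] <- classify_mutation(
      mutations$gene[i], mutations$exon[i], mutations$type[i],
      mutations$codon_start[i], mutations$codon_end[i])
  }
  cats <- mutation_categories()
  ind <- matrix(0L, n, 7L, dimnames = list(mutations$subject, cats))
  ind[cbind(seq_len(n), match(category, cats))] <- 1L
  structure(list(subject = mutations$subject,
                 category = factor(category, levels = cats),
                 indicator = ind),
            class = "outcome_set")
}

#' @export
print.outcome_set <- function(x, ...) {
  cat(sprintf("outcome_set: %d subjects\n", length(x$subject)))
  print(table(x$category))
  invisible(x)
}
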