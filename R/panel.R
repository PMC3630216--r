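#' Somatic mutation signature categories
#'
#' The seven mutually exclusive somatic outcome categories used throughout
#' the package, in their conventional order: (i) KIT exon 11 deletion
#' covering codons 557-558, (ii) any other KIT exon 11 deletion, (iii) KIT
#' exon 11 insertion, (iv) KIT exon 11 point mutation, (v) KIT mutation in
#' exon 9, 13, 14 or 17, (vi) PDGFRA exon 12 or 18 mutation, (vii) wild
#' type (no KIT or PDGFRA mutation).
#'
#' @return Character vector of the seven category labels.
#' @export
mutation_categories <- function() {
  c("kit_ex11_del557_558", "kit_ex11_del_other", "kit_ex11_ins",
    "kit_ex11_point", "kit_other_exon", "pdgfra", "wild_type")
}

#' Construct a genotype panel
#'
#' A genotype panel couples a samples x variants dosage matrix (counted on
#' the coded allele, re-oriented to the minor allele by
#' [compute_maf_and_orient()]) with per-variant metadata.  Dosages are 0, 1,
#' 2 or `NA` (missing); binary pseudo-variants (e.g. GSTM1/GSTT1 null
#' genotype assays) take dosages 0/1 only, 1 marking the null genotype.
#'
#' @param dosage Integer matrix, samples in rows (rownames = subject ids),
#'   variants in columns (colnames = variant ids); entries 0/1/2/`NA`.
#' @param variants Data frame with columns `variant`, `gene`, `ref`, `alt`,
#'   and optionally `is_binary` (default `FALSE`), `cluster_pass` (default
#'   `TRUE`), `class` (functional class, default `"unknown"`).
#' @param orientation Optional data frame recording, per variant, which
#'   allele is coded as minor (`minor_allele`), whether the original coding
#'   was flipped (`flipped`), and the resulting `maf`.  Normally filled in
#'   by [compute_maf_and_orient()].
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `variants`, `subjects`, `orientation`.
#' @export
genotype_panel <- function(dosage, variants, orientation = NULL) {
  if (!is.matrix(dosage)) stopf("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("`dosage` needs subject rownames and variant colnames")
  if (anyDuplicated(rownames(dosage)))
    stopf("duplicate subject ids in dosage matrix")
  req <- c("variant", "gene", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stopf("`variants` missing column(s): %s", paste(miss, collapse = ", "))
  if (!identical(as.character(variants$variant), colnames(dosage)))
    stopf("`variants$variant` must match dosage column names in order")
  if (is.null(variants$is_binary)) variants$is_binary <- FALSE
  if (is.null(variants$cluster_pass)) variants$cluster_pass <- TRUE
  if (is.null(variants$class)) variants$class <- "unknown"
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stopf("dosages must be 0, 1, 2 or NA")
  bin <- variants$is_binary
  if (any(bin) && any(dosage[, bin, drop = FALSE] == 2L, na.rm = TRUE))
    stopf("binary pseudo-variants cannot carry dosage 2")
  structure(
    list(dosage = dosage, variants = variants,
         subjects = rownames(dosage), orientation = orientation),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d subjects x %d variants (%d genes)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$variants$gene))))
  cat(sprintf("  missing calls: %.2f%%; oriented: %s\n",
              100 * mean(is.na(x$dosage)),
              if (is.null(x$orientation)) "no" else "yes"))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by subjects and/or variants
#'
#' @param panel A [genotype_panel()].
#' @param subjects,variants Character vectors of ids to keep (`NULL` keeps
#'   all); order follows the panel, not the selector.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, subjects = NULL, variants = NULL) {
  keep_s <- if (is.null(subjects)) panel$subjects else
    panel$subjects[panel$subjects %in% subjects]
  keep_v <- if (is.null(variants)) colnames(panel$dosage) else
    colnames(panel$dosage)[colnames(panel$dosage) %in% variants]
  d <- panel$dosage[keep_s, keep_v, drop = FALSE]
  v <- panel$variants[match(keep_v, panel$variants$variant), , drop = FALSE]
  rownames(v) <- NULL
  ori <- panel$orientation
  if (!is.null(ori)) {
    ori <- ori[match(keep_v, ori$variant), , drop = FALSE]
    rownames(ori) <- NULL
  }
  out <- genotype_panel(d, v, orientation = ori)
  # carry simulation attributes (e.g. stratum assignment) through subsetting
  st <- attr(panel, "stratum")
  if (!is.null(st)) attr(out, "stratum") <- st[keep_s]
  out
}
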