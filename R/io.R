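# Native tabular dialects and standard-format I/O.
#
# dosage-tsv: samples as rows, variants as columns, header row of variant
# ids, missing calls encoded "NA"; accompanied by a variant annotation TSV
# (variant, gene, ref, alt, is_binary, cluster_pass, class).  VCF input is
# VCF 4.x, GT fields only, bi-allelic records only; alt-allele counts are
# re-oriented to minor-allele dosage later by compute_maf_and_orient().

variant_cols <- c("variant", "gene", "ref", "alt")

#' Read a genotype panel
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` (VCF 4.x, GT only, bi-allelic) or `"dosage-tsv"`
#'   (native dialect, read verbatim).
#' @param variant_file Variant annotation TSV; required for `dosage-tsv`,
#'   optional for VCF (overrides the `GENE` INFO key).
#' @return A [genotype_panel()] in alt-count (VCF) or verbatim (TSV)
#'   coding; orientation to the minor allele is applied by
#'   [compute_maf_and_orient()].
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "vcf"),
                           variant_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi))
      stopf("multi-allelic VCF record(s) not supported: %s",
            paste(fix$ID[multi], collapse = ", "))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles == "1")
    }
    dosage <- apply(gt, c(1, 2), alt_count)
    info <- fix$INFO
    gene <- sub(".*GENE=([^;]+).*", "\\1", info)
    gene[!grepl("GENE=", info)] <- NA_character_
    is_binary <- grepl("(^|;)BIN($|;)", info)
    cluster_pass <- !grepl("(^|;)CLUSTFAIL($|;)", info)
    # binary pseudo-variants: carrier of the null genotype coded 1
    if (any(is_binary))
      dosage[is_binary, ] <- pmin(dosage[is_binary, , drop = FALSE], 1L)
    variants <- data.frame(variant = fix$ID, gene = gene, ref = fix$REF,
                           alt = fix$ALT, is_binary = is_binary,
                           cluster_pass = cluster_pass)
    if (!is.null(variant_file)) {
      ann <- read_variant_annotation(variant_file)
      m <- match(variants$variant, ann$variant)
      if (anyNA(m)) stopf("variant annotation missing for: %s",
                          paste(variants$variant[is.na(m)], collapse = ", "))
      variants <- ann[m, , drop = FALSE]
      rownames(variants) <- NULL
    }
    return(genotype_panel(t(dosage), variants))
  }
  if (is.null(variant_file))
    stopf("dosage-tsv input requires a variant annotation file")
  tab <- read.delim(path, check.names = FALSE, row.names = 1L)
  dosage <- as.matrix(tab)
  storage.mode(dosage) <- "integer"
  ann <- read_variant_annotation(variant_file)
  m <- match(colnames(dosage), ann$variant)
  if (anyNA(m))
    stopf("variant annotation missing for: %s",
          paste(colnames(dosage)[is.na(m)], collapse = ", "))
  ann <- ann[m, , drop = FALSE]
  rownames(ann) <- NULL
  genotype_panel(dosage, ann)
}

read_variant_annotation <- function(path) {
  if (!file.exists(path)) stopf("variant annotation not found: %s", path)
  ann <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(variant_cols, names(ann))
  if (length(miss))
    stopf("variant annotation missing column(s): %s",
          paste(miss, collapse = ", "))
  if (is.null(ann$is_binary)) ann$is_binary <- FALSE
  if (is.null(ann$cluster_pass)) ann$cluster_pass <- TRUE
  ann$is_binary <- as.logical(ann$is_binary)
  ann$cluster_pass <- as.logical(ann$cluster_pass)
  ann
}

#' Write a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param path Output path; for `dosage-tsv` the variant annotation is
#'   written next to it with suffix `.variants.tsv`.
#' @param format `"dosage-tsv"` or `"vcf"` (plain-text VCF 4.2, GT only).
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(panel, path, format = c("dosage-tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage-tsv") {
    tab <- data.frame(subject = panel$subjects, panel$dosage,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    vpath <- paste0(path, ".variants.tsv")
    write.table(panel$variants, vpath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(c(path, vpath)))
  }
  v <- panel$variants
  gt_code <- function(d, binary) {
    if (is.na(d)) return("./.")
    if (binary) return(if (d == 1L) "1/1" else "0/0")
    c("0/0", "0/1", "1/1")[d + 1L]
  }
  info <- paste0("GENE=", v$gene,
                 ifelse(v$is_binary, ";BIN", ""),
                 ifelse(v$cluster_pass, "", ";CLUSTFAIL"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    gts <- vapply(panel$dosage[, i], gt_code, "", binary = v$is_binary[i])
    paste(c("1", i, v$variant[i], v$ref[i], v$alt[i], ".", "PASS",
            info[i], "GT", gts), collapse = "\t")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=BIN,Number=0,Type=Flag,Description=\"Binary pseudo-variant (null-genotype assay)\">",
    "##INFO=<ID=CLUSTFAIL,Number=0,Type=Flag,Description=\"Failed array clustering QC\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$subjects), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

check_levels <- function(x, allowed, what, allow_na = FALSE) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad))
    stopf("invalid %s value(s): %s (allowed: %s)", what,
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  if (!allow_na && anyNA(x)) stopf("missing values not allowed in %s", what)
}

#' Read covariate, mutation and reference-frequency tables
#'
#' All three are tab-separated with one header row.  Covariates require
#' columns `subject`, `age`, `sex` (male/female), `race` (white/other) and
#' `site` (stomach/small_intestine/rectum/other, may be missing).  The
#' mutation table requires `subject`, `gene`, `exon`, `type`,
#' `codon_start`, `codon_end`; a row whose `gene` is empty or `none` is a
#' wild-type record.  The optional reference table requires `variant`,
#' `ref_maf`, `n0`, `n1`, `n2` (reference genotype-class counts).
#'
#' @param covariates_path,mutations_path,reference_path File paths;
#'   `reference_path` may be `NULL`.
#' @return List with `covariates`, `mutations` and (possibly `NULL`)
#'   `reference`.
#' @export
read_tables <- function(covariates_path, mutations_path,
                        reference_path = NULL) {
  for (p in c(covariates_path, mutations_path))
    if (!file.exists(p)) stopf("input table not found: %s", p)
  cov <- read.delim(covariates_path, stringsAsFactors = FALSE)
  need <- c("subject", "age", "sex", "race", "site")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stopf("covariate table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cov$subject))
    stopf("duplicate subject id in covariate table")
  check_levels(cov$sex, c("male", "female"), "sex")
  check_levels(cov$race, c("white", "other"), "race")
  check_levels(cov$site, c("stomach", "small_intestine", "rectum", "other"),
               "site", allow_na = TRUE)
  if (any(cov$age < 0 | cov$age > 120, na.rm = TRUE))
    stopf("age outside plausible bounds [0, 120]")

  mut <- read.delim(mutations_path, stringsAsFactors = FALSE)
  needm <- c("subject", "gene", "exon", "type", "codon_start", "codon_end")
  missm <- setdiff(needm, names(mut))
  if (length(missm))
    stopf("mutation table missing column(s): %s", paste(missm, collapse = ", "))
  if (anyDuplicated(mut$subject))
    stopf("duplicate subject id in mutation table")
  mut$gene[is.na(mut$gene) | mut$gene == ""] <- "none"
  mut$type[!is.na(mut$type) & mut$type == ""] <- NA_character_
  check_levels(mut$gene, c("KIT", "PDGFRA", "none"), "gene")
  check_levels(mut$type, c("deletion", "insertion", "point"), "type",
               allow_na = TRUE)
  wild <- mut$gene == "none"
  mut$exon[wild] <- NA_integer_
  mut$type[wild] <- NA_character_
  mut$codon_start[wild] <- NA_integer_
  mut$codon_end[wild] <- NA_integer_

  ref <- NULL
  if (!is.null(reference_path)) {
    if (!file.exists(reference_path))
      stopf("reference table not found: %s", reference_path)
    ref <- read.delim(reference_path, stringsAsFactors = FALSE)
    needr <- c("variant", "ref_maf", "n0", "n1", "n2")
    missr <- setdiff(needr, names(ref))
    if (length(missr))
      stopf("reference table missing column(s): %s",
            paste(missr, collapse = ", "))
    if (any(ref$ref_maf < 0 | ref$ref_maf > 1))
      stopf("reference MAF outside [0, 1]")
  }
  list(covariates = cov, mutations = mut, reference = ref)
}

#' Reconcile subject ids across inputs
#'
#' @param panel A [genotype_panel()].
#' @param covariates,mutations The corresponding tables.
#' @return Data frame, one row per subject seen anywhere, with logical
#'   columns `in_genotypes`, `in_covariates`, `in_mutations`.
#' @export
reconcile_subjects <- function(panel, covariates, mutations) {
  ids <- unique(c(panel$subjects, covariates$subject, mutations$subject))
  data.frame(subject = ids,
             in_genotypes = ids %in% panel$subjects,
             in_covariates = ids %in% covariates$subject,
             in_mutations = ids %in% mutations$subject)
}

#' Write analysis result files
#'
#' Emits (a) the long-form per-variant association table, (b) gene x
#' outcome matrices of -log10 p for the per-variant analysis (strongest
#' variant per gene) and for the gene-level kernel test, (c) the gene-level
#' result table, and (d) a run manifest (seed, config hash, stage counts).
#'
#' @param assoc Per-variant association table from [scan()].
#' @param skat Gene-level result table from [gene_scan()].
#' @param dir Output directory (created if needed).
#' @param manifest Named character/numeric vector of run metadata.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(assoc, skat, dir, manifest = c()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(assoc = file.path(dir, "variant_results.tsv"),
             skat = file.path(dir, "gene_results.tsv"),
             mat_variant = file.path(dir, "neglog10p_variant.tsv"),
             mat_gene = file.path(dir, "neglog10p_gene.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  write.table(assoc, paths[["assoc"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(skat, paths[["skat"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  neglog_matrix <- function(df, pcol) {
    genes <- sort(unique(df$gene))
    cats <- mutation_categories()
    m <- matrix(NA_real_, length(genes), length(cats),
                dimnames = list(genes, cats))
    for (k in seq_len(nrow(df))) {
      p <- df[[pcol]][k]
      if (is.na(p)) next
      g <- df$gene[k]; o <- df$outcome[k]
      v <- -log10(p)
      if (is.na(m[g, o]) || v > m[g, o]) m[g, o] <- v
    }
    m
  }
  mv <- neglog_matrix(assoc, "p")
  mg <- neglog_matrix(skat, "p")
  write.table(data.frame(gene = rownames(mv), mv, check.names = FALSE),
              paths[["mat_variant"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = rownames(mg), mg, check.names = FALSE),
              paths[["mat_gene"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("%s\t%s", names(manifest), as.character(manifest)),
             paths[["manifest"]])
  invisible(paths)
}

#' Serialize / restore a cohort specification
#'
#' The spec is written as structured text (YAML) so that fixture
#' generation is reproducible from a flat config file.
#'
#' @param spec A [cohort_spec()].
#' @param path Output (or input) path.
#' @return `write_cohort_spec()`: the path, invisibly;
#'   `read_cohort_spec()`: a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$strata <- as.list(x$strata)
  x$variants <- as.list(x$variants)
  x$effects <- as.list(x$effects)
  x$maf <- list(values = as.vector(x$maf), ncol = ncol(x$maf),
                colnames = colnames(x$maf))
  x$baseline_probs <- as.list(x$baseline_probs)
  x$ld_rho <- as.list(x$ld_rho)
  x$site_probs <- as.list(x$site_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  maf <- matrix(unlist(x$maf$values), ncol = x$maf$ncol)
  colnames(maf) <- unlist(x$maf$colnames)
  cohort_spec(
    n_subjects = x$n_subjects,
    strata = as.data.frame(x$strata),
    variants = as.data.frame(x$variants),
    maf = maf,
    ld_rho = unlist(x$ld_rho),
    age = x$age,
    sex_prop_male = x$sex_prop_male,
    site_probs = unlist(x$site_probs),
    baseline_probs = unlist(x$baseline_probs),
    effects = if (length(x$effects$variant))
      as.data.frame(x$effects)
    else data.frame(variant = character(), category = character(),
                    log_or = numeric()),
    missing_rate = x$missing_rate,
    seed = x$seed)
}
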