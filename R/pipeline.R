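# One-command orchestration: QC cascade -> outcome classification ->
# per-variant scan -> gene-level kernel scan -> result files + manifest.
# Single-process and deterministic given the config and seed.

#' Build and validate a pipeline run configuration
#'
#' @param genotypes Path to the genotype file.
#' @param format `"dosage-tsv"` or `"vcf"`.
#' @param covariates,mutations Paths to the covariate and mutation TSVs.
#' @param variant_file Variant annotation TSV (required for dosage-tsv).
#' @param reference Optional reference-frequency TSV.
#' @param out_dir Output directory.
#' @param maf_min,missingness_max,homozygote_rule QC thresholds (see
#'   [apply_variant_filters()] and [exclude_samples()]).
#' @param fdr_q,family FDR settings (see [snp_scan()]).
#' @param kernel `"ibs"` (default) or `"linear"`.
#' @param pvalue `"moments"`, `"exact"` or `"permutation"`.
#' @param n_perm Permutations when `pvalue = "permutation"`.
#' @param site_filter Optional character vector of tumor sites for a
#'   site-restricted subanalysis.
#' @param seed Integer seed (permutation mode and manifest).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genotypes, format = "dosage-tsv", covariates,
                       mutations, variant_file = NULL, reference = NULL,
                       out_dir = "results", maf_min = 0.05,
                       missingness_max = 0.10,
                       homozygote_rule = "any_level", fdr_q = 0.25,
                       family = "per-outcome", kernel = "ibs",
                       pvalue = "moments", n_perm = 10000L,
                       site_filter = NULL, seed = 1L) {
  config <- list(genotypes = genotypes, format = format,
                 covariates = covariates, mutations = mutations,
                 variant_file = variant_file, reference = reference,
                 out_dir = out_dir, maf_min = maf_min,
                 missingness_max = missingness_max,
                 homozygote_rule = homozygote_rule, fdr_q = fdr_q,
                 family = family, kernel = kernel, pvalue = pvalue,
                 n_perm = as.integer(n_perm), site_filter = site_filter,
                 seed = as.integer(seed))
  if (!format %in% c("dosage-tsv", "vcf")) stopf("unknown format")
  if (!kernel %in% c("ibs", "linear")) stopf("unknown kernel")
  if (!pvalue %in% c("moments", "exact", "permutation"))
    stopf("unknown p-value mode")
  if (!family %in% c("per-outcome", "pooled")) stopf("unknown FDR family")
  for (p in c(genotypes, covariates, mutations)) {
    if (!file.exists(p))
      stopf("input stage: file not found: %s", p)
  }
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input reading and reconciliation, sample exclusion,
#' minor-allele orientation, variant filtering, outcome classification,
#' the per-variant logistic scan (plus an optional site-restricted
#' subanalysis), the gene-level kernel scan, and result writing with a
#' run manifest of stage counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the filtered panel, QC reports, result
#'   tables and output paths.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  panel <- stage("read_genotypes",
    read_genotypes(config$genotypes, config$format, config$variant_file))
  tabs <- stage("read_tables",
    read_tables(config$covariates, config$mutations, config$reference))
  recon <- reconcile_subjects(panel, tabs$covariates, tabs$mutations)

  s <- stage("exclude_samples",
    exclude_samples(panel, tabs$mutations,
                    missingness_threshold = config$missingness_max))
  panel <- stage("orient", compute_maf_and_orient(s$panel))
  mut <- tabs$mutations[match(panel$subjects, tabs$mutations$subject), ,
                        drop = FALSE]
  outcomes <- stage("classify", build_outcome_matrix(mut))
  vf <- stage("variant_filters",
    apply_variant_filters(panel, outcomes, maf_min = config$maf_min,
                          homozygote_rule = config$homozygote_rule))
  panel <- vf$panel
  covariates <- tabs$covariates[
    tabs$covariates$subject %in% panel$subjects, , drop = FALSE]

  assoc <- stage("scan",
    snp_scan(panel, outcomes, covariates, q = config$fdr_q,
         family = config$family))
  assoc_subset <- NULL
  if (!is.null(config$site_filter))
    assoc_subset <- stage("subset_scan",
      subset_scan(panel, outcomes, covariates, config$site_filter,
                  q = config$fdr_q, family = config$family))
  skat <- stage("gene_scan", {
    if (config$kernel == "linear") {
      gene_scan_linear(panel, outcomes, covariates, config$pvalue,
                       config$n_perm, config$seed)
    } else {
      gene_scan(panel, outcomes, covariates, method = config$pvalue,
                n_perm = config$n_perm, seed = config$seed)
    }
  })
  freq <- stage("stratified_frequencies",
    stratified_frequency_test(panel,
      race = align_covariates(panel, covariates)$race))

  manifest <- c(
    seed = config$seed,
    config_hash = fnv1a_hash(paste(deparse(unclass(config)), collapse = "")),
    subjects_input = s$report$n[s$report$rule == "input"],
    subjects_missing_mutation =
      s$report$n[s$report$rule == "missing_mutation_data"],
    subjects_high_missingness =
      s$report$n[s$report$rule == "genotype_missingness"],
    subjects_retained = s$report$n[s$report$rule == "retained"],
    variants_input = vf$report$n[vf$report$rule == "input"],
    variants_retained = vf$report$n[vf$report$rule == "retained"],
    variant_rows = nrow(assoc),
    gene_rows = nrow(skat))
  paths <- stage("write_results",
    write_results(assoc, skat, config$out_dir, manifest))
  if (!is.null(assoc_subset))
    write.table(assoc_subset,
                file.path(config$out_dir, "variant_results_subset.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(panel = panel, sample_report = s$report,
                 variant_report = vf$report,
                 attribution = vf$attribution, outcomes = outcomes,
                 assoc = assoc, assoc_subset = assoc_subset, skat = skat,
                 frequency_tests = freq, reconciliation = recon,
                 manifest = manifest, paths = paths))
}

# linear-kernel variant of the gene scan (shares all plumbing)
gene_scan_linear <- function(panel, outcomes, covariates, method,
                             n_perm, seed) {
  ind <- align_outcomes(panel, outcomes)
  cov <- align_covariates(panel, covariates)
  genes <- sort(unique(panel$variants$gene))
  cats <- mutation_categories()
  rows <- list(); i <- 0L
  for (k in seq_along(cats)) {
    null <- tryCatch(fit_null(ind[, k], cov), error = function(e) NULL)
    for (g in genes) {
      i <- i + 1L
      cols <- panel$variants$variant[panel$variants$gene == g]
      G <- panel$dosage[, cols, drop = FALSE]
      for (j in seq_len(ncol(G))) {
        x <- G[, j]; x[is.na(x)] <- mean(x, na.rm = TRUE); G[, j] <- x
      }
      K <- tcrossprod(G) / (2 * ncol(G))
      row <- data.frame(gene = g, outcome = cats[k],
                        n_variants = ncol(G), Q = NA_real_,
                        kappa = NA_real_, nu = NA_real_, p = NA_real_,
                        status = "failed")
      if (!is.null(null)) {
        Q <- q_statistic(K, null)
        row$Q <- Q
        if (method == "permutation") {
          row$p <- as.numeric(permutation_p(K, null, n_perm = n_perm,
                                            seed = sub_seed(seed, i)))
          row$status <- "ok"
        } else {
          mm <- moment_matched_p(Q, K, null, method = method)
          row$kappa <- mm$kappa; row$nu <- mm$nu; row$p <- mm$p
          row$status <- if (is.na(mm$p)) "degenerate" else "ok"
        }
      }
      rows[[i]] <- row
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene, match(res$outcome, cats)), ]
  rownames(res) <- NULL
  res
}

#' Write a synthetic cohort to disk as an analysis fixture
#'
#' Simulates the cohort described by `spec` and writes it in the native
#' formats: genotypes as both plain-text VCF and dosage-tsv (with variant
#' annotation), covariate and mutation TSVs, the truth record of planted
#' effects, and the spec itself as a flat config file.
#'
#' @param spec A [cohort_spec()] or a path to a serialized spec.
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
make_fixture <- function(spec, dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  validate_cohort_spec(spec)
  cohort <- simulate_cohort(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             dosage = file.path(dir, "genotypes.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             truth = file.path(dir, "truth.tsv"),
             spec = file.path(dir, "cohort_spec.yaml"))
  write_genotypes(cohort$panel, paths[["vcf"]], format = "vcf")
  write_genotypes(cohort$panel, paths[["dosage"]], format = "dosage-tsv")
  write.table(cohort$covariates, paths[["covariates"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$mutations, paths[["mutations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$effects, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_cohort_spec(spec, paths[["spec"]])
  invisible(paths)
}
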