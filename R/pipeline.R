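# End-to-end orchestration in the standard analysis order: QC ->
# singleton exclusion -> single-variant scan (with/without ClinVar) ->
# genomic inflation -> gene scan (nonsynonymous + synonymous) -> RVTT on
# result-derived gene sets.

#' Pipeline configuration
#'
#' @param hard_filters a [hard_filter_thresholds()].
#' @param site_config a [site_filter_config()].
#' @param relatedness_threshold A_jk flag level (default 0.3).
#' @param relatedness_maf_min MAF floor for the sites entering the A_jk
#'   estimate (default 0.01; rare sites make the estimator noise-
#'   dominated).
#' @param relatedness_min_variants skip the relatedness stage (with a
#'   note in the QC report) when fewer informative sites are available.
#' @param maf_max rare-variant MAF ceiling used by every test.
#' @param exclude_clinvar also report a ClinVar-excluded variant scan and
#'   its genomic inflation factor.
#' @param gene_config a [gene_test_config()].
#' @param rvtt_B RVTT permutations (default 1000 for pipeline runs; raise
#'   to 10000 for production analyses).
#' @param rvtt_masks masks for the RVTT channels.
#' @param n_perm_fdr permutations for the empirical FDR of the variant
#'   scan (0 uses Bonferroni only).
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(hard_filters = hard_filter_thresholds(),
                            site_config = site_filter_config(),
                            relatedness_threshold = 0.3,
                            relatedness_maf_min = 0.01,
                            relatedness_min_variants = 100L,
                            maf_max = 0.01,
                            exclude_clinvar = TRUE,
                            gene_config = gene_test_config(),
                            rvtt_B = 1000L,
                            rvtt_masks = default_masks()[c("missense",
                                                           "synonymous")],
                            n_perm_fdr = 100L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full case-control rare-variant pipeline
#'
#' Stages, in order: hard filters; site filters; relatedness-based sample
#' removal; ultra-rare balance checks (AC = 1, 2, 3); singleton
#' exclusion; one-sided Fisher variant scan (all rare variants, and with
#' ClinVar-pathogenic variants excluded) with Bonferroni and permutation
#' FDR plus genomic inflation factors; SKAT-O gene scan under the
#' nonsynonymous mask with the synonymous mask as negative control; RVTT
#' with Cauchy-combination meta table on the supplied gene sets.
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param genesets list of [gene_set()]s for the RVTT stage (optional).
#' @param config a [pipeline_config()].
#' @param extra_cohorts optional named list of additional annotated
#'   cohorts for the RVTT meta-analysis (each passed through the same QC).
#' @return a `pipeline_result` list: `qc_reports`, `balance_tests`,
#'   `dataset` (post-QC), `variant_results`,
#'   `variant_results_no_clinvar`, `lambda`, `lambda_no_clinvar`,
#'   `gene_results`, `rvtt` (per-cohort + meta tables), `manifest`.
#' @export
run_pipeline <- function(dataset, genesets = NULL,
                         config = pipeline_config(),
                         extra_cohorts = NULL) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qc_reports <- list()

  hf <- stage("hard_filters",
              apply_hard_filters(dataset, config$hard_filters))
  qc_reports$hard_filters <- hf$report
  hf$dataset$gq <- NULL          # consumed by the GQ rule above
  sf <- stage("site_filters", site_filters(hf$dataset,
                                           config$site_config))
  qc_reports$site_filters <- sf$report
  ds <- sf$dataset
  ds$dp <- NULL                  # consumed by the depth rules
  hf <- sf <- NULL
  gc(FALSE)

  maf_all <- compute_maf(ds, "combined")
  n_informative <- sum(!is.na(maf_all) &
                         maf_all >= config$relatedness_maf_min)
  if (n_informative >= config$relatedness_min_variants) {
    rel <- stage("relatedness",
                 relatedness_ajk(ds, config$relatedness_threshold,
                                 maf_min = config$relatedness_maf_min))
    if (length(rel$remove))
      ds <- subset_cohort(ds, sample_ids = setdiff(ds$samples$sample_id,
                                                   rel$remove))
    qc_reports$relatedness <- list(step = "relatedness",
                                   flagged_pairs = rel$flagged_pairs,
                                   removed_samples = rel$remove)
  } else {
    qc_reports$relatedness <- list(
      step = "relatedness", skipped = TRUE,
      note = sprintf("only %d sites at MAF >= %g; stage skipped",
                     n_informative, config$relatedness_maf_min))
  }

  balance <- stage("ultra_rare_balance",
                   lapply(1:3, function(ac)
                     ultra_rare_balance_test(ds, ac)))
  names(balance) <- c("singletons", "doubletons", "tripletons")

  sing <- stage("exclude_singletons", exclude_singletons(ds))
  qc_reports$singletons <- list(step = "exclude_singletons",
                                n_removed = sing$n_removed)
  ds <- sing$dataset

  vs <- stage("variant_scan",
              variant_scan(ds, maf_max = config$maf_max,
                           exclude_clinvar = FALSE,
                           n_perm_fdr = config$n_perm_fdr,
                           seed = seed + 1L))
  lambda <- genomic_lambda(vs$p_raw)
  vs_nc <- NULL; lambda_nc <- NA_real_
  if (config$exclude_clinvar) {
    vs_nc <- stage("variant_scan_no_clinvar",
                   variant_scan(ds, maf_max = config$maf_max,
                                exclude_clinvar = TRUE,
                                n_perm_fdr = config$n_perm_fdr,
                                seed = seed + 2L))
    lambda_nc <- genomic_lambda(vs_nc$p_raw)
  }

  gs <- stage("gene_scan",
              gene_scan(ds, config = config$gene_config,
                        n_perm_fdr = 0L, seed = seed + 3L))

  rv <- NULL
  if (!is.null(genesets)) {
    cohorts <- c(list(discovery = ds), extra_cohorts)
    rv <- stage("rvtt", rvtt_meta(
      cohorts, genesets,
      config = rvtt_config(B = config$rvtt_B, seed = seed + 4L,
                           maf_max = config$maf_max),
      masks = config$rvtt_masks))
  }

  structure(list(
    qc_reports = qc_reports, balance_tests = balance, dataset = ds,
    variant_results = vs, variant_results_no_clinvar = vs_nc,
    lambda = lambda, lambda_no_clinvar = lambda_nc,
    gene_results = gs, rvtt = rv,
    manifest = list(seed = seed, n_samples = nrow(ds$geno),
                    n_variants_retained = ncol(ds$geno),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    config_hash = config_hash(config))),
    class = "pipeline_result")
}

# order-stable hash of the configuration (for the run manifest)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small polynomial rolling hash over the serialized config
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write the pipeline result bundle
#'
#' Emits the QC report (JSON + BED-like removals), the variant- and
#' gene-level result TSVs (unit, counts/statistics, raw, Bonferroni and
#' FDR-adjusted p), QQ-plot data, the RVTT per-cohort and meta tables and
#' the run manifest.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_qc_report(result$qc_reports, file.path(dir, "qc_report.json"))
  wt(result$variant_results, "variant_results.tsv")
  if (!is.null(result$variant_results_no_clinvar))
    wt(result$variant_results_no_clinvar,
       "variant_results_no_clinvar.tsv")
  wt(result$gene_results, "gene_results.tsv")
  wt(qq_data(result$variant_results$p_raw), "qq_data.tsv")
  if (!is.null(result$rvtt)) {
    wt(result$rvtt$per_cohort, "rvtt_per_cohort.tsv")
    wt(result$rvtt$meta, "rvtt_meta.tsv")
  }
  jsonlite::write_json(
    c(result$manifest, list(lambda = result$lambda,
                            lambda_no_clinvar = result$lambda_no_clinvar)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
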