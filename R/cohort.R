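#' Construct a case-control cohort dataset
#'
#' The central container of the package: an aligned genotype matrix plus
#' sample phenotypes, variant records and (optionally) functional
#' annotations. Every analysis stage consumes and returns this object, so
#' quality-control steps compose with association tests without re-aligning
#' identifiers.
#'
#' @param geno integer matrix of alt-allele dosages (0, 1, 2, `NA` =
#'   missing genotype); rows are samples, columns are variants. Row names
#'   must be sample ids and column names variant ids (`"chrom:pos:ref:alt"`).
#' @param samples data.frame with columns `sample_id`, `phenotype`
#'   (`"case"` or `"control"`) and optionally `cohort` plus per-sample QC
#'   metrics (`tstv`, `hethom`, `missing_rate`).
#' @param variants data.frame of variant records with columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `vid`, and optionally `qual` and the
#'   site-level metrics `QD`, `SOR`, `MQ`, `FS`, `MQRankSum`,
#'   `ReadPosRankSum`. A `vtype` column (`"snv"`/`"indel"`) is derived from
#'   the alleles when absent.
#' @param annotations optional data.frame of per-variant annotations; see
#'   [read_annotations()] for the schema.
#' @param gq,dp optional matrices of per-genotype quality and depth, with
#'   the same dimensions as `geno`.
#'
#' @return An object of class `cohort_dataset`.
#' @seealso [read_vcf()], [simulate_cohort()]
#' @export
cohort_dataset <- function(geno, samples, variants, annotations = NULL,
                           gq = NULL, dp = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  if (is.null(variants$vid)) {
    variants$vid <- paste(variants$chrom, variants$pos, variants$ref,
                          variants$alt, sep = ":")
  }
  if (is.null(variants$vtype)) {
    variants$vtype <- ifelse(nchar(variants$ref) == 1L &
                               nchar(variants$alt) == 1L, "snv", "indel")
  }
  if (is.null(rownames(geno))) rownames(geno) <- samples$sample_id
  if (is.null(colnames(geno))) colnames(geno) <- variants$vid
  obj <- structure(
    list(geno = geno, samples = samples, variants = variants,
         annotations = annotations, gq = gq, dp = dp),
    class = "cohort_dataset")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  g <- x$geno
  if (nrow(g) != nrow(x$samples))
    stop("genotype rows (", nrow(g), ") != sample table rows (",
         nrow(x$samples), ")")
  if (ncol(g) != nrow(x$variants))
    stop("genotype columns (", ncol(g), ") != variant records (",
         nrow(x$variants), ")")
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicate sample ids")
  if (anyDuplicated(x$variants$vid))
    stop("duplicate variant ids (vid)")
  if (!all(x$samples$phenotype %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'")
  if (any(x$variants$pos < 1L))
    stop("positions must be 1-based (pos >= 1)")
  if (any(x$variants$ref == x$variants$alt))
    stop("alt allele equal to ref allele")
  if (length(g)) {
    rng <- suppressWarnings(range(g, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
      stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (!identical(rownames(g), as.character(x$samples$sample_id)))
    stop("genotype row names do not match sample ids")
  if (!identical(colnames(g), as.character(x$variants$vid)))
    stop("genotype column names do not match variant ids")
  for (m in c("gq", "dp")) {
    if (!is.null(x[[m]]) && !identical(dim(x[[m]]), dim(g)))
      stop(m, " matrix dimensions do not match genotypes")
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  ph <- table(factor(x$samples$phenotype, c("case", "control")))
  cat("cohort_dataset:", nrow(x$geno), "samples (", ph[["case"]], "cases /",
      ph[["control"]], "controls ),", ncol(x$geno), "variants\n")
  if (!is.null(x$annotations))
    cat("  annotations:", nrow(x$annotations), "records,",
        length(unique(x$annotations$gene)), "genes\n")
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$geno)

#' Subset a cohort dataset by variants and/or samples
#'
#' @param dataset a [cohort_dataset()].
#' @param vids variant ids to keep (default all, original order preserved).
#' @param sample_ids sample ids to keep (default all).
#' @return the subset `cohort_dataset`.
#' @export
subset_cohort <- function(dataset, vids = NULL, sample_ids = NULL) {
  keep_v <- if (is.null(vids)) rep(TRUE, ncol(dataset$geno))
            else dataset$variants$vid %in% vids
  keep_s <- if (is.null(sample_ids)) rep(TRUE, nrow(dataset$geno))
            else dataset$samples$sample_id %in% sample_ids
  ann <- dataset$annotations
  if (!is.null(ann)) ann <- ann[ann$vid %in% dataset$variants$vid[keep_v], ,
                                drop = FALSE]
  cohort_dataset(
    geno = dataset$geno[keep_s, keep_v, drop = FALSE],
    samples = dataset$samples[keep_s, , drop = FALSE],
    variants = dataset$variants[keep_v, , drop = FALSE],
    annotations = ann,
    gq = if (!is.null(dataset$gq)) dataset$gq[keep_s, keep_v, drop = FALSE],
    dp = if (!is.null(dataset$dp)) dataset$dp[keep_s, keep_v, drop = FALSE])
}

#' Per-variant alternate allele count
#'
#' `AC(v)` is the sum of dosages over non-missing genotypes, optionally
#' restricted to one phenotype group.
#'
#' @param dataset a [cohort_dataset()].
#' @param group `"combined"`, `"cases"` or `"controls"`.
#' @return named integer vector of allele counts per variant.
#' @export
compute_ac <- function(dataset, group = c("combined", "cases", "controls")) {
  group <- match.arg(group)
  g <- group_rows(dataset, group)
  colSums(dataset$geno[g, , drop = FALSE], na.rm = TRUE)
}

group_rows <- function(dataset, group) {
  switch(group,
         combined = rep(TRUE, nrow(dataset$samples)),
         cases    = dataset$samples$phenotype == "case",
         controls = dataset$samples$phenotype == "control")
}

#' Define a gene set
#'
#' @param name set label.
#' @param genes character vector of gene symbols (deduplicated).
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}
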