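# Readers and writers: VCF (via vcfR), annotation / phenotype / gene-set
# tables, and result exports.

#' Read a multi-sample VCF
#'
#' Reads a VCF 4.x (plain or bgzipped) into the genotype/variant part of a
#' cohort. Genotypes are coded as alt-allele dosage (0/1/2) regardless of
#' phasing; missing genotypes (`./.`) map to `NA`. Multiallelic records
#' are refused: split them upstream (`bcftools norm -m-`).
#'
#' @param path VCF file path.
#' @param region_filter optional list(chrom, start, end) restricting the
#'   records read.
#' @return a `vcf_part` list: `geno` (samples x variants), `variants`
#'   (with QUAL and any of QD/SOR/MQ/FS/MQRankSum/ReadPosRankSum found in
#'   INFO), `gq`, `dp` (matrices or NULL), `sample_ids`. Combine with a
#'   phenotype table via [assemble_cohort()].
#' @export
read_vcf <- function(path, region_filter = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) at ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                           3), collapse = ", "),
         ": split required (e.g. bcftools norm -m-)")
  if (!is.null(region_filter)) {
    keep <- fix$CHROM == region_filter$chrom &
      as.integer(fix$POS) >= region_filter$start &
      as.integer(fix$POS) <= region_filter$end
    vcf <- vcf[keep, ]
    fix <- fix[keep, , drop = FALSE]
    if (nrow(fix) == 0L) stop("no records in the requested region")
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw) || all(is.na(gt_raw)))
    stop("GT field missing from ", path)
  codes <- gt_to_dosage(gt_raw)
  geno <- t(codes)                        # samples x variants
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    vid = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    qual = suppressWarnings(as.numeric(fix$QUAL)))
  for (metric in c("QD", "SOR", "MQ", "FS", "MQRankSum",
                   "ReadPosRankSum")) {
    val <- suppressWarnings(
      vcfR::extract.info(vcf, element = metric, as.numeric = TRUE))
    if (!is.null(val) && !all(is.na(val))) variants[[metric]] <- val
  }
  variants$vtype <- ifelse(nchar(variants$ref) == 1L &
                             nchar(variants$alt) == 1L, "snv", "indel")
  grab <- function(el) {
    if (!grepl(el, vcf@gt[1, "FORMAT"])) return(NULL)
    v <- suppressWarnings(vcfR::extract.gt(vcf, element = el,
                                           as.numeric = TRUE))
    if (is.null(v)) NULL else t(v)
  }
  rownames(geno) <- colnames(gt_raw)
  colnames(geno) <- variants$vid
  gq <- grab("GQ"); dp <- grab("DP")
  if (!is.null(gq)) dimnames(gq) <- dimnames(geno)
  if (!is.null(dp)) dimnames(dp) <- dimnames(geno)
  structure(list(geno = geno, variants = variants, gq = gq, dp = dp,
                 sample_ids = rownames(geno)), class = "vcf_part")
}

# GT strings -> 0/1/2/NA dosage (phase-agnostic)
gt_to_dosage <- function(gt) {
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
             ".|." = NA_integer_, "." = NA_integer_, "0" = 0L, "1" = 1L,
             "./1" = NA_integer_, "1/." = NA_integer_,
             "./0" = NA_integer_, "0/." = NA_integer_)
  out <- known[gt]
  unseen <- is.na(out) & !is.na(gt) & !(gt %in% names(known))
  if (any(unseen))
    stop("unsupported GT string(s): ",
         paste(utils::head(unique(gt[unseen]), 3), collapse = ", "))
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Assemble a cohort from VCF, phenotype and annotation parts
#'
#' @param part a [read_vcf()] result.
#' @param samples phenotype table (data.frame with `sample_id`,
#'   `phenotype`, optional `cohort`), e.g. from [read_phenotypes()].
#'   Samples are matched by id; every VCF sample must be present.
#' @param annotations optional annotation table from [read_annotations()].
#' @return a [cohort_dataset()].
#' @export
assemble_cohort <- function(part, samples, annotations = NULL) {
  idx <- match(part$sample_ids, samples$sample_id)
  if (anyNA(idx))
    stop("phenotype table missing sample(s): ",
         paste(utils::head(part$sample_ids[is.na(idx)], 5),
               collapse = ", "))
  cohort_dataset(part$geno, samples[idx, , drop = FALSE], part$variants,
                 annotations = annotations, gq = part$gq, dp = part$dp)
}

#' Write a cohort's genotypes as VCF 4.2
#'
#' Emits GT (and GQ/DP when present) plus the retained site metrics as
#' INFO fields, so that reading the file back reproduces the genotype
#' codes, positions, alleles and metrics exactly.
#'
#' @param dataset a [cohort_dataset()].
#' @param path output path (plain text; use a `.vcf` name).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(dataset, path) {
  v <- dataset$variants
  metrics <- intersect(c("QD", "SOR", "MQ", "FS", "MQRankSum",
                         "ReadPosRankSum"), names(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rvburden",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            metrics, metrics),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(dataset$gq))
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    if (!is.null(dataset$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", dataset$samples$sample_id),
          collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  fmt <- paste(c("GT", if (!is.null(dataset$gq)) "GQ",
                 if (!is.null(dataset$dp)) "DP"), collapse = ":")
  g <- dataset$geno
  for (j in seq_len(ncol(g))) {
    info <- if (length(metrics)) {
      vals <- vapply(metrics, function(mm) v[[mm]][j], numeric(1))
      ok <- !is.na(vals)
      if (any(ok)) paste(sprintf("%s=%.6g", metrics[ok], vals[ok]),
                         collapse = ";") else "."
    } else "."
    gt <- ifelse(is.na(g[, j]), "./.", gt_str[g[, j] + 1L])
    if (!is.null(dataset$gq))
      gt <- paste(gt, ifelse(is.na(dataset$gq[, j]), ".",
                             dataset$gq[, j]), sep = ":")
    if (!is.null(dataset$dp))
      gt <- paste(gt, ifelse(is.na(dataset$dp[, j]), ".",
                             dataset$dp[, j]), sep = ":")
    qual <- if (is.na(v$qual[j])) "." else sprintf("%.6g", v$qual[j])
    writeLines(paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j],
                       qual, "PASS", info, fmt, gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a variant annotation table
#'
#' TSV with header; mandatory columns `gene` and `consequence` plus
#' either `vid` or all of `chrom`, `pos`, `ref`, `alt`. Optional columns:
#' `polyphen` (P/D/B), `sift` (deleterious/tolerated), `ext_maf`
#' (fraction or NA), `clinvar` or `clinvar_pathogenic` (0/1 or
#' TRUE/FALSE). Consequence strings are matched case-insensitively
#' against the supported annotator dialects; unknown strings map to
#' `"other"` with a warning.
#'
#' @param path TSV path.
#' @return annotation data.frame with canonical columns.
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"vid" %in% names(x)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(x)))
      stop("annotation schema error: need 'vid' or ",
           paste(need, collapse = "/"))
    x$vid <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  }
  for (col in c("gene", "consequence"))
    if (!col %in% names(x))
      stop("annotation schema error: missing column '", col, "'")
  x$consequence <- normalize_consequence(x$consequence)
  if (!"polyphen" %in% names(x)) x$polyphen <- NA_character_
  if (!"sift" %in% names(x)) x$sift <- NA_character_
  x$polyphen[x$polyphen %in% c("", "NA", ".")] <- NA_character_
  x$sift <- tolower(x$sift)
  x$sift[x$sift %in% c("", "na", ".")] <- NA_character_
  if (!"ext_maf" %in% names(x)) x$ext_maf <- NA_real_
  x$ext_maf <- suppressWarnings(as.numeric(x$ext_maf))
  if (any(!is.na(x$ext_maf) & (x$ext_maf < 0 | x$ext_maf > 1)))
    stop("ext_maf outside [0, 1]")
  cv <- if ("clinvar_pathogenic" %in% names(x)) x$clinvar_pathogenic
        else if ("clinvar" %in% names(x)) x$clinvar else
          rep(FALSE, nrow(x))
  x$clinvar_pathogenic <- cv %in% c(TRUE, 1, "1", "TRUE", "true", "yes")
  x[, c("vid", "gene", "consequence", "polyphen", "sift", "ext_maf",
        "clinvar_pathogenic")]
}

#' Read a phenotype table
#'
#' TSV with columns `sample_id`, `phenotype` (case/control) and optional
#' `cohort`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "phenotype"))
    if (!col %in% names(x)) stop("phenotype schema error: missing '",
                                 col, "'")
  x$phenotype <- tolower(x$phenotype)
  if (!all(x$phenotype %in% c("case", "control")))
    stop("phenotype must be case/control")
  x
}

#' Read gene-set file(s)
#'
#' Two supported layouts: a two-column TSV (`set_name`, `gene`), or a
#' one-gene-per-line file whose first line is `#<set name>`.
#'
#' @param path file path.
#' @return named list of [gene_set()]s.
#' @export
read_gene_sets <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    genes <- readLines(path)[-1L]
    nm <- sub("^#\\s*", "", first)
    out <- list(gene_set(nm, genes[nzchar(genes)]))
    names(out) <- nm
    return(out)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene") %in% names(x)))
    stop("gene-set schema error: need columns set_name, gene")
  spl <- split(x$gene, x$set_name)
  out <- lapply(names(spl), function(nm) gene_set(nm, spl[[nm]]))
  names(out) <- names(spl)
  out
}

#' Write a cohort to disk (VCF + annotation + phenotype TSVs)
#'
#' @param dataset a [cohort_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(dataset, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             annotations = file.path(dir, paste0(prefix,
                                                 ".annotations.tsv")),
             phenotypes = file.path(dir, paste0(prefix,
                                                ".phenotypes.tsv")))
  write_vcf(dataset, paths["vcf"])
  if (!is.null(dataset$annotations))
    utils::write.table(dataset$annotations, paths["annotations"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
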