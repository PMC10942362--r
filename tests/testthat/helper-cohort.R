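# Small deterministic cohort builders used across the test files.

# hand-built cohort: explicit genotypes, annotations and metrics
make_toy_cohort <- function(geno, consequences = NULL, genes = NULL,
                            phenotype = NULL, polyphen = NULL,
                            sift = NULL, clinvar = NULL,
                            gq = NULL, dp = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  sample_id <- sprintf("S%03d", seq_len(n))
  if (is.null(phenotype))
    phenotype <- rep(c("case", "control"), length.out = n)
  variants <- data.frame(
    chrom = "chr1", pos = seq_len(m) * 100L, ref = "A", alt = "G",
    vid = paste0("chr1:", seq_len(m) * 100L, ":A:G"),
    qual = rep(100, m), QD = rep(20, m), SOR = rep(1, m),
    MQ = rep(60, m), FS = rep(1, m), MQRankSum = rep(0, m),
    ReadPosRankSum = rep(0, m))
  if (is.null(consequences)) consequences <- rep("missense", m)
  if (is.null(genes)) genes <- rep("GENE1", m)
  if (is.null(polyphen))
    polyphen <- ifelse(consequences == "missense", "D", NA)
  if (is.null(sift))
    sift <- ifelse(consequences == "missense", "deleterious", NA)
  if (is.null(clinvar)) clinvar <- rep(FALSE, m)
  ann <- data.frame(vid = variants$vid, gene = genes,
                    consequence = consequences, polyphen = polyphen,
                    sift = sift, ext_maf = NA_real_,
                    clinvar_pathogenic = clinvar)
  rownames(geno) <- sample_id
  colnames(geno) <- variants$vid
  storage.mode(geno) <- "integer"
  if (!is.null(gq)) dimnames(gq) <- dimnames(geno)
  if (!is.null(dp)) dimnames(dp) <- dimnames(geno)
  cohort_dataset(geno,
                 data.frame(sample_id = sample_id, phenotype = phenotype,
                            cohort = "test"),
                 variants, ann, gq = gq, dp = dp)
}

# random cohort with given per-variant alt frequencies (HWE genotypes)
make_random_cohort <- function(n_case, n_control, freqs, seed = 1,
                               consequences = NULL, genes = NULL) {
  set.seed(seed)
  n <- n_case + n_control
  geno <- vapply(freqs, function(p) rbinom(n, 2, p),
                 integer(n))
  make_toy_cohort(geno, consequences = consequences, genes = genes,
                  phenotype = rep(c("case", "control"),
                                  c(n_case, n_control)))
}

# a small, deterministic VCF text fixture (3 samples x 2 sites)
write_tiny_vcf <- function(path, multiallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "A", "B", "C"), collapse = "\t"),
    paste(c("chr1", "101", ".", "A", "G", "90", "PASS", "QD=21.5",
            "GT:GQ", "0/0:99", "0/1:88", "1/1:77"), collapse = "\t"),
    paste(c("chr2", "202", ".", "T",
            if (multiallelic) "C,G" else "C", "80", "PASS", "QD=18.25",
            "GT:GQ", "0|1:60", "./.:.", "0/0:50"), collapse = "\t"))
  writeLines(lines, path)
  path
}
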