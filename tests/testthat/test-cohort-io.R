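# Cohort container, VCF/annotation/phenotype/gene-set readers, masks.

test_that("cohort_dataset enforces its invariants", {
  g <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  samples <- data.frame(sample_id = c("a", "b"),
                        phenotype = c("case", "control"))
  variants <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                         alt = "G")
  d <- cohort_dataset(g, samples, variants)
  expect_s3_class(d, "cohort_dataset")
  expect_equal(d$variants$vtype, c("snv", "snv"))
  expect_equal(dim(d), c(2L, 2L))
  # bad genotype code
  g2 <- g; g2[1, 1] <- 3L
  expect_error(cohort_dataset(g2, samples, variants), "codes")
  # duplicate sample ids
  expect_error(cohort_dataset(g, data.frame(
    sample_id = c("a", "a"), phenotype = c("case", "control")),
    variants), "duplicate sample")
  # ref == alt
  v2 <- variants; v2$alt <- c("A", "G")
  expect_error(cohort_dataset(g, samples, v2), "alt allele")
})

test_that("read_vcf codes dosage, missing GT, QUAL and INFO metrics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(path)
  part <- read_vcf(path)
  expect_equal(unname(part$geno[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(part$geno[, 2]), c(1L, NA_integer_, 0L))
  expect_equal(part$variants$pos, c(101L, 202L))
  expect_equal(part$variants$QD, c(21.5, 18.25))
  expect_equal(part$variants$qual, c(90, 80))
  expect_equal(unname(part$gq[, 1]), c(99, 88, 77))
  # missing genotype excluded from AC
  d <- assemble_cohort(part, data.frame(
    sample_id = c("A", "B", "C"),
    phenotype = c("case", "case", "control")))
  expect_equal(unname(compute_ac(d)), c(3L, 1L))
})

test_that("multiallelic records are refused with a split-required error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(path, multiallelic = TRUE)
  expect_error(read_vcf(path), "split required")
})

test_that("write_vcf/read_vcf round-trips codes and site metrics", {
  sim <- simulate_cohort(simulation_params(
    n_case = 12, n_control = 30, n_genes = 5, variants_per_gene = 6,
    risk_sets = c(rs = 2), missing_rate = 0.05, seed = 11))
  d <- sim$dataset
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(d, path)
  part <- read_vcf(path)
  idx <- match(d$variants$vid, part$variants$vid)
  expect_false(anyNA(idx))
  expect_equal(unname(part$geno[, idx]), unname(d$geno))
  expect_equal(part$variants$pos[idx], d$variants$pos)
  for (metric in c("QD", "SOR", "MQ", "FS")) {
    expect_equal(part$variants[[metric]][idx],
                 as.numeric(sprintf("%.6g", d$variants[[metric]])),
                 tolerance = 1e-12)
  }
  expect_equal(unname(part$dp[, idx]), unname(d$dp))
})

test_that("read_annotations normalises the schema and vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- data.frame(
    vid = sprintf("chr1:%d:A:G", 1:10 * 10),
    gene = rep(c("G1", "G2"), 5),
    consequence = c("missense_variant", "intergenic", "stop_gained",
                    "splice_acceptor_variant", "synonymous_variant",
                    "Missense_variant", "frameshift_variant",
                    "inframe_insertion", "SYNONYMOUS_VARIANT",
                    "upstream_gene_variant"),
    polyphen = c("D", ".", NA, NA, NA, "B", NA, NA, NA, NA),
    sift = c("deleterious", ".", NA, NA, NA, "tolerated", NA, NA, NA,
             NA),
    ext_maf = c(0.0004, NA, 0.001, NA, 0.2, 0.004, NA, NA, 0.01, NA),
    clinvar = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ann <- read_annotations(path), "other")
  # hand count of the consequence classes
  expect_equal(as.vector(table(ann$consequence)[c(
    "missense", "synonymous", "other", "nonsense")]), c(2L, 2L, 2L, 1L))
  expect_equal(ann$consequence[c(1, 2, 4)],
               c("missense", "other", "splice_acceptor"))
  expect_true(ann$clinvar_pathogenic[3])
  expect_equal(ann$ext_maf[1], 4e-4)
  # missing mandatory column
  write.table(rows[, -2], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(suppressWarnings(read_annotations(path)), "schema")
})

test_that("gene-set and phenotype readers handle both layouts", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set_name\tgene", "s1\tG1", "s1\tG2", "s2\tG3"), p1)
  gs <- read_gene_sets(p1)
  expect_named(gs, c("s1", "s2"))
  expect_equal(gs$s1$genes, c("G1", "G2"))
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# myset", "G1", "G9"), p2)
  gs2 <- read_gene_sets(p2)
  expect_equal(gs2[[1]]$genes, c("G1", "G9"))

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tphenotype", "a\tCase", "b\tcontrol"), p3)
  ph <- read_phenotypes(p3)
  expect_equal(ph$phenotype, c("case", "control"))
})

test_that("mask selection applies consequence, MAF and deleteriousness", {
  set.seed(42)
  n <- 40; m <- 20
  geno <- matrix(rbinom(n * m, 2, 0.004), n, m)
  geno[, 20] <- rep(1L, n)   # common variant: folded MAF 0.5
  cons <- rep(c("missense", "missense", "splice_acceptor", "synonymous",
                "other"), 4)
  poly <- rep(c("D", "B", NA, NA, NA), 4)
  sift <- rep(c("deleterious", "tolerated", NA, NA, NA), 4)
  d <- make_toy_cohort(geno, consequences = cons, polyphen = poly,
                       sift = sift)
  dmg <- default_masks()$damaging
  got <- select_mask_variants(d, dmg)
  # brute-force predicate over the annotation rows
  maf <- compute_maf(d)
  ok <- (cons %in% dmg$consequences) & !is.na(maf) & maf < 0.01 &
    (cons != "missense" | (!is.na(poly) & poly %in% c("P", "D")) |
       (!is.na(sift) & sift == "deleterious"))
  expect_setequal(got, d$variants$vid[ok])
  # benign missense excluded, splice_acceptor included (LoF bypass)
  expect_false(d$variants$vid[2] %in% got)
  expect_true(d$variants$vid[3] %in% got)
  # the two discovery masks never overlap
  ns <- select_mask_variants(d, default_masks()$nonsynonymous)
  syn <- select_mask_variants(d, default_masks()$synonymous)
  expect_length(intersect(ns, syn), 0)
  # deterministic (chrom, pos, alt) order
  pos <- d$variants$pos[match(got, d$variants$vid)]
  expect_true(all(diff(pos) > 0))
})
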