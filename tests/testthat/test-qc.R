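# Variant- and sample-level QC cascade.

test_that("hard filters remove exactly the planted metric violations", {
  set.seed(1)
  geno <- matrix(rbinom(20 * 12, 2, 0.2), 20, 12)
  d <- make_toy_cohort(geno)
  # plant violations: SNV QD at/below 2, SOR >= 3, low QUAL; indel limits
  d$variants$QD[1] <- 1.9
  d$variants$SOR[2] <- 3.4
  d$variants$qual[3] <- 49
  d$variants$MQ[4] <- 39
  d$variants$FS[5] <- 61
  d$variants$MQRankSum[6] <- -13
  d$variants$ReadPosRankSum[7] <- -6.5
  res <- apply_hard_filters(d)
  expect_setequal(res$report$removed_vids, d$variants$vid[1:7])
  expect_equal(res$report$n_retained, 5L)
  expect_equal(sum(res$report$removed_by_metric), 7L)
  # indel thresholds are laxer: SOR 3.4 passes for an indel
  d2 <- make_toy_cohort(geno)
  d2$variants$vtype[2] <- "indel"
  d2$variants$SOR[2] <- 3.4
  expect_equal(apply_hard_filters(d2)$report$n_removed, 0L)
})

test_that("missing site metrics pass vacuously but are flagged", {
  geno <- matrix(rep(0:2, 4), 4, 3)
  d <- make_toy_cohort(geno)
  for (mm in c("QD", "SOR", "MQ", "FS", "MQRankSum", "ReadPosRankSum"))
    d$variants[[mm]][2] <- NA
  res <- apply_hard_filters(d)
  expect_equal(res$report$n_removed, 0L)
  expect_equal(res$report$flagged_missing_metric, d$variants$vid[2])
})

test_that("GQ rule masks genotypes to missing", {
  geno <- matrix(1L, 3, 2)
  gq <- matrix(c(99, 15, 30, 20, 99, 99), 3, 2)
  d <- make_toy_cohort(geno, gq = gq)
  res <- apply_hard_filters(d)
  expect_equal(res$report$n_genotypes_gq_masked, 2L)
  expect_true(is.na(res$dataset$geno[2, 1]))
  expect_true(is.na(res$dataset$geno[1, 2]))  # GQ == 20 is masked too
})

test_that("HWE exact test matches full enumeration and edge cases", {
  expect_equal(hwe_exact_p(100, 0, 0), 1)            # monomorphic
  expect_equal(hwe_exact_p(88, 10, 2), hwe_enum_oracle(88, 10, 2),
               tolerance = 1e-12)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)            # het deficit
  expect_error(hwe_exact_p(0, 0, 0), "no individuals")
  # property: agreement with enumeration over random tables (<=200 alleles)
  set.seed(7)
  for (i in 1:400) {
    n <- sample(2:100, 1)
    na <- sample(0:(2 * n), 1)
    nh_max <- min(na, 2 * n - na)
    nh <- if (nh_max == 0) 0 else sample(seq(na %% 2, nh_max, by = 2), 1)
    naa <- (na - nh) / 2
    nAA <- n - nh - naa
    expect_equal(hwe_exact_p(nAA, nh, naa),
                 hwe_enum_oracle(nAA, nh, naa), tolerance = 1e-12)
  }
})

test_that("site filters apply the ordered rule cascade", {
  set.seed(2)
  n <- 100; m <- 10
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  dp <- matrix(30L, n, m)
  d <- make_toy_cohort(geno, dp = dp)
  d$variants$chrom[1] <- "chrX"                  # autosome rule
  d$geno[1:7, 2] <- NA_integer_                  # 7% missing
  ctrl <- which(d$samples$phenotype == "control")
  d$geno[ctrl, 3] <- 0L                          # HWE: het deficit
  d$geno[ctrl[1:10], 3] <- 2L
  d$dp[1:10, 4] <- 5L                            # 10% below 10x
  d$dp[, 5] <- 80L                               # > 2x mean depth
  res <- site_filters(d)
  expect_equal(unname(res$report$removed_by_rule),
               c(1L, 1L, 1L, 1L, 1L))
  expect_setequal(res$report$removed_vids, d$variants$vid[1:5])
  expect_equal(res$report$n_retained, 5L)
  # removal reasons follow the fixed order
  expect_equal(unname(res$report$removal_reason[d$variants$vid[1]]),
               "autosome")
  # no controls and HWE enabled is a configuration error
  dc <- make_toy_cohort(geno, phenotype = rep("case", n))
  expect_error(suppressWarnings(site_filters(dc)), "control")
})

test_that("A_jk is ~1 for duplicates, ~0 for unrelated, and matches hand
           arithmetic", {
  set.seed(3)
  n <- 30; m <- 5000
  freqs <- runif(m, 0.05, 0.5)
  geno <- vapply(freqs, function(p) rbinom(n, 2, p), integer(n))
  geno[2, ] <- geno[1, ]                          # duplicate pair
  d <- make_toy_cohort(geno)
  rel <- relatedness_ajk(d)
  expect_gt(rel$ajk[1, 2], 0.9)
  expect_lt(rel$ajk[1, 2], 1.1)
  off <- rel$ajk[3:10, 11:20]
  expect_true(all(abs(off) < 0.1))
  expect_equal(rel$flagged_pairs$id1, "S001")
  expect_equal(rel$flagged_pairs$id2, "S002")
  # ties in missingness resolve to the lexicographically larger id
  expect_equal(rel$remove, "S002")
  # symmetry
  expect_equal(rel$ajk[1, 2], rel$ajk[2, 1])
  expect_true(is.na(rel$ajk[1, 1]))
  # 2 samples x 3 variants hand example
  g2 <- matrix(c(0L, 1L, 1L, 1L, 2L, 0L), 2, 3)
  d2 <- make_toy_cohort(g2)
  p <- colMeans(g2) / 2
  hand <- mean((g2[1, ] - 2 * p) * (g2[2, ] - 2 * p) /
                 (2 * p * (1 - p)))
  expect_equal(relatedness_ajk(d2)$ajk[1, 2], hand)
})

test_that("sample outliers: z-rule, zero variance, missingness ceiling", {
  s <- data.frame(sample_id = sprintf("S%02d", 1:20),
                  tstv = rep(2, 20), hethom = rep(1.5, 20),
                  missing_rate = rep(0.01, 20))
  expect_length(sample_outliers(s), 0)            # zero variance
  set.seed(4)
  s$tstv <- rnorm(20, 2, 0.1)
  s$tstv[7] <- 2 + 5 * sd(s$tstv[-7])
  out <- sample_outliers(s)
  expect_equal(out, "S07")
  s$missing_rate[3] <- 0.3
  expect_setequal(sample_outliers(s), c("S07", "S03"))
})

test_that("ultra-rare balance test is exact and directional", {
  # 100 singletons at f = 0.5, 50 in cases: the mode, p = 1
  g <- matrix(0L, 20, 100)
  for (j in 1:100) g[ifelse(j <= 50, 1, 11) + (j %% 10), j] <- 1L
  d <- make_toy_cohort(g, phenotype = rep(c("case", "control"),
                                          each = 10))
  res <- ultra_rare_balance_test(d, 1)
  expect_equal(res$n_alleles, 100L)
  expect_equal(res$case_alleles, 50L)
  expect_equal(res$p_value, 1)
  # agreement with the exact binomial enumeration at skewed f
  res2 <- ultra_rare_balance_test(d, 2)
  expect_true(res2$untestable)
  # oracle check on a hand table via the same pooled construction
  expect_equal(binom_two_sided_oracle(40, 300, 496 / 3012),
               binom.test(40, 300, 496 / 3012)$p.value,
               tolerance = 1e-12)
})

test_that("control singleton inflation is detected by the balance test", {
  hits <- 0L
  for (r in 1:40) {
    sim <- simulate_cohort(simulation_params(
      n_case = 150, n_control = 450, n_genes = 25,
      variants_per_gene = 14,
      maf_spectrum = c(singleton = 0.6, rare = 0.3, common = 0.1),
      risk_sets = c(rs = 5), carrier_or = 1,
      control_singleton_inflation = 2, with_depth = FALSE,
      seed = 100 + r))
    res <- ultra_rare_balance_test(sim$dataset, 1)
    if (res$p_value < 0.05 && res$direction == "control_excess")
      hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})

test_that("singleton exclusion uses combined-cohort AC = 1", {
  set.seed(5)
  geno <- matrix(0L, 50, 50)
  singles <- 1:7
  for (j in singles) geno[j, j] <- 1L      # AC = 1
  geno[1, 8] <- 2L                         # hom carrier: AC = 2, kept
  for (j in 9:50) geno[sample(50, 5), j] <- 1L
  d <- make_toy_cohort(geno)
  res <- exclude_singletons(d)
  expect_equal(res$n_removed, 7L)
  expect_setequal(res$removed_vids, d$variants$vid[singles])
  expect_true(d$variants$vid[8] %in% res$dataset$variants$vid)
  expect_equal(ncol(res$dataset$geno), 43L)
})

test_that("MAF computation folds and handles missing calls", {
  geno <- matrix(0L, 500, 3)
  geno[1, 1] <- 1L                     # AC 1 / 1000 chromosomes
  geno[, 2] <- 2L; geno[1, 2] <- 1L    # f = 0.999 folds to 0.001
  geno[, 3] <- NA_integer_             # no calls
  d <- make_toy_cohort(geno)
  maf <- compute_maf(d)
  expect_equal(unname(maf), c(0.001, 0.001, NA_real_))
  # brute-force count check on a random matrix incl. missing entries
  set.seed(6)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE,
                     prob = c(.7, .15, .05, .1)), 20, 10)
  d2 <- make_toy_cohort(g)
  maf2 <- compute_maf(d2, "cases")
  case_rows <- d2$samples$phenotype == "case"
  brute <- apply(g[case_rows, ], 2, function(col) {
    f <- sum(col, na.rm = TRUE) / (2 * sum(!is.na(col)))
    min(f, 1 - f)
  })
  expect_equal(unname(maf2), unname(brute))
})
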