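# Cochran-Armitage trend, variable-threshold RVTT, Cauchy combination.

test_that("Cochran-Armitage trend: proportional rows, oracle, affine
           invariance", {
  # proportional rows: no trend
  tab0 <- rbind(case = c(40, 20, 10), control = c(80, 40, 20))
  z0 <- ca_trend(tab0)
  expect_equal(z0$Z, 0)
  expect_equal(z0$p_two_sided, 1)
  # integer-arithmetic oracle
  tab <- rbind(case = c(80, 15, 5), control = c(90, 9, 1))
  z <- ca_trend(tab, 0:2)
  expect_equal(z$Z, ca_trend_oracle_z(tab, 0:2), tolerance = 1e-12)
  # affine score invariance s -> a s + b, a > 0
  z2 <- ca_trend(tab, 3 * (0:2) + 7)
  expect_equal(z$Z, z2$Z, tolerance = 1e-12)
  # degenerate: all mass in one category
  expect_true(ca_trend(rbind(c(5, 0), c(7, 0)))$untestable)
  expect_error(ca_trend(rbind(c(1, 2), c(0, 0))), "non-empty")
})

test_that("trend statistic matches exact arithmetic on random tables", {
  set.seed(30)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    tab <- matrix(rpois(2 * k, 20), 2, k)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    s <- 0:(k - 1)
    z <- ca_trend(tab, s)
    if (isTRUE(z$untestable)) next
    expect_equal(z$Z, ca_trend_oracle_z(tab, s), tolerance = 1e-11)
  }
})

test_that("qualifying counts sum dosages and are monotone in threshold", {
  geno <- rbind(c(1L, 1L, 2L, 0L),
                c(0L, NA, 1L, 2L),
                c(0L, 0L, 0L, 0L),
                c(0L, 0L, 0L, 0L))
  d <- make_toy_cohort(geno, genes = rep("GENE1", 4),
                       phenotype = c("case", "control", "control",
                                     "control"))
  gs <- gene_set("s", "GENE1")
  mask <- mask_spec("m", "missense", maf_max = 0.5)
  cnt <- qualifying_counts(d, gs, mask, threshold = 0.5)
  # sample 1: het at 2 qualifying variants, hom at 1 -> 4
  expect_equal(as.integer(cnt[1]), 4L)
  expect_equal(as.integer(cnt[2]), 3L)    # missing contributes 0
  maf <- compute_maf(d)
  # brute-force double loop at each threshold; monotone in t
  prev <- rep(0L, 4)
  for (t in sort(unique(maf))) {
    ct <- qualifying_counts(d, gs, mask, t)
    brute <- integer(4)
    for (i in 1:4) for (j in 1:4)
      if (!is.na(maf[j]) && maf[j] <= t && !is.na(geno[i, j]))
        brute[i] <- brute[i] + geno[i, j]
    expect_equal(as.integer(ct), brute)
    expect_true(all(ct >= prev))
    prev <- ct
  }
})

test_that("RVTT exhaustive permutation p equals full enumeration", {
  set.seed(31)
  n <- 8; m <- 6
  geno <- matrix(rbinom(n * m, 2, 0.3), n, m)
  geno[1:3, 1] <- 2L   # put some signal in cases
  d <- make_toy_cohort(geno, genes = rep("GENE1", m),
                       phenotype = rep(c("case", "control"), each = 4))
  gs <- gene_set("s", "GENE1")
  cfg <- rvtt_config(mask = mask_spec("m", "missense", maf_max = 0.5),
                     maf_max = 0.5, exhaustive = TRUE,
                     max_count_category = 3L)
  res <- rvtt(d, gs, cfg)
  maf <- compute_maf(d)
  oracle <- rvtt_exhaustive_oracle(geno, unname(maf),
                                   sort(unique(unname(maf))),
                                   n_case = 4, cap = 3L)
  expect_equal(res$T_max, oracle$T_max, tolerance = 1e-12)
  expect_equal(res$p_perm, oracle$p, tolerance = 1e-12)
  expect_equal(res$B_effective, choose(8, 4))
})

test_that("RVTT results are reproducible and T_max dominates the grid", {
  sim <- simulate_cohort(simulation_params(
    n_case = 80, n_control = 240, n_genes = 8, variants_per_gene = 10,
    risk_sets = c(rs = 4), carrier_or = 2,
    control_singleton_inflation = 1, with_depth = FALSE, seed = 55))
  cfg <- rvtt_config(B = 300, seed = 9)
  r1 <- rvtt(sim$dataset, sim$truth$risk_sets$rs, cfg)
  r2 <- rvtt(sim$dataset, sim$truth$risk_sets$rs, cfg)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$T_max, max(r1$grid$Z))
  expect_true(all(r1$T_max >= r1$grid$Z))
  expect_equal(r1$chosen_threshold,
               r1$grid$threshold[which.max(r1$grid$Z)])
  expect_gte(r1$p_perm, 1 / (cfg$B + 1))
})

test_that("RVTT distinguishes untestable gene sets from p = 1", {
  geno <- matrix(0L, 10, 2)
  d <- make_toy_cohort(geno, genes = c("GENE1", "GENE1"))
  res <- rvtt(d, gene_set("s", "GENE1"),
              rvtt_config(B = 100, seed = 1))
  expect_true(res$untestable)
  expect_null(res$p_perm)
})

test_that("single-threshold grid reduces to a fixed-threshold trend
           permutation test", {
  set.seed(32)
  n <- 60
  geno <- matrix(rbinom(n * 5, 2, 0.1), n, 5)  # all MAFs distinct? force:
  d <- make_toy_cohort(geno, genes = rep("GENE1", 5),
                       phenotype = rep(c("case", "control"),
                                       c(20, 40)))
  gs <- gene_set("s", "GENE1")
  maf <- sort(unique(compute_maf(d)))
  maf <- maf[maf > 0]
  # ceiling between the two smallest MAFs: the grid has one threshold
  cut <- mean(maf[1:2])
  cfg <- rvtt_config(mask = mask_spec("m", "missense", maf_max = 0.5),
                     maf_max = cut, B = 400, seed = 4,
                     max_count_category = 3L)
  res <- rvtt(d, gs, cfg)
  expect_false(isTRUE(res$untestable))
  expect_equal(nrow(res$grid), 1L)
  expect_equal(res$chosen_threshold, maf[1])
  # equals the fixed-threshold Cochran-Armitage permutation test
  cnt <- qualifying_counts(d, gs, mask_spec("m", "missense",
                                            maf_max = 0.5), maf[1])
  cat_i <- pmin(cnt, 3L)
  lev <- sort(unique(cat_i))
  y <- d$samples$phenotype == "case"
  tab <- rbind(vapply(lev, function(l) sum(cat_i == l & y), numeric(1)),
               vapply(lev, function(l) sum(cat_i == l & !y), numeric(1)))
  expect_equal(res$T_max, ca_trend(tab, lev)$Z, tolerance = 1e-12)
})

test_that("Cauchy combination: identities, precision oracle, invariances", {
  expect_equal(cct_combine(0.2), 0.2, tolerance = 1e-14)
  expect_equal(cct_combine(rep(0.5, 4)), 0.5, tolerance = 1e-14)
  # reference values from 50-digit arithmetic
  expect_equal(cct_combine(c(1e-4, 0.3, 0.6)),
               0.00029996207378951914957542920771929546, tolerance = 1e-12)
  expect_equal(cct_combine(c(0.01, 0.5, 0.9), weights = c(1, 2, 3)),
               0.082645369969574280339185413581986083, tolerance = 1e-12)
  expect_equal(cct_combine(c(0.04, 0.04)), 0.04, tolerance = 1e-12)
  expect_equal(cct_combine(c(1e-12, 0.999)),
               2.0000000019999934222593704134215987e-12, tolerance = 1e-9)
  # agreement with the Cauchy-distribution form on random inputs
  set.seed(33)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    p <- runif(k, 1e-6, 1 - 1e-6)
    w <- runif(k, 0.1, 2)
    oracle <- pcauchy(sum(w / sum(w) * qcauchy(p, lower.tail = FALSE)),
                      lower.tail = FALSE)
    expect_equal(cct_combine(p, w), oracle, tolerance = 1e-10)
  }
  # order invariance and weight rescaling
  p <- c(0.03, 0.4, 0.77); w <- c(1, 2, 3)
  expect_equal(cct_combine(p, w), cct_combine(rev(p), rev(w)))
  expect_equal(cct_combine(p, w), cct_combine(p, 10 * w))
  expect_error(cct_combine(c(0.5, 1)), "strictly inside")
  expect_error(cct_combine(c(0, 0.5)), "strictly inside")
})

test_that("meta-analysis combines cohorts and handles untestable ones", {
  simA <- simulate_cohort(simulation_params(
    n_case = 60, n_control = 180, n_genes = 6, variants_per_gene = 10,
    risk_sets = c(rs = 3), carrier_or = 2,
    control_singleton_inflation = 1, with_depth = FALSE, seed = 60))
  simB <- simulate_cohort(simulation_params(
    n_case = 60, n_control = 180, n_genes = 6, variants_per_gene = 10,
    risk_sets = c(rs = 3), carrier_or = 2,
    control_singleton_inflation = 1, with_depth = FALSE, seed = 61))
  gs <- simA$truth$risk_sets$rs
  cfg <- rvtt_config(B = 200, seed = 2)
  meta <- rvtt_meta(list(A = simA$dataset, B = simB$dataset), gs,
                    config = cfg,
                    masks = default_masks()[c("missense", "synonymous")])
  expect_equal(nrow(meta$meta), 2L)
  mis <- meta$meta[meta$meta$mask == "missense", ]
  pa <- meta$per_cohort[meta$per_cohort$mask == "missense", "p_perm"]
  expect_equal(mis$p_cct, cct_combine(pmin(pa, 1 - 1e-12)),
               tolerance = 1e-12)
  # one cohort untestable: meta p equals the other cohort's p
  empty <- simA$dataset
  empty$annotations$consequence <- "other"
  meta2 <- rvtt_meta(list(A = empty, B = simB$dataset), gs,
                     config = cfg,
                     masks = default_masks()["missense"])
  pB <- meta2$per_cohort$p_perm[meta2$per_cohort$cohort == "B"]
  expect_equal(meta2$meta$p_cct, pB, tolerance = 1e-9)
  expect_equal(meta2$meta$n_cohorts, 1L)
})
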