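# Gene-level collapsing tests: CMC carrier collapsing, a SKAT-O style
# combined burden/variance-component score test, and CAST.

#' Gene-test configuration
#'
#' @param mask a [mask_spec()] defining qualifying variants.
#' @param maf_max MAF ceiling (default 0.01; also used for weights).
#' @param weights_beta Beta-density weight parameters `(a1, a2)`; the
#'   default (1, 25) up-weights the rarest variants.
#' @param rho_grid grid of burden/variance-component mixing values; must
#'   contain 0 (pure SKAT) and 1 (pure burden).
#' @param min_variants minimum qualifying variants per gene (genes below
#'   this are reported untested; single-variant genes belong in the
#'   single-variant scan).
#' @param grid_combine how the per-rho p-values are combined: `"cauchy"`
#'   (default; Cauchy combination across the grid, calibrated under the
#'   null) or `"bonferroni"` (minimum p times grid size, conservative).
#' @return a `gene_test_config` object.
#' @export
gene_test_config <- function(mask = default_masks()$nonsynonymous,
                             maf_max = 0.01,
                             weights_beta = c(1, 25),
                             rho_grid = c(0, 0.01, 0.04, 0.09, 0.16,
                                          0.25, 0.5, 1),
                             min_variants = 2L,
                             grid_combine = c("cauchy", "bonferroni")) {
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1), 0 %in% rho_grid,
            1 %in% rho_grid, min_variants >= 1)
  structure(list(mask = mask, maf_max = maf_max,
                 weights_beta = weights_beta, rho_grid = sort(rho_grid),
                 min_variants = as.integer(min_variants),
                 grid_combine = match.arg(grid_combine)),
            class = "gene_test_config")
}

#' CMC collapsing of a gene's qualifying variants
#'
#' Collapses the qualifying variants of one gene into a per-sample
#' carrier indicator (1 if the sample carries at least one alt allele
#' across the qualifying variants). Missing genotypes are imputed to 0
#' alt alleles -- the conservative choice for rare variants -- and the
#' per-sample count of missing genotypes is reported. The raw qualifying
#' submatrix is returned for the variance-component part of the gene
#' test.
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param gene gene symbol.
#' @param mask a [mask_spec()].
#' @param maf_group group on which MAF eligibility is computed.
#' @param maf optional precomputed MAF vector (named by vid).
#' @return a `gene_burden` list: `gene`, `vids`, `carrier` (0/1 per
#'   sample), `dosage` (summed alt alleles per sample), `G` (samples x
#'   qualifying-variants dosage matrix, missing as 0), `n_missing` per
#'   sample; or an untested record (`untested = TRUE, reason`).
#' @export
collapse_cmc <- function(dataset, gene, mask, maf_group = "combined",
                         maf = NULL) {
  vids <- select_mask_variants(dataset, mask,
                               gene_filter = gene_set(gene, gene),
                               maf_group = maf_group, maf = maf)
  if (length(vids) == 0L)
    return(list(gene = gene, untested = TRUE,
                reason = "no qualifying variants"))
  G <- dataset$geno[, vids, drop = FALSE]
  n_missing <- rowSums(is.na(G))
  G[is.na(G)] <- 0L
  list(gene = gene, untested = FALSE, vids = vids,
       carrier = as.integer(rowSums(G) > 0),
       dosage = rowSums(G), G = G, n_missing = n_missing)
}

# Beta-density variant weights on MAF (SKAT convention)
beta_maf_weights <- function(maf, a1 = 1, a2 = 25) {
  stats::dbeta(maf, a1, a2)
}

# tail of Q ~ sum(lambda_i chi^2_1) by four-moment matching to a scaled
# noncentral chi-square (Liu-style modified matching)
mixture_chisq_p <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2 * (l + 2 * delta))
  t_star <- (q - mu_q) / sigma_q * sigma_x + mu_x
  stats::pchisq(t_star, df = l, ncp = delta, lower.tail = FALSE)
}

# score statistics for one gene: returns per-rho Q and p-values
skato_grid_p <- function(G, y, weights, rho_grid) {
  n <- length(y)
  mu <- mean(y)
  # finite-population (permutation-consistent) score variance
  sigma2 <- mu * (1 - mu) * n / (n - 1)
  S <- crossprod(G, y - mu)[, 1]               # per-variant scores
  Gc <- sweep(G, 2L, colMeans(G))
  V <- sigma2 * crossprod(Gc)                  # cov(S) under the null
  w <- weights
  Q_skat <- sum((w * S)^2)
  Q_burden <- sum(w * S)^2
  m <- length(S)
  Vw <- (w %o% w) * V                          # cov of weighted scores
  out <- data.frame(rho = rho_grid, Q = NA_real_, p = NA_real_)
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    Q <- (1 - rho) * Q_skat + rho * Q_burden
    R <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
    lambda <- eigen(R %*% Vw, symmetric = FALSE, only.values = TRUE)$values
    lambda <- Re(lambda[Re(lambda) > 0])
    out$Q[i] <- Q
    out$p[i] <- mixture_chisq_p(Q, lambda)
  }
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out
}

#' SKAT-O style combined burden / variance-component gene test
#'
#' Score-based omnibus test under an intercept-only binomial null
#' (fitted null mean = case fraction). Per-variant scores are weighted by
#' the Beta(1, 25) density of the MAF; for each mixing value rho on the
#' grid, `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` is referred to its
#' weighted mixture-of-chi-squares null via four-moment matching, and the
#' per-rho p-values are combined across the grid (Cauchy combination by
#' default, or the conservative Bonferroni-over-grid bound).
#'
#' @param burden a [collapse_cmc()] result.
#' @param phenotype per-sample phenotype vector (`"case"`/`"control"`)
#'   aligned with the burden's rows.
#' @param config a [gene_test_config()].
#' @param maf optional per-variant MAF for the weights; computed from the
#'   burden submatrix when omitted.
#' @return list: `gene`, `p` (combined), `p_grid` (per-rho data.frame),
#'   `n_variants`; or untested record.
#' @export
skato_test <- function(burden, phenotype, config = gene_test_config(),
                       maf = NULL) {
  if (isTRUE(burden$untested)) return(burden)
  G <- burden$G
  if (ncol(G) < config$min_variants)
    return(list(gene = burden$gene, untested = TRUE,
                reason = "fewer qualifying variants than min_variants"))
  if (all(G == 0))
    return(list(gene = burden$gene, untested = TRUE,
                reason = "degenerate (all-zero) genotype submatrix"))
  y <- as.integer(phenotype == "case")
  if (length(unique(y)) < 2L) stop("both phenotype classes required")
  if (is.null(maf)) {
    f <- colMeans(G) / 2
    maf <- pmin(f, 1 - f)
  }
  w <- beta_maf_weights(pmax(maf, 1e-8), config$weights_beta[1],
                        config$weights_beta[2])
  grid <- skato_grid_p(G, y, w, config$rho_grid)
  p_min <- min(grid$p)
  p <- switch(config$grid_combine,
              bonferroni = min(1, p_min * nrow(grid)),
              cauchy = cct_combine(pmin(pmax(grid$p, 1e-15), 1 - 1e-15)))
  list(gene = burden$gene, untested = FALSE, p = p, p_grid = grid,
       p_min_grid = p_min, n_variants = ncol(G), vids = burden$vids)
}

#' Gene-level scan over a mask battery
#'
#' Runs the SKAT-O style test for every gene under each mask. Multiple-
#' testing adjustments (Bonferroni and, optionally, permutation FDR) are
#' computed within each mask battery separately, so the synonymous
#' channel acts as an independent negative control.
#'
#' @param dataset an annotated [cohort_dataset()] (post-QC, singletons
#'   excluded in the standard pipeline order).
#' @param genes genes to test (default: all annotated genes).
#' @param config a [gene_test_config()]; its mask is replaced per battery.
#' @param masks named list of [mask_spec()]s (default nonsynonymous +
#'   synonymous).
#' @param n_perm_fdr label permutations for the empirical FDR (0 skips).
#' @param seed RNG seed for the permutation null.
#' @return data.frame: gene, mask, n_variants, p_raw, p_bonferroni,
#'   p_fdr (NA when not computed), untested flag; sorted by mask then p.
#' @export
gene_scan <- function(dataset, genes = NULL, config = gene_test_config(),
                      masks = default_masks()[c("nonsynonymous",
                                                "synonymous")],
                      n_perm_fdr = 0L, seed = NULL) {
  if (is.null(dataset$annotations)) stop("annotations required")
  if (is.null(genes)) genes <- sort(unique(dataset$annotations$gene))
  phenotype <- dataset$samples$phenotype
  maf <- compute_maf(dataset, "combined")
  res <- list()
  for (mk in names(masks)) {
    cfg <- config; cfg$mask <- masks[[mk]]
    burdens <- lapply(genes, function(g)
      collapse_cmc(dataset, g, cfg$mask, maf = maf))
    batt <- gene_battery_p(burdens, genes, phenotype, cfg)
    tested <- !is.na(batt$p_raw)
    batt$p_bonferroni <- NA_real_
    batt$p_bonferroni[tested] <- bonferroni_adjust(batt$p_raw[tested],
                                                   sum(tested))
    batt$p_fdr <- NA_real_
    if (n_perm_fdr > 0L && any(tested)) {
      if (!is.null(seed)) set.seed(seed)
      n <- length(phenotype)
      null_p <- t(vapply(seq_len(n_perm_fdr), function(b) {
        perm <- phenotype[sample.int(n)]
        gene_battery_p(burdens[tested], genes[tested], perm, cfg)$p_raw
      }, numeric(sum(tested))))
      batt$p_fdr[tested] <- permutation_fdr(batt$p_raw[tested], null_p)
    }
    batt$mask <- mk
    res[[mk]] <- batt
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$mask, out$p_raw), , drop = FALSE]
}

# one battery: p per gene from precollapsed burdens under given labels
gene_battery_p <- function(burdens, genes, phenotype, cfg) {
  rows <- mapply(function(b, g) {
    r <- skato_test(b, phenotype, cfg)
    data.frame(gene = g,
               n_variants = if (isTRUE(r$untested)) 0L else r$n_variants,
               p_raw = if (isTRUE(r$untested)) NA_real_ else r$p,
               untested = isTRUE(r$untested),
               reason = if (isTRUE(r$untested)) r$reason else "")
  }, burdens, genes, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Cohort Allelic Sums Test (CAST)
#'
#' One-sided Fisher exact test on carrier counts between an arbitrary
#' binary sample partition (e.g. mutation-carrier cases vs all other
#' cases): a sample is a carrier if it bears at least one alt allele
#' across the qualifying variants. Works per gene, per gene set, or per
#' single variant (pass a single-gene mask selection of one variant via
#' `vids`).
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param group1,group2 character vectors of sample ids forming the two
#'   groups (enrichment is tested in `group1`).
#' @param genes gene symbol(s) defining the unit (ignored when `vids`
#'   given).
#' @param mask a [mask_spec()].
#' @param vids optional explicit variant ids (per-variant CAST).
#' @return list: `p`, the 2x2 carrier table, and the unit label.
#' @export
cast_test <- function(dataset, group1, group2, genes = NULL,
                      mask = default_masks()$nonsynonymous, vids = NULL) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2)))
    stop("groups overlap")
  if (is.null(vids)) {
    if (is.null(genes)) stop("give either genes or vids")
    vids <- select_mask_variants(dataset, mask,
                                 gene_filter = gene_set("unit", genes))
    unit <- paste(genes, collapse = ",")
  } else unit <- paste(vids, collapse = ",")
  if (!length(vids))
    return(list(unit = unit, untested = TRUE,
                reason = "no qualifying variants"))
  G <- dataset$geno[, vids, drop = FALSE]
  G[is.na(G)] <- 0L
  carrier <- rowSums(G) > 0
  names(carrier) <- rownames(dataset$geno)
  a <- sum(carrier[group1]); b <- length(group1) - a
  c_ <- sum(carrier[group2]); d <- length(group2) - c_
  list(unit = unit, untested = FALSE,
       p = fisher_one_sided(a, b, c_, d),
       table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("group1", "group2"),
                                      c("carrier", "non_carrier"))))
}
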