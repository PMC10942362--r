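# Rare Variant Trend Test: variable-MAF-threshold Cochran-Armitage trend
# on per-sample qualifying-variant counts with a permutation null, plus
# Cauchy combination meta-analysis across cohorts.

#' RVTT configuration
#'
#' @param mask a [mask_spec()] selecting qualifying consequences.
#' @param maf_max MAF ceiling for the variable-threshold grid (default
#'   0.01).
#' @param B number of case/control label permutations (default 10000).
#' @param seed RNG seed (required for random permutations).
#' @param max_count_category optional cap on the count categories; by
#'   default the cap is the 99th percentile of the nonzero per-sample
#'   counts, never below 3, to avoid sparse-tail instability.
#' @param maf_group group on which MAFs are computed: `"combined"`
#'   (default; pooled case+control frequency) or `"controls"`.
#' @param exhaustive enumerate all distinct label assignments instead of
#'   sampling (only feasible for tiny cohorts).
#' @param two_sided maximize `|Z|` (chi-square style) across thresholds
#'   instead of the default one-sided signed Z (case-ward trend).
#' @return an `rvtt_config` object.
#' @export
rvtt_config <- function(mask = default_masks()$missense, maf_max = 0.01,
                        B = 10000L, seed = NULL,
                        max_count_category = NULL,
                        maf_group = c("combined", "controls"),
                        exhaustive = FALSE, two_sided = FALSE) {
  stopifnot(B >= 100L || exhaustive, maf_max > 0, maf_max <= 0.5)
  structure(list(mask = mask, maf_max = maf_max, B = as.integer(B),
                 seed = seed, max_count_category = max_count_category,
                 maf_group = match.arg(maf_group),
                 exhaustive = isTRUE(exhaustive),
                 two_sided = isTRUE(two_sided)),
            class = "rvtt_config")
}

#' Cochran-Armitage trend test
#'
#' Linear-trend test on a 2 x k contingency table of phenotype by ordered
#' category. With `r_i` cases of `n_i` samples in category i, scores
#' `s_i`, `R` total cases and `N` total samples:
#' `U = sum_i s_i (r_i - n_i R / N)` and
#' `Var(U) = R (N - R) / N^2 * (N sum s_i^2 n_i - (sum s_i n_i)^2) / (N - 1)`
#' (the hypergeometric/permutation variance with an `N - 1` denominator).
#' `Z = U / sqrt(Var U)`; positive Z means cases are shifted toward
#' higher-scored categories.
#'
#' @param table 2 x k matrix of counts; row 1 = cases, row 2 = controls.
#' @param scores numeric category scores (default the category indices
#'   `0:(k-1)`).
#' @return list: `Z` (signed), `chi2 = Z^2`, `p_two_sided` from the normal
#'   tail; `untestable = TRUE` when the variance is zero (all mass in one
#'   category).
#' @export
ca_trend <- function(table, scores = NULL) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("need a 2 x k table with k >= 2")
  k <- ncol(table)
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(scores) != k) stop("scores length must match columns")
  r <- table[1L, ]; n_i <- colSums(table)
  R <- sum(r); N <- sum(n_i)
  if (R == 0 || R == N) stop("both phenotype rows must be non-empty")
  U <- sum(scores * (r - n_i * R / N))
  varU <- R * (N - R) / N^2 *
    (N * sum(scores^2 * n_i) - sum(scores * n_i)^2) / (N - 1)
  if (varU <= 0)
    return(list(untestable = TRUE, Z = NA_real_, chi2 = NA_real_,
                p_two_sided = NA_real_))
  Z <- U / sqrt(varU)
  list(untestable = FALSE, Z = Z, chi2 = Z^2,
       p_two_sided = 2 * stats::pnorm(-abs(Z)))
}

#' Per-sample qualifying-variant counts at a MAF threshold
#'
#' For each sample, the number of alt alleles summed over the gene-set
#' variants that match the mask consequences (and deleteriousness
#' predicate) and have MAF at or below the threshold. Missing genotypes
#' contribute 0.
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param geneset a [gene_set()].
#' @param mask a [mask_spec()].
#' @param threshold MAF threshold in (0, mask ceiling].
#' @param maf_group group on which MAF is computed.
#' @return integer vector of per-sample counts (named by sample id);
#'   attribute `n_variants` gives the number of qualifying variants
#'   (0 means no signal at this threshold).
#' @export
qualifying_counts <- function(dataset, geneset, mask, threshold,
                              maf_group = "combined") {
  vids <- select_mask_variants(dataset, mask, gene_filter = geneset,
                               maf_group = maf_group)
  maf <- compute_maf(dataset, maf_group)[vids]
  vids <- vids[!is.na(maf) & maf <= threshold]
  if (!length(vids)) {
    out <- stats::setNames(integer(nrow(dataset$geno)),
                           rownames(dataset$geno))
    attr(out, "n_variants") <- 0L
    return(out)
  }
  G <- dataset$geno[, vids, drop = FALSE]
  G[is.na(G)] <- 0L
  out <- as.integer(rowSums(G))
  names(out) <- rownames(dataset$geno)
  attr(out, "n_variants") <- length(vids)
  out
}

# default top-bin cap: 99th percentile of per-sample counts, >= 3
default_count_cap <- function(counts) {
  max(3L, as.integer(stats::quantile(counts, 0.99, type = 1)))
}

#' Rare Variant Trend Test
#'
#' Variable-threshold Cochran-Armitage trend test on a gene set. The
#' threshold grid is the set of distinct MAFs of the mask-qualifying
#' gene-set variants (truncated at `maf_max`). At each threshold the
#' per-sample qualifying-variant counts are binned (0, 1, ..., cap with
#' the top bin aggregated) and the signed trend statistic Z is computed;
#' the test statistic is `T_max = max_t Z(t)` (one-sided, case-ward
#' trend). The p-value is the permutation estimate
#' `(1 + #{b : T_max(b) >= T_max}) / (B + 1)` where each permutation
#' reshuffles the case/control labels and re-maximizes over the full
#' threshold grid.
#'
#' @param dataset an annotated [cohort_dataset()].
#' @param geneset a [gene_set()].
#' @param config an [rvtt_config()].
#' @param maf optional precomputed per-variant MAF (named by vid) on the
#'   configured `maf_group`; computed when omitted.
#' @return an `rvtt_result` list: `T_max`, `chosen_threshold`, `p_perm`,
#'   `contingency` (2 x k table at the chosen threshold), `B_effective`,
#'   `grid` (per-threshold data.frame), `geneset`, `mask`; or an
#'   untestable record when no threshold admits a testable table.
#' @export
rvtt <- function(dataset, geneset, config = rvtt_config(), maf = NULL) {
  mask <- config$mask
  mask$maf_max <- min(mask$maf_max, config$maf_max)
  if (is.null(maf)) maf <- compute_maf(dataset, config$maf_group)
  maf_all <- maf
  vids <- select_mask_variants(dataset, mask, gene_filter = geneset,
                               maf_group = config$maf_group,
                               maf = maf_all)
  maf <- maf_all[vids]
  ok <- !is.na(maf) & maf <= config$maf_max
  vids <- vids[ok]; maf <- maf[ok]
  base <- list(geneset = geneset$name, mask = mask$name,
               B_effective = 0L)
  if (!length(vids)) {
    base$untestable <- TRUE; base$reason <- "no qualifying variants"
    return(structure(base, class = "rvtt_result"))
  }
  thresholds <- sort(unique(maf))
  G <- dataset$geno[, vids, drop = FALSE]
  G[is.na(G)] <- 0
  y <- as.integer(dataset$samples$phenotype == "case")
  N <- length(y); R <- sum(y)
  if (R == 0L || R == N) stop("both phenotype groups required")

  # per-threshold binned category indicators, stacked column-wise
  ind <- matrix(maf <= rep(thresholds, each = length(maf)),
                nrow = length(maf))
  counts <- G %*% ind                      # n x T qualifying counts
  blocks <- vector("list", length(thresholds))
  for (t in seq_along(thresholds)) {
    ct <- counts[, t]
    cap <- if (!is.null(config$max_count_category))
      config$max_count_category else default_count_cap(ct)
    cat_t <- pmin(ct, cap)
    lev <- sort(unique(cat_t))
    if (length(lev) < 2L) { blocks[[t]] <- NULL; next }
    Imat <- outer(cat_t, lev, `==`) * 1
    blocks[[t]] <- list(threshold = thresholds[t], scores = lev,
                        Imat = Imat, n_i = colSums(Imat))
  }
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) {
    base$untestable <- TRUE
    base$reason <- "no threshold yields a testable table"
    return(structure(base, class = "rvtt_result"))
  }

  # fixed per-block constants for the Z statistic
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    s <- b$scores; n_i <- b$n_i
    b$e <- R / N * sum(s * n_i)
    varU <- R * (N - R) / N^2 *
      (N * sum(s^2 * n_i) - sum(s * n_i)^2) / (N - 1)
    b$sd <- sqrt(varU)
    blocks[[i]] <- b
  }
  I_all <- do.call(cbind, lapply(blocks, `[[`, "Imat"))
  block_id <- rep(seq_along(blocks),
                  vapply(blocks, function(b) length(b$scores), integer(1)))
  s_all <- unlist(lapply(blocks, `[[`, "scores"))
  e_all <- vapply(blocks, `[[`, numeric(1), "e")
  sd_all <- vapply(blocks, `[[`, numeric(1), "sd")

  z_stat <- function(case_cat_counts) {
    # case_cat_counts: B x K matrix of case counts per stacked category
    su <- (case_cat_counts * rep(s_all, each = nrow(case_cat_counts)))
    U <- t(rowsum(t(su), block_id)) - rep(e_all, each = nrow(su))
    Z <- U / rep(sd_all, each = nrow(U))
    if (config$two_sided) abs(Z) else Z
  }
  obs_counts <- matrix(crossprod(y, I_all), nrow = 1)
  Z_obs <- z_stat(obs_counts)[1, ]
  T_max <- max(Z_obs)
  best <- which.max(Z_obs)

  # permutation null of T_max
  if (config$exhaustive) {
    combos <- utils::combn(N, R)
    exceed <- 0L; B_eff <- ncol(combos)
    for (j in seq_len(ncol(combos))) {
      yb <- integer(N); yb[combos[, j]] <- 1L
      Tb <- max(z_stat(matrix(crossprod(yb, I_all), nrow = 1))[1, ])
      if (Tb >= T_max - 1e-12) exceed <- exceed + 1L
    }
    p_perm <- exceed / B_eff                # observed is one of the combos
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    B <- config$B; B_eff <- B
    exceed <- 0L
    chunk <- 2000L
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      Y <- matrix(0, nrow = nb, ncol = N)
      for (b in seq_len(nb)) Y[b, sample.int(N, R)] <- 1
      Tb <- apply(z_stat(Y %*% I_all), 1L, max)
      exceed <- exceed + sum(Tb >= T_max - 1e-12)
      done <- done + nb
    }
    p_perm <- (1 + exceed) / (B + 1)
  }

  bb <- blocks[[best]]
  cases_cat <- as.numeric(crossprod(y, bb$Imat))
  contingency <- rbind(case = cases_cat, control = bb$n_i - cases_cat)
  colnames(contingency) <- bb$scores
  structure(list(
    geneset = geneset$name, mask = mask$name, untestable = FALSE,
    T_max = T_max, chosen_threshold = bb$threshold, p_perm = p_perm,
    contingency = contingency, B_effective = B_eff,
    grid = data.frame(threshold = vapply(blocks, `[[`, numeric(1),
                                         "threshold"),
                      Z = Z_obs),
    n_variants = length(vids)), class = "rvtt_result")
}

#' @export
print.rvtt_result <- function(x, ...) {
  cat("RVTT:", x$geneset, "/", x$mask, "mask\n")
  if (isTRUE(x$untestable)) {
    cat("  untestable:", x$reason, "\n")
  } else {
    cat(sprintf("  T_max = %.3f at MAF threshold %.5g; permutation p = %.4g (B = %d)\n",
                x$T_max, x$chosen_threshold, x$p_perm, x$B_effective))
  }
  invisible(x)
}

#' Cauchy combination test (CCT)
#'
#' Combines p-values as a weighted sum of Cauchy-transformed p-values,
#' `T = sum_i w_i tan((0.5 - p_i) pi)` (weights normalised to sum 1),
#' referred to the standard Cauchy distribution:
#' `p = 0.5 - arctan(T) / pi`. Valid under arbitrary correlation between
#' the inputs. For `p_i < 1e-15` the numerically tail-equivalent term
#' `w_i / (p_i * pi)` is used.
#'
#' @param p p-values, all strictly inside (0, 1). Permutation p-values
#'   must be floored at `1/(B+1)` by the caller (the add-one estimator
#'   guarantees this).
#' @param weights positive weights (default equal).
#' @return the combined p-value in (0, 1).
#' @export
cct_combine <- function(p, weights = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1))
    stop("all p-values must lie strictly inside (0, 1)")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  tiny <- p < 1e-15
  terms <- numeric(length(p))
  terms[!tiny] <- w[!tiny] * tan((0.5 - p[!tiny]) * pi)
  terms[tiny] <- w[tiny] / (p[tiny] * pi)
  T_stat <- sum(terms)
  pc <- 0.5 - atan(T_stat) / pi
  min(max(pc, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' RVTT meta-analysis across cohorts
#'
#' Runs the RVTT per cohort and per mask for each gene set, then combines
#' the per-cohort permutation p-values with the Cauchy combination test
#' (equal weights, renormalised when a cohort is untestable for a mask).
#' The synonymous channel is the built-in negative control: enrichment in
#' cases is expected in the damaging/missense channels only.
#'
#' @param datasets named list of [cohort_dataset()]s (one per cohort).
#' @param genesets list of [gene_set()]s.
#' @param config an [rvtt_config()]; its mask field is replaced per
#'   channel.
#' @param masks named list of [mask_spec()]s (default damaging, missense,
#'   synonymous).
#' @return list with `per_cohort` (data.frame: geneset, mask, cohort,
#'   T_max, threshold, p_perm, n_variants) and `meta` (data.frame:
#'   geneset, mask, p_cct, n_cohorts).
#' @export
rvtt_meta <- function(datasets, genesets,
                      config = rvtt_config(),
                      masks = default_masks()[c("damaging", "missense",
                                                "synonymous")]) {
  if (is.null(names(datasets)))
    names(datasets) <- paste0("cohort", seq_along(datasets))
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  mafs <- lapply(datasets, compute_maf, group = config$maf_group)
  per <- list(); meta <- list()
  for (gs in genesets) for (mk in names(masks)) {
    ps <- c(); rows <- list()
    for (co in names(datasets)) {
      cfg <- config; cfg$mask <- masks[[mk]]
      r <- rvtt(datasets[[co]], gs, cfg, maf = mafs[[co]])
      rows[[co]] <- data.frame(
        geneset = gs$name, mask = mk, cohort = co,
        T_max = if (isTRUE(r$untestable)) NA_real_ else r$T_max,
        threshold = if (isTRUE(r$untestable)) NA_real_ else
          r$chosen_threshold,
        p_perm = if (isTRUE(r$untestable)) NA_real_ else r$p_perm,
        n_variants = if (isTRUE(r$untestable)) 0L else r$n_variants,
        untestable = isTRUE(r$untestable))
      if (!isTRUE(r$untestable)) ps <- c(ps, r$p_perm)
    }
    per[[paste(gs$name, mk)]] <- do.call(rbind, rows)
    meta[[paste(gs$name, mk)]] <- data.frame(
      geneset = gs$name, mask = mk,
      p_cct = if (length(ps)) cct_combine(pmin(ps, 1 - 1e-12)) else
        NA_real_,
      n_cohorts = length(ps))
  }
  per <- do.call(rbind, per); rownames(per) <- NULL
  meta <- do.call(rbind, meta); rownames(meta) <- NULL
  list(per_cohort = per, meta = meta)
}
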