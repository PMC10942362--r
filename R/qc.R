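# Variant- and sample-level quality control cascade.

#' Hard-filter thresholds for site metrics
#'
#' GATK-style hard filters applied per variant type. Defaults are the
#' standard short-variant cutoffs: SNVs require QD > 2, SOR < 3, MQ > 40,
#' FS < 60, MQRankSum > -12.5 and ReadPosRankSum > -6; indels require
#' QD > 2, SOR < 10, FS < 200 and ReadPosRankSum > -10. Site quality must
#' exceed `qual_min` (50) and genotypes with GQ <= `gq_min` (20) are set
#' to missing.
#'
#' @param snv,indel named lists of per-type thresholds (see defaults).
#' @param qual_min minimum phred site quality (exclusive).
#' @param gq_min genotypes at or below this GQ are set missing.
#' @return a `hard_filter_thresholds` object.
#' @export
hard_filter_thresholds <- function(
    snv = list(qd_min = 2.0, sor_max = 3.0, mq_min = 40.0, fs_max = 60,
               mqranksum_min = -12.5, readpos_min = -6.0),
    indel = list(qd_min = 2.0, sor_max = 10.0, fs_max = 200.0,
                 readpos_min = -10.0),
    qual_min = 50, gq_min = 20) {
  structure(list(snv = snv, indel = indel, qual_min = qual_min,
                 gq_min = gq_min), class = "hard_filter_thresholds")
}

#' Apply hard filters to a cohort
#'
#' A variant is retained iff every *available* site metric satisfies the
#' thresholds for its variant type and its site quality exceeds
#' `qual_min`; a missing metric passes vacuously (rank-sum metrics are
#' undefined at sites without heterozygotes) and such sites are flagged in
#' the report. Genotypes with GQ <= `gq_min` are set to missing when a GQ
#' matrix is present.
#'
#' @param dataset a [cohort_dataset()].
#' @param thresholds a [hard_filter_thresholds()].
#' @return list with elements `dataset` (filtered) and `report`
#'   (per-metric removal counts, removed vids, vids with missing metrics,
#'   number of genotypes masked by the GQ rule).
#' @export
apply_hard_filters <- function(dataset,
                               thresholds = hard_filter_thresholds()) {
  v <- dataset$variants
  n <- nrow(v)
  met <- function(name) if (name %in% names(v)) v[[name]] else
    rep(NA_real_, n)
  qd <- met("QD"); sor <- met("SOR"); mq <- met("MQ"); fs <- met("FS")
  mqr <- met("MQRankSum"); rpr <- met("ReadPosRankSum")
  qual <- if ("qual" %in% names(v)) v$qual else rep(NA_real_, n)
  is_snv <- v$vtype == "snv"
  s <- thresholds$snv; i <- thresholds$indel

  fails <- list(
    QD  = ifelse(is_snv, !is.na(qd) & qd <= s$qd_min,
                 !is.na(qd) & qd <= i$qd_min),
    SOR = ifelse(is_snv, !is.na(sor) & sor >= s$sor_max,
                 !is.na(sor) & sor >= i$sor_max),
    MQ  = is_snv & !is.na(mq) & mq <= s$mq_min,
    FS  = ifelse(is_snv, !is.na(fs) & fs >= s$fs_max,
                 !is.na(fs) & fs >= i$fs_max),
    MQRankSum = is_snv & !is.na(mqr) & mqr <= s$mqranksum_min,
    ReadPosRankSum = ifelse(is_snv, !is.na(rpr) & rpr <= s$readpos_min,
                            !is.na(rpr) & rpr <= i$readpos_min),
    QUAL = !is.na(qual) & qual <= thresholds$qual_min)
  removed <- Reduce(`|`, fails)
  metric_missing <- is.na(qd) | is.na(sor) | is.na(fs) |
    (is_snv & (is.na(mq) | is.na(mqr))) | is.na(rpr)

  n_gq_masked <- 0L
  if (!is.null(dataset$gq)) {
    mask <- !is.na(dataset$gq) & dataset$gq <= thresholds$gq_min &
      !is.na(dataset$geno)
    n_gq_masked <- sum(mask)
    dataset$geno[mask] <- NA_integer_
  }
  out <- subset_cohort(dataset, vids = v$vid[!removed])
  report <- list(
    step = "hard_filters",
    n_input = n, n_retained = sum(!removed), n_removed = sum(removed),
    removed_by_metric = vapply(fails, sum, integer(1)),
    removed_vids = v$vid[removed],
    flagged_missing_metric = v$vid[metric_missing & !removed],
    n_genotypes_gq_masked = n_gq_masked)
  list(dataset = out, report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg genotype proportions,
#' conditional on the observed allele counts: the p-value sums the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count (Wigginton-style exact
#' test). Probabilities are computed by the stable mode-outward
#' recurrence.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0L) stop("no individuals")
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa   # minor allele count
  if (n_minor == 0L) return(1)            # monomorphic
  probs <- hwe_het_distribution(n, n_minor)
  obs <- n_Aa
  p_obs <- probs[as.character(obs)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  min(1, max(p, .Machine$double.xmin))
}

# conditional distribution of the heterozygote count given n individuals
# and n_minor minor alleles; returns named vector over feasible het counts
hwe_het_distribution <- function(n, n_minor) {
  n_major <- 2L * n - n_minor
  hets <- seq(n_minor %% 2L, min(n_minor, n_major), by = 2L)
  # unnormalized recurrence: P(h+2)/P(h) = 4*nAA(h)*naa(h) / ((h+2)(h+1))
  w <- numeric(length(hets))
  mid_idx <- which.min(abs(hets - n_minor * n_major / (2 * n)))
  w[mid_idx] <- 1
  if (mid_idx < length(hets)) {
    for (k in mid_idx:(length(hets) - 1L)) {
      h <- hets[k]
      naa <- (n_minor - h) / 2; nAA <- (n_major - h) / 2
      w[k + 1L] <- w[k] * 4 * naa * nAA / ((h + 2) * (h + 1))
    }
  }
  if (mid_idx > 1L) {
    for (k in mid_idx:2L) {
      h <- hets[k]
      naa <- (n_minor - h) / 2; nAA <- (n_major - h) / 2
      w[k - 1L] <- w[k] * h * (h - 1) / (4 * (naa + 1) * (nAA + 1))
    }
  }
  stats::setNames(w / sum(w), hets)
}

#' Site-filter configuration
#'
#' @param max_missing maximum fraction of missing genotypes per site.
#' @param hwe_min_p minimum HWE exact p in controls (exclusive).
#' @param min_depth,min_depth_sample_frac a site must be covered at
#'   `>= min_depth` in at least this fraction of samples.
#' @param max_depth_multiplier sites with mean depth above this multiple of
#'   the cohort mean depth are removed.
#' @param autosomes_only,biallelic_only restrict to autosomal sites (the
#'   biallelic restriction is enforced by the VCF reader).
#' @return a `site_filter_config` object.
#' @export
site_filter_config <- function(max_missing = 0.05, hwe_min_p = 1e-6,
                               min_depth = 10, min_depth_sample_frac = 0.95,
                               max_depth_multiplier = 2.0,
                               autosomes_only = TRUE,
                               biallelic_only = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_depth_sample_frac >= 0, min_depth_sample_frac <= 1)
  structure(list(max_missing = max_missing, hwe_min_p = hwe_min_p,
                 min_depth = min_depth,
                 min_depth_sample_frac = min_depth_sample_frac,
                 max_depth_multiplier = max_depth_multiplier,
                 autosomes_only = autosomes_only,
                 biallelic_only = biallelic_only),
            class = "site_filter_config")
}

is_autosome <- function(chrom) {
  grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", as.character(chrom))
}

#' Apply site-level filters
#'
#' Applies, in a fixed order, (1) the autosome restriction, (2) the
#' missing-genotype ceiling, (3) the Hardy-Weinberg exact test in
#' controls, (4) the minimum-coverage rule (>= `min_depth`x in at least
#' `min_depth_sample_frac` of samples) and (5) the excess-depth rule
#' (site mean depth above `max_depth_multiplier` times the cohort mean).
#' Depth rules are skipped with a warning when no DP matrix is attached.
#' Per-rule attrition is recorded in the report; a site counts against the
#' first rule that removes it.
#'
#' @param dataset a [cohort_dataset()].
#' @param config a [site_filter_config()].
#' @return list(dataset, report) as in [apply_hard_filters()].
#' @export
site_filters <- function(dataset, config = site_filter_config()) {
  v <- dataset$variants
  g <- dataset$geno
  n_input <- nrow(v)
  alive <- rep(TRUE, n_input)
  removed_by <- c(autosome = 0L, missingness = 0L, hwe = 0L,
                  min_depth = 0L, excess_depth = 0L)
  reason <- rep(NA_character_, n_input)

  take <- function(rule, bad) {
    bad <- bad & alive
    removed_by[[rule]] <<- sum(bad)
    reason[bad] <<- rule
    alive <<- alive & !bad
  }

  if (config$autosomes_only) take("autosome", !is_autosome(v$chrom))

  miss_frac <- colMeans(is.na(g))
  take("missingness", miss_frac > config$max_missing)

  ctrl <- dataset$samples$phenotype == "control"
  if (!is.null(config$hwe_min_p)) {
    if (!any(ctrl)) stop("HWE rule enabled but no control samples present")
    gc <- g[ctrl, , drop = FALSE]
    n_aa <- colSums(gc == 2L, na.rm = TRUE)
    n_Aa <- colSums(gc == 1L, na.rm = TRUE)
    n_AA <- colSums(gc == 0L, na.rm = TRUE)
    hwe_p <- vapply(seq_len(ncol(gc)), function(j) {
      if (n_AA[j] + n_Aa[j] + n_aa[j] == 0L) return(NA_real_)
      hwe_exact_p(n_AA[j], n_Aa[j], n_aa[j])
    }, numeric(1))
    take("hwe", !is.na(hwe_p) & hwe_p <= config$hwe_min_p)
  }

  if (is.null(dataset$dp)) {
    warning("no per-genotype depth available; depth rules skipped")
  } else {
    dp <- dataset$dp
    frac_ok <- colMeans(dp >= config$min_depth, na.rm = TRUE)
    take("min_depth", frac_ok < config$min_depth_sample_frac)
    site_mean <- colMeans(dp, na.rm = TRUE)
    cohort_mean <- mean(dp, na.rm = TRUE)
    take("excess_depth",
         site_mean > config$max_depth_multiplier * cohort_mean)
  }

  out <- subset_cohort(dataset, vids = v$vid[alive])
  report <- list(
    step = "site_filters", n_input = n_input, n_retained = sum(alive),
    n_removed = sum(!alive), removed_by_rule = removed_by,
    removed_vids = v$vid[!alive],
    removal_reason = stats::setNames(reason[!alive], v$vid[!alive]),
    rule_order = names(removed_by))
  list(dataset = out, report = report)
}

#' Pairwise relatedness (unadjusted A_jk)
#'
#' Genotype-correlation relatedness over variants that are polymorphic in
#' the cohort: for samples j != k,
#' `A_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the variants where both genotypes are called. The expectation is
#' about 0 for unrelated pairs and about 1 for duplicates. Pairs with
#' `A_jk` above the threshold are flagged; from each flagged pair the
#' member with the higher genotype missingness (ties broken by sample id)
#' is marked for removal.
#'
#' @param dataset a [cohort_dataset()].
#' @param threshold relatedness flag level (default 0.3).
#' @param maf_min restrict to sites at or above this cohort MAF (default
#'   0: all polymorphic sites). On rare-variant-only panels the
#'   per-variant terms `(x - 2p)^2 / (2p(1-p))` are huge, so estimating
#'   relatedness on the common sites only (e.g. `maf_min = 0.01`) is
#'   strongly recommended.
#' @return list with `ajk` (symmetric matrix, `NA` diagonal),
#'   `flagged_pairs` (data.frame id1, id2, ajk, n_variants),
#'   `remove` (sample ids marked for removal) and `untestable_pairs`.
#' @export
relatedness_ajk <- function(dataset, threshold = 0.3, maf_min = 0) {
  g <- dataset$geno
  if (nrow(g) < 2L) stop("need at least two samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1 & pmin(p, 1 - p) >= maf_min
  g <- g[, use, drop = FALSE]
  p <- p[use]
  denom <- 2 * p * (1 - p)
  x <- sweep(g, 2L, 2 * p)            # x_ij - 2p_i, NA where missing
  xs <- sweep(x, 2L, sqrt(denom), "/")
  xs0 <- xs; xs0[is.na(xs0)] <- 0
  called <- !is.na(xs)
  num <- tcrossprod(xs0)              # sum over variants called in both
  m <- tcrossprod(called * 1)         # pair-wise usable variant counts
  ajk <- num / m
  diag(ajk) <- NA_real_
  ids <- rownames(g)
  dimnames(ajk) <- list(ids, ids)

  ut <- which(upper.tri(ajk), arr.ind = TRUE)
  untestable <- ut[m[ut] == 0, , drop = FALSE]
  flag <- ut[!is.na(ajk[ut]) & ajk[ut] > threshold, , drop = FALSE]
  miss <- rowMeans(is.na(dataset$geno))
  remove <- character(0)
  if (nrow(flag)) {
    for (r in seq_len(nrow(flag))) {
      j <- flag[r, 1]; k <- flag[r, 2]
      worse <- if (miss[j] > miss[k]) j
        else if (miss[k] > miss[j]) k
        else if (ids[j] > ids[k]) j else k
      remove <- c(remove, ids[worse])
    }
  }
  list(
    ajk = ajk,
    flagged_pairs = data.frame(
      id1 = ids[flag[, 1]], id2 = ids[flag[, 2]],
      ajk = ajk[flag], n_variants = m[flag]),
    remove = unique(remove),
    untestable_pairs = data.frame(id1 = ids[untestable[, 1]],
                                  id2 = ids[untestable[, 2]]))
}

#' Flag sample-level QC outliers
#'
#' A sample is an outlier if any supplied metric (e.g. Ts/Tv, Het/Hom)
#' lies more than `z` sample standard deviations (denominator n - 1) from
#' the cohort mean, or if its genotype missingness exceeds
#' `max_missing_rate`.
#'
#' @param samples a sample table (data.frame with `sample_id`).
#' @param metrics character vector of metric column names to screen.
#' @param z SD multiple defining an outlier (default 3).
#' @param max_missing_rate absolute missingness ceiling (default 0.25).
#' @return character vector of outlier sample ids.
#' @export
sample_outliers <- function(samples, metrics = c("tstv", "hethom"),
                            z = 3, max_missing_rate = 0.25) {
  out <- logical(nrow(samples))
  for (m in intersect(metrics, names(samples))) {
    x <- samples[[m]]
    ok <- !is.na(x)
    if (sum(ok) < 3L) next
    s <- stats::sd(x[ok])
    if (s == 0) next                     # zero variance: no outliers
    out <- out | (ok & abs(x - mean(x[ok])) > z * s)
  }
  if ("missing_rate" %in% names(samples))
    out <- out | (!is.na(samples$missing_rate) &
                    samples$missing_rate > max_missing_rate)
  samples$sample_id[out]
}

#' Ultra-rare variant case/control balance test
#'
#' For variants with total cohort allele count `ac` (singletons AC=1,
#' doubletons AC=2, tripletons AC=3), pools all copies across variants and
#' tests whether the number borne by cases is binomially distributed with
#' the case chromosome fraction. A control excess (as seen when control
#' and case call sets differ technically) drives the p-value down.
#'
#' @param dataset a [cohort_dataset()].
#' @param ac the allele-count class to test (1, 2 or 3).
#' @return list with the exact two-sided `p_value` (sum of outcomes no
#'   more probable than the observed), `n_alleles` pooled, `case_alleles`
#'   observed, `expected_case_fraction`, `observed_case_fraction` and
#'   `direction` (`"case_excess"`/`"control_excess"`/`"balanced"`);
#'   `untestable = TRUE` when no variant has the requested AC.
#' @export
ultra_rare_balance_test <- function(dataset, ac = 1L) {
  stopifnot(ac %in% 1:3)
  ph <- dataset$samples$phenotype
  if (!any(ph == "case") || !any(ph == "control"))
    stop("both phenotype groups must be non-empty")
  total_ac <- compute_ac(dataset, "combined")
  sel <- total_ac == ac
  if (!any(sel)) {
    return(list(untestable = TRUE, ac = ac, n_alleles = 0L))
  }
  case_ac <- compute_ac(dataset, "cases")[sel]
  x <- sum(case_ac)
  n <- sum(total_ac[sel])
  f <- 2 * sum(ph == "case") / (2 * length(ph))
  ht <- stats::binom.test(x, n, p = f, alternative = "two.sided")
  obs_frac <- x / n
  list(untestable = FALSE, ac = ac, p_value = ht$p.value,
       n_alleles = n, case_alleles = x,
       expected_case_fraction = f, observed_case_fraction = obs_frac,
       direction = if (obs_frac > f) "case_excess"
                   else if (obs_frac < f) "control_excess" else "balanced")
}

#' Remove singleton variants
#'
#' Drops variants whose combined-cohort allele count is exactly 1 (one alt
#' allele across cases and controls together). Set `per_group = TRUE` for
#' the alternative reading that removes variants appearing exactly once
#' within each group separately.
#'
#' @param dataset a [cohort_dataset()].
#' @param per_group use the per-group singleton definition.
#' @return list(dataset, n_removed, removed_vids).
#' @export
exclude_singletons <- function(dataset, per_group = FALSE) {
  if (per_group) {
    singleton <- compute_ac(dataset, "cases") == 1L |
      compute_ac(dataset, "controls") == 1L
  } else {
    singleton <- compute_ac(dataset, "combined") == 1L
  }
  vids <- dataset$variants$vid[singleton]
  list(dataset = subset_cohort(dataset, vids = dataset$variants$vid[!singleton]),
       n_removed = sum(singleton), removed_vids = vids)
}

#' Per-variant minor allele frequency
#'
#' `MAF = min(f, 1 - f)` with `f = AC / (2 n_called)` computed in the
#' requested group; variants with no called genotypes in the group get
#' `NA`.
#'
#' @param dataset a [cohort_dataset()].
#' @param group `"combined"`, `"cases"` or `"controls"`.
#' @return named numeric vector of MAFs.
#' @export
compute_maf <- function(dataset, group = c("combined", "cases", "controls")) {
  group <- match.arg(group)
  rows <- group_rows(dataset, group)
  g <- dataset$geno[rows, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0L] <- NA_real_
  pmin(f, 1 - f)
}

#' Serialise a QC report
#'
#' Writes the per-step QC report as JSON plus, when variant removals are
#' recorded, a BED-like TSV (chrom, pos-1, pos, vid, reason) using 0-based
#' half-open intervals.
#'
#' @param reports list of per-step report lists.
#' @param path output JSON path; the BED-like TSV goes next to it.
#' @param variants variant table used to resolve removed vids (optional).
#' @return invisibly, the JSON path.
#' @export
write_qc_report <- function(reports, path, variants = NULL) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(variants)) {
    rows <- list()
    for (rep in reports) {
      if (is.null(rep$removed_vids) || !length(rep$removed_vids)) next
      reason <- if (!is.null(rep$removal_reason))
        unname(rep$removal_reason) else rep(rep$step, length(rep$removed_vids))
      v <- variants[match(rep$removed_vids, variants$vid), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom, start = v$pos - 1L, end = v$pos,
        vid = rep$removed_vids, reason = reason)
    }
    if (length(rows)) {
      bed <- do.call(rbind, rows)
      utils::write.table(bed, sub("\\.json$", ".removed.bed", path),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}
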