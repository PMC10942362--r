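# Single-variant association: one-sided Fisher scan, genomic inflation,
# Bonferroni and the permutation-resampling FDR adjustment.

#' One-sided Fisher exact test for case enrichment
#'
#' Upper-tail exact test on a 2x2 table of allele (or carrier) counts:
#' `p = P(X >= a)` for the hypergeometric distribution of the case-alt
#' cell given the table margins. No mid-p correction is applied.
#'
#' @param a case alt count.
#' @param b case ref count.
#' @param c_ control alt count.
#' @param d control ref count.
#' @return exact upper-tail p-value.
#' @export
fisher_one_sided <- function(a, b, c_, d) {
  x <- c(a, b, c_, d)
  if (any(x < 0) || any(x != round(x)))
    stop("table entries must be nonnegative integers")
  # margins: alt total m = a + c_, ref total n = b + d, case draws k = a + b
  stats::phyper(a - 1, m = a + c_, n = b + d, k = a + b,
                lower.tail = FALSE)
}

#' Single-variant one-sided Fisher scan
#'
#' Tests each qualifying rare variant (combined-cohort MAF strictly below
#' `maf_max`) for alt-allele enrichment in cases, on allele-count 2x2
#' tables (each called individual contributes two chromosomes).
#' ClinVar-pathogenic variants can be dropped before testing.
#'
#' @param dataset a [cohort_dataset()] (QC'd, singletons already excluded
#'   in the standard pipeline order).
#' @param maf_max MAF ceiling (default 0.01).
#' @param exclude_clinvar drop variants flagged pathogenic in the
#'   annotations before testing.
#' @param n_perm_fdr permutations for the empirical FDR (0 skips it).
#' @param seed RNG seed for the permutation null.
#' @return data.frame with vid, gene (when annotated), the 2x2 counts,
#'   `p_raw`, `p_bonferroni` and (when `n_perm_fdr > 0`) `p_fdr`, sorted
#'   by `p_raw`.
#' @export
variant_scan <- function(dataset, maf_max = 0.01, exclude_clinvar = FALSE,
                         n_perm_fdr = 0L, seed = NULL) {
  maf <- compute_maf(dataset, "combined")
  keep <- !is.na(maf) & maf < maf_max
  if (exclude_clinvar) {
    if (is.null(dataset$annotations))
      stop("exclude_clinvar requires annotations")
    path_vids <- dataset$annotations$vid[
      dataset$annotations$clinvar_pathogenic %in% TRUE]
    keep <- keep & !(dataset$variants$vid %in% path_vids)
  }
  if (!any(keep)) {
    warning("no qualifying variants to test")
    return(data.frame(vid = character(0), p_raw = numeric(0)))
  }
  sub <- subset_cohort(dataset, vids = dataset$variants$vid[keep])
  case <- sub$samples$phenotype == "case"
  tab <- scan_tables(sub$geno, case)
  p <- fisher_scan_p(tab)
  res <- data.frame(vid = sub$variants$vid,
                    case_alt = tab$a, case_ref = tab$b,
                    control_alt = tab$c_, control_ref = tab$d,
                    p_raw = p)
  if (!is.null(sub$annotations))
    res$gene <- sub$annotations$gene[match(res$vid, sub$annotations$vid)]
  res$p_bonferroni <- bonferroni_adjust(res$p_raw, nrow(res))
  if (n_perm_fdr > 0L) {
    null_p <- permutation_null_p(sub$geno, case, B = n_perm_fdr, seed = seed)
    res$p_fdr <- permutation_fdr(res$p_raw, null_p)
  }
  res[order(res$p_raw), , drop = FALSE]
}

# allele-count 2x2 tables for all variants at once
scan_tables <- function(geno, case) {
  gcase <- geno[case, , drop = FALSE]
  gctrl <- geno[!case, , drop = FALSE]
  a <- colSums(gcase, na.rm = TRUE)
  b <- 2 * colSums(!is.na(gcase)) - a
  c_ <- colSums(gctrl, na.rm = TRUE)
  d <- 2 * colSums(!is.na(gctrl)) - c_
  list(a = a, b = b, c_ = c_, d = d)
}

fisher_scan_p <- function(tab) {
  stats::phyper(tab$a - 1, m = tab$a + tab$c_, n = tab$b + tab$d,
                k = tab$a + tab$b, lower.tail = FALSE)
}

# B x n_variants matrix of scan p-values under permuted phenotype labels
permutation_null_p <- function(geno, case, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(case)
  t(vapply(seq_len(B), function(b) {
    perm <- case[sample.int(n)]
    fisher_scan_p(scan_tables(geno, perm))
  }, numeric(ncol(geno))))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`: the
#' median observed one-degree-of-freedom chi-square statistic over its
#' null median (about 0.4549). Values near 1 indicate calibrated tests;
#' inflation from an excess of true (or artefactual) signal pushes it up.
#'
#' @param p_values p-values in (0, 1].
#' @return the inflation factor lambda.
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Permutation-based FDR adjustment
#'
#' Empirical false-discovery-rate adjustment against a permutation null:
#' for each observed p-value p(i), the estimate is the mean number of
#' null p-values at or below p(i) per permutation, divided by the number
#' of observed p-values at or below p(i); the ratio is floored at the
#' resolution `1/(B * n)` and at p(i) itself, capped at 1, and finally
#' monotonized step-up (from the largest observed p downward, each
#' adjusted value is the running minimum) so adjusted values are
#' non-decreasing in the raw p.
#'
#' @param observed_p numeric vector of observed p-values (length n).
#' @param null_p matrix of null p-values, `B x m` (each row one complete
#'   re-test battery under permuted labels; usually m = n).
#' @return adjusted p-values aligned with `observed_p`.
#' @export
permutation_fdr <- function(observed_p, null_p) {
  null_p <- as.matrix(null_p)
  B <- nrow(null_p)
  if (B < 1L) stop("need at least one permutation")
  n <- length(observed_p)
  pooled <- sort(as.numeric(null_p))
  # mean null count <= p via binary search on the pooled sorted null
  null_count <- findInterval(observed_p, pooled) / B
  obs_count <- rank(observed_p, ties.method = "max")
  fdr <- null_count / obs_count
  fdr <- pmax(fdr, observed_p, 1 / (B * n))
  fdr <- pmin(fdr, 1)
  # step-up monotonization
  o <- order(observed_p, decreasing = TRUE)
  fdr[o] <- cummin(fdr[o])
  fdr
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param n_tests number of tests in the battery (>= 1).
#' @return `min(1, p * n_tests)`.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  pmin(1, p * n_tests)
}

#' QQ-plot export data
#'
#' @param p_values raw p-values.
#' @return data.frame of expected vs observed -log10 p, sorted.
#' @export
qq_data <- function(p_values) {
  p <- sort(p_values)
  n <- length(p)
  data.frame(expected = -log10(stats::ppoints(n)), observed = -log10(p))
}
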