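# Gene-set overlap and permutation enrichment statistics.

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric test of the overlap between a query and a
#' reference gene set drawn from a universe of `universe_size` genes:
#' `p = P(overlap >= observed)`.
#'
#' @param query,reference [gene_set()]s (or character vectors).
#' @param universe_size number of genes in the universe.
#' @param observed optional overlap count; computed from the sets when
#'   omitted.
#' @return upper-tail p-value.
#' @export
hypergeom_overlap <- function(query, reference, universe_size,
                              observed = NULL) {
  q <- if (inherits(query, "gene_set")) query$genes else unique(query)
  r <- if (inherits(reference, "gene_set")) reference$genes else
    unique(reference)
  if (length(q) > universe_size || length(r) > universe_size)
    stop("sets larger than the universe")
  if (is.null(observed)) observed <- length(intersect(q, r))
  if (observed > min(length(q), length(r)))
    stop("overlap exceeds the smaller set")
  stats::phyper(observed - 1, m = length(r),
                n = universe_size - length(r), k = length(q),
                lower.tail = FALSE)
}

#' Random-sampling permutation enrichment
#'
#' Tests whether a target gene set carries more of some per-gene feature
#' (e.g. significant eQTLs within a window) than random gene sets of the
#' same size: the observed statistic is the summed feature count over the
#' target genes; the null is built by drawing `n_perm` same-size gene sets
#' from the universe without replacement. The permutation p uses the
#' add-one estimator and the confidence interval is read off the null
#' percentiles.
#'
#' @param target a [gene_set()] (must be a subset of the universe).
#' @param feature_counts named numeric vector: per-gene feature counts for
#'   every universe gene.
#' @param n_perm number of random draws (default 1000).
#' @param seed RNG seed.
#' @param ci confidence level for the empirical interval (default 0.95).
#' @return an `enrichment_result` list: `observed`, `null_mean`,
#'   `ci_lower`, `ci_upper`, `p`, `n_permutations`.
#' @export
sampling_enrichment <- function(target, feature_counts, n_perm = 1000L,
                                seed = NULL, ci = 0.95) {
  genes <- target$genes
  universe <- names(feature_counts)
  if (is.null(universe)) stop("feature_counts must be named by gene")
  missing_genes <- setdiff(genes, universe)
  if (length(missing_genes))
    stop("target genes absent from the universe: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  n_target <- length(genes)
  if (n_target > length(universe)) stop("target larger than universe")
  observed <- sum(feature_counts[genes])
  if (!is.null(seed)) set.seed(seed)
  null_sums <- vapply(seq_len(n_perm), function(i)
    sum(feature_counts[sample.int(length(universe), n_target)]),
    numeric(1))
  alpha <- (1 - ci) / 2
  structure(list(
    observed = observed,
    null_mean = mean(null_sums),
    ci_lower = unname(stats::quantile(null_sums, alpha)),
    ci_upper = unname(stats::quantile(null_sums, 1 - alpha)),
    p = (1 + sum(null_sums >= observed)) / (n_perm + 1),
    n_permutations = n_perm,
    null_sums = null_sums), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "sampling enrichment: observed = %g, null mean = %.2f [%g, %g], p = %.4g (%d permutations)\n",
    x$observed, x$null_mean, x$ci_lower, x$ci_upper, x$p,
    x$n_permutations))
  invisible(x)
}
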