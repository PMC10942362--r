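# Synthetic case-control targeted-panel cohorts with the statistical
# structure the analysis pipeline assumes: a rare-variant frequency
# spectrum with singletons, consequence-class labels, cohort-imbalanced
# singleton rates, and case enrichment of qualifying variants in
# designated risk gene sets at a configurable carrier odds ratio.

#' Simulation parameters
#'
#' Defaults emulate a targeted sequencing panel of 430 genes in 496 cases
#' and 2,516 controls, with controls carrying about twice as many
#' singletons as balanced sampling would give.
#'
#' @param n_case,n_control cohort sizes.
#' @param n_genes number of panel genes.
#' @param variants_per_gene mean of the Poisson variant count per gene.
#' @param risk_sets named integer vector: number of genes in each risk
#'   gene set (sets are disjoint, assigned from the front of the panel).
#' @param carrier_or odds ratio applied to the carrier probability of
#'   qualifying (rare nonsynonymous) variants in risk genes, cases only.
#'   Either a single value for all risk sets or a named vector giving one
#'   odds ratio per risk set (e.g. one enriched module among matched null
#'   modules).
#' @param maf_spectrum mixture weights over the variant frequency classes
#'   `singleton`, `rare` (Beta-shaped on (0, 0.01)) and `common`
#'   (uniform on 0.01-0.05, retained for QC exercises).
#' @param consequence_mix named proportions over
#'   [consequence_vocabulary()].
#' @param deleterious_frac fraction of missense variants given a damaging
#'   PolyPhen2/SIFT call.
#' @param n_clinvar_pathogenic number of planted ClinVar-pathogenic
#'   strong-signal variants (rare missense in risk genes at
#'   `clinvar_or`).
#' @param clinvar_or carrier odds ratio of the planted ClinVar variants.
#' @param control_singleton_inflation factor by which control singletons
#'   exceed balanced expectation (extra control-private singletons are
#'   added post hoc).
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param gq_mean Poisson mean of genotype quality (capped at 99).
#' @param with_depth generate per-genotype DP/GQ matrices (needed by the
#'   depth and GQ rules; disable to save memory).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return a `simulation_params` object.
#' @export
simulation_params <- function(
    n_case = 496L, n_control = 2516L, n_genes = 430L,
    variants_per_gene = 36,
    risk_sets = c(risk_module = 20L),
    carrier_or = 1,
    maf_spectrum = c(singleton = 0.40, rare = 0.50, common = 0.10),
    consequence_mix = c(missense = 0.45, synonymous = 0.30,
                        nonsense = 0.03, stop_lost = 0.005,
                        start_lost = 0.005, splice_donor = 0.01,
                        splice_acceptor = 0.01, splice_region = 0.05,
                        frameshift = 0.04, inframe_ins = 0.01,
                        inframe_del = 0.01, other = 0.08),
    deleterious_frac = 0.5,
    n_clinvar_pathogenic = 0L, clinvar_or = 8,
    control_singleton_inflation = 2.0,
    missing_rate = 0.002,
    depth_mean = 45, depth_size = 8, gq_mean = 60,
    with_depth = TRUE, seed = 1L) {
  if (length(carrier_or) > 1L &&
      !setequal(names(carrier_or), names(risk_sets)))
    stop("named carrier_or must cover exactly the risk sets")
  stopifnot(n_case > 0, n_control > 0, n_genes > 0,
            all(carrier_or >= 1), clinvar_or >= 1,
            abs(sum(maf_spectrum) - 1) < 1e-8,
            abs(sum(consequence_mix) - 1) < 1e-8,
            all(names(consequence_mix) %in% consequence_vocabulary()),
            control_singleton_inflation >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (sum(risk_sets) > n_genes) stop("risk sets exceed the panel")
  structure(as.list(environment()), class = "simulation_params")
}

# tilt a per-allele frequency so the carrier odds ratio equals `or`
tilt_carrier_freq <- function(p, or) {
  q0 <- 1 - (1 - p)^2
  odds1 <- or * q0 / (1 - q0)
  q1 <- odds1 / (1 + odds1)
  if (q1 >= 1) stop("infeasible carrier tilt (carrier probability 1)")
  p1 <- 1 - sqrt(1 - q1)
  if (p1 > 0.5) stop("infeasible carrier tilt (allele frequency > 0.5)")
  p1
}

nonsyn_classes <- function() {
  c("missense", "nonsense", "stop_lost", "start_lost",
    "splice_donor", "splice_acceptor", "splice_region")
}

#' Simulate a case-control targeted-panel cohort
#'
#' Per gene, draws a Poisson variant count; per variant, a frequency class
#' from the spectrum, a consequence class and (for missense) a
#' deleteriousness call. Genotypes are drawn under Hardy-Weinberg
#' equilibrium within each phenotype group; qualifying (rare
#' nonsynonymous) variants in risk genes have their case carrier odds
#' multiplied by `carrier_or`. Singleton-class variants place exactly one
#' alt allele in one individual; extra control-private singletons are
#' added post hoc to reach the configured control singleton inflation.
#' Site metrics, QUAL, DP and GQ are drawn from filter-passing
#' distributions so that planted QC violations (see
#' [plant_qc_violations()]) are the only removals.
#'
#' @param params a [simulation_params()].
#' @return list: `dataset` (an annotated [cohort_dataset()]) and `truth`
#'   (list: per-variant table with planted frequencies and qualifying
#'   flags, risk-set membership, params).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  set.seed(params$seed)
  n_case <- params$n_case; n_control <- params$n_control
  N <- n_case + n_control
  genes <- sprintf("GENE%04d", seq_len(params$n_genes))
  set_assign <- rep(NA_character_, params$n_genes)
  idx <- 1L
  for (s in names(params$risk_sets)) {
    k <- params$risk_sets[[s]]
    set_assign[idx:(idx + k - 1L)] <- s
    idx <- idx + k
  }
  gene_chrom <- paste0("chr", 1L + (seq_len(params$n_genes) - 1L) %% 22L)

  n_var <- pmax(1L, stats::rpois(params$n_genes, params$variants_per_gene))
  gene_of <- rep(seq_len(params$n_genes), n_var)
  m <- length(gene_of)

  freq_class <- sample(names(params$maf_spectrum), m, replace = TRUE,
                       prob = params$maf_spectrum)
  consequence <- sample(names(params$consequence_mix), m, replace = TRUE,
                        prob = params$consequence_mix)
  planted_maf <- numeric(m)
  planted_maf[freq_class == "singleton"] <- 1 / (2 * N)
  planted_maf[freq_class == "rare"] <-
    pmax(2 / (2 * N), 0.01 * stats::rbeta(sum(freq_class == "rare"),
                                          0.5, 3))
  planted_maf[freq_class == "common"] <-
    stats::runif(sum(freq_class == "common"), 0.01, 0.05)

  in_risk <- !is.na(set_assign[gene_of])
  qualifying <- in_risk & consequence %in% nonsyn_classes() &
    freq_class != "common"

  set_or <- if (length(params$carrier_or) > 1L)
    params$carrier_or[names(params$risk_sets)]
  else stats::setNames(rep(params$carrier_or, length(params$risk_sets)),
                       names(params$risk_sets))
  gene_or <- rep(1, params$n_genes)
  for (s in names(params$risk_sets))
    gene_or[which(set_assign == s)] <- set_or[[s]]

  # planted ClinVar pathogenic strong signals: rare missense variants in
  # genes of the effect-carrying modules (so null modules stay null)
  clinvar <- rep(FALSE, m)
  if (params$n_clinvar_pathogenic > 0L) {
    cand <- which(gene_or[gene_of] > 1 & consequence == "missense" &
                    freq_class == "rare")
    if (!length(cand)) cand <- which(consequence == "missense" &
                                       freq_class == "rare")
    pick <- sample(cand, min(params$n_clinvar_pathogenic, length(cand)))
    clinvar[pick] <- TRUE
    planted_maf[pick] <- pmax(planted_maf[pick], 0.002)
  }

  or_of <- rep(1, m)
  or_of[qualifying] <- gene_or[gene_of[qualifying]]
  or_of[clinvar] <- params$clinvar_or

  case_rows <- seq_len(n_case)
  ctrl_rows <- n_case + seq_len(n_control)
  p_ctrl <- planted_maf
  p_case <- vapply(seq_len(m), function(v)
    if (or_of[v] > 1) tilt_carrier_freq(p_ctrl[v], or_of[v]) else
      p_ctrl[v], numeric(1))

  # singleton class: exactly one alt allele in one individual, assigned
  # before the genotype fill; case-assignment odds follow the chromosome
  # share, tilted by the carrier OR for qualifying singletons
  singleton <- freq_class == "singleton"
  singleton_row <- rep(NA_integer_, m)
  if (any(singleton)) {
    sidx <- which(singleton)
    pr_case_base <- n_case / N
    odds <- or_of[sidx] * pr_case_base / (1 - pr_case_base)
    pr_case <- odds / (1 + odds)
    pick_case <- stats::runif(length(sidx)) < pr_case
    singleton_row[sidx] <- ifelse(
      pick_case, sample(case_rows, length(sidx), replace = TRUE),
      sample(ctrl_rows, length(sidx), replace = TRUE))
  }

  # control-private singleton inflation, added post hoc to the base draw
  extra <- 0L
  if (params$control_singleton_inflation > 1 && any(singleton)) {
    base_ctrl <- sum(singleton_row > n_case, na.rm = TRUE)
    extra <- round((params$control_singleton_inflation - 1) * base_ctrl)
  }
  if (extra > 0L) {
    gene_of <- c(gene_of, sample(seq_len(params$n_genes), extra,
                                 replace = TRUE))
    consequence <- c(consequence,
                     sample(names(params$consequence_mix), extra,
                            replace = TRUE,
                            prob = params$consequence_mix))
    freq_class <- c(freq_class, rep("singleton", extra))
    planted_maf <- c(planted_maf, rep(1 / (2 * N), extra))
    qualifying <- c(qualifying, rep(FALSE, extra))
    clinvar <- c(clinvar, rep(FALSE, extra))
    p_case <- c(p_case, rep(NA_real_, extra))
    p_ctrl <- c(p_ctrl, rep(NA_real_, extra))
    singleton <- c(singleton, rep(TRUE, extra))
    singleton_row <- c(singleton_row,
                       sample(ctrl_rows, extra, replace = TRUE))
    m <- m + extra
  }

  # order variants by gene (metadata only; the matrix is filled in order)
  ord <- order(gene_of)
  gene_of <- gene_of[ord]; consequence <- consequence[ord]
  freq_class <- freq_class[ord]; planted_maf <- planted_maf[ord]
  qualifying <- qualifying[ord]; clinvar <- clinvar[ord]
  p_case <- p_case[ord]; p_ctrl <- p_ctrl[ord]
  singleton <- singleton[ord]; singleton_row <- singleton_row[ord]

  # genotypes: HWE within group at group-specific allele frequencies,
  # filled chunk-wise into one preallocated matrix
  geno <- matrix(0L, nrow = N, ncol = m)
  pc <- ifelse(singleton, 0, p_case)
  pt <- ifelse(singleton, 0, p_ctrl)
  chunk <- max(1L, floor(4e6 / N))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L); idx <- s:e
    geno[case_rows, idx] <- stats::rbinom(n_case * length(idx), 2L,
                                          rep(pc[idx], each = n_case))
    geno[ctrl_rows, idx] <- stats::rbinom(n_control * length(idx), 2L,
                                          rep(pt[idx], each = n_control))
  }
  sidx <- which(singleton)
  if (length(sidx)) geno[cbind(singleton_row[sidx], sidx)] <- 1L

  # positions: 1 kb apart inside a 100 kb window per gene
  within <- stats::ave(seq_len(m), gene_of, FUN = seq_along)
  pos <- gene_of * 100000L + within * 1000L
  is_indel <- consequence %in% c("frameshift", "inframe_ins",
                                 "inframe_del")
  ref <- ifelse(is_indel, "AT", "A")
  alt <- ifelse(is_indel, "A", "G")
  # same-position duplicates impossible by construction; vids unique
  vid <- paste(gene_chrom[gene_of], pos, ref, alt, sep = ":")

  # site metrics drawn from comfortably filter-passing distributions
  variants <- data.frame(
    chrom = gene_chrom[gene_of], pos = pos, ref = ref, alt = alt,
    vid = vid,
    qual = 60 + stats::rgamma(m, 4, rate = 1 / 100),
    QD = 5 + stats::rgamma(m, 8, rate = 1 / 2.5),
    SOR = stats::runif(m, 0.3, 2.0),
    MQ = stats::runif(m, 50, 60),
    FS = stats::runif(m, 0, 10),
    MQRankSum = stats::rnorm(m, 0, 1),
    ReadPosRankSum = stats::rnorm(m, 0, 1),
    vtype = ifelse(is_indel, "indel", "snv"))

  if (params$missing_rate > 0) {
    n_miss <- stats::rbinom(1L, N * m, params$missing_rate)
    geno[sample.int(N * m, n_miss)] <- NA_integer_
  }
  dp <- gq <- NULL
  if (params$with_depth) {
    dp <- matrix(0L, N, m)
    gq <- matrix(0L, N, m)
    for (s in seq(1L, m, by = chunk)) {
      e <- min(m, s + chunk - 1L); idx <- s:e
      k <- N * length(idx)
      # baseline coverage passes the 10x rule by construction
      dp[, idx] <- pmax(as.integer(stats::rnbinom(
        k, size = params$depth_size, mu = params$depth_mean)), 12L)
      gq[, idx] <- pmin(99L, 25L + stats::rpois(k, params$gq_mean - 25))
    }
  }

  sample_id <- c(sprintf("CASE%04d", seq_len(n_case)),
                 sprintf("CTRL%04d", seq_len(n_control)))
  samples <- data.frame(
    sample_id = sample_id,
    phenotype = rep(c("case", "control"), c(n_case, n_control)),
    cohort = rep(c("cases", "reference"), c(n_case, n_control)))

  annotations <- data.frame(
    vid = vid, gene = genes[gene_of], consequence = consequence,
    polyphen = NA_character_, sift = NA_character_,
    ext_maf = pmin(0.5, planted_maf *
                     exp(stats::rnorm(m, 0, 0.2))),
    clinvar_pathogenic = clinvar)
  mis <- consequence == "missense"
  dam <- mis & stats::runif(m) < params$deleterious_frac
  annotations$polyphen[mis] <- ifelse(dam[mis],
                                      sample(c("P", "D"), sum(mis),
                                             replace = TRUE), "B")
  annotations$sift[mis] <- ifelse(dam[mis], "deleterious", "tolerated")
  annotations$polyphen[clinvar] <- "D"
  annotations$sift[clinvar] <- "deleterious"

  rownames(geno) <- sample_id; colnames(geno) <- vid
  if (!is.null(dp)) dimnames(dp) <- dimnames(gq) <- dimnames(geno)
  dataset <- cohort_dataset(geno, samples, variants, annotations,
                            gq = gq, dp = dp)
  risk_sets <- lapply(names(params$risk_sets), function(s)
    gene_set(s, genes[which(set_assign == s)]))
  names(risk_sets) <- names(params$risk_sets)
  truth <- list(
    variants = data.frame(vid = vid, gene = genes[gene_of],
                          freq_class = freq_class,
                          planted_maf = planted_maf,
                          case_freq = p_case, control_freq = p_ctrl,
                          qualifying = qualifying, clinvar = clinvar),
    risk_sets = risk_sets,
    genes = genes,
    n_extra_control_singletons = extra,
    params = params)
  list(dataset = dataset, truth = truth)
}

#' Plant QC violations into a clean cohort
#'
#' Injects a planned set of rule violations so the QC cascade can be
#' tested against a known manifest: hard-filter metric breaches, site
#' missingness, Hardy-Weinberg breaches (heterozygote deficit in
#' controls), low/excess depth, and duplicated samples for the
#' relatedness check. Target sites are chosen disjointly at random.
#'
#' @param dataset a [cohort_dataset()] whose sites currently pass QC.
#' @param plan named integer vector of violation counts; supported names:
#'   `qd`, `sor`, `qual`, `missingness`, `hwe`, `low_depth`,
#'   `excess_depth`, `duplicate_sample`.
#' @param seed RNG seed for target selection.
#' @return list: `dataset` (modified) and `manifest` (data.frame with
#'   columns `unit` (vid or sample pair), `rule`).
#' @export
plant_qc_violations <- function(dataset, plan, seed = 1L) {
  set.seed(seed)
  site_rules <- c("qd", "sor", "qual", "missingness", "hwe",
                  "low_depth", "excess_depth")
  bad <- setdiff(names(plan), c(site_rules, "duplicate_sample"))
  if (length(bad)) stop("unknown violation type(s): ",
                        paste(bad, collapse = ", "))
  n_sites_needed <- sum(plan[names(plan) %in% site_rules])
  m <- ncol(dataset$geno)
  if (n_sites_needed > m) stop("plan exceeds the number of sites")
  targets <- sample.int(m, n_sites_needed)
  manifest <- list()
  take_sites <- function(k) {
    out <- targets[seq_len(k)]; targets <<- targets[-seq_len(k)]; out
  }
  ctrl <- dataset$samples$phenotype == "control"
  n <- nrow(dataset$geno)
  for (rule in intersect(names(plan), site_rules)) {
    k <- plan[[rule]]
    if (k == 0L) next
    sites <- take_sites(k)
    vids <- dataset$variants$vid[sites]
    for (j in seq_along(sites)) {
      s <- sites[j]
      switch(rule,
        qd = { dataset$variants$QD[s] <- stats::runif(1, 0.1, 1.9) },
        sor = { dataset$variants$SOR[s] <-
          if (dataset$variants$vtype[s] == "snv")
            stats::runif(1, 3.5, 6) else stats::runif(1, 10.5, 14) },
        qual = { dataset$variants$qual[s] <- stats::runif(1, 5, 45) },
        missingness = {
          rows <- sample.int(n, ceiling(0.08 * n))
          dataset$geno[rows, s] <- NA_integer_
        },
        hwe = {
          # extreme heterozygote deficit among controls
          cr <- which(ctrl)
          dataset$geno[cr, s] <- 0L
          dataset$geno[sample(cr, max(8L, round(0.02 * length(cr)))),
                       s] <- 2L
        },
        low_depth = {
          if (is.null(dataset$dp)) stop("dataset has no DP matrix")
          rows <- sample.int(n, ceiling(0.10 * n))
          dataset$dp[rows, s] <- sample(0:8, length(rows), replace = TRUE)
        },
        excess_depth = {
          if (is.null(dataset$dp)) stop("dataset has no DP matrix")
          dataset$dp[, s] <- as.integer(round(3 * mean(dataset$dp)))
        })
    }
    manifest[[rule]] <- data.frame(unit = vids, rule = rule)
  }
  if (!is.null(plan[["duplicate_sample"]]) &&
      plan[["duplicate_sample"]] > 0L) {
    k <- plan[["duplicate_sample"]]
    picks <- matrix(sample.int(n, 2L * k), ncol = 2L)
    for (r in seq_len(k)) {
      src <- picks[r, 1]; dst <- picks[r, 2]
      dataset$geno[dst, ] <- dataset$geno[src, ]
    }
    manifest[["duplicate_sample"]] <- data.frame(
      unit = paste(rownames(dataset$geno)[picks[, 1]],
                   rownames(dataset$geno)[picks[, 2]], sep = "|"),
      rule = "duplicate_sample")
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(dataset = dataset, manifest = manifest)
}
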