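# Independent oracles: brute-force enumerations and exact-arithmetic
# reference implementations, deliberately written along different paths
# than the package code they check.

# upper-tail hypergeometric by full enumeration with the stable ratio
# recurrence (exact up to float rounding of the ratios)
hyper_upper_oracle <- function(a, b, c_, d) {
  m <- a + c_; nn <- b + d; k <- a + b
  lo <- max(0L, k - nn); hi <- min(k, m)
  x <- lo:hi
  w <- numeric(length(x))
  w[1] <- 1
  if (length(x) > 1L) {
    for (i in seq_len(length(x) - 1L)) {
      xi <- x[i]
      w[i + 1L] <- w[i] * (m - xi) / (xi + 1) * (k - xi) /
        (nn - k + xi + 1)
    }
  }
  w <- w / sum(w)
  sum(w[x >= a])
}

# HWE exact two-sided p by direct log-factorial enumeration over all
# feasible heterozygote counts (independent of the package recurrence)
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_minor == 0) return(1)
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (n_minor - h) / 2; nAA <- (n_major - h) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2) + lfactorial(n_minor) + lfactorial(n_major) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[hets == n_Aa]
  sum(p[p <= obs * (1 + 1e-9)])
}

# exact two-sided binomial p: sum of outcome probabilities not exceeding
# the observed one (same tie convention as stats::binom.test)
binom_two_sided_oracle <- function(x, n, f) {
  d <- stats::dbinom(0:n, n, f)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Cochran-Armitage Z from integer arithmetic: every product below stays
# within 2^53 for the table sizes used, so the only rounding is the
# final square root
ca_trend_oracle_z <- function(tab, scores) {
  r <- tab[1, ]; n_i <- colSums(tab)
  R <- sum(r); N <- sum(n_i)
  num <- N * sum(scores * r) - R * sum(scores * n_i)      # integer exact
  den2 <- R * (N - R) * (N * sum(scores^2 * n_i) - sum(scores * n_i)^2)
  num * sqrt((N - 1) / den2)
}

# permutation-FDR by the literal double loop of the frozen definition
fdr_bruteforce <- function(obs, null_mat) {
  B <- nrow(null_mat); n <- length(obs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nc <- 0
    for (b in seq_len(B)) nc <- nc + sum(null_mat[b, ] <= obs[i])
    oc <- sum(obs <= obs[i])
    out[i] <- min(1, max(nc / B / oc, obs[i], 1 / (B * n)))
  }
  o <- order(obs, decreasing = TRUE)
  out[o] <- cummin(out[o])
  out
}

# exhaustive RVTT oracle for tiny cohorts: recomputes counts, tables and
# the trend maximum with plain loops over every case/control assignment
rvtt_exhaustive_oracle <- function(geno, maf, thresholds, n_case,
                                   cap = 3L) {
  n <- nrow(geno)
  tmax_for <- function(y) {
    best <- -Inf
    for (t in thresholds) {
      counts <- integer(n)
      for (i in seq_len(n)) for (j in seq_len(ncol(geno)))
        if (maf[j] <= t && !is.na(geno[i, j]))
          counts[i] <- counts[i] + geno[i, j]
      cat_i <- pmin(counts, cap)
      lev <- sort(unique(cat_i))
      if (length(lev) < 2L) next
      tab <- rbind(case = vapply(lev, function(l) sum(cat_i == l & y == 1),
                                 numeric(1)),
                   control = vapply(lev, function(l)
                     sum(cat_i == l & y == 0), numeric(1)))
      z <- ca_trend(tab, lev)
      if (!isTRUE(z$untestable) && z$Z > best) best <- z$Z
    }
    best
  }
  y0 <- rep(0L, n); y0[seq_len(n_case)] <- 1L
  t_obs <- tmax_for(y0)
  combos <- utils::combn(n, n_case)
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    y <- rep(0L, n); y[combos[, j]] <- 1L
    if (tmax_for(y) >= t_obs - 1e-12) hits <- hits + 1L
  }
  list(T_max = t_obs, p = hits / ncol(combos))
}
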