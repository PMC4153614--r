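# Independent brute-force oracles, coded directly from the defining
# formulas with plain loops. They share no code with the package internals
# they are used to check.

# Weir & Cockerham (1984) theta from raw genotype tables.
oracle_wc_theta <- function(a1, a2, pop) {
  pop <- as.factor(pop)
  loci <- seq_len(ncol(a1))
  sum_a <- 0; sum_abc <- 0
  for (l in loci) {
    keep <- !is.na(a1[, l])
    if (!any(keep)) next
    x1 <- a1[keep, l]; x2 <- a2[keep, l]; pp <- droplevels(pop[keep])
    if (nlevels(pp) < 2) next
    alleles <- sort(unique(c(x1, x2)))
    r <- nlevels(pp)
    n_i <- as.numeric(table(pp))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        in_pop <- pp == levels(pp)[k]
        p_i[k] <- (sum(x1[in_pop] == al) + sum(x2[in_pop] == al)) /
          (2 * n_i[k])
        h_i[k] <- sum((x1[in_pop] == al) != (x2[in_pop] == al)) / n_i[k]
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# Jost's D for two populations with the sample-size-corrected H_S / H_T
# estimators; harmonic mean across loci with positive estimates.
oracle_jost_d_pair <- function(a1, a2, pop) {
  pop <- as.factor(pop)
  stopifnot(nlevels(pop) == 2)
  d_l <- c()
  for (l in seq_len(ncol(a1))) {
    keep <- !is.na(a1[, l])
    x1 <- a1[keep, l]; x2 <- a2[keep, l]; pp <- droplevels(pop[keep])
    if (nlevels(pp) < 2) next
    alleles <- sort(unique(c(x1, x2)))
    n <- as.numeric(table(pp))
    P <- matrix(0, 2, length(alleles))
    for (k in 1:2) {
      in_pop <- pp == levels(pp)[k]
      for (j in seq_along(alleles)) {
        P[k, j] <- (sum(x1[in_pop] == alleles[j]) +
                      sum(x2[in_pop] == alleles[j])) / (2 * n[k])
      }
    }
    ntil <- 2 / (1 / n[1] + 1 / n[2])
    hs <- 1 - mean(c(sum(P[1, ]^2), sum(P[2, ]^2)))
    ht <- 1 - sum(colMeans(P)^2)
    hs_est <- (2 * ntil / (2 * ntil - 1)) * hs
    ht_est <- ht + hs_est / (4 * ntil)
    if (1 - hs_est <= 0) next
    d_l <- c(d_l, ((ht_est - hs_est) / (1 - hs_est)) * 2)
  }
  pos <- d_l[d_l > 0]
  if (length(pos) == 0) return(0)
  length(pos) / sum(1 / pos)
}

# Dense Moore-Penrose effective resistance straight from the edge list.
oracle_resistance_dense <- function(edges, n, i, j) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$i[k]; b <- edges$j[k]; g <- edges$conductance[k]
    L[a, b] <- L[a, b] - g
    L[b, a] <- L[b, a] - g
    L[a, a] <- L[a, a] + g
    L[b, b] <- L[b, b] + g
  }
  Lp <- MASS::ginv(L)
  Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
}

# Random small genotype dataset (codes 1..k alleles, no missing data).
random_dataset <- function(seed, n_pops = 3, n_loci = 4, n_ind = 12,
                           n_alleles = 2) {
  set.seed(seed)
  total <- n_pops * n_ind
  a1 <- matrix(sample.int(n_alleles, total * n_loci, replace = TRUE),
               total, n_loci)
  a2 <- matrix(sample.int(n_alleles, total * n_loci, replace = TRUE),
               total, n_loci)
  genotype_dataset(a1, a2, rep(paste0("p", seq_len(n_pops)), each = n_ind))
}

# Random connected conductance grid for resistance checks.
random_grid <- function(seed, nr = 8, nc = 8) {
  set.seed(seed)
  matrix(stats::runif(nr * nc, 0.05, 1), nr, nc)
}
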