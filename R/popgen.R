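# Genetic diversity and differentiation statistics.
#
# Differentiation uses the Weir & Cockerham (1984) variance-components
# estimator theta for F_ST and Jost's D with the nearly unbiased
# heterozygosity estimators (Nei & Chesser correction, harmonic-mean sample
# size) for D_est. Both are multi-locus: theta as the ratio of summed
# variance components, D as the harmonic mean of positive per-locus
# estimates (the smogd convention).

# Per-locus, per-population allele summary for one locus of a dataset.
# Returns NULL if fewer than 2 populations carry data at the locus.
locus_summary <- function(ds, l) {
  a1 <- ds$a1[, l]; a2 <- ds$a2[, l]
  typed <- !is.na(a1)
  if (!any(typed)) return(NULL)
  pops <- levels(ds$pop)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  r <- length(pops)
  n <- as.vector(tapply(typed, ds$pop, sum, default = 0L))
  P <- matrix(0, r, length(alleles), dimnames = list(pops, alleles))
  H <- P
  for (j in seq_along(alleles)) {
    a <- alleles[j]
    cnt <- (a1 == a) + (a2 == a)
    P[, j] <- as.vector(tapply(ifelse(typed, cnt, 0), ds$pop, sum,
                               default = 0))
    H[, j] <- as.vector(tapply(ifelse(typed, cnt == 1L, 0), ds$pop, sum,
                               default = 0))
  }
  use <- n > 0
  if (sum(use) < 2) return(NULL)
  list(n = n[use], p = P[use, , drop = FALSE] / (2 * n[use]),
       h = H[use, , drop = FALSE] / n[use], alleles = alleles)
}

# Weir & Cockerham (1984) variance components a (among populations),
# b (among individuals within populations), c (within individuals),
# summed over the alleles of one locus summary.
wc_locus_components <- function(s) {
  n <- s$n; r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  for (j in seq_len(ncol(s$p))) {
    p <- s$p[, j]; h <- s$h[, j]
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

# Multi-locus theta: ratio of summed components across loci.
wc_theta <- function(ds) {
  comps <- vapply(seq_along(ds$loci), function(l) {
    s <- locus_summary(ds, l)
    if (is.null(s)) return(c(a = 0, b = 0, c = 0))
    wc_locus_components(s)
  }, numeric(3))
  tot <- sum(comps)
  if (tot == 0) return(NA_real_)
  sum(comps["a", ]) / tot
}

# Jost's D for one locus summary across r populations: nearly unbiased
# H_S and H_T with harmonic-mean sample size, scaled by r/(r-1).
jost_d_locus <- function(s) {
  n <- s$n; r <- length(n)
  ntil <- r / sum(1 / n)
  hs <- mean(1 - rowSums(s$p^2))
  pbar <- colMeans(s$p)
  ht <- 1 - sum(pbar^2)
  hs_est <- (2 * ntil / (2 * ntil - 1)) * hs
  ht_est <- ht + hs_est / (2 * ntil * r)
  if (1 - hs_est <= 0) return(NA_real_)
  ((ht_est - hs_est) / (1 - hs_est)) * r / (r - 1)
}

# Multi-locus D: harmonic mean over loci with positive estimates; 0 when no
# locus estimate is positive (flagged upstream).
jost_d <- function(ds) {
  dl <- vapply(seq_along(ds$loci), function(l) {
    s <- locus_summary(ds, l)
    if (is.null(s)) return(NA_real_)
    jost_d_locus(s)
  }, numeric(1))
  dl <- dl[is.finite(dl)]
  if (length(dl) == 0) return(NA_real_)
  pos <- dl[dl > 0]
  if (length(pos) == 0) return(0)
  length(pos) / sum(1 / pos)
}

#' Per-population diversity summary
#'
#' For each population: rarefied allelic richness (AR), unbiased expected
#' heterozygosity (He, percent), observed heterozygosity (Ho, percent), and
#' the percentage of polymorphic loci under the total (`P_tot`, any second
#' allele) and 95 percent (`P_95`, most common allele at frequency <= 0.95)
#' criteria; plus the mean and standard error across populations.
#'
#' He per locus uses the unbiased estimator `(2n/(2n-1)) (1 - sum p^2)`
#' averaged over loci; AR rarefies allele counts to `g` gene copies via the
#' hypergeometric expectation `sum_a [1 - C(N - N_a, g) / C(N, g)]`.
#'
#' @param ds A [genotype_dataset()].
#' @param rarefaction_g Number of gene copies to rarefy to (>= 2 and at most
#'   twice the smallest per-locus sample size).
#' @return Data frame with one row per population plus `mean` and `se` rows;
#'   columns `AR`, `He`, `Ho`, `P_tot`, `P_95` (heterozygosities and
#'   polymorphism percentages on the 0-100 scale).
#' @export
diversity_summary <- function(ds, rarefaction_g = NULL) {
  pops <- levels(ds$pop)
  nloc <- length(ds$loci)
  # smallest per-population, per-locus sample (gene copies)
  min_copies <- Inf
  for (p in pops) {
    idx <- ds$pop == p
    assert_that(any(idx), paste0("population ", p, " is empty"))
    typed <- !is.na(ds$a1[idx, , drop = FALSE])
    min_copies <- min(min_copies, 2 * colSums(typed))
  }
  if (is.null(rarefaction_g)) rarefaction_g <- max(2, min_copies)
  assert_that(rarefaction_g >= 2, "rarefaction_g must be >= 2")
  assert_that(rarefaction_g <= min_copies,
              "rarefaction_g exceeds twice the smallest per-locus sample")
  res <- data.frame(population = pops, AR = NA_real_, He = NA_real_,
                    Ho = NA_real_, P_tot = NA_real_, P_95 = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(pops)) {
    idx <- ds$pop == pops[k]
    ar <- he <- ho <- numeric(nloc)
    poly_tot <- poly_95 <- logical(nloc)
    for (l in seq_len(nloc)) {
      a1 <- ds$a1[idx, l]; a2 <- ds$a2[idx, l]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n == 0) { ar[l] <- NA; he[l] <- NA; ho[l] <- NA; next }
      copies <- c(a1[ok], a2[ok])
      tab <- table(copies)
      p <- as.numeric(tab) / (2 * n)
      he[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      ho[l] <- mean(a1[ok] != a2[ok])
      ar[l] <- rarefied_richness(as.numeric(tab), rarefaction_g)
      poly_tot[l] <- length(tab) > 1
      poly_95[l] <- max(p) <= 0.95
    }
    res$AR[k] <- mean(ar, na.rm = TRUE)
    res$He[k] <- 100 * mean(he, na.rm = TRUE)
    res$Ho[k] <- 100 * mean(ho, na.rm = TRUE)
    res$P_tot[k] <- 100 * mean(poly_tot[!is.na(ar)])
    res$P_95[k] <- 100 * mean(poly_95[!is.na(ar)])
  }
  summary_rows <- data.frame(
    population = c("mean", "se"),
    AR = c(mean(res$AR), se(res$AR)),
    He = c(mean(res$He), se(res$He)),
    Ho = c(mean(res$Ho), se(res$Ho)),
    P_tot = c(mean(res$P_tot), se(res$P_tot)),
    P_95 = c(mean(res$P_95), se(res$P_95)),
    stringsAsFactors = FALSE)
  rbind(res, summary_rows)
}

#' Rarefied allelic richness for one locus
#'
#' Expected number of alleles in a random subsample of `g` gene copies:
#' `sum_a [1 - C(N - N_a, g) / C(N, g)]` with `N` total copies and `N_a`
#' copies of allele `a`.
#'
#' @param counts Allele copy counts at the locus.
#' @param g Rarefaction size in gene copies.
#' @return Expected allele count, in `[1, length(counts)]`.
#' @export
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  assert_that(g <= N, "rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Per population and locus: shuffles the allele copies within the
#' population and compares the observed heterozygote count against its
#' permutation distribution, two-sided around the Hardy-Weinberg
#' expectation. `p = (1 + n_as_or_more_extreme) / (1 + n_shuffles)`.
#' Loci monomorphic within a population are reported as `p = 1` and
#' flagged (no test possible).
#'
#' @param ds A [genotype_dataset()].
#' @param n_shuffles Number of shuffles (>= 999).
#' @param seed RNG seed.
#' @return Data frame with columns `population`, `locus`, `p`,
#'   `monomorphic`.
#' @export
hwe_test <- function(ds, n_shuffles = 999, seed = 1) {
  assert_that(n_shuffles >= 999, "n_shuffles must be >= 999")
  pops <- levels(ds$pop)
  out <- list()
  with_seed(seed, {
    for (p in pops) {
      idx <- which(ds$pop == p)
      for (l in seq_along(ds$loci)) {
        a1 <- ds$a1[idx, l]; a2 <- ds$a2[idx, l]
        ok <- !is.na(a1)
        copies <- c(a1[ok], a2[ok])
        mono <- length(unique(copies)) < 2
        if (mono || sum(ok) < 2) {
          out[[length(out) + 1L]] <-
            data.frame(population = p, locus = ds$loci[l], p = 1,
                       monomorphic = TRUE, stringsAsFactors = FALSE)
          next
        }
        n <- sum(ok)
        freq <- table(copies) / (2 * n)
        expected_het <- n * (1 - sum(freq^2)) * (2 * n) / (2 * n - 1)
        d_obs <- abs(sum(a1[ok] != a2[ok]) - expected_het)
        extreme <- 0L
        for (s in seq_len(n_shuffles)) {
          perm <- sample(copies)
          het <- sum(perm[seq_len(n)] != perm[n + seq_len(n)])
          if (abs(het - expected_het) >= d_obs - 1e-12) extreme <- extreme + 1L
        }
        out[[length(out) + 1L]] <-
          data.frame(population = p, locus = ds$loci[l],
                     p = (1 + extreme) / (1 + n_shuffles),
                     monomorphic = FALSE, stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, out)
}

# Shared pairwise-matrix scaffolding.
pairwise_matrix <- function(ds, fun, metric) {
  pops <- levels(ds$pop)
  assert_that(length(pops) >= 2, "need at least 2 populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  flags <- character(0)
  for (i in seq_along(pops)[-1]) {
    for (j in seq_len(i - 1)) {
      v <- fun(subset_pops(ds, c(pops[j], pops[i])))
      if (!is.finite(v)) {
        flags <- c(flags, paste0(pops[j], ":", pops[i], " undefined"))
        v <- NA_real_
      } else if (v < 0) {
        flags <- c(flags, paste0(pops[j], ":", pops[i], " negative estimate"))
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  structure(list(metric = metric, ids = pops, values = m, flags = flags,
                 global = NULL, p = NULL),
            class = "diff_matrix")
}

#' Pairwise F_ST (Weir-Cockerham theta)
#'
#' Multi-locus theta for every population pair, computed on each pair alone
#' as the ratio of summed among-population variance components to summed
#' total variance components across loci. Negative estimates are reported
#' as computed and flagged, not clamped.
#'
#' @param ds A [genotype_dataset()] with at least 2 populations.
#' @return A `diff_matrix`: list with `metric`, `ids`, symmetric `values`
#'   matrix (zero diagonal), and `flags`.
#' @export
pairwise_fst <- function(ds) pairwise_matrix(ds, wc_theta, "F_ST")

#' Pairwise Jost's D_est
#'
#' Jost's D per pair with the nearly unbiased H_S / H_T estimators
#' (harmonic-mean sample size) and the `n/(n-1)` correction with `n = 2`
#' populations; multi-locus value as the harmonic mean of positive
#' per-locus estimates.
#'
#' @param ds A [genotype_dataset()] with at least 2 populations.
#' @return A `diff_matrix` (see [pairwise_fst()]).
#' @export
pairwise_dest <- function(ds) pairwise_matrix(ds, jost_d, "D_est")

#' @export
print.diff_matrix <- function(x, ...) {
  cat(sprintf("diff_matrix (%s), %d populations\n", x$metric,
              length(x$ids)))
  if (!is.null(x$global)) {
    cat(sprintf("  global = %.4f, permutation p = %.4g\n", x$global, x$p))
  }
  if (length(x$flags)) cat("  flags:", length(x$flags), "entries\n")
  invisible(x)
}

# --- fast biallelic path for the permutation screen ---------------------

# Recode to 0/1/2 counts of the second allele per locus; NULL if any locus
# carries more than two alleles.
recode_biallelic <- function(ds) {
  nloc <- ncol(ds$a1)
  x <- matrix(0, nrow(ds$a1), nloc)
  het <- matrix(0, nrow(ds$a1), nloc)
  typed <- !is.na(ds$a1)
  for (l in seq_len(nloc)) {
    codes <- sort(unique(c(ds$a1[typed[, l], l], ds$a2[typed[, l], l])))
    if (length(codes) > 2) return(NULL)
    if (length(codes) == 2) {
      ref <- codes[2]
      cnt <- (ds$a1[, l] == ref) + (ds$a2[, l] == ref)
      cnt[!typed[, l]] <- 0
      x[, l] <- cnt
      h <- ds$a1[, l] != ds$a2[, l]
      h[!typed[, l]] <- FALSE
      het[, l] <- h
    }
  }
  list(x = x, het = het, typed = typed * 1)
}

# Vectorised multi-locus theta from the biallelic recode, for a given
# population labelling. Matrix ops only, so the permutation screen stays
# fast.
theta_fast <- function(rc, pop) {
  n <- rowsum(rc$typed, pop)                      # pops x loci
  sx <- rowsum(rc$x * rc$typed, pop)
  sh <- rowsum(rc$het * rc$typed, pop)
  use <- colSums(n > 0) >= 2
  n <- n[, use, drop = FALSE]; sx <- sx[, use, drop = FALSE]
  sh <- sh[, use, drop = FALSE]
  r <- colSums(n > 0)
  # guard: pops absent at a locus contribute 0 to every sum below
  p <- ifelse(n > 0, sx / (2 * pmax(n, 1)), 0)
  h <- ifelse(n > 0, sh / pmax(n, 1), 0)
  nbar <- colSums(n) / r
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2 * (n > 0)) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- sum(2 * (a + b + cc))   # both alleles carry identical components
  if (tot == 0) return(NA_real_)
  sum(2 * a) / tot
}

# Vectorised multi-locus Jost D (harmonic mean over positive loci).
dest_fast <- function(rc, pop) {
  n <- rowsum(rc$typed, pop)
  sx <- rowsum(rc$x * rc$typed, pop)
  use <- colSums(n > 0) >= 2
  n <- n[, use, drop = FALSE]; sx <- sx[, use, drop = FALSE]
  r <- colSums(n > 0)
  p <- ifelse(n > 0, sx / (2 * pmax(n, 1)), NA)
  ntil <- r / colSums(ifelse(n > 0, 1 / pmax(n, 1), 0))
  hs <- colMeans(1 - (p^2 + (1 - p)^2), na.rm = TRUE)
  pbar <- colMeans(p, na.rm = TRUE)
  ht <- 1 - (pbar^2 + (1 - pbar)^2)
  hs_est <- (2 * ntil / (2 * ntil - 1)) * hs
  ht_est <- ht + hs_est / (2 * ntil * r)
  d <- ((ht_est - hs_est) / (1 - hs_est)) * r / (r - 1)
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  pos <- d[d > 0]
  if (length(pos) == 0) return(0)
  length(pos) / sum(1 / pos)
}

#' Global differentiation with a permutation panmixia screen
#'
#' Computes the global multi-locus statistic (theta or Jost's D over all
#' populations) and a permutation p-value obtained by shuffling individuals
#' among populations with sample sizes preserved:
#' `p = (1 + n_perm_ge_observed) / (1 + n_perm)`. A non-significant p is
#' the package's panmixia screen.
#'
#' @param ds A [genotype_dataset()].
#' @param metric `"fst"` or `"dest"`.
#' @param n_perm Number of permutations (>= 99; use >= 999 for reporting).
#' @param seed RNG seed.
#' @return List with `metric`, `value`, `p`, `n_perm`.
#' @export
global_differentiation <- function(ds, metric = c("fst", "dest"),
                                   n_perm = 999, seed = 1) {
  metric <- match.arg(metric)
  assert_that(n_perm >= 99, "n_perm must be >= 99")
  rc <- recode_biallelic(ds)
  stat <- if (!is.null(rc)) {
    f <- if (metric == "fst") theta_fast else dest_fast
    function(pop) f(rc, pop)
  } else {
    g <- if (metric == "fst") wc_theta else jost_d
    function(pop) {
      ds2 <- ds; ds2$pop <- pop
      g(ds2)
    }
  }
  obs <- stat(ds$pop)
  with_seed(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- stat(sample(ds$pop))
      if (is.finite(perm) && perm >= obs - 1e-12) ge <- ge + 1L
    }
    list(metric = metric, value = obs, p = (1 + ge) / (1 + n_perm),
         n_perm = n_perm)
  })
}
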