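test_that("theta is 1 under complete fixation and ~0 for identical tables", {
  a1 <- matrix(c(rep(1L, 10), rep(2L, 10)), ncol = 1)
  ds <- genotype_dataset(a1, a1, rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst(ds)$values["A", "B"], 1)

  set.seed(42)
  half <- cbind(sample(1:2, 50, TRUE), sample(1:2, 50, TRUE),
                sample(1:2, 50, TRUE))
  a1 <- rbind(half, half)
  half2 <- cbind(sample(1:2, 50, TRUE), sample(1:2, 50, TRUE),
                 sample(1:2, 50, TRUE))
  a2 <- rbind(half2, half2)
  ds <- genotype_dataset(a1, a2, rep(c("A", "B"), each = 50))
  th <- pairwise_fst(ds)$values["A", "B"]
  expect_lte(th, 0)
  expect_lt(abs(th), 0.02)
  expect_true(any(grepl("negative", pairwise_fst(ds)$flags)))
})

test_that("theta matches the brute-force variance-components oracle", {
  for (seed in 1:25) {
    n_alleles <- 2 + seed %% 3
    ds <- random_dataset(seed, n_pops = 2 + seed %% 3, n_loci = 5,
                         n_ind = 15, n_alleles = n_alleles)
    expect_equal(pairwise_fst(ds)$values[2, 1],
                 oracle_wc_theta(ds$a1[ds$pop %in% levels(ds$pop)[1:2], ],
                                 ds$a2[ds$pop %in% levels(ds$pop)[1:2], ],
                                 droplevels(ds$pop[ds$pop %in%
                                                     levels(ds$pop)[1:2]])),
                 tolerance = 1e-10)
  }
})

test_that("Jost's D hits its closed forms and matches the hand oracle", {
  a1 <- matrix(c(rep(1L, 10), rep(2L, 10)), ncol = 1)
  ds <- genotype_dataset(a1, a1, rep(c("A", "B"), each = 10))
  expect_equal(pairwise_dest(ds)$values["A", "B"], 1)

  # identical genotype tables: every per-locus estimate is slightly
  # negative, so the harmonic-mean-over-positives convention returns 0
  set.seed(7)
  half <- cbind(sample(1:2, 40, TRUE), sample(1:2, 40, TRUE))
  ds2 <- genotype_dataset(rbind(half, half), rbind(half, half),
                          rep(c("A", "B"), each = 40))
  expect_equal(pairwise_dest(ds2)$values["A", "B"], 0)

  for (seed in 26:50) {
    ds <- random_dataset(seed, n_pops = 2, n_loci = 4, n_ind = 14,
                         n_alleles = 2 + seed %% 3)
    expect_equal(pairwise_dest(ds)$values[2, 1],
                 oracle_jost_d_pair(ds$a1, ds$a2, ds$pop),
                 tolerance = 1e-10)
  }
})

test_that("diff matrices are symmetric with zero diagonal", {
  ds <- random_dataset(99, n_pops = 4, n_loci = 5, n_ind = 12)
  for (m in list(pairwise_fst(ds), pairwise_dest(ds))) {
    expect_equal(m$values, t(m$values))
    expect_equal(diag(m$values), setNames(rep(0, 4), levels(ds$pop)))
  }
})

test_that("diversity summary reproduces hand-computed values", {
  # one locus, two alleles at 0.5 in perfect HW-like state (all het), n=50:
  # unbiased He = (100/99) * 0.5 * 100 = 50.505..., Ho = 100
  ds <- genotype_dataset(matrix(rep(1L, 50), ncol = 1),
                         matrix(rep(2L, 50), ncol = 1), rep("A", 50))
  dv <- diversity_summary(ds, rarefaction_g = 2)
  expect_equal(dv$He[1], 100 * (100 / 99) * 0.5, tolerance = 1e-12)
  expect_equal(dv$Ho[1], 100)
  expect_equal(dv$P_tot[1], 100)

  # monomorphic locus: He = Ho = 0, AR = 1, not polymorphic
  ds0 <- genotype_dataset(matrix(rep(1L, 20), ncol = 1),
                          matrix(rep(1L, 20), ncol = 1), rep("A", 20))
  dv0 <- diversity_summary(ds0, rarefaction_g = 2)
  expect_equal(dv0$He[1], 0)
  expect_equal(dv0$Ho[1], 0)
  expect_equal(dv0$AR[1], 1)
  expect_equal(dv0$P_tot[1], 0)
})

test_that("rarefied richness matches exhaustive subsample enumeration", {
  # alleles A,A,A,B at g = 2: 1 + [1 - C(3,2)/C(4,2)] = 1.5
  expect_equal(rarefied_richness(c(3, 1), 2), 1.5)
  # exhaustive enumeration oracle on a 3-allele toy
  counts <- c(4, 2, 1); N <- sum(counts); g <- 3
  pool <- rep(seq_along(counts), counts)
  subs <- combn(N, g)
  expected <- mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
  expect_equal(rarefied_richness(counts, g), expected, tolerance = 1e-12)
  # non-decreasing in g; at g = N equals the observed allele count
  ar <- sapply(2:N, function(gg) rarefied_richness(counts, gg))
  expect_true(all(diff(ar) >= -1e-12))
  expect_equal(rarefied_richness(counts, N), 3)
})

test_that("HWE test flags heterozygote deficit and passes HW data", {
  # all homozygotes at a 50/50 two-allele locus, n = 20: extreme deficit
  a <- matrix(rep(c(1L, 2L), each = 10), ncol = 1)
  ds <- genotype_dataset(a, a, rep("A", 20))
  res <- hwe_test(ds, n_shuffles = 999, seed = 3)
  expect_lt(res$p, 0.01)

  # perfect HW proportions at p = 0.5, n = 100: 25/50/25
  a1 <- matrix(c(rep(1L, 75), rep(2L, 25)), ncol = 1)
  a2 <- matrix(c(rep(1L, 25), rep(2L, 75)), ncol = 1)
  dsh <- genotype_dataset(a1, a2, rep("A", 100))
  expect_gt(hwe_test(dsh, n_shuffles = 999, seed = 4)$p, 0.05)

  # monomorphic: p = 1 and flagged
  ds0 <- genotype_dataset(matrix(rep(1L, 20), ncol = 1),
                          matrix(rep(1L, 20), ncol = 1), rep("A", 20))
  r0 <- hwe_test(ds0, n_shuffles = 999, seed = 5)
  expect_equal(r0$p, 1)
  expect_true(r0$monomorphic)
})

test_that("global differentiation is ~0 for a duplicated population", {
  set.seed(11)
  half <- matrix(sample(1:2, 100, TRUE), 20, 5)
  half2 <- matrix(sample(1:2, 100, TRUE), 20, 5)
  ds <- genotype_dataset(rbind(half, half), rbind(half2, half2),
                         rep(c("A", "B"), each = 20))
  g <- global_differentiation(ds, "fst", n_perm = 99, seed = 1)
  expect_lt(abs(g$value), 0.05)
  expect_gt(g$p, 0.05)
})

test_that("fast global statistics agree with the general estimators", {
  for (seed in 1:5) {
    ds <- random_dataset(seed + 200, n_pops = 4, n_loci = 6, n_ind = 15,
                         n_alleles = 2)
    rc <- ibrscape:::recode_biallelic(ds)
    expect_equal(ibrscape:::theta_fast(rc, ds$pop), ibrscape:::wc_theta(ds),
                 tolerance = 1e-10)
    expect_equal(ibrscape:::dest_fast(rc, ds$pop), ibrscape:::jost_d(ds),
                 tolerance = 1e-10)
  }
})
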