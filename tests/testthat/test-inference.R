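test_that("lower-triangle unfolding uses the stated pair order", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 21
  m[3, 1] <- m[1, 3] <- 31
  m[3, 2] <- m[2, 3] <- 32
  expect_equal(lower_triangle(m), c(21, 31, 32))
  # row-major order for n = 4: (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)
  m4 <- matrix(0, 4, 4)
  for (i in 2:4) for (j in seq_len(i - 1)) m4[i, j] <- m4[j, i] <- 10 * i + j
  expect_equal(lower_triangle(m4), c(21, 31, 32, 41, 42, 43))
  expect_length(lower_triangle(diag(0, 12)), 66)
  ma <- m; ma[1, 2] <- 99
  expect_error(lower_triangle(ma), "asymmetric")
})

test_that("euclidean distances are planar and translation invariant", {
  s <- data.frame(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  d <- euclidean_distance_matrix(s)
  expect_equal(d["a", "b"], 5)
  s2 <- transform(s, x = x + 100, y = y - 50)
  expect_equal(unclass(euclidean_distance_matrix(s2)), unclass(d),
               ignore_attr = TRUE)
  s3 <- data.frame(id = c("a", "b"), x = c(1, 1), y = c(2, 2))
  d3 <- euclidean_distance_matrix(s3)
  expect_equal(d3["a", "b"], 0)
  expect_length(attr(d3, "duplicates"), 1)
})

test_that("distance regression matches the normal-equations oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 20
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    r <- distance_regression(y, x)
    # closed-form normal equations
    sl <- cov(x, y) / var(x); ic <- mean(y) - sl * mean(x)
    rss <- sum((y - ic - sl * x)^2)
    expect_equal(r$slope, sl, tolerance = 1e-12)
    expect_equal(r$intercept, ic, tolerance = 1e-12)
    expect_equal(r$rss, rss, tolerance = 1e-12)
    ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
    expect_equal(r$aicc, -2 * ll + 6 + 24 / (n - 4), tolerance = 1e-10)
    expect_equal(r$adj_r2, 1 - (1 - r$r2) * (n - 1) / (n - 2),
                 tolerance = 1e-12)
  }
  # degenerate exact fit: RSS floored with a warning
  x <- 1:6
  expect_warning(r <- distance_regression(2 * x, x), "numerically zero")
  expect_equal(r$r2, 1)
  expect_error(distance_regression(rnorm(6), rep(1, 6)), "constant")
})

test_that("adjusted R2 under the null is near zero and can be negative", {
  set.seed(5)
  vals <- replicate(200, {
    distance_regression(rnorm(66), rnorm(66))$adj_r2
  })
  expect_lt(abs(mean(vals)), 0.02)
  expect_true(any(vals < 0))
})

test_that("Akaike weights satisfy the degenerate closed forms", {
  expect_equal(aicc_rank(c(m1 = -100))$weight, 1)
  rk <- aicc_rank(c(a = -10, b = -10, c = -10, d = -10))
  expect_equal(rk$weight, rep(0.25, 4))
  rk2 <- aicc_rank(c(a = 0, b = 2))
  expect_equal(sum(rk2$weight), 1, tolerance = 1e-12)
  expect_equal(rk2$delta_aicc, c(0, 2))
  expect_true(rk2$supported[1] && !rk2$supported[2])
})

test_that("MRDM hits its closed-form cases", {
  set.seed(9)
  n <- 8
  x <- as.matrix(dist(cbind(runif(n), runif(n))))
  # y proportional to x: R2 = 1 and minimal p
  res <- mrdm(3 * x, x, n_perm = 199, seed = 2)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 200)
  # identity permutation reproduces the observed statistic
  yv <- lower_triangle(x[seq_len(n), seq_len(n)])
  expect_equal(lower_triangle(x), yv)
})

test_that("MRDM enumerates exhaustively for tiny matrices", {
  set.seed(10)
  n <- 4  # 4! = 24 < n_perm
  x <- as.matrix(dist(cbind(runif(n), runif(n))))
  ys <- as.matrix(dist(rnorm(n)))
  res <- mrdm(ys, x, n_perm = 999, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 24)
  # exhaustive p is a multiple of 1/24 and at least 1/24
  expect_gte(res$p, 1 / 24)
  expect_equal(res$p * 24, round(res$p * 24), tolerance = 1e-9)
})

test_that("matrix-level permutation is not equivalent to vector shuffling", {
  # response with strong row-and-column structure: y_ij = a_i + a_j.
  # Permuting population labels preserves that structure (correct null);
  # shuffling the unfolded vector destroys it and gives an anti-conservative
  # null with far smaller permuted R2 values.
  set.seed(33)
  n <- 10
  a <- rnorm(n, sd = 2)
  y <- outer(a, a, `+`); diag(y) <- 0
  b <- rnorm(n, sd = 2)
  x <- outer(b, b, `+`); diag(x) <- 0
  yv <- lower_triangle(y); xv <- lower_triangle(x)
  r2 <- function(yy) summary(lm(yy ~ xv))$r.squared
  set.seed(34)
  null_matrix <- replicate(300, {
    pp <- sample.int(n)
    r2(lower_triangle(y[pp, pp]))
  })
  null_vector <- replicate(300, r2(sample(yv)))
  expect_gt(mean(null_matrix), 5 * mean(null_vector))
})

test_that("scenario tables rank, weight and flag support correctly", {
  set.seed(40)
  n <- 10
  sites <- data.frame(id = paste0("p", 1:n), x = runif(n, 0, 50),
                      y = runif(n, 0, 50))
  dmat <- euclidean_distance_matrix(sites)
  truth <- dmat^0.8
  y <- truth / max(truth) * 0.2
  y <- y + as.matrix(dist(rnorm(n, sd = 0.05)))
  diag(y) <- 0
  noise <- as.matrix(dist(rnorm(n)))
  tab <- build_scenario_table(
    y, list(truth = truth, noise = noise, distance = unclass(dmat)),
    metric = "F_ST", n_perm = 199, seed = 3)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(tab$delta_aicc[1], 0)
  expect_equal(sum(tab$delta_aicc == 0), 1)
  expect_true(all(diff(tab$aicc) >= 0))
  expect_true(all(tab$mrdm_r2 >= 0 & tab$mrdm_r2 <= 1))
  # determinism: same seed gives the identical table
  tab2 <- build_scenario_table(
    y, list(truth = truth, noise = noise, distance = unclass(dmat)),
    metric = "F_ST", n_perm = 199, seed = 3)
  expect_identical(tab, tab2)
  expect_error(build_scenario_table(y, list(truth = truth)), "distance")
})
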