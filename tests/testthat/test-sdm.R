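make_test_stack <- function(seed = 1, n = 40) {
  truth <- make_landscape(seed, n, n)
  stack <- truth$layers
  terr <- terrain_slope_aspect(stack$layers$altitude, stack$cellsize)
  stack$layers$slope <- terr$slope
  stack$layers$aspect <- terr$aspect
  stack$kind <- c(stack$kind, slope = "continuous", aspect = "continuous")
  list(truth = truth, stack = stack)
}

test_that("slope and aspect match closed forms on planes", {
  flat <- matrix(5, 6, 6)
  t1 <- terrain_slope_aspect(flat)
  expect_true(all(t1$slope == 0))
  expect_true(all(t1$aspect == -1))

  # plane z = x (unit cell): slope 45 degrees in the interior
  plane <- matrix(rep(1:8, each = 8), 8, 8)
  t2 <- terrain_slope_aspect(plane, cell_size = 1)
  expect_equal(t2$slope[2:7, 2:7], matrix(45, 6, 6))
  # descending due west -> aspect 270 in the interior
  expect_equal(t2$aspect[2:7, 2:7], matrix(270, 6, 6))

  # plane rising southwards (row index): steepest descent toward north
  plane_n <- matrix(rep(1:8, times = 8), 8, 8)
  t3 <- terrain_slope_aspect(plane_n)
  expect_equal(t3$aspect[2:7, 2:7], matrix(0, 6, 6))
})

test_that("resampling preserves identity, constants and class sets", {
  st <- make_test_stack(3)$stack
  expect_identical(resample_stack(st, st$cellsize), st)

  const <- layer_stack(list(k = matrix(7, 20, 20)), c(k = "continuous"))
  rs <- resample_stack(const, 2)
  expect_true(all(rs$layers$k == 7))
  expect_equal(dim(rs), c(10, 10))

  checker <- matrix(rep(c(1L, 2L), 200), 20, 20)
  cs <- layer_stack(list(lu = checker), c(lu = "categorical"))
  down <- resample_stack(cs, 2)
  expect_true(all(down$layers$lu %in% c(1L, 2L)))
})

test_that("correlation screen flags duplicates and negations but not noise", {
  set.seed(2)
  a <- matrix(rnorm(10000), 100, 100)
  b <- matrix(rnorm(10000), 100, 100)
  st <- layer_stack(list(a = a, dup = a, neg = -a, b = b),
                    c(a = "continuous", dup = "continuous",
                      neg = "continuous", b = "continuous"))
  scr <- correlation_screen(st)
  get <- function(l1, l2) {
    scr[(scr$layer1 == l1 & scr$layer2 == l2) |
          (scr$layer1 == l2 & scr$layer2 == l1), ]
  }
  expect_equal(get("a", "dup")$r2, 1)
  expect_true(get("a", "dup")$flagged)
  expect_equal(get("a", "neg")$r2, 1)
  expect_true(get("a", "neg")$flagged)
  expect_lt(get("a", "b")$r2, 0.05)
  expect_false(get("a", "b")$flagged)

  stc <- layer_stack(list(a = a, k = matrix(1, 100, 100)),
                     c(a = "continuous", k = "continuous"))
  expect_equal(attr(correlation_screen(stc), "constant_layers"), "k")
})

test_that("rank-based AUC counts concordant pairs with half ties", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.7, 0.6)), 1)
  expect_equal(auc_score(c(0.9, 0.4), c(0.7, 0.6)), 0.5)
  expect_equal(auc_score(rep(0.5, 4), rep(0.5, 9)), 0.5)
  expect_equal(auc_score(c(1, 0), c(0.5)), 0.5)
})

test_that("the SDM recovers a one-layer truth and is deterministic", {
  ts <- make_test_stack(11)
  truth <- ts$truth; stack <- ts$stack
  pres <- sample_presences(truth, 30, seed = 5)
  scen <- scenario_spec("land use", "land_use")
  fit <- fit_sdm(pres, scen, stack, n_background = 1000, reps = 10,
                 seed = 42)
  expect_gt(fit$mean_auc, 0.6)
  expect_true(all(fit$suitability >= 0 & fit$suitability <= 1))
  expect_true(all(fit$auc >= 0 & fit$auc <= 1))
  fit2 <- fit_sdm(pres, scen, stack, n_background = 1000, reps = 10,
                  seed = 42)
  expect_identical(fit$suitability, fit2$suitability)
  expect_identical(fit$auc, fit2$auc)

  # a multi-layer truth signal is recovered with good discrimination
  scen_all <- scenario_spec("all", c("clim1", "clim2", "clim3", "land_use"))
  fit_all <- fit_sdm(pres, scen_all, stack, n_background = 1000, reps = 10,
                     seed = 42)
  expect_gt(fit_all$mean_auc, 0.6)
})

test_that("uniformly random presences give chance-level AUC", {
  ts <- make_test_stack(12)
  stack <- ts$stack
  set.seed(9)
  pres <- data.frame(row = sample(40, 30, TRUE), col = sample(40, 30, TRUE))
  fit <- fit_sdm(pres, scenario_spec("climate", c("clim1", "clim2")),
                 stack, n_background = 1000, reps = 20, seed = 7)
  expect_gt(fit$mean_auc, 0.4)
  expect_lt(fit$mean_auc, 0.6)
})

test_that("variable contributions are normalised and identify the driver", {
  ts <- make_test_stack(13)
  pres <- sample_presences(ts$truth, 40, seed = 6)
  scen1 <- scenario_spec("land use", "land_use")
  fit1 <- fit_sdm(pres, scen1, ts$stack, n_background = 500, reps = 5,
                  seed = 1)
  vc1 <- variable_contributions(fit1, ts$stack)
  expect_equal(vc1$contribution, 100)

  # truth is land-use-driven, so land use dominates the mixed scenario
  scen <- scenario_spec("mixed", c("clim1", "clim2", "land_use"))
  fit <- fit_sdm(pres, scen, ts$stack, n_background = 1000, reps = 10,
                 seed = 2)
  vc <- variable_contributions(fit, ts$stack, seed = 3)
  expect_equal(sum(vc$contribution), 100, tolerance = 0.01)
  expect_true(all(vc$contribution >= 0))
  expect_gt(vc$contribution[vc$variable == "land_use"], 50)
})

test_that("stability surface is the element-wise mean", {
  a <- matrix(runif(36), 6, 6)
  b <- matrix(runif(36), 6, 6)
  expect_equal(stability_surface(a, b), (a + b) / 2)
  expect_equal(stability_surface(a, a), a)
  expect_equal(stability_surface(matrix(1, 2, 2), matrix(0, 2, 2)),
               matrix(0.5, 2, 2))
  expect_error(stability_surface(a, matrix(0.5, 3, 3)), "shape")
})

test_that("projection reuses coefficients: identical epochs, identical fit", {
  ts <- make_test_stack(14)
  stack <- ts$stack
  stack$layers$land_use_same <- stack$layers$land_use
  stack$kind <- c(stack$kind, land_use_same = "categorical")
  pres <- sample_presences(ts$truth, 25, seed = 2)
  plain <- fit_sdm(pres, scenario_spec("land use", "land_use"), stack,
                   n_background = 500, reps = 4, seed = 5)
  change <- fit_sdm(pres, scenario_spec("land use change", "land_use",
                                        epoch2 = "land_use_same"),
                    stack, n_background = 500, reps = 4, seed = 5)
  expect_equal(change$suitability, plain$suitability, tolerance = 1e-12)
})
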