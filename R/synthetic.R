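# Synthetic landscapes and resistance-structured genotypes.
#
# The generator emulates the inputs of a comparative landscape-genetics
# study: smooth continuous environmental gradients (climate, altitude), a
# categorical land-use mosaic observed at two epochs, a known "truth"
# suitability/conductance surface, presence records, sampling sites, and
# multilocus co-dominant genotypes whose differentiation increases with
# effective resistance on the truth surface.

# Gaussian low-pass filter of a matrix by separable 1-D kernels with
# standard deviation `width` (cells). Rows are renormalised so constant
# fields stay constant at the edges.
gaussian_blur <- function(m, width) {
  stopifnot(width > 0)
  half <- max(1L, ceiling(3 * width))
  k <- stats::dnorm(-half:half, sd = width)
  k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      jdx <- idx + o
      ok <- jdx >= 1 & jdx <= n
      B[cbind(idx[ok], jdx[ok])] <- k[o + half + 1]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Smooth random field: low-pass-filtered white noise plus a linear gradient
# in a random direction, standardised to zero mean / unit sd.
smooth_field <- function(nrows, ncols, patchiness, gradient = 1) {
  z <- gaussian_blur(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                     width = patchiness)
  z <- (z - mean(z)) / stats::sd(z)
  theta <- stats::runif(1, 0, 2 * pi)
  gx <- outer(rep(1, nrows), seq_len(ncols)) / ncols
  gy <- outer(seq_len(nrows), rep(1, ncols)) / nrows
  g <- cos(theta) * gx + sin(theta) * gy
  z <- z + gradient * (g - mean(g)) / stats::sd(g)
  (z - mean(z)) / stats::sd(z)
}

# Connected components of equal-class cells under 4-neighbour adjacency.
# Returns an integer matrix of patch ids.
class_patches <- function(class_grid) {
  nr <- nrow(class_grid); nc <- ncol(class_grid)
  id <- function(r, c) (c - 1L) * nr + r
  rows <- as.vector(row(class_grid)); cols <- as.vector(col(class_grid))
  edges <- NULL
  right <- cols < nc & class_grid == cbind(class_grid[, -1], NA)
  down  <- rows < nr & class_grid == rbind(class_grid[-1, ], NA)
  e1 <- which(right); e2 <- which(down)
  from <- c(e1, e2)
  to <- c(e1 + nr, e2 + 1L)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nr * nc - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  matrix(comp[seq_len(nr * nc)], nr, nc)
}

#' Generate a synthetic landscape with known truth surfaces
#'
#' Builds an aligned stack of continuous layers (smoothed noise plus a
#' linear macro-gradient, emulating climate and altitude) and a categorical
#' land-use mosaic observed at two epochs, where the earlier epoch equals
#' the current one with a configured fraction of contiguous patches
#' reassigned to a different class. The truth habitat suitability is a
#' logistic function of a configured weighted sum of (standardised) layers;
#' the truth conductance equals the truth suitability.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param nrows,ncols Grid dimensions (each at least 20).
#' @param n_climate Number of continuous climate layers (at least 2).
#' @param patchiness Gaussian smoothing width in cells (> 0); larger values
#'   give larger patches and smoother gradients.
#' @param n_classes Number of land-use classes (at least 3).
#' @param epoch_change Fraction of cells (via whole patches) whose land-use
#'   class differs between the two epochs, in `[0, 1)`.
#' @param epoch_mode How changed patches are reassigned in the past epoch:
#'   `"loss"` (default) draws a strictly better class, emulating habitat
#'   loss between the epochs (the past landscape held more habitat);
#'   `"random"` draws any other class (symmetric turnover).
#' @param suitability_weights Named numeric vector of weights over layer
#'   names defining the truth suitability. Default `c(land_use = 1)`: the
#'   truth is driven by the land-use mosaic alone, the regime in which a
#'   sedentary habitat specialist experiences the landscape.
#' @param gain Steepness of the logistic link from the weighted layer score
#'   to suitability; the default gives strong habitat/matrix contrast
#'   (conductance ratio near 50 between best and worst class).
#' @return An object of class `landscape_truth`: list with `layers`
#'   ([layer_stack()] holding `clim1..climN`, `altitude`, `land_use`,
#'   `land_use_past`), `true_suitability`, `true_conductance` (matrices in
#'   `[0, 1]`), and `seed`.
#' @export
make_landscape <- function(seed, nrows, ncols, n_climate = 3,
                           patchiness = 5, n_classes = 4,
                           epoch_change = 0.3,
                           epoch_mode = c("loss", "random"),
                           suitability_weights = c(land_use = 1),
                           gain = 3) {
  epoch_mode <- match.arg(epoch_mode)
  assert_that(nrows >= 20 && ncols >= 20, "nrows and ncols must be >= 20")
  assert_that(n_climate >= 2, "n_climate must be >= 2")
  assert_that(patchiness > 0, "patchiness must be positive")
  assert_that(n_classes >= 3, "need at least 3 land-use classes")
  assert_that(epoch_change >= 0 && epoch_change < 1,
              "epoch_change must be in [0, 1)")
  with_seed(seed, {
    layers <- list()
    for (k in seq_len(n_climate)) {
      layers[[paste0("clim", k)]] <- smooth_field(nrows, ncols, patchiness)
    }
    # Altitude: smooth field rescaled to a plausible low-mountain range (m).
    alt <- smooth_field(nrows, ncols, patchiness * 1.5)
    layers[["altitude"]] <- 300 + 120 * alt
    # Land use: quantile-thresholded smooth noise -> mosaic of >= 3 classes.
    lu_field <- smooth_field(nrows, ncols, patchiness, gradient = 0)
    qs <- stats::quantile(lu_field, probs = seq_len(n_classes - 1) / n_classes)
    lu <- matrix(findInterval(lu_field, qs) + 1L, nrows, ncols)
    layers[["land_use"]] <- lu
    # Past epoch: reassign whole patches until ~epoch_change of cells differ.
    lu_past <- lu
    if (epoch_change > 0) {
      patches <- class_patches(lu)
      pid <- sample(unique(as.vector(patches)))
      target <- epoch_change * nrows * ncols
      changed <- 0
      for (p in pid) {
        cells <- patches == p
        sz <- sum(cells)
        if (changed + sz - target > target - changed) next
        old <- lu[cells][1]
        pool <- if (epoch_mode == "loss") {
          seq_len(n_classes)[seq_len(n_classes) > old]
        } else {
          setdiff(seq_len(n_classes), old)
        }
        if (length(pool) == 0) next
        lu_past[cells] <- if (length(pool) == 1) pool else sample(pool, 1)
        changed <- changed + sz
        if (changed >= target) break
      }
    }
    layers[["land_use_past"]] <- lu_past
    kind <- stats::setNames(rep("continuous", length(layers)), names(layers))
    kind[c("land_use", "land_use_past")] <- "categorical"
    stack <- layer_stack(layers, kind)
    suit <- truth_suitability(stack, suitability_weights, gain)
    structure(list(layers = stack, true_suitability = suit,
                   true_conductance = suit, seed = seed,
                   params = list(n_climate = n_climate,
                                 patchiness = patchiness,
                                 n_classes = n_classes,
                                 epoch_change = epoch_change,
                                 epoch_mode = epoch_mode,
                                 suitability_weights = suitability_weights,
                                 gain = gain)),
              class = "landscape_truth")
  })
}

# Monotone truth suitability: logistic of a weighted sum of standardised
# layer scores. Categorical layers enter through their class score
# (class k of K -> (k-1)/(K-1)), so higher classes are better habitat.
truth_suitability <- function(stack, weights, gain = 2) {
  assert_that(all(names(weights) %in% names(stack$layers)),
              "suitability weight names must match layer names")
  d <- dim(stack)
  score <- matrix(0, d[1], d[2])
  for (nm in names(weights)) {
    v <- stack$layers[[nm]]
    if (stack$kind[[nm]] == "categorical") {
      K <- max(v)
      v <- (v - 1) / max(1, K - 1)
    }
    z <- (v - mean(v)) / stats::sd(v)
    score <- score + weights[[nm]] * z
  }
  stats::plogis(gain * score / sqrt(sum(weights^2)))
}

#' @export
print.landscape_truth <- function(x, ...) {
  d <- dim(x$layers)
  cat(sprintf("landscape_truth: %d x %d grid (seed %s)\n", d[1], d[2],
              format(x$seed)))
  print(x$layers)
  invisible(x)
}

#' Sample presence records proportional to truth suitability
#'
#' Draws distinct cells with inclusion probability proportional to the
#' truth suitability and returns their cell-centre coordinates, emulating
#' presence records of a species that occupies suitable habitat.
#'
#' @param truth A [make_landscape()] result.
#' @param n Number of presences (at least 5).
#' @param seed RNG seed.
#' @return Data frame with columns `x`, `y`, `row`, `col`.
#' @export
sample_presences <- function(truth, n, seed) {
  assert_that(n >= 5, "need at least 5 presence records")
  suit <- truth$true_suitability
  pos <- which(suit > 0)
  assert_that(n <= length(pos),
              "n exceeds the number of cells with positive suitability")
  with_seed(seed, {
    cells <- if (n == length(pos)) pos else
      sample(pos, n, prob = suit[pos])
    nr <- nrow(suit)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    xy <- cell_xy(rows, cols, nr, truth$layers$xll, truth$layers$yll,
                  truth$layers$cellsize)
    data.frame(x = xy[, "x"], y = xy[, "y"], row = rows, col = cols)
  })
}

#' Place sampling populations on suitable, mutually separated cells
#'
#' Selects `n_pops` cells with truth suitability at or above a threshold,
#' pairwise at least `min_separation_cells` apart (Euclidean distance in
#' cell units), by randomised greedy selection with restarts. Fails
#' explicitly if the separation constraint cannot be met.
#'
#' @param truth A [make_landscape()] result.
#' @param n_pops Number of populations (3 to 15).
#' @param min_separation_cells Minimum pairwise separation in cells.
#' @param seed RNG seed.
#' @param threshold Suitability threshold for eligible cells.
#' @param max_restarts Number of greedy restarts before giving up.
#' @return Data frame with columns `id`, `x`, `y`, `row`, `col`.
#' @export
place_populations <- function(truth, n_pops, min_separation_cells, seed,
                              threshold = 0.5, max_restarts = 100) {
  assert_that(n_pops >= 3 && n_pops <= 15, "n_pops must be in [3, 15]")
  suit <- truth$true_suitability
  nr <- nrow(suit)
  cand <- which(suit >= threshold)
  assert_that(length(cand) >= n_pops,
              "not enough cells above the suitability threshold")
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      ord <- sample.int(length(cand))
      sel <- integer(0)
      for (i in ord) {
        if (length(sel) == 0L ||
            all(sqrt((rows[sel] - rows[i])^2 + (cols[sel] - cols[i])^2) >=
                min_separation_cells)) {
          sel <- c(sel, i)
          if (length(sel) == n_pops) break
        }
      }
      if (length(sel) == n_pops) {
        xy <- cell_xy(rows[sel], cols[sel], nr, truth$layers$xll,
                      truth$layers$yll, truth$layers$cellsize)
        return(data.frame(id = paste0("pop", seq_len(n_pops)),
                          x = xy[, "x"], y = xy[, "y"],
                          row = rows[sel], col = cols[sel],
                          stringsAsFactors = FALSE))
      }
    }
    stop("could not place ", n_pops, " populations at separation >= ",
         min_separation_cells, " cells; separation is infeasible",
         call. = FALSE)
  })
}

#' Simulate genotypes with isolation-by-resistance structure
#'
#' A logistic-normal drift approximation: for each biallelic locus the
#' per-population logit allele frequencies are drawn from a multivariate
#' normal with covariance `sigma^2 * exp(-R/lambda)` (`R` = pairwise
#' effective resistance on the truth conductance surface), then diploid
#' genotypes are drawn as two independent Bernoulli allele copies per
#' individual (Hardy-Weinberg within populations). Larger `lambda` means
#' resistance decays more slowly in the covariance, hence weaker structure;
#' `sigma = 0` removes all between-population variance (panmixia).
#'
#' @param truth_resistance Symmetric resistance matrix between populations
#'   (zero diagonal), typically from [effective_resistance_matrix()] on the
#'   truth conductance.
#' @param populations Data frame from [place_populations()] (needs `id`,
#'   `x`, `y`).
#' @param n_loci Number of loci (at least 5).
#' @param n_ind Individuals per population (at least 10).
#' @param sigma Between-population standard deviation on the logit scale
#'   (>= 0).
#' @param lambda Covariance decay scale in resistance units (> 0).
#' @param seed RNG seed.
#' @param base_freq_range Range from which each locus's overall minor/major
#'   allele frequency is drawn.
#' @return A `genotype_dataset` (see [genotype_dataset()]).
#' @export
simulate_genotypes <- function(truth_resistance, populations, n_loci = 18,
                               n_ind = 20, sigma = 1, lambda, seed,
                               base_freq_range = c(0.2, 0.8)) {
  assert_that(n_loci >= 5, "n_loci must be >= 5")
  assert_that(n_ind >= 10, "n_ind must be >= 10")
  assert_that(sigma >= 0, "sigma must be non-negative")
  assert_that(lambda > 0, "lambda must be positive")
  R <- as.matrix(truth_resistance)
  npop <- nrow(R)
  assert_that(npop == nrow(populations),
              "resistance matrix and population table disagree in size")
  Sigma <- sigma^2 * exp(-R / lambda)
  # Cholesky with jitter-and-retry: exp(-R/lambda) of a resistance metric is
  # not guaranteed positive definite on every lattice.
  L <- NULL
  if (sigma > 0) {
    for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
      ch <- try(chol(Sigma + diag(jit * sigma^2, npop)), silent = TRUE)
      if (!inherits(ch, "try-error")) { L <- ch; break }
    }
    assert_that(!is.null(L),
                "covariance not positive semi-definite even after jitter")
  }
  with_seed(seed, {
    total <- npop * n_ind
    a1 <- matrix(NA_integer_, total, n_loci)
    a2 <- matrix(NA_integer_, total, n_loci)
    pop <- factor(rep(populations$id, each = n_ind),
                  levels = populations$id)
    for (l in seq_len(n_loci)) {
      p0 <- stats::runif(1, base_freq_range[1], base_freq_range[2])
      dev <- if (sigma > 0) as.vector(t(L) %*% stats::rnorm(npop)) else
        rep(0, npop)
      p_pop <- stats::plogis(stats::qlogis(p0) + dev)
      pr <- rep(p_pop, each = n_ind)
      a1[, l] <- 1L + stats::rbinom(total, 1L, pr)
      a2[, l] <- 1L + stats::rbinom(total, 1L, pr)
    }
    genotype_dataset(a1, a2, pop,
                     loci = sprintf("loc%02d", seq_len(n_loci)),
                     pop_info = data.frame(id = populations$id,
                                           x = populations$x,
                                           y = populations$y,
                                           n = n_ind,
                                           stringsAsFactors = FALSE))
  })
}

#' Build a complete simulated study
#'
#' Convenience wrapper chaining [make_landscape()], [sample_presences()],
#' [place_populations()], truth effective resistance, and
#' [simulate_genotypes()] into one seeded object.
#'
#' @param seed Master seed (expanded deterministically into stage seeds).
#' @param nrows,ncols Grid size.
#' @param n_pops Number of populations.
#' @param n_presences Number of presence records.
#' @param n_loci,n_ind Genotype dimensions.
#' @param sigma Between-population logit SD; 0 simulates panmixia.
#' @param lambda Covariance decay scale; `NULL` sets it to twice the maximum
#'   truth resistance, so expected differentiation grows approximately
#'   linearly with resistance across the observed range (the regime the
#'   linear-regression comparison assumes).
#' @param min_separation_cells Population separation; default scales with
#'   the grid.
#' @param ... Passed to [make_landscape()].
#' @return List of class `simulated_study` with `truth`, `presences`,
#'   `populations`, `genotypes`, `truth_resistance`, `lambda`.
#' @export
simulate_study <- function(seed, nrows = 60, ncols = 60, n_pops = 12,
                           n_presences = 30, n_loci = 18, n_ind = 30,
                           sigma = 1.5, lambda = NULL,
                           min_separation_cells = NULL, ...) {
  truth <- make_landscape(derive_seed(seed, "landscape"), nrows, ncols, ...)
  pres <- sample_presences(truth, n_presences, derive_seed(seed, "presences"))
  if (is.null(min_separation_cells)) {
    min_separation_cells <- max(3L, floor(min(nrows, ncols) / 8))
  }
  pops <- place_populations(truth, n_pops, min_separation_cells,
                            derive_seed(seed, "populations"))
  cond <- suitability_to_conductance(truth$true_conductance)
  graph <- build_lattice_graph(cond)
  sites <- map_sites_to_cells(pops, cond)
  R <- effective_resistance_matrix(graph, sites)
  if (is.null(lambda)) lambda <- 2 * max(R)
  geno <- simulate_genotypes(R, pops, n_loci = n_loci, n_ind = n_ind,
                             sigma = sigma, lambda = lambda,
                             seed = derive_seed(seed, "genotypes"))
  structure(list(truth = truth, presences = pres, populations = pops,
                 genotypes = geno, truth_resistance = R, lambda = lambda,
                 seed = seed),
            class = "simulated_study")
}
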