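# Presence/background suitability modelling per landscape scenario:
# terrain derivatives, collinearity screening, an L1-penalised logistic
# presence/background model with bootstrap AUC evaluation, permutation
# variable contributions, and the two-epoch stability surface.

#' Resample a layer stack to a new cell size
#'
#' Continuous layers are interpolated bilinearly; categorical layers take
#' the nearest-neighbour class (no invented classes). The grid origin is
#' preserved and the new extent covers the old one.
#'
#' @param stack A [layer_stack()].
#' @param cell_size Target cell size (> 0).
#' @return A resampled [layer_stack()]. If `cell_size` equals the current
#'   cell size the input is returned unchanged.
#' @export
resample_stack <- function(stack, cell_size) {
  assert_that(cell_size > 0, "cell_size must be positive")
  if (cell_size == stack$cellsize) return(stack)
  d <- dim(stack)
  width <- d[2] * stack$cellsize; height <- d[1] * stack$cellsize
  nc2 <- max(1L, round(width / cell_size))
  nr2 <- max(1L, round(height / cell_size))
  assert_that(nr2 >= 1 && nc2 >= 1, "empty overlap region")
  # target cell centres in source fractional row/col units
  cx <- (seq_len(nc2) - 0.5) * cell_size / stack$cellsize + 0.5
  ry <- (seq_len(nr2) - 0.5) * cell_size / stack$cellsize + 0.5
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  out <- list()
  for (nm in names(stack$layers)) {
    src <- stack$layers[[nm]]
    if (stack$kind[[nm]] == "categorical") {
      rr <- clamp(round(ry), 1, d[1]); cc <- clamp(round(cx), 1, d[2])
      out[[nm]] <- src[rr, cc, drop = FALSE]
    } else {
      r0 <- clamp(floor(ry), 1, d[1] - 1); c0 <- clamp(floor(cx), 1, d[2] - 1)
      fr <- clamp(ry - r0, 0, 1); fc <- clamp(cx - c0, 0, 1)
      m <- matrix(NA_real_, nr2, nc2)
      for (jj in seq_len(nc2)) {
        j0 <- c0[jj]; wj <- fc[jj]
        m[, jj] <- (1 - fr) * ((1 - wj) * src[r0, j0] + wj * src[r0, j0 + 1]) +
          fr * ((1 - wj) * src[r0 + 1, j0] + wj * src[r0 + 1, j0 + 1])
      }
      out[[nm]] <- m
    }
  }
  layer_stack(out, stack$kind, xll = stack$xll, yll = stack$yll,
              cellsize = cell_size)
}

#' Slope and aspect from an altitude grid (Horn's method)
#'
#' Horn 3x3 finite differences on an edge-padded grid. Slope is returned in
#' degrees (>= 0); aspect in compass degrees `[0, 360)` with 0 = north,
#' clockwise; flat cells get aspect `-1`.
#'
#' @param altitude Numeric matrix (row 1 = north).
#' @param cell_size Cell size in the same units as altitude.
#' @return List with `slope` and `aspect` matrices.
#' @export
terrain_slope_aspect <- function(altitude, cell_size = 1) {
  stopifnot(is.matrix(altitude))
  assert_that(nrow(altitude) >= 3 && ncol(altitude) >= 3,
              "altitude needs at least 3 x 3 cells")
  assert_that(any(!is.na(altitude)), "altitude is all nodata")
  nr <- nrow(altitude); nc <- ncol(altitude)
  pad <- rbind(altitude[1, , drop = FALSE], altitude,
               altitude[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cell_size)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cell_size)  # +y = north
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # compass bearing of steepest descent: east component -dzdx, north -dzdy
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- -1
  list(slope = slope, aspect = aspect)
}

#' Pairwise collinearity screen over continuous layers
#'
#' Pearson R-squared between every pair of continuous layers over jointly
#' valid cells; pairs at or above the threshold are flagged. Constant
#' layers (undefined correlation) are flagged separately. Selection of
#' which layer to drop is left to the analyst.
#'
#' @param stack A [layer_stack()] with at least 2 continuous layers.
#' @param r2_threshold Flagging threshold on R-squared.
#' @return Data frame `layer1`, `layer2`, `r2`, `flagged`, with attribute
#'   `constant_layers`.
#' @export
correlation_screen <- function(stack, r2_threshold = 0.75) {
  cont <- names(stack$layers)[stack$kind == "continuous"]
  assert_that(length(cont) >= 2, "need at least 2 continuous layers")
  constant <- cont[vapply(cont, function(nm) {
    stats::sd(stack$layers[[nm]], na.rm = TRUE) == 0
  }, logical(1))]
  usable <- setdiff(cont, constant)
  prs <- if (length(usable) >= 2) utils::combn(usable, 2) else
    matrix(character(0), nrow = 2)
  out <- data.frame(layer1 = prs[1, ], layer2 = prs[2, ],
                    r2 = rep(NA_real_, ncol(prs)),
                    flagged = rep(FALSE, ncol(prs)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    x <- as.vector(stack$layers[[out$layer1[k]]])
    y <- as.vector(stack$layers[[out$layer2[k]]])
    ok <- !is.na(x) & !is.na(y)
    out$r2[k] <- stats::cor(x[ok], y[ok])^2
  }
  out$flagged <- out$r2 >= r2_threshold
  attr(out, "constant_layers") <- constant
  out
}

#' Rank-based AUC (Mann-Whitney, ties count one half)
#'
#' Probability that a random presence score exceeds a random background
#' score, with ties counted 1/2.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(presence_scores, background_scores) {
  assert_that(length(presence_scores) > 0 && length(background_scores) > 0,
              "both score vectors must be non-empty")
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Define a landscape scenario
#'
#' @param name Scenario name (e.g. `"climate"`, `"topography"`,
#'   `"land use"`, `"land use change"`, `"all"`).
#' @param layers Layer names entering the model.
#' @param epoch2 For a land-use-change scenario: the name of the
#'   second-epoch categorical layer the fitted model is projected onto.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, layers, epoch2 = NULL) {
  assert_that(length(layers) >= 1, "a scenario needs at least one layer")
  structure(list(name = name, layers = layers, epoch2 = epoch2),
            class = "scenario_spec")
}

#' Default five-scenario set plus geographic distance
#'
#' Builds the climate / topography / land use / land use change / all
#' scenario list from a stack's layer names (climate layers are those named
#' `clim*`; topography is altitude plus derived slope and aspect).
#'
#' @param stack A [layer_stack()] containing `altitude`, `slope`, `aspect`,
#'   `land_use`, `land_use_past`, and `clim*` layers.
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(stack) {
  nms <- names(stack$layers)
  clim <- grep("^clim", nms, value = TRUE)
  topo <- intersect(c("altitude", "slope", "aspect"), nms)
  assert_that(length(clim) >= 1 && length(topo) >= 1 &&
                all(c("land_use", "land_use_past") %in% nms),
              "stack lacks the layers needed for the default scenarios")
  list(
    climate = scenario_spec("climate", clim),
    topography = scenario_spec("topography", topo),
    `land use` = scenario_spec("land use", "land_use"),
    `land use change` = scenario_spec("land use change", "land_use",
                                      epoch2 = "land_use_past"),
    all = scenario_spec("all", c(clim, topo, "land_use"))
  )
}

# Design matrix for given cells: standardised linear + quadratic terms of
# continuous layers, one-hot class indicators for categorical layers.
# `stats` carries training means/sds and the class sets so projection reuses
# training statistics. `override` substitutes a layer's values (second-epoch
# projection).
sdm_design <- function(stack, layers, cells, stats = NULL, override = NULL) {
  cols <- list(); newstats <- list()
  for (nm in layers) {
    v <- (override[[nm]] %||% stack$layers[[nm]])[cells]
    if (stack$kind[[nm]] == "categorical") {
      classes <- if (!is.null(stats)) stats[[nm]]$classes else
        sort(unique(as.vector(stack$layers[[nm]])))
      for (cl in classes) cols[[paste0(nm, "_c", cl)]] <- as.numeric(v == cl)
      newstats[[nm]] <- list(classes = classes)
    } else {
      m <- if (!is.null(stats)) stats[[nm]]$mean else mean(v)
      s <- if (!is.null(stats)) stats[[nm]]$sd else stats::sd(v)
      if (!is.finite(s) || s == 0) s <- 1
      z <- (v - m) / s
      cols[[paste0(nm, "_z")]] <- z
      cols[[paste0(nm, "_z2")]] <- z^2
      newstats[[nm]] <- list(mean = m, sd = s)
    }
  }
  list(X = do.call(cbind, cols), stats = newstats)
}

# Fit one penalised presence/background logistic replicate and return the
# coefficient path point at the configured penalty.
fit_penalised_logistic <- function(X, y, penalty) {
  lam <- penalty / length(y)
  # a short warm-start path; on quasi-separable data glmnet may stop the
  # path early, in which case the smallest converged lambda is used
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                   lambda = lam * c(100, 10, 1), standardize = FALSE,
                   maxit = 2e5))
  k <- length(fit$lambda)
  list(a0 = as.numeric(fit$a0[k]), beta = as.numeric(fit$beta[, k]))
}

predict_logistic <- function(coefs, X) {
  stats::plogis(coefs$a0 + as.vector(X %*% coefs$beta))
}

#' Fit a bootstrap-replicated presence/background suitability model
#'
#' Per replicate: presences are split into training and test sets
#' (`train_frac`), a background sample is drawn uniformly without
#' replacement from valid cells (presences not excluded), an L1-penalised
#' logistic model is fit on linear + quadratic terms of the standardised
#' continuous layers and one-hot indicators of categorical layers, and the
#' test AUC (test presences vs the background sample) is recorded. The
#' final suitability grid is the mean of the per-replicate suitability
#' grids, hence guaranteed in `[0, 1]`.
#'
#' For a land-use-change scenario (`epoch2` set), the fitted coefficients
#' are also projected, without refitting, onto the second-epoch layer, and
#' the replicate's suitability is the stability surface (element-wise mean)
#' of the two projections.
#'
#' @param presences Data frame with `row`, `col` cell indices (e.g. from
#'   [sample_presences()]), at least 10 rows.
#' @param scenario A [scenario_spec()].
#' @param stack A [layer_stack()] containing the scenario's layers.
#' @param n_background Background sample size.
#' @param reps Number of bootstrap replicates.
#' @param train_frac Training fraction in (0, 1).
#' @param penalty Total L1 penalty weight on the standardised coefficients.
#' @param seed RNG seed.
#' @return Object of class `sdm_fit`: `suitability` (mean grid), `auc`
#'   (per-replicate test AUC), `mean_auc`, `scenario`, and per-replicate
#'   fit records used by [variable_contributions()].
#' @export
fit_sdm <- function(presences, scenario, stack, n_background = 2000,
                    reps = 100, train_frac = 0.7, penalty = 1, seed = 1) {
  assert_that(nrow(presences) >= 10, "need at least 10 presences")
  assert_that(reps >= 1, "reps must be >= 1")
  assert_that(train_frac > 0 && train_frac < 1,
              "train_frac must be in (0, 1)")
  assert_that(all(scenario$layers %in% names(stack$layers)),
              "scenario layers missing from the stack")
  d <- dim(stack)
  valid <- which(!is.na(stack$layers[[scenario$layers[1]]]))
  n_background <- min(n_background, length(valid))
  pres_cells <- (presences$col - 1L) * d[1] + presences$row
  npres <- nrow(presences)
  n_train <- floor(train_frac * npres)
  assert_that(npres - n_train >= 2,
              "train_frac leaves fewer than 2 test presences")
  all_cells <- seq_len(d[1] * d[2])
  override_past <- NULL
  if (!is.null(scenario$epoch2)) {
    override_past <- stats::setNames(
      list(stack$layers[[scenario$epoch2]]), scenario$layers[
        stack$kind[scenario$layers] == "categorical"][1])
  }
  suit_sum <- matrix(0, d[1], d[2])
  aucs <- numeric(reps)
  replicates <- vector("list", reps)
  with_seed(seed, {
    for (b in seq_len(reps)) {
      tr <- sample.int(npres, n_train)
      bg <- sample(valid, n_background)
      rows <- c(pres_cells[tr], bg)
      y <- c(rep(1, n_train), rep(0, n_background))
      des <- sdm_design(stack, scenario$layers, rows)
      coefs <- fit_penalised_logistic(des$X, y, penalty)
      # logistic-output calibration: raw presence/background intercepts are
      # prevalence-dependent, so recentre the linear predictor to give the
      # typical training presence a score of 0.5
      coefs$a0 <- coefs$a0 -
        mean(coefs$a0 + des$X[seq_len(n_train), , drop = FALSE] %*%
               coefs$beta)
      # test AUC on the epoch-now projection
      test_scores <- predict_logistic(
        coefs, sdm_design(stack, scenario$layers, pres_cells[-tr],
                          stats = des$stats)$X)
      bg_scores <- predict_logistic(
        coefs, sdm_design(stack, scenario$layers, bg, stats = des$stats)$X)
      aucs[b] <- auc_score(test_scores, bg_scores)
      pred_now <- predict_logistic(
        coefs, sdm_design(stack, scenario$layers, all_cells,
                          stats = des$stats)$X)
      suit_b <- matrix(pred_now, d[1], d[2])
      if (!is.null(override_past)) {
        pred_past <- predict_logistic(
          coefs, sdm_design(stack, scenario$layers, all_cells,
                            stats = des$stats, override = override_past)$X)
        suit_b <- stability_surface(suit_b, matrix(pred_past, d[1], d[2]))
      }
      suit_sum <- suit_sum + suit_b
      replicates[[b]] <- list(train = pres_cells[tr], bg = bg,
                              stats = des$stats, coefs = coefs)
    }
  })
  structure(list(suitability = suit_sum / reps, auc = aucs,
                 mean_auc = mean(aucs), scenario = scenario,
                 penalty = penalty, replicates = replicates),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit '%s': %d replicates, mean test AUC %.3f\n",
              x$scenario$name, length(x$auc), x$mean_auc))
  invisible(x)
}

#' Permutation variable contributions of a fitted suitability model
#'
#' Per replicate and variable (layer), the layer's values are shuffled
#' across the replicate's training rows (all derived columns of the layer
#' permuted together) and the drop in training AUC under the stored
#' coefficients is recorded. Mean drops are floored at zero and normalised
#' to sum to 100. A single-variable scenario returns 100 for that variable.
#'
#' @param fit An [fit_sdm()] result.
#' @param stack The [layer_stack()] the model was fitted on.
#' @param seed RNG seed for the shuffles.
#' @return Data frame `variable`, `contribution` (percent, sums to 100).
#' @export
variable_contributions <- function(fit, stack, seed = 1) {
  layers <- fit$scenario$layers
  if (length(layers) == 1) {
    return(data.frame(variable = layers, contribution = 100,
                      stringsAsFactors = FALSE))
  }
  drops <- matrix(0, length(fit$replicates), length(layers),
                  dimnames = list(NULL, layers))
  with_seed(seed, {
    for (b in seq_along(fit$replicates)) {
      rep <- fit$replicates[[b]]
      rows <- c(rep$train, rep$bg)
      npres <- length(rep$train)
      des <- sdm_design(stack, layers, rows, stats = rep$stats)
      base_scores <- predict_logistic(rep$coefs, des$X)
      base_auc <- auc_score(base_scores[seq_len(npres)],
                            base_scores[-seq_len(npres)])
      for (nm in layers) {
        cols <- grep(paste0("^", nm, "_(z2?|c[0-9]+)$"), colnames(des$X))
        Xp <- des$X
        Xp[, cols] <- Xp[sample.int(nrow(Xp)), cols, drop = FALSE]
        sc <- predict_logistic(rep$coefs, Xp)
        drops[b, nm] <- base_auc -
          auc_score(sc[seq_len(npres)], sc[-seq_len(npres)])
      }
    }
  })
  contrib <- pmax(colMeans(drops), 0)
  if (sum(contrib) == 0) contrib <- rep(1, length(contrib))
  data.frame(variable = layers,
             contribution = 100 * contrib / sum(contrib),
             stringsAsFactors = FALSE)
}

#' Two-epoch habitat stability surface
#'
#' Element-wise mean of two suitability projections; high values mark
#' habitat that is both suitable and temporally stable.
#'
#' @param suit_epoch_now,suit_epoch_past Suitability matrices in `[0, 1]`
#'   of identical shape.
#' @return Matrix of the same shape.
#' @export
stability_surface <- function(suit_epoch_now, suit_epoch_past) {
  assert_that(all(dim(suit_epoch_now) == dim(suit_epoch_past)),
              "epoch grids differ in shape")
  rng <- range(c(suit_epoch_now, suit_epoch_past), na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 1, "suitability must lie in [0, 1]")
  (suit_epoch_now + suit_epoch_past) / 2
}
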