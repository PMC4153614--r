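# Comparing genetic differentiation with scenario resistance matrices:
# distance-matrix unfolding, OLS with AICc, Akaike weights, and multiple
# regression on distance matrices (MRDM) with matrix-level permutation
# tests.

#' Unfold the lower triangle of a symmetric matrix
#'
#' Row-major order: pairs (2,1), (3,1), (3,2), (4,1), ... so that response
#' and predictor matrices unfold identically.
#'
#' @param m Symmetric matrix with zero diagonal.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
lower_triangle <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  assert_that(max(abs(m - t(m)), na.rm = TRUE) <= tol,
              "matrix is asymmetric beyond tolerance")
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx]
}

# Pair labels in the same order as lower_triangle().
pair_labels <- function(ids) {
  n <- length(ids)
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste(ids[idx[, 2]], ids[idx[, 1]], sep = ":")
}

#' Euclidean distance matrix between sites
#'
#' Straight-line distances in map units (planar coordinates); the classical
#' isolation-by-distance predictor.
#'
#' @param sites Data frame with `id`, `x`, `y`.
#' @return Symmetric matrix with id dimnames; duplicated coordinates give a
#'   zero distance and are flagged via the `duplicates` attribute.
#' @export
euclidean_distance_matrix <- function(sites) {
  m <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  dimnames(m) <- list(sites$id, sites$id)
  dup <- which(m == 0 & upper.tri(m), arr.ind = TRUE)
  attr(m, "duplicates") <- if (nrow(dup)) {
    paste(sites$id[dup[, 1]], sites$id[dup[, 2]], sep = ":")
  } else character(0)
  m
}

#' Simple distance regression with small-sample AIC
#'
#' OLS of genetic distance on one predictor distance. Reports the slope and
#' intercept, adjusted R-squared (`1 - (1 - R2)(n-1)/(n-2)`, may be
#' negative), the slope t-test p (descriptive only: pairs are not
#' independent), RSS, and AICc with `k = 3` estimated parameters
#' (intercept, slope, error variance) under the Gaussian likelihood
#' `L = -(n/2)(log(2 pi RSS / n) + 1)`.
#'
#' @param y Response vector (>= 5 pairs).
#' @param x Predictor vector, non-constant.
#' @return List `slope`, `intercept`, `r2`, `adj_r2`, `p`, `rss`, `aicc`,
#'   `n`.
#' @export
distance_regression <- function(y, x) {
  n <- length(y)
  assert_that(n >= 5 && length(x) == n, "need >= 5 pairs of equal length")
  assert_that(stats::sd(x) > 0, "predictor is constant")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0 || rss < tss * 1e-20) {
    warning("residual sum of squares is numerically zero (exact fit); ",
            "RSS floored for the likelihood")
  }
  rss <- max(rss, 1e-300)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  k <- 3
  ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  slope <- unname(stats::coef(fit)["x"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  se_slope <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  p <- 2 * stats::pt(abs(slope) / se_slope, df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r2 = r2, adj_r2 = adj_r2,
       p = p, rss = rss, aicc = aicc, n = n)
}

#' Delta-AICc and Akaike weights
#'
#' `dAICc_i = AICc_i - min(AICc)`;
#' `w_i = exp(-dAICc_i / 2) / sum_j exp(-dAICc_j / 2)`. Models with
#' `dAICc < 2` are flagged as supported (the final support call additionally
#' requires a significant regression, applied by the caller).
#'
#' @param aicc Numeric vector of AICc values (optionally named by scenario).
#' @return Data frame `scenario`, `aicc`, `delta_aicc`, `weight`,
#'   `supported`, in input order. Ties for the minimum keep a single zero by
#'   input order and are all flagged supported.
#' @export
aicc_rank <- function(aicc) {
  assert_that(length(aicc) >= 1, "need at least one model")
  nms <- names(aicc) %||% paste0("model", seq_along(aicc))
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  data.frame(scenario = nms, aicc = as.numeric(aicc),
             delta_aicc = as.numeric(delta), weight = w,
             supported = delta < 2, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Multiple regression on distance matrices (MRDM)
#'
#' Regresses the unfolded response matrix on one or more unfolded predictor
#' matrices and assesses significance by jointly permuting the rows and
#' columns of the response matrix (population labels), refitting, and
#' collecting the permuted R-squared:
#' `p = (1 + n_perm_ge_observed) / (1 + n_perm)`. If `n_perm` is at least
#' the number of distinct label permutations, all of them are enumerated
#' instead. The reported R-squared is unadjusted.
#'
#' @param y_matrix Symmetric response matrix (zero diagonal).
#' @param x_matrices List of symmetric predictor matrices with the same
#'   ids.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List `r2`, `p`, `coefficients`, `n_perm`, `exhaustive`.
#' @export
mrdm <- function(y_matrix, x_matrices, n_perm = 1000, seed = 1) {
  assert_that(n_perm >= 99, "n_perm must be >= 99")
  if (is.matrix(x_matrices)) x_matrices <- list(x_matrices)
  n <- nrow(y_matrix)
  for (xm in x_matrices) {
    assert_that(all(dim(xm) == n), "predictor matrices must match y in size")
  }
  yv <- lower_triangle(y_matrix)
  X <- cbind(1, vapply(x_matrices, lower_triangle, numeric(length(yv))))
  qrX <- qr(X)
  coefs <- qr.coef(qrX, yv)
  Q <- qr.Q(qrX)
  r2_of <- function(v) {
    tss <- sum((v - mean(v))^2)
    fit <- Q %*% crossprod(Q, v)
    1 - sum((v - fit)^2) / tss
  }
  r2_obs <- r2_of(yv)
  exhaustive <- factorial(n) <= n_perm
  with_seed(seed, {
    perms <- if (exhaustive) {
      all_permutations(n)
    } else {
      lapply(seq_len(n_perm), function(i) sample.int(n))
    }
    r2_perm <- vapply(perms, function(pp) {
      r2_of(lower_triangle(y_matrix[pp, pp]))
    }, numeric(1))
    if (exhaustive) {
      # enumeration includes the identity; p is the exact proportion
      p <- mean(r2_perm >= r2_obs - 1e-12)
      n_eff <- length(perms)
    } else {
      p <- (1 + sum(r2_perm >= r2_obs - 1e-12)) / (1 + n_perm)
      n_eff <- n_perm
    }
    list(r2 = r2_obs, p = p, coefficients = as.numeric(coefs),
         n_perm = n_eff, exhaustive = exhaustive)
  })
}

# All permutations of 1..n (used only for tiny n).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos)
    }
  }
  out
}

#' Build a per-metric scenario comparison table
#'
#' For one genetic differentiation matrix and a set of scenario predictor
#' matrices (circuit resistances plus Euclidean distance), runs
#' [distance_regression()] per scenario, ranks models by [aicc_rank()], and
#' runs [mrdm()] per scenario. Rows are sorted by AICc. A scenario is
#' flagged supported when `dAICc < 2` and its regression p is at or below
#' `alpha`.
#'
#' @param gen_matrix Symmetric genetic distance matrix (`diff_matrix`
#'   accepted).
#' @param predictors Named list of symmetric predictor matrices; must
#'   include `"distance"`.
#' @param auc Optional named vector of per-scenario mean AUC (NA for
#'   distance).
#' @param metric Label for the response (`"F_ST"` or `"D_est"`).
#' @param n_perm MRDM permutations.
#' @param seed RNG seed.
#' @param alpha Significance level in the support rule.
#' @return Data frame with one row per scenario: `scenario`, `auc`, `aicc`,
#'   `delta_aicc`, `weight`, `adj_r2`, `p`, `mrdm_r2`, `mrdm_p`,
#'   `supported`, sorted by AICc.
#' @export
build_scenario_table <- function(gen_matrix, predictors, auc = NULL,
                                 metric = "F_ST", n_perm = 1000, seed = 1,
                                 alpha = 0.05) {
  if (inherits(gen_matrix, "diff_matrix")) gen_matrix <- gen_matrix$values
  assert_that(length(predictors) >= 2 && "distance" %in% names(predictors),
              "need at least 2 scenarios including 'distance'")
  y <- lower_triangle(gen_matrix)
  keep <- is.finite(y)
  n_dropped <- sum(!keep)
  regs <- list(); mrdms <- list()
  for (nm in names(predictors)) {
    x <- lower_triangle(predictors[[nm]])
    reg <- tryCatch(distance_regression(y[keep], x[keep]),
                    error = function(e) {
                      stop("scenario '", nm, "': ", conditionMessage(e),
                           call. = FALSE)
                    })
    regs[[nm]] <- reg
    ymat <- gen_matrix
    # flagged pairs are dropped from the regression; MRDM permutes whole
    # matrices, so the rare non-finite entry is imputed at the mean
    ymat[!is.finite(ymat)] <- mean(y[keep])
    diag(ymat) <- 0
    mrdms[[nm]] <- mrdm(ymat, predictors[[nm]],
                        n_perm = n_perm, seed = derive_seed(seed, nm))
  }
  rk <- aicc_rank(vapply(regs, `[[`, numeric(1), "aicc"))
  tab <- data.frame(
    scenario = rk$scenario,
    auc = if (is.null(auc)) NA_real_ else unname(auc[rk$scenario]),
    aicc = rk$aicc, delta_aicc = rk$delta_aicc, weight = rk$weight,
    adj_r2 = vapply(regs, `[[`, numeric(1), "adj_r2"),
    p = vapply(regs, `[[`, numeric(1), "p"),
    mrdm_r2 = vapply(mrdms, `[[`, numeric(1), "r2"),
    mrdm_p = vapply(mrdms, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$supported <- tab$delta_aicc < 2 & tab$p <= alpha
  tab <- tab[order(tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "metric") <- metric
  attr(tab, "n_pairs_dropped") <- n_dropped
  tab
}
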