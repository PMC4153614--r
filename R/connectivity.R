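# Circuit-theory connectivity: conductance lattice, graph Laplacian,
# pairwise effective resistance between focal sites.

#' Convert a suitability surface into a conductance grid
#'
#' High suitability means good conductivity. Cells are clamped below by a
#' small positive floor so the lattice never disconnects through
#' zero-suitability cells (habitat-matrix interpretation).
#'
#' @param suitability Numeric matrix in `[0, 1]` (NA = nodata) or a
#'   `landscape_truth` (its truth conductance is used).
#' @param floor Positive lower clamp, strictly below 1.
#' @param xll,yll,cellsize Geotransform of the grid.
#' @return Object of class `conductance_grid`: list with `values`, `xll`,
#'   `yll`, `cellsize`.
#' @export
suitability_to_conductance <- function(suitability, floor = 1e-4,
                                       xll = 0, yll = 0, cellsize = 1) {
  if (inherits(suitability, "landscape_truth")) {
    xll <- suitability$layers$xll; yll <- suitability$layers$yll
    cellsize <- suitability$layers$cellsize
    suitability <- suitability$true_conductance
  }
  stopifnot(is.matrix(suitability))
  assert_that(floor > 0, "floor must be positive (a zero floor risks disconnection)")
  assert_that(floor < 1, "floor must be below 1")
  rng <- range(suitability, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 1, "suitability must lie in [0, 1]")
  structure(list(values = pmax(suitability, floor), xll = xll, yll = yll,
                 cellsize = cellsize),
            class = "conductance_grid")
}

#' Build the resistor lattice of a conductance grid
#'
#' One node per valid (non-nodata) cell; edges join 4- or 8-neighbours.
#' Edge conductance is the arithmetic mean of the two cell conductances
#' (harmonic mean available as an option); diagonal edges under the
#' 8-neighbour scheme are scaled by `1/sqrt(2)` for the longer step.
#'
#' @param cond A [suitability_to_conductance()] result, or a plain
#'   non-negative matrix.
#' @param scheme Neighbourhood scheme, 4 (default) or 8.
#' @param edge_rule `"arithmetic"` (default) or `"harmonic"` mean.
#' @return Object of class `lattice_graph`: list with `nodes` (data frame
#'   `node`, `row`, `col`), `edges` (data frame `i`, `j`, `conductance`),
#'   `nrows`, `ncols`, and the grid geotransform.
#' @export
build_lattice_graph <- function(cond, scheme = 4,
                                edge_rule = c("arithmetic", "harmonic")) {
  edge_rule <- match.arg(edge_rule)
  geo <- list(xll = 0, yll = 0, cellsize = 1)
  if (inherits(cond, "conductance_grid")) {
    geo <- cond[c("xll", "yll", "cellsize")]
    cond <- cond$values
  }
  stopifnot(is.matrix(cond))
  vals <- cond[!is.na(cond)]
  assert_that(all(is.finite(vals)) && all(vals >= 0),
              "conductances must be finite and non-negative")
  assert_that(scheme %in% c(4, 8), "scheme must be 4 or 8")
  nr <- nrow(cond); nc <- ncol(cond)
  valid <- !is.na(cond)
  assert_that(sum(valid) >= 2, "need at least 2 valid cells")
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[valid] <- seq_len(sum(valid))
  combine <- function(g1, g2) {
    if (edge_rule == "arithmetic") (g1 + g2) / 2 else 2 / (1 / g1 + 1 / g2)
  }
  offsets <- list(c(0, 1), c(1, 0))
  if (scheme == 8) offsets <- c(offsets, list(c(1, 1), c(1, -1)))
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    idx1 <- as.vector(outer(r1, (c1 - 1) * nr, `+`))
    idx2 <- idx1 + dr + dc * nr
    ok <- valid[idx1] & valid[idx2]
    g <- combine(cond[idx1[ok]], cond[idx2[ok]])
    if (dr != 0 && dc != 0) g <- g / sqrt(2)
    ii <- c(ii, node_id[idx1[ok]]); jj <- c(jj, node_id[idx2[ok]])
    gg <- c(gg, g)
  }
  rc <- which(valid, arr.ind = TRUE)
  structure(list(nodes = data.frame(node = node_id[valid],
                                    row = rc[, 1], col = rc[, 2]),
                 edges = data.frame(i = ii, j = jj, conductance = gg),
                 nrows = nr, ncols = nc,
                 xll = geo$xll, yll = geo$yll, cellsize = geo$cellsize),
            class = "lattice_graph")
}

# Sparse graph Laplacian of a lattice_graph (n x n, dgCMatrix).
graph_laplacian <- function(graph, nodes = NULL) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  L <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = -c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(L)) + L
}

#' Map site coordinates to lattice cells
#'
#' Assigns each site to the nearest cell centre; a site landing on a nodata
#' cell is snapped to the nearest valid cell within `snap_radius` cells
#' (the snap is recorded), otherwise the call fails naming the site.
#' Two sites resolving to the same cell is an error.
#'
#' @param sites Data frame with `id`, `x`, `y`.
#' @param grid A [suitability_to_conductance()] result (or any list with
#'   `values`, `xll`, `yll`, `cellsize`).
#' @param snap_radius Snap search radius in cells.
#' @return Data frame `id`, `x`, `y`, `row`, `col`, `snapped`.
#' @export
map_sites_to_cells <- function(sites, grid, snap_radius = 3) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  within <- sites$x >= grid$xll & sites$x <= grid$xll + nc * grid$cellsize &
    sites$y >= grid$yll & sites$y <= grid$yll + nr * grid$cellsize
  assert_that(all(within),
              paste0("site(s) outside grid bounds: ",
                     paste(sites$id[!within], collapse = ", ")))
  rc <- xy_cell(sites$x, sites$y, nr, nc, grid$xll, grid$yll, grid$cellsize)
  snapped <- logical(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    if (!is.na(v[rc[k, "row"], rc[k, "col"]])) next
    rr <- max(1, rc[k, "row"] - snap_radius):min(nr, rc[k, "row"] + snap_radius)
    cc <- max(1, rc[k, "col"] - snap_radius):min(nc, rc[k, "col"] + snap_radius)
    cand <- expand.grid(row = rr, col = cc)
    cand <- cand[!is.na(v[as.matrix(cand)]), , drop = FALSE]
    assert_that(nrow(cand) > 0,
                paste0("site ", sites$id[k],
                       " cannot be snapped to a valid cell within radius ",
                       snap_radius))
    d <- (cand$row - rc[k, "row"])^2 + (cand$col - rc[k, "col"])^2
    best <- cand[which.min(d), ]
    rc[k, "row"] <- best$row; rc[k, "col"] <- best$col
    snapped[k] <- TRUE
  }
  key <- paste(rc[, "row"], rc[, "col"])
  assert_that(!anyDuplicated(key),
              "two sites resolve to the same cell")
  data.frame(id = sites$id, x = sites$x, y = sites$y,
             row = rc[, "row"], col = rc[, "col"], snapped = snapped,
             stringsAsFactors = FALSE)
}

#' Pairwise effective resistance between focal sites
#'
#' For each unordered site pair, solves the lattice Laplacian system with
#' unit current injected at one site and extracted at the other (one node
#' grounded); the effective resistance is the resulting voltage difference.
#' The sparse Cholesky factor is computed once and reused across pairs.
#' Sites in different connected components raise an explicit
#' infinite-resistance error naming the offending pair.
#'
#' @param graph A [build_lattice_graph()] result.
#' @param sites A [map_sites_to_cells()] result (columns `id`, `row`,
#'   `col`).
#' @return Symmetric matrix of effective resistances with site ids as
#'   dimnames (class `resistance_matrix`).
#' @export
effective_resistance_matrix <- function(graph, sites) {
  node_of <- function(r, c) {
    m <- graph$nodes$node[graph$nodes$row == r & graph$nodes$col == c]
    assert_that(length(m) == 1, "focal site does not map to a lattice node")
    m
  }
  focal <- mapply(node_of, sites$row, sites$col)
  n <- nrow(graph$nodes)
  ig <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                      directed = FALSE,
                                      vertices = data.frame(seq_len(n)))
  comp <- igraph::components(ig)$membership
  fc <- comp[focal]
  if (length(unique(fc)) > 1) {
    bad <- which(fc != fc[1])[1]
    stop("infinite resistance: sites ", sites$id[1], " and ",
         sites$id[bad], " lie in different connected components",
         call. = FALSE)
  }
  keep <- which(comp == fc[1])
  remap <- integer(n); remap[keep] <- seq_along(keep)
  e <- graph$edges[comp[graph$edges$i] == fc[1], , drop = FALSE]
  sub <- list(nodes = data.frame(node = seq_along(keep)),
              edges = data.frame(i = remap[e$i], j = remap[e$j],
                                 conductance = e$conductance))
  L <- graph_laplacian(sub)
  focal <- remap[focal]
  m <- length(keep)
  ground <- m                         # any node works; voltage reference
  Lred <- L[-ground, -ground, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lred), LDL = FALSE)
  k <- length(focal)
  R <- matrix(0, k, k, dimnames = list(sites$id, sites$id))
  idx_red <- function(node) if (node < ground) node else node - 1L
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      b <- numeric(m - 1)
      if (focal[i] != ground) b[idx_red(focal[i])] <- 1
      if (focal[j] != ground) b[idx_red(focal[j])] <- -1
      x <- as.vector(Matrix::solve(ch, b, system = "A"))
      vi <- if (focal[i] == ground) 0 else x[idx_red(focal[i])]
      vj <- if (focal[j] == ground) 0 else x[idx_red(focal[j])]
      R[i, j] <- R[j, i] <- vi - vj
    }
  }
  class(R) <- c("resistance_matrix", class(R))
  R
}

#' Dense pseudo-inverse oracle for effective resistance
#'
#' Independent cross-check route: forms the dense graph Laplacian, takes
#' its Moore-Penrose pseudo-inverse, and evaluates
#' `R_ij = L+_ii + L+_jj - 2 L+_ij`. Refuses graphs above 400 nodes.
#'
#' @param graph A [build_lattice_graph()] result with <= 400 nodes.
#' @param pair Integer vector of two node ids (not site ids).
#' @return Effective resistance between the two nodes.
#' @export
oracle_effective_resistance <- function(graph, pair) {
  n <- nrow(graph$nodes)
  assert_that(n <= 400, "oracle refuses graphs above 400 nodes")
  assert_that(length(pair) == 2 && all(pair %in% seq_len(n)),
              "pair must name two nodes of the graph")
  L <- as.matrix(graph_laplacian(graph))
  Lp <- MASS::ginv(L)
  Lp[pair[1], pair[1]] + Lp[pair[2], pair[2]] - 2 * Lp[pair[1], pair[2]]
}
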