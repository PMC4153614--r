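#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by
#' whitespace-separated cell values, row 1 = top of the map).
#'
#' @param path Path to a `.asc` file.
#' @return A list with `values` (numeric matrix, row 1 = northernmost row),
#'   `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  assert_that(file.exists(path), paste0("raster file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    assert_that(!is.null(hdr[[key]]),
                paste0("missing ESRI ASCII header field '", key, "' in ", path))
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  assert_that(length(vals) == nr * nc,
              paste0("expected ", nr * nc, " cells, found ", length(vals),
                     " in ", path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = top). `NA` cells are written as the
#'   nodata value.
#' @param path Output path.
#' @param xll,yll Coordinates of the lower-left corner.
#' @param cellsize Cell size in map units.
#' @param nodata Nodata sentinel value.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  stopifnot(is.matrix(values))
  out <- values
  out[is.na(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  # Fixed 6-decimal text so identical grids serialise bit-identically.
  body <- apply(out, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Construct an aligned raster layer stack
#'
#' A `layer_stack` holds named grids sharing one geotransform. Continuous
#' layers hold real values; categorical layers hold integer class codes.
#'
#' @param layers Named list of numeric matrices, all the same dimension.
#' @param kind Character vector (same names), each `"continuous"` or
#'   `"categorical"`.
#' @param xll,yll Lower-left corner of the grid.
#' @param cellsize Cell size in map units.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, kind, xll = 0, yll = 0, cellsize = 1) {
  assert_that(is.list(layers) && length(layers) >= 1 &&
                !is.null(names(layers)) && all(nzchar(names(layers))),
              "layers must be a non-empty named list of matrices")
  dims <- vapply(layers, dim, integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all layers must share the same dimensions")
  assert_that(all(names(layers) %in% names(kind)) || is.null(names(kind)),
              "kind must be named by layer or unnamed in layer order")
  if (is.null(names(kind))) names(kind) <- names(layers)
  kind <- kind[names(layers)]
  assert_that(all(kind %in% c("continuous", "categorical")),
              "layer kind must be 'continuous' or 'categorical'")
  for (nm in names(layers)[kind == "categorical"]) {
    v <- layers[[nm]]
    assert_that(all(is.na(v) | v == round(v)),
                paste0("categorical layer '", nm, "' holds non-integer codes"))
  }
  structure(list(layers = layers, kind = kind, xll = xll, yll = yll,
                 cellsize = cellsize),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("layer_stack: %d layers, %d x %d cells, cellsize %g\n",
              length(x$layers), d[1], d[2], x$cellsize))
  for (nm in names(x$layers)) cat(sprintf("  %-16s %s\n", nm, x$kind[[nm]]))
  invisible(x)
}

#' @export
dim.layer_stack <- function(x) dim(x$layers[[1]])

# Cell-centre coordinates for (row, col) under the raster convention
# (row 1 = top). Used everywhere sites and cells meet.
cell_xy <- function(row, col, nrows, xll = 0, yll = 0, cellsize = 1) {
  cbind(x = xll + (col - 0.5) * cellsize,
        y = yll + (nrows - row + 0.5) * cellsize)
}

# Inverse of cell_xy: nearest cell indices for planar coordinates.
xy_cell <- function(x, y, nrows, ncols, xll = 0, yll = 0, cellsize = 1) {
  col <- pmin(pmax(floor((x - xll) / cellsize) + 1L, 1L), ncols)
  row <- pmin(pmax(nrows - floor((y - yll) / cellsize), 1L), nrows)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Write all layers of a stack as ESRI ASCII grids
#'
#' One `.asc` file per layer plus a `layers.csv` sidecar recording each
#' layer's kind, so [read_layer_dir()] can restore the stack.
#'
#' @param stack A [layer_stack()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_layer_dir <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_esri_ascii(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     xll = stack$xll, yll = stack$yll,
                     cellsize = stack$cellsize)
  }
  utils::write.csv(
    data.frame(layer = names(stack$layers), kind = unname(stack$kind)),
    file.path(dir, "layers.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a directory of ESRI ASCII grids back into a layer stack
#'
#' @param dir Directory written by [write_layer_dir()].
#' @return A [layer_stack()].
#' @export
read_layer_dir <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "layers.csv"),
                          stringsAsFactors = FALSE)
  grids <- list()
  geo <- NULL
  for (nm in meta$layer) {
    g <- read_esri_ascii(file.path(dir, paste0(nm, ".asc")))
    grids[[nm]] <- g$values
    geo <- g
  }
  layer_stack(grids, stats::setNames(meta$kind, meta$layer),
              xll = geo$xll, yll = geo$yll, cellsize = geo$cellsize)
}

#' Write a symmetric matrix with id headers to CSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a square id-headed matrix from CSV
#' @param path CSV written by [write_matrix_csv()].
#' @return A matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
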