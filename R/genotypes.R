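# Genotype container and Genepop-format I/O.

#' Construct a multilocus diploid genotype dataset
#'
#' @param a1,a2 Integer matrices (individuals x loci) holding the two allele
#'   codes of each genotype; `NA` marks a missing genotype (both matrices
#'   must agree on missingness). Allele codes are positive integers.
#' @param pop Factor of population labels, one per individual.
#' @param loci Character vector of locus names.
#' @param pop_info Optional data frame with one row per population: `id`,
#'   `x`, `y`, `n`. Coordinates are needed for spatial analyses only.
#' @return Object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, pop, loci = colnames(a1),
                             pop_info = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  assert_that(identical(is.na(a1), is.na(a2)),
              "a1 and a2 must agree on missing genotypes")
  assert_that(all(a1 >= 1, na.rm = TRUE) && all(a2 >= 1, na.rm = TRUE),
              "allele codes must be positive integers")
  pop <- as.factor(pop)
  assert_that(length(pop) == nrow(a1),
              "pop must have one label per individual")
  if (is.null(loci)) loci <- sprintf("loc%02d", seq_len(ncol(a1)))
  if (is.null(pop_info)) {
    pop_info <- data.frame(id = levels(pop), x = NA_real_, y = NA_real_,
                           n = as.integer(table(pop)),
                           stringsAsFactors = FALSE)
  }
  assert_that(all(levels(pop) %in% pop_info$id),
              "every individual must belong to a declared population")
  structure(list(a1 = a1, a2 = a2, pop = pop, loci = loci,
                 pop_info = pop_info),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d populations\n",
              nrow(x$a1), ncol(x$a1), nlevels(x$pop)))
  invisible(x)
}

#' Number of populations in a dataset
#' @param ds A `genotype_dataset`.
#' @return Integer.
#' @export
n_populations <- function(ds) nlevels(ds$pop)

# Subset a dataset to the given population ids (used for pairwise stats).
subset_pops <- function(ds, ids) {
  keep <- ds$pop %in% ids
  genotype_dataset(ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
                   factor(ds$pop[keep], levels = ids), loci = ds$loci,
                   pop_info = ds$pop_info[match(ids, ds$pop_info$id), ,
                                          drop = FALSE])
}

#' Read genotypes from a Genepop file
#'
#' Supports 2- and 3-digit allele coding, loci listed one per line or
#' comma-separated on a single line, and `POP`-delimited populations.
#' All-zero allele codes are preserved as missing genotypes.
#'
#' @param path Path to a Genepop text file.
#' @return A [genotype_dataset()]. Population ids are taken from the last
#'   individual label of each POP block (the usual Genepop convention), with
#'   a numbered fallback when labels repeat.
#' @export
read_genepop <- function(path) {
  assert_that(file.exists(path), paste0("Genepop file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) >= 3, "Genepop file too short")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  assert_that(!is.na(first_pop), "no POP record found")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], "\\s*,\\s*"))
  assert_that(length(loci) >= 1, "no locus names before first POP")
  nloc <- length(loci)

  pop_starts <- which(is_pop)
  a1 <- list(); a2 <- list(); pops <- character(0); labels <- character(0)
  for (b in seq_along(pop_starts)) {
    from <- pop_starts[b] + 1L
    to <- if (b < length(pop_starts)) pop_starts[b + 1L] - 1L else length(lines)
    block <- lines[from:to]
    block_no <- from:to
    keep <- nzchar(trimws(block))
    block <- block[keep]; block_no <- block_no[keep]
    last_label <- NA_character_
    for (i in seq_along(block)) {
      parts <- strsplit(block[i], ",")[[1]]
      assert_that(length(parts) == 2,
                  paste0("line ", block_no[i],
                         ": expected 'label , genotypes'"))
      label <- trimws(parts[1])
      gts <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      assert_that(length(gts) == nloc,
                  paste0("line ", block_no[i], ": expected ", nloc,
                         " genotypes, found ", length(gts)))
      width <- nchar(gts[1])
      assert_that(all(nchar(gts) == width) && width %in% c(4L, 6L) &&
                    all(grepl("^[0-9]+$", gts)),
                  paste0("line ", block_no[i],
                         ": malformed genotype field(s)"))
      half <- width / 2
      x1 <- as.integer(substr(gts, 1, half))
      x2 <- as.integer(substr(gts, half + 1, width))
      miss <- x1 == 0L | x2 == 0L
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      a1[[length(a1) + 1L]] <- x1
      a2[[length(a2) + 1L]] <- x2
      labels <- c(labels, paste0("pop", b))
      last_label <- label
    }
    pops <- c(pops, if (nzchar(last_label)) last_label else paste0("pop", b))
  }
  if (anyDuplicated(pops)) pops <- paste0("pop", seq_along(pops))
  pop <- factor(labels, levels = paste0("pop", seq_along(pops)),
                labels = pops)
  genotype_dataset(do.call(rbind, a1), do.call(rbind, a2), pop, loci = loci)
}

#' Write genotypes to a Genepop file
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @param digits Allele-code width, 2 or 3.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, digits = 2, title = "ibrscape export") {
  assert_that(digits %in% c(2, 3), "digits must be 2 or 3")
  assert_that(max(ds$a1, ds$a2, na.rm = TRUE) < 10^digits,
              "allele codes too large for the requested digit width")
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (p in levels(ds$pop)) {
    writeLines("POP", con)
    idx <- which(ds$pop == p)
    for (i in idx) {
      g1 <- ds$a1[i, ]; g2 <- ds$a2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      writeLines(paste0(p, " ,  ",
                        paste0(sprintf(fmt, g1), sprintf(fmt, g2),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
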