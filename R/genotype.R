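#' Gene value ranges for the biomorph genotype
#'
#' A biomorph genotype has nine integer genes. Genes 1--8 ("vector genes")
#' set the components of the eight drawing vectors and share one symmetric
#' range; gene 9 sets the number of recursion stages and has its own range.
#' The default ranges (genes 1--8 in \[-3, 3\], gene 9 in \[1, 8\]) span
#' 7^8 x 8 = 46,118,408 genotypes.
#'
#' @param vector_min,vector_max Integer bounds for genes 1--8.
#' @param g9_min,g9_max Integer bounds for gene 9 (`g9_min >= 1`).
#' @return An object of class `gene_ranges`: a list with the bounds, the
#'   number of values per vector gene `k`, and the per-gene `mins`/`maxs`.
#' @examples
#' gene_ranges()              # the default enumeration range
#' gene_ranges(-1, 1, 1, 4)   # the small desk-scale fixture range
#' @export
gene_ranges <- function(vector_min = -3L, vector_max = 3L,
                        g9_min = 1L, g9_max = 8L) {
  vector_min <- as.integer(vector_min); vector_max <- as.integer(vector_max)
  g9_min <- as.integer(g9_min); g9_max <- as.integer(g9_max)
  stopifnot(vector_min <= vector_max, g9_min >= 1L, g9_min <= g9_max)
  structure(list(
    vector_min = vector_min, vector_max = vector_max,
    g9_min = g9_min, g9_max = g9_max,
    k = vector_max - vector_min + 1L,
    mins = c(rep(vector_min, 8L), g9_min),
    maxs = c(rep(vector_max, 8L), g9_max)
  ), class = "gene_ranges")
}

#' @export
print.gene_ranges <- function(x, ...) {
  cat("<gene_ranges> genes 1-8 in [", x$vector_min, ", ", x$vector_max,
      "] (k = ", x$k, "), gene 9 in [", x$g9_min, ", ", x$g9_max, "]; ",
      format(n_genotypes(x), big.mark = ","), " genotypes\n", sep = "")
  invisible(x)
}

#' Number of genotypes in a range
#'
#' @param ranges A [gene_ranges()] object.
#' @return A double (the count can exceed `.Machine$integer.max`).
#' @examples
#' n_genotypes(gene_ranges())  # 46118408
#' @export
n_genotypes <- function(ranges) {
  prod(as.numeric(ranges$maxs - ranges$mins + 1L))
}

range_sizes <- function(ranges) ranges$maxs - ranges$mins + 1L

#' Coerce to a genotype
#'
#' Accepts a numeric vector of length nine, a comma-separated string such as
#' `"1,0,0,1,1,0,0,0,2"`, or a one-row data frame with columns `g1`..`g9`.
#'
#' @param x Object to coerce.
#' @return An integer vector of length nine, named `g1`..`g9`.
#' @export
as_genotype <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.integer(strsplit(trimws(x), ",")[[1L]])
  } else if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.integer(unlist(x[1L, paste0("g", 1:9)]))
  }
  x <- as.integer(x)
  if (length(x) != 9L || anyNA(x)) {
    stop("a genotype is nine integers (g1..g9)", call. = FALSE)
  }
  names(x) <- paste0("g", 1:9)
  x
}

#' Validate a genotype against gene ranges
#'
#' @param genotype Anything [as_genotype()] accepts.
#' @param ranges A [gene_ranges()] object.
#' @return The validated integer genotype, invisibly usable downstream.
#' @export
validate_genotype <- function(genotype, ranges = gene_ranges()) {
  g <- as_genotype(genotype)
  if (any(g < ranges$mins) || any(g > ranges$maxs)) {
    bad <- which(g < ranges$mins | g > ranges$maxs)
    stop("gene(s) ", paste0("g", bad, collapse = ", "),
         " outside the declared range", call. = FALSE)
  }
  g
}

#' Construct the eight drawing vectors from a genotype
#'
#' The first eight genes define eight 2D integer vectors:
#' v1 = (-g3, g7), v2 = (-g2, g6), v3 = (-g1, g5), v4 = (0, g4),
#' v5 = (g1, g5), v6 = (g2, g6), v7 = (g3, g7), v8 = (0, g8).
#' Vectors 5--7 mirror vectors 3--1 across the y-axis, which forces the
#' axial symmetry of every biomorph.
#'
#' @inheritParams validate_genotype
#' @return A tibble with columns `index` (1--8), `x`, `y`.
#' @examples
#' define_vectors(c(1, 2, 3, 4, 5, 6, 7, 8, 1))
#' @export
define_vectors <- function(genotype) {
  g <- as_genotype(genotype)
  tibble(
    index = 1:8,
    x = unname(c(-g[3], -g[2], -g[1], 0L, g[1], g[2], g[3], 0L)),
    y = unname(c(g[7], g[6], g[5], g[4], g[5], g[6], g[7], g[8]))
  )
}

#' Draw a biomorph
#'
#' Runs the recursive development: starting at the origin with vector index
#' `i = 4` and `c = g9` stages remaining, each call draws a line of `c`
#' times the current vector and, while `c > 1`, recurses with indices
#' `i - 1` and `i + 1` (wrapping 0 -> 8 and 9 -> 1) and `c - 1`. The result
#' is an ordered list of `2^g9 - 1` integer line segments (depth-first,
#' left child first); segment order is documented but downstream phenotype
#' equality never depends on it.
#'
#' @inheritParams validate_genotype
#' @return A tibble of class `biomorph_drawing` with integer columns
#'   `x0`, `y0`, `x1`, `y1`, one row per drawn segment.
#' @examples
#' draw_biomorph(c(1, 0, 0, 1, 1, 0, 0, 0, 2))
#' @export
draw_biomorph <- function(genotype) {
  g <- as_genotype(genotype)
  stopifnot(g[9] >= 1L)
  segs <- cpp_draw(g)
  new_drawing(as_tibble(segs), genotype = g)
}

new_drawing <- function(tbl, genotype = NULL) {
  structure(tbl, class = c("biomorph_drawing", class(tibble())),
            genotype = genotype)
}

drawing_matrix <- function(drawing) {
  m <- as.matrix(as.data.frame(drawing)[, c("x0", "y0", "x1", "y1")])
  storage.mode(m) <- "integer"
  m
}

#' Single point-mutation neighborhood of a genotype
#'
#' A point mutation increases or decreases a single gene by one integer
#' step. Mutations that would leave the declared range are absent from the
#' neighborhood (not clamped or wrapped), so an interior genotype has 18
#' neighbors and boundary genotypes fewer.
#'
#' @inheritParams validate_genotype
#' @return A tibble with columns `g1`..`g9` plus `gene` (mutated position)
#'   and `step` (+1 or -1), one row per neighbor.
#' @examples
#' nrow(mutational_neighbors(c(0, 0, 0, 0, 0, 0, 0, 0, 4)))  # 18
#' @export
mutational_neighbors <- function(genotype, ranges = gene_ranges()) {
  g <- validate_genotype(genotype, ranges)
  gene <- rep(1:9, each = 2L)
  step <- rep(c(-1L, 1L), times = 9L)
  val <- g[gene] + step
  ok <- val >= ranges$mins[gene] & val <= ranges$maxs[gene]
  gene <- gene[ok]; step <- step[ok]; val <- val[ok]
  m <- matrix(rep(g, each = length(gene)), nrow = length(gene), ncol = 9L)
  m[cbind(seq_along(gene), gene)] <- val
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("g", 1:9)
  out$gene <- gene
  out$step <- step
  out
}

#' Enumerate all genotypes in a range
#'
#' Genotypes are generated in odometer order over (g1, ..., g9) with g1 the
#' slowest-varying digit and g9 the fastest. This order is the package-wide
#' convention: it defines the enumeration index used for example-genotype
#' selection and for fast neighbor arithmetic.
#'
#' @inheritParams n_genotypes
#' @param limit Refuse to materialize more than this many genotypes
#'   (guards against accidentally expanding the 4.6e7 default range).
#' @return A tibble with integer columns `g1`..`g9`.
#' @examples
#' nrow(enumerate_genotypes(gene_ranges(-1, 1, 1, 4)))  # 26244
#' @export
enumerate_genotypes <- function(ranges, limit = 5e6) {
  n <- n_genotypes(ranges)
  if (n > limit) {
    stop("range holds ", format(n, big.mark = ","), " genotypes (> limit); ",
         "use genotype_at()/gp_map_shard() for block-wise processing",
         call. = FALSE)
  }
  genotype_at(seq_len(n), ranges)
}

#' Genotype at a given enumeration index
#'
#' @param index 1-based enumeration index (odometer order, g1 slowest).
#' @inheritParams n_genotypes
#' @return A tibble with columns `g1`..`g9` (one row per index).
#' @export
genotype_at <- function(index, ranges) {
  m <- cpp_genotypes_at(as.numeric(index) - 1, ranges$mins,
                        range_sizes(ranges))
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("g", 1:9)
  out
}

#' Enumeration index of a genotype
#'
#' @inheritParams validate_genotype
#' @return The 1-based index in odometer order (a double).
#' @export
genotype_index <- function(genotype, ranges) {
  g <- validate_genotype(genotype, ranges)
  sizes <- range_sizes(ranges)
  strides <- rev(cumprod(rev(c(as.numeric(sizes)[-1], 1))))
  sum((as.numeric(g) - ranges$mins) * strides) + 1
}

gene_strides <- function(ranges) {
  sizes <- as.numeric(range_sizes(ranges))
  rev(cumprod(rev(c(sizes[-1], 1))))
}

genotype_strings <- function(tbl) {
  do.call(paste, c(as.list(as.data.frame(tbl)[paste0("g", 1:9)]), sep = ","))
}

#' Read / write genotype lists
#'
#' Plain-text interchange format: nine comma-separated integers, one
#' genotype per line. Lines starting with `#` are ignored on read.
#'
#' @param path File path.
#' @param genotypes A data frame with columns `g1`..`g9`.
#' @return `read_genotypes()` returns a tibble with columns `g1`..`g9`.
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- do.call(rbind, lapply(lines, function(l) as_genotype(l)))
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("g", 1:9)
  out
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  writeLines(genotype_strings(genotypes), path)
  invisible(path)
}
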