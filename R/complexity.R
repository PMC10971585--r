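the_cache <- new.env(parent = emptyenv())

#' Synthetic small-block algorithmic-probability table
#'
#' The block decomposition method scores a binary array by summing
#' algorithmic-complexity estimates of its small blocks. Published tables
#' of such estimates are derived from exhaustive Turing-machine
#' enumerations; this package ships a SYNTHETIC substitute computed in
#' code by a coding-theorem-style enumeration of a small, fully documented
#' machine class: all 256 elementary cellular automaton rules run for
#' three steps from every 3-cell seed (periodic boundary), each run
#' emitting a 3x3 binary block. Block complexity is -log2 of the
#' add-one-smoothed output frequency, so blocks produced by many simple
#' rules score low and unreachable blocks score highest. The table is
#' deterministic, ordinal comparisons are meaningful, and absolute values
#' are in bits of this machine class only (the package never compares them
#' to published CTM values).
#'
#' @return Named numeric vector of length 512; names are the 9 row-major
#'   block bits as a binary string.
#' @export
synthetic_ctm_table <- function() {
  if (!is.null(the_cache$ctm3)) return(the_cache$ctm3)
  counts <- integer(512L)
  rule_bits <- function(rule) as.integer(intToBits(rule))[1:8]
  for (rule in 0:255) {
    rb <- rule_bits(rule)
    for (seed in 0:7) {
      row <- as.integer(intToBits(seed))[1:3]
      block <- integer(9L)
      block[1:3] <- row
      for (t in 1:2) {
        l <- row[c(3, 1, 2)]; r <- row[c(2, 3, 1)]
        row <- rb[4L * l + 2L * row + r + 1L]
        block[(3 * t + 1):(3 * t + 3)] <- row
      }
      id <- sum(block * 2L^(8:0)) + 1L
      counts[id] <- counts[id] + 1L
    }
  }
  total <- sum(counts)
  k <- -log2((counts + 1) / (total + 512))
  names(k) <- vapply(0:511, function(i) {
    paste(as.integer(intToBits(i))[9:1], collapse = "")
  }, "")
  the_cache$ctm3 <- k
  k
}

#' Right half of a phenotype grid
#'
#' All biomorphs are axially symmetric, so complexity is estimated from
#' one half of the raster: the columns covering x >= 0 (the right half of
#' the stored full-figure grid).
#'
#' @param grid A `phenotype_grid` (or 0/1 matrix with an even number of
#'   columns).
#' @return A matrix with the same rows and half the columns.
#' @export
half_grid <- function(grid) {
  m <- unclass(grid)
  m[, (ncol(m) %/% 2 + 1):ncol(m), drop = FALSE]
}

#' Block decomposition complexity of a binary array
#'
#' Cuts the array into small blocks, looks each block up in a
#' block-complexity table, and aggregates as
#' sum over unique blocks of (K(block) + log2 multiplicity).
#' `boundary = "sliding"` moves the block window with stride 1 so edge
#' pixels are never ignored (the non-default boundary treatment);
#' `boundary = "ignore"` tiles with stride equal to the block size and
#' drops leftovers.
#'
#' @param half A binary matrix, conventionally [half_grid()] of a
#'   phenotype (15 x 30 at default raster settings).
#' @param block_table Named numeric vector mapping row-major block bit
#'   strings to complexity values; defaults to the package's synthetic
#'   table ([synthetic_ctm_table()]). Supplying `NULL` is a configuration
#'   error: the method cannot run without a block table.
#' @param boundary `"sliding"` (default) or `"ignore"`.
#' @return Complexity estimate (bits; non-negative double).
#' @export
bdm_complexity <- function(half, block_table = synthetic_ctm_table(),
                           boundary = c("sliding", "ignore")) {
  boundary <- match.arg(boundary)
  if (is.null(block_table)) {
    stop("no block-complexity table configured; pass `block_table = ",
         "synthetic_ctm_table()` or a published CTM table keyed by ",
         "row-major block bit strings", call. = FALSE)
  }
  b <- as.integer(sqrt(nchar(names(block_table)[1L])))
  m <- unclass(half)
  if (nrow(m) < b || ncol(m) < b) {
    stop("array smaller than the block size", call. = FALSE)
  }
  stride <- if (boundary == "sliding") 1L else b
  ri <- seq.int(1L, nrow(m) - b + 1L, by = stride)
  ci <- seq.int(1L, ncol(m) - b + 1L, by = stride)
  blocks <- character(length(ri) * length(ci))
  idx <- 1L
  for (r in ri) {
    for (ccol in ci) {
      sub <- m[r:(r + b - 1L), ccol:(ccol + b - 1L)]
      blocks[idx] <- paste(as.integer(t(sub)), collapse = "")
      idx <- idx + 1L
    }
  }
  tab <- table(blocks)
  kv <- block_table[names(tab)]
  if (anyNA(kv)) {
    stop("block(s) missing from the block-complexity table", call. = FALSE)
  }
  sum(kv + log2(as.integer(tab)))
}

#' Lempel-Ziv complexity of a phenotype grid
#'
#' LZ76 phrase count of the row-major flattened binary string (row 1 left
#' to right, then row 2, ...). A constant string attains the minimum among
#' strings of its length; incompressible strings approach n / log2(n).
#'
#' @param grid A `phenotype_grid`, binary matrix, or 0/1 vector.
#' @return Non-negative integer phrase count.
#' @export
lz_complexity <- function(grid) {
  bits <- if (is.matrix(grid) || inherits(grid, "phenotype_grid")) {
    as.integer(t(unclass(grid)))
  } else {
    as.integer(grid)
  }
  cpp_lz76(bits)
}

#' Number of distinct lines in a biomorph
#'
#' Segment count after merging coincident pieces; duplicated strokes count
#' once. A depth-1 biomorph has one line; a depth-g9 biomorph without any
#' coinciding strokes has 2^g9 - 1.
#'
#' @param drawing A drawing tibble (merged or not), or a genotype.
#' @return Integer count.
#' @export
line_count_complexity <- function(drawing) {
  if (!is.data.frame(drawing)) drawing <- draw_biomorph(drawing)
  nrow(merge_coincident_segments(drawing))
}

# both grid-based estimators see the same half-phenotype representation:
# the figure is axially symmetric, so one half carries all the information
complexity_of_example <- function(example, config, method, block_table) {
  g <- as_genotype(example)
  switch(method,
    bdm = bdm_complexity(half_grid(phenotype_grid_of(g, config)), block_table),
    lz = lz_complexity(half_grid(phenotype_grid_of(g, config))),
    lines = line_count_complexity(draw_biomorph(g))
  )
}

#' Complexity-frequency table for a GP map
#'
#' One row per phenotype with the complexity of its example grid (complexity
#' is a phenotype property: every genotype of the neutral set renders the
#' identical grid). To restrict to a fixed recursion gene (the fixed-g9
#' analysis), build the map over a range with `g9_min = g9_max`.
#'
#' @inheritParams gp_genotype_stats
#' @param method `"bdm"`, `"lz"`, or `"lines"`.
#' @param block_table Block table for `method = "bdm"`.
#' @return The phenotype tibble with added columns `complexity`, `method`.
#' @export
complexity_frequency_table <- function(map, method = c("bdm", "lz", "lines"),
                                       block_table = synthetic_ctm_table()) {
  method <- match.arg(method)
  tbl <- map$phenotypes
  tbl$complexity <- vapply(tbl$example, complexity_of_example, numeric(1),
                           config = map$config, method = method,
                           block_table = block_table)
  tbl$method <- method
  tbl
}

#' Distribution of phenotype complexity
#'
#' Histogram of complexity over the map, genotype-weighted (each phenotype
#' weighted by its frequency f_p: the probability that a random genotype
#' has complexity in the bin) or phenotype-weighted (each phenotype counts
#' once).
#'
#' @param table Output of [complexity_frequency_table()].
#' @param bins Number of histogram bins.
#' @param weight `"genotype"` (by f_p) or `"phenotype"` (uniform).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `bin_mid`, `weight`,
#'   `n_phenotypes`.
#' @export
complexity_distribution <- function(table, bins = 12L,
                                    weight = c("genotype", "phenotype")) {
  weight <- match.arg(weight)
  w <- if (weight == "genotype") table$f else rep(1 / nrow(table), nrow(table))
  rng <- range(table$complexity)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(table$complexity, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tibble(
    bin_lo = br[-length(br)], bin_hi = br[-1L],
    bin_mid = (br[-1L] + br[-length(br)]) / 2,
    weight = as.numeric(tapply(w, factor(bin, levels = seq_len(bins)), sum,
                               default = 0)),
    n_phenotypes = as.integer(tapply(rep(1L, nrow(table)),
                                     factor(bin, levels = seq_len(bins)),
                                     sum, default = 0))
  )
}
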