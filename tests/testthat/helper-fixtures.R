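# Shared desk-scale fixtures, built once per test run and memoized.
# "tiny"  : genes 1-8 in [-1,1], g9 in [1,2]  (13,122 genotypes, fast graphs)
# "small" : genes 1-8 in [-1,1], g9 in [1,4]  (26,244 genotypes, the main
#           exhaustive fixture)

.fx <- new.env(parent = emptyenv())

small_ranges <- function() gene_ranges(-1L, 1L, 1L, 4L)
tiny_ranges <- function() gene_ranges(-1L, 1L, 1L, 2L)

small_map <- function() {
  if (is.null(.fx$small)) .fx$small <- build_gp_map(small_ranges())
  .fx$small
}

tiny_map <- function() {
  if (is.null(.fx$tiny)) .fx$tiny <- build_gp_map(tiny_ranges())
  .fx$tiny
}

fixed_g9_map <- function(g9 = 4L) {
  key <- paste0("g9_", g9)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- build_gp_map(gene_ranges(-1L, 1L, g9, g9))
  }
  .fx[[key]]
}

small_phenotype_stats <- function() {
  if (is.null(.fx$small_ps)) .fx$small_ps <- gp_phenotype_stats(small_map())
  .fx$small_ps
}

small_genotype_stats <- function() {
  if (is.null(.fx$small_gs)) .fx$small_gs <- gp_genotype_stats(small_map())
  .fx$small_gs
}

# a deterministic sample of fixture genotypes for property checks
sample_genotypes <- function(n, ranges = small_ranges(), seed = 42L) {
  withr::with_seed(seed, {
    idx <- sample.int(n_genotypes(ranges), n)
    genotype_at(idx, ranges)
  })
}

# independent, non-recursive development oracle: explicit breadth-wise
# expansion of the binary recursion tree, kept deliberately different in
# structure from the package's depth-first implementation
oracle_draw <- function(genotype) {
  g <- as.integer(genotype)
  vx <- c(-g[3], -g[2], -g[1], 0L, g[1], g[2], g[3], 0L)
  vy <- c(g[7], g[6], g[5], g[4], g[5], g[6], g[7], g[8])
  wrap <- function(i) ifelse(i == 0L, 8L, ifelse(i == 9L, 1L, i))
  nodes <- data.frame(i = 4L, c = g[9], x = 0L, y = 0L)
  segs <- NULL
  while (nrow(nodes) > 0L) {
    ii <- wrap(nodes$i)
    xn <- nodes$x + nodes$c * vx[ii]
    yn <- nodes$y + nodes$c * vy[ii]
    segs <- rbind(segs, data.frame(x0 = nodes$x, y0 = nodes$y,
                                   x1 = xn, y1 = yn))
    deeper <- nodes$c > 1L
    nodes <- rbind(
      data.frame(i = ii[deeper] - 1L, c = nodes$c[deeper] - 1L,
                 x = xn[deeper], y = yn[deeper]),
      data.frame(i = ii[deeper] + 1L, c = nodes$c[deeper] - 1L,
                 x = xn[deeper], y = yn[deeper])
    )
  }
  segs
}

seg_multiset <- function(d) {
  d <- as.data.frame(d)
  sw <- d$x0 > d$x1 | (d$x0 == d$x1 & d$y0 > d$y1)
  sort(paste(ifelse(sw, d$x1, d$x0), ifelse(sw, d$y1, d$y0),
             ifelse(sw, d$x0, d$x1), ifelse(sw, d$y0, d$y1)))
}
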