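seg_tbl <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 4, byrow = TRUE)
  tibble::tibble(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
}

test_that("merging removes duplicates and unions collinear overlaps", {
  # identical segment drawn twice -> one instance
  expect_identical(nrow(merge_coincident_segments(
    seg_tbl(0, 0, 0, 2,  0, 0, 0, 2))), 1L)

  # partial overlap: covered set is (0,0)-(0,3), retained length 3 not 4
  m <- merge_coincident_segments(seg_tbl(0, 0, 0, 2,  0, 1, 0, 3))
  expect_identical(nrow(m), 1L)
  expect_equal(drawing_length(m), 3)

  # disjoint non-collinear input is unchanged
  d <- seg_tbl(0, 0, 1, 1,  5, 5, 6, 5)
  expect_equal(seg_multiset(merge_coincident_segments(d)), seg_multiset(d))

  # zero-length segments are dropped
  expect_identical(nrow(merge_coincident_segments(seg_tbl(2, 2, 2, 2))), 0L)
})

test_that("merged drawings preserve the covered point set (interval oracle)", {
  # collinear diagonal pieces with gaps and overlaps
  d <- seg_tbl(0, 0, 2, 2,  1, 1, 4, 4,  6, 6, 8, 8)
  m <- merge_coincident_segments(d)
  expect_identical(nrow(m), 2L)
  expect_equal(drawing_length(m), (4 + 2) * sqrt(2))
})

test_that("half_figure clips at the axis and rejects asymmetric input", {
  h <- half_figure(seg_tbl(-1, 0, 1, 0))
  expect_equal(as.data.frame(h), data.frame(x0 = 0, y0 = 0, x1 = 1, y1 = 0))

  h2 <- half_figure(seg_tbl(0, 0, 0, 3))
  expect_identical(nrow(h2), 1L)

  expect_error(half_figure(seg_tbl(1, 0, 2, 0)), "mirror")
})

test_that("the x >= 0 half carries the full figure (mirror raster oracle)", {
  gs <- sample_genotypes(8, seed = 12)
  for (i in seq_len(nrow(gs))) {
    d <- merge_coincident_segments(draw_biomorph(as_genotype(gs[i, ])))
    if (nrow(d) == 0) next
    h <- half_figure(d)
    # the half plus its mirror tiles the figure; axis segments belong to
    # both halves and are retained once, so L = 2 len(h) - len(axis part)
    axis_len <- drawing_length(h[h$x0 == 0 & h$x1 == 0, ])
    expect_equal(2 * drawing_length(h) - axis_len, drawing_length(d))
  }
})

test_that("rasterize handles empty and degenerate drawings", {
  empty <- seg_tbl(integer(0))
  expect_equal(sum(rasterize(empty)), 0)

  # a dot maps to one set pixel at the grid center
  dotgrid <- phenotype_grid_of(c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(dotgrid), 1)
  expect_equal(unclass(dotgrid)[16, 16], 1L)
  # all dots share a phenotype regardless of depth
  expect_identical(phenotype_of(c(0, 0, 0, 0, 0, 0, 0, 0, 1)),
                   phenotype_of(c(0, 0, 0, 0, 0, 0, 0, 0, 4)))
})

test_that("an axial vertical line fills the two center columns by halving", {
  # the figure has zero width, so the line lies exactly on the boundary
  # between the two middle pixel columns and contributes half to each;
  # a full pixel traversal (length 1 >= 0.2) sets both sides
  g <- rasterize(seg_tbl(0, 0, 0, 5))
  on <- which(colSums(unclass(g)) > 0)
  expect_equal(on, c(15, 16))
  expect_equal(unclass(g)[, 15], unclass(g)[, 16])
  # interior rows fully traversed are set
  expect_gt(sum(g), 40)
})

test_that("raster is invariant under integer rescaling of coordinates", {
  gs <- sample_genotypes(12, seed = 5)
  for (i in seq_len(nrow(gs))) {
    d <- merge_coincident_segments(draw_biomorph(as_genotype(gs[i, ])))
    if (nrow(d) == 0) next
    for (s in c(3L, 7L)) {
      d2 <- d
      d2[, c("x0", "y0", "x1", "y1")] <- d[, c("x0", "y0", "x1", "y1")] * s
      expect_identical(unclass(rasterize(d2))[, ], unclass(rasterize(d))[, ])
    }
  }
})

test_that("raster ignores segment order, splitting, and duplication", {
  d <- merge_coincident_segments(draw_biomorph(c(1, 0, 1, 2, 1, 0, 1, 1, 3)))
  base <- unclass(rasterize(d))[, ]

  shuffled <- d[rev(seq_len(nrow(d))), ]
  expect_identical(unclass(rasterize(shuffled))[, ], base)

  # split the first segment at its midpoint-ish lattice point if possible
  s <- as.integer(d[1, ])
  if ((s[1] + s[3]) %% 2 == 0 && (s[2] + s[4]) %% 2 == 0) {
    mid <- c((s[1] + s[3]) %/% 2, (s[2] + s[4]) %/% 2)
    split <- dplyr::bind_rows(
      d[-1, ],
      seg_tbl(s[1], s[2], mid[1], mid[2], mid[1], mid[2], s[3], s[4]))
    expect_identical(unclass(rasterize(split))[, ], base)
  }

  # duplicates must be removed by merging, not rewarded by rasterize
  dup <- merge_coincident_segments(dplyr::bind_rows(d, d))
  expect_identical(unclass(rasterize(dup))[, ], base)
})

test_that("phenotype keys are deterministic, mirror-invariant, and redundant", {
  g <- c(1, -1, 0, 2, 1, 0, -1, 1, 3)
  expect_identical(phenotype_of(g), phenotype_of(g))

  gs <- sample_genotypes(20, seed = 9)
  for (i in seq_len(nrow(gs))) {
    a <- as_genotype(gs[i, ])
    b <- a; b[1:3] <- -b[1:3]
    expect_identical(phenotype_of(a), phenotype_of(b))
  }

  # strictly fewer phenotypes than genotypes on the tiny fixture
  tm <- tiny_map()
  expect_lt(nrow(tm$phenotypes), tm$n_genotypes)
})

test_that("keys round-trip through grids and serialize as lowercase hex", {
  gr <- phenotype_grid_of(c(1, 0, 1, 2, 1, 0, 1, 1, 4))
  key <- phenotype_key(gr)
  expect_match(key, "^[0-9a-f]+$")
  expect_identical(unclass(key_to_grid(key))[, ], unclass(gr)[, ])
  expect_identical(key, phenotype_of(c(1, 0, 1, 2, 1, 0, 1, 1, 4)))
})

test_that("grids round-trip through text and PBM export is well-formed", {
  gr <- phenotype_grid_of(c(0, 1, -1, 2, 1, 1, 0, 1, 4))
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_grid_text(gr, p1)
  expect_identical(unclass(read_grid_text(p1))[, ], unclass(gr)[, ])

  p2 <- withr::local_tempfile(fileext = ".pbm")
  write_grid_pbm(gr, p2)
  lines <- readLines(p2)
  expect_identical(lines[1], "P1")
  expect_identical(lines[2], "30 30")
  expect_identical(length(lines), 32L)
})
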