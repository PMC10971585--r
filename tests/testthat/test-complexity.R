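test_that("the synthetic block table is deterministic and complete", {
  tab <- synthetic_ctm_table()
  expect_length(tab, 512)
  expect_true(all(tab > 0))
  expect_identical(tab, synthetic_ctm_table())
  # uniform blocks are among the most compressible
  expect_lt(tab[["000000000"]], stats::median(tab))
  expect_lt(tab[["111111111"]], stats::median(tab))
})

test_that("bdm scores all-zero arrays lowest and is deterministic", {
  zero <- matrix(0L, 15, 30)
  k0 <- bdm_complexity(zero)
  expect_identical(k0, bdm_complexity(zero))
  # argmin among same-shape inputs (random probes + structured ones)
  withr::with_seed(5, {
    for (i in 1:10) {
      probe <- matrix(rbinom(450, 1, runif(1, 0.2, 0.8)), 15, 30)
      expect_gt(bdm_complexity(probe), k0)
    }
  })
  stripes <- matrix(rep(c(0L, 1L), length.out = 450), 15, 30)
  expect_gt(bdm_complexity(stripes), k0)
})

test_that("periodic patterns score below density-matched noise", {
  stripes <- matrix(rep_len(c(1L, 0L), 450), 15, 30)   # density 1/2
  withr::with_seed(11, {
    noise <- matrix(sample(rep_len(c(1L, 0L), 450)), 15, 30)
  })
  expect_lt(bdm_complexity(stripes), bdm_complexity(noise))
  expect_lt(lz_complexity(stripes), lz_complexity(noise))
})

test_that("a missing block table is a configuration error", {
  expect_error(bdm_complexity(matrix(0L, 15, 30), block_table = NULL),
               "block-complexity table")
})

test_that("boundary handling options cover the array differently", {
  m <- matrix(0L, 15, 30); m[1, 1] <- 1L; m[15, 30] <- 1L
  expect_gt(bdm_complexity(m, boundary = "sliding"),
            bdm_complexity(matrix(0L, 15, 30), boundary = "sliding"))
  expect_no_error(bdm_complexity(m, boundary = "ignore"))
})

test_that("LZ76 behaves on canonical strings", {
  expect_equal(lz_complexity(rep(0L, 100)), 2)       # constant: minimal
  expect_equal(lz_complexity(integer(0)), 0)
  # constant attains the minimum among equal-length inputs
  withr::with_seed(3, {
    for (i in 1:10) {
      expect_gte(lz_complexity(rbinom(100, 1, 0.5)), 2)
    }
  })
  # appending an incompressible suffix cannot decrease the phrase count
  withr::with_seed(8, {
    base <- rbinom(200, 1, 0.5)
    suffix <- rbinom(200, 1, 0.5)
    expect_gte(lz_complexity(c(base, suffix)), lz_complexity(base))
  })
})

test_that("line counts merge duplicates and count full trees exactly", {
  expect_equal(line_count_complexity(c(0, 0, 0, 3, 0, 0, 0, 0, 1)), 1)

  dup <- dplyr::bind_rows(draw_biomorph(c(0, 0, 0, 3, 0, 0, 0, 0, 1)),
                          draw_biomorph(c(0, 0, 0, 3, 0, 0, 0, 0, 1)))
  expect_equal(line_count_complexity(dup), 1)

  # a spread-out tree with no coinciding strokes keeps all 2^g9 - 1 lines
  g <- c(1, 2, 3, 1, 2, 1, 3, 2, 4)
  d <- draw_biomorph(g)
  if (nrow(merge_coincident_segments(d)) == nrow(d)) {
    expect_equal(line_count_complexity(d), 2^4 - 1)
  }
})

test_that("bdm and lz complexities rank fixture phenotypes consistently", {
  gp <- small_map()
  ct_bdm <- complexity_frequency_table(gp, "bdm")
  ct_lz <- complexity_frequency_table(gp, "lz")
  expect_identical(nrow(ct_bdm), nrow(gp$phenotypes))
  expect_gt(cor(ct_bdm$complexity, ct_lz$complexity, method = "spearman"), 0.3)
  .fx$ct_bdm <- ct_bdm
  .fx$ct_lz <- ct_lz
})

test_that("high-complexity phenotypes have smaller maximal neutral sets", {
  for (ct in list(.fx$ct_bdm, .fx$ct_lz)) {
    skip_if(is.null(ct))
    lo <- stats::quantile(ct$complexity, 0.25)
    hi <- stats::quantile(ct$complexity, 0.75)
    expect_lt(max(ct$n_genotypes[ct$complexity >= hi]),
              max(ct$n_genotypes[ct$complexity <= lo]))
  }
  # fixed-g9 restriction shows the same quartile ordering
  ct4 <- complexity_frequency_table(fixed_g9_map(4L), "bdm")
  lo <- stats::quantile(ct4$complexity, 0.25)
  hi <- stats::quantile(ct4$complexity, 0.75)
  expect_lt(max(ct4$n_genotypes[ct4$complexity >= hi]),
            max(ct4$n_genotypes[ct4$complexity <= lo]))
})

test_that("the per-bin maximum neutral set size decays with complexity", {
  # simplicity-bias envelope with one bin of estimator slack; six bins so
  # each holds enough phenotypes for a stable per-bin maximum
  for (ct in list(.fx$ct_bdm, .fx$ct_lz)) {
    skip_if(is.null(ct))
    dist <- complexity_distribution(ct, bins = 6)
    br <- c(dist$bin_lo[1], dist$bin_hi)
    bin <- findInterval(ct$complexity, br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    env <- tapply(ct$n_genotypes, factor(bin, levels = 1:6), max)
    env <- env[!is.na(env)]
    env <- env[-1]  # beyond the first bin
    violations <- sum(diff(log(as.numeric(env))) > 1e-9)
    expect_lte(violations, 1)
  }
})

test_that("complexity distributions are normalized and broad", {
  ct <- .fx$ct_bdm
  skip_if(is.null(ct))
  gd <- complexity_distribution(ct, bins = 10, weight = "genotype")
  pd <- complexity_distribution(ct, bins = 10, weight = "phenotype")
  expect_equal(sum(gd$weight), 1)
  expect_equal(sum(pd$weight), 1)
  expect_gt(sum(gd$weight > 0), 2)          # support spans multiple bins
  expect_false(isTRUE(all.equal(gd$weight, pd$weight)))  # bias shifts mass
})
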