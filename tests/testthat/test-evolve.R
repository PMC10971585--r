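test_that("population size is conserved and mu = 0 freezes a lone lineage", {
  cfg <- wright_fisher_config(N = 1, mu = 0, ranges = small_ranges())
  pop <- genotype_at(123, small_ranges())
  for (i in 1:5) {
    pop2 <- wright_fisher_step(pop, flat_landscape(), cfg)
    expect_identical(nrow(pop2), 1L)
    expect_equal(as.data.frame(pop2), as.data.frame(pop))
    pop <- pop2
  }
})

test_that("zero-fitness lineages never reproduce", {
  r <- small_ranges()
  cfg <- wright_fisher_config(N = 20, mu = 0, ranges = r)
  a <- c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 2L)  # viable
  b <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 4L)  # unviable under the landscape
  pop <- dplyr::bind_rows(genotype_at(genotype_index(a, r), r)[rep(1, 10), ],
                          genotype_at(genotype_index(b, r), r)[rep(1, 10), ])
  land <- fitness_landscape(
    tibble::tibble(phenotype = phenotype_of(a), fitness = 1), default = 0)
  withr::with_seed(1, {
    pop2 <- wright_fisher_step(pop, land, cfg)
  })
  expect_true(all(phenotype_keys(pop2) == phenotype_of(a)))

  # an all-zero-fitness population is an extinction error
  dead <- pop[11:20, ]
  expect_error(wright_fisher_step(dead, land, cfg), "zero fitness")
})

test_that("offspring shares match the multinomial expectation under selection", {
  # two genotypes with distinct phenotypes, fitness 1 + s vs 1
  r <- small_ranges()
  s <- 0.5
  a <- c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 2L)   # branching shape
  b <- c(0L, 0L, 0L, -1L, 1L, 0L, 0L, 0L, 2L)  # vertical line
  ka <- phenotype_of(a); kb <- phenotype_of(b)
  expect_false(ka == kb)
  land <- fitness_landscape(
    tibble::tibble(phenotype = c(ka, kb), fitness = c(1 + s, 1)), default = 0)
  cfg <- wright_fisher_config(N = 10, mu = 0, ranges = r)
  pop <- dplyr::bind_rows(
    genotype_at(rep(genotype_index(a, r), 5), r),
    genotype_at(rep(genotype_index(b, r), 5), r))
  reps <- 3000
  count_a <- withr::with_seed(99, {
    vapply(seq_len(reps), function(i) {
      sum(phenotype_keys(wright_fisher_step(pop, land, cfg)) == ka)
    }, numeric(1))
  })
  p_exp <- 5 * (1 + s) / (5 * (1 + s) + 5)   # multinomial mean share
  se <- sqrt(p_exp * (1 - p_exp) / (10 * reps))
  expect_lt(abs(mean(count_a) / 10 - p_exp), 4 * se)
})

test_that("boundary genes mutate inward with full per-site probability", {
  r <- small_ranges()
  m <- matrix(rep(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 4L), each = 400),
              nrow = 400)  # every site at its upper boundary
  withr::with_seed(7, {
    res <- biomorphr:::mutate_population(m, mu = 1, ranges = r)
  })
  expect_true(all(res$m[, 1:8] == 0L))
  expect_true(all(res$m[, 9] == 3L))
})

test_that("neutral drift visits phenotypes in proportion to their frequency", {
  gp <- small_map()
  cfg <- wright_fisher_config(N = 200, mu = 0.1, generations = 3000,
                              ranges = small_ranges())
  withr::with_seed(31, {
    fs <- run_flat_scenario(cfg, map = gp)
  })
  ap <- fs$appearance
  expect_equal(sum(ap$appearance_freq), 1)
  seen <- ap$occurrences > 0
  expect_gt(cor(ap$appearance_freq[seen], ap$f[seen], method = "spearman"),
            0.5)
  gl <- glance(fs)
  expect_identical(nrow(gl), 1L)
})

test_that("a degenerate one-phenotype map appears every generation", {
  r <- gene_ranges(0, 0, 1, 2)   # two genotypes, both the dot phenotype
  gp <- build_gp_map(r)
  expect_identical(nrow(gp$phenotypes), 1L)
  cfg <- wright_fisher_config(N = 5, mu = 0.1, generations = 50, ranges = r)
  withr::with_seed(2, {
    fs <- run_flat_scenario(cfg, map = gp,
                            focal_phenotypes = gp$phenotypes$phenotype)
  })
  expect_true(all(fs$focal_series$count == 5))
  expect_equal(fs$appearance$appearance_freq, 1)
})

test_that("the two-peak scenario shows the arrival of the frequent", {
  # reduced-scale sweep on the small fixture: pick an NC with a clear
  # frequent/rare contrast in its mutation spectrum
  gp <- small_map()
  g0 <- as_genotype(gp$phenotypes$example[which.max(gp$phenotypes$n_genotypes)])
  nc <- neutral_component(g0, gp$ranges, gp$config, map = gp)
  sp <- nc_phi_spectrum(nc, gp$ranges, gp$config)
  tg <- pick_two_peak_targets(sp, ratio = 0.02)
  expect_lt(tg$phi2, tg$phi1)

  cfg <- wright_fisher_config(N = 100, mu = 1e-4, ranges = gp$ranges,
                              raster = gp$config)
  res <- run_two_peak_scenario(nc, tg$p1, tg$p2,
                               s1 = c(0.02, 0.1, 0.3), s2 = 0.3,
                               config = cfg, repetitions = 60, seed = 5)
  # the frequent phenotype fixes first in most repetitions even though
  # p2 is at least as fit (equal fitness in the s1 = 0.3 cell)
  eq <- res[res$s1 == 0.3 & res$s2 == 0.3, ]
  expect_gt(eq$p1_fixed_first, 0.5)
  expect_gt(eq$p1_fixed_first, eq$p2_fixed_first)
  # fixation requires appearance, cell by cell
  expect_true(all(res$p2_fixed_first <= res$p2_appeared + 1e-12))
  # more selection on p1 leaves less time for p2 to appear (common RNs)
  ord <- order(res$s1)
  expect_true(all(diff(res$p2_appeared[ord]) <= 1e-12))
  .fx$two_peak_small <- res
})
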