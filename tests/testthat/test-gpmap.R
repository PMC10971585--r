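test_that("neutral set sizes conserve the genotype count", {
  gp <- small_map()
  expect_equal(sum(gp$phenotypes$n_genotypes), 26244)
  expect_equal(sum(gp$phenotypes$f), 1)
  expect_true(all(gp$phenotypes$f > 0))
  # example genotype is the first of its neutral set in enumeration order
  i <- which.max(gp$phenotypes$n_genotypes)
  ex <- as_genotype(gp$phenotypes$example[i])
  expect_identical(phenotype_of(ex), gp$phenotypes$phenotype[i])
  expect_equal(min(which(gp$keys == gp$phenotypes$phenotype[i])),
               gp$phenotypes$example_index[i])
})

test_that("ranks agree with the brute-force greater-or-equal count", {
  gp <- tiny_map()
  rc <- rank_curve(gp)
  oracle <- vapply(rc$n_genotypes, function(n) {
    sum(rc$n_genotypes >= n)
  }, numeric(1))
  expect_equal(rc$rank, oracle)
  expect_equal(max(rc$rank), nrow(rc))
  expect_gte(min(rc$rank), 1)

  # distinct sizes give ranks 1..P
  fake <- tibble::tibble(phenotype = letters[1:5], n_genotypes = c(50, 20, 9, 3, 1))
  expect_equal(rank_curve(fake)$rank, 1:5)
})

test_that("cached map statistics equal direct per-genotype recomputation", {
  gp <- small_map()
  gs <- small_genotype_stats()
  idx <- withr::with_seed(21, sample.int(gp$n_genotypes, 40))
  for (i in idx) {
    g <- as_genotype(genotype_at(i, gp$ranges)[1, ])
    expect_equal(gs$robustness[i],
                 genotype_robustness(g, gp$ranges, gp$config))
    expect_equal(gs$evolvability[i],
                 genotype_evolvability(g, gp$ranges, gp$config))
  }
})

test_that("phenotype robustness and evolvability satisfy their bounds", {
  ps <- small_phenotype_stats()
  gs <- small_genotype_stats()
  expect_true(all(ps$robustness >= 0 & ps$robustness <= 1))

  # rho_p is the mean over the neutral set; epsilon_p at least the max
  # member genotype evolvability (union bound), at most the sum
  agg <- dplyr::summarise(
    dplyr::group_by(gs, .data$phenotype),
    mean_rho = mean(.data$robustness),
    max_evo = max(.data$evolvability),
    sum_evo = sum(.data$evolvability))
  j <- match(ps$phenotype, agg$phenotype)
  expect_equal(ps$robustness, agg$mean_rho[j])
  expect_true(all(ps$evolvability >= agg$max_evo[j]))
  expect_true(all(ps$evolvability <= agg$sum_evo[j]))

  # a neutral set of size one has the evolvability of its single member
  singles <- ps$phenotype[ps$n_genotypes == 1]
  if (length(singles)) {
    expect_equal(ps$evolvability[match(singles, ps$phenotype)],
                 agg$max_evo[match(singles, agg$phenotype)])
  }
})

test_that("phi is a probability partition: rho_q + sum_p phi_pq = 1", {
  gp <- small_map()
  mm <- mutation_matrix(gp)
  agg <- dplyr::summarise(dplyr::group_by(mm, .data$from),
                          s = sum(.data$phi) + .data$rho[1])
  expect_equal(nrow(agg), nrow(gp$phenotypes))
  expect_true(all(abs(agg$s - 1) < 1e-12))

  q <- gp$phenotypes$phenotype[which.max(gp$phenotypes$n_genotypes)]
  pf <- phi_from(q, gp)
  expect_equal(sum(pf$phi) + attr(pf, "rho"), 1)
  expect_true(all(pf$phi > 0 & pf$phi <= 1))
})

test_that("phi increases with target frequency among allowed transitions", {
  gp <- small_map()
  q <- gp$phenotypes$phenotype[which.max(gp$phenotypes$n_genotypes)]
  pf <- phi_from(q, gp)
  f <- gp$phenotypes$f[match(pf$phenotype, gp$phenotypes$phenotype)]
  expect_gt(cor(pf$phi, f, method = "spearman"), 0)
})

test_that("neutral components are closed and match the graph oracle", {
  skip_if_not_installed("igraph")
  gp <- tiny_map()
  g0 <- as_genotype(gp$phenotypes$example[which.max(gp$phenotypes$n_genotypes)])
  nc <- neutral_component(g0, gp$ranges, gp$config, map = gp)
  key0 <- attr(nc, "phenotype")
  expect_identical(key0, phenotype_of(g0, gp$config))

  # closure: every neutral neighbor of every member is a member
  members <- genotype_strings(nc)
  for (i in seq_len(min(nrow(nc), 40))) {
    nb <- mutational_neighbors(as_genotype(nc[i, ]), gp$ranges)
    nk <- phenotype_keys(nb, gp$config)
    expect_true(all(genotype_strings(nb[nk == key0, ]) %in% members))
  }

  # independent oracle: connected components of the neutral subgraph
  nodes <- which(gp$keys == key0)
  nm <- biomorphr:::neighbor_index_matrix(gp$ranges, gp$n_genotypes)
  e <- cbind(rep(nodes, 18), as.vector(nm[nodes, ]))
  e <- e[!is.na(e[, 2]) & gp$keys[e[, 2]] == key0, , drop = FALSE]
  gr <- igraph::graph_from_edgelist(matrix(as.character(e), ncol = 2),
                                    directed = FALSE)
  comp <- igraph::components(gr)
  mine <- as.character(attr(nc, "indices"))
  start <- as.character(genotype_index(g0, gp$ranges))
  oracle <- names(comp$membership)[comp$membership == comp$membership[start]]
  expect_setequal(mine, oracle)

  # map-free search gives the identical component
  nc2 <- neutral_component(g0, gp$ranges, gp$config)
  expect_setequal(genotype_strings(nc2), members)
})

test_that("a genotype without neutral neighbors forms a singleton component", {
  # a single-point range has no mutations at all, the degenerate case of
  # an isolated genotype
  r <- gene_ranges(0, 0, 1, 1)
  gp <- build_gp_map(r)
  nc <- neutral_component(c(0, 0, 0, 0, 0, 0, 0, 0, 1), r, gp$config,
                          map = gp)
  expect_identical(nrow(nc), 1L)
  nc2 <- neutral_component(c(0, 0, 0, 0, 0, 0, 0, 0, 1), r, gp$config)
  expect_identical(nrow(nc2), 1L)
})

test_that("null model expects rho and phi equal to f", {
  gp <- tiny_map()
  nm <- null_model_expectations(gp)
  expect_equal(nm$rho_null, gp$phenotypes$f)
  expect_equal(sum(nm$phi_null), 1)

  uniform <- tibble::tibble(phenotype = c("a", "b"), f = c(0.5, 0.5))
  expect_equal(null_model_expectations(uniform)$rho_null, c(0.5, 0.5))
})

test_that("observed robustness beats the null model (genetic correlations)", {
  ps <- small_phenotype_stats()
  top <- dplyr::slice_max(ps, .data$n_genotypes, prop = 0.1, with_ties = FALSE)
  expect_true(all(top$robustness > top$f))
  expect_gt(cor(ps$robustness, log(ps$f)), 0.5)
})

test_that("fixed g9 still shows orders-of-magnitude neutral set variation", {
  gp <- fixed_g9_map(4L)
  np <- gp$phenotypes$n_genotypes
  expect_gt(max(np) / min(np), 10)
})

test_that("sharded building merges to the directly built map", {
  r <- tiny_ranges()
  gp <- tiny_map()
  shards <- list()
  for (g1 in r$vector_min:r$vector_max) {
    for (g9 in r$g9_min:r$g9_max) {
      shards[[length(shards) + 1]] <- gp_map_shard(r, gp$config, g1, g9)
    }
  }
  merged <- merge_gp_shards(shards, r, gp$config)
  a <- dplyr::arrange(gp$phenotypes, .data$phenotype)
  b <- dplyr::arrange(merged$phenotypes, .data$phenotype)
  expect_equal(a$phenotype, b$phenotype)
  expect_equal(a$n_genotypes, b$n_genotypes)
  expect_equal(a$example_index, b$example_index)
  expect_equal(a$example, b$example)
  # merged maps have no keys: genotype-level statistics refuse politely
  expect_error(gp_genotype_stats(merged), "shards")
})

test_that("tidy and glance summarise a gp_map", {
  gp <- tiny_map()
  td <- tidy(gp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n_genotypes[1], max(gp$phenotypes$n_genotypes))
  gl <- glance(gp)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$n_genotypes, gp$n_genotypes)
})
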