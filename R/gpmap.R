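#' Build the genotype-phenotype map by exhaustive enumeration
#'
#' Enumerates every genotype in the range (odometer order), computes its
#' phenotype key, and tabulates neutral set sizes. The per-genotype key
#' vector is retained, which is what makes all downstream statistics
#' (robustness, evolvability, mutation probabilities, neutral components)
#' fast: the neighbor of an enumeration index is an index offset.
#'
#' For ranges too large to hold in memory use [gp_map_shard()] /
#' [merge_gp_shards()], which process one (g1, g9) prefix at a time.
#'
#' @param ranges A [gene_ranges()] object (finite by construction).
#' @param config A [raster_config()].
#' @param chunk_size Genotypes per enumeration block.
#' @param limit Refuse to enumerate more than this many genotypes in memory.
#' @return An object of class `gp_map`: ranges, config, the key vector, and
#'   a `phenotypes` tibble with columns `phenotype`, `n_genotypes`, `f`
#'   (frequency), `example_index` and `example` (first genotype of the
#'   neutral set in enumeration order).
#' @examples
#' \donttest{
#' gp <- build_gp_map(gene_ranges(-1, 1, 1, 2), raster_config())
#' glance(gp)
#' }
#' @export
build_gp_map <- function(ranges, config = raster_config(),
                         chunk_size = 262144L, limit = 5e6) {
  n <- n_genotypes(ranges)
  if (n > limit) {
    stop("range holds ", format(n, big.mark = ","),
         " genotypes; use gp_map_shard()/merge_gp_shards()", call. = FALSE)
  }
  sizes <- range_sizes(ranges)
  keys <- character(n)
  from <- 0
  while (from < n) {
    to <- min(from + chunk_size, n)
    keys[(from + 1):to] <- cpp_keys_for_index_range(
      from, to, ranges$mins, sizes, config$grid_size, config$margin_pct,
      config$fill_threshold, config$length_rounding)
    from <- to
  }
  first <- !duplicated(keys)
  uk <- keys[first]
  id <- match(keys, uk)
  counts <- tabulate(id, nbins = length(uk))
  example_index <- which(first)
  phen <- tibble(
    phenotype = uk,
    n_genotypes = counts,
    f = counts / n,
    example_index = as.numeric(example_index),
    example = genotype_strings(genotype_at(example_index, ranges))
  )
  structure(list(ranges = ranges, config = config, n_genotypes = n,
                 keys = keys, phenotypes = phen),
            class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  cat("<gp_map> ", format(x$n_genotypes, big.mark = ","), " genotypes, ",
      format(nrow(x$phenotypes), big.mark = ","), " phenotypes\n", sep = "")
  print(x$ranges)
  invisible(x)
}

#' @rdname build_gp_map
#' @param x,object A `gp_map`.
#' @param ... Unused.
#' @export
tidy.gp_map <- function(x, ...) {
  dplyr::arrange(x$phenotypes, dplyr::desc(.data$n_genotypes),
                 .data$phenotype)
}

#' @rdname build_gp_map
#' @export
glance.gp_map <- function(x, ...) {
  tibble(
    n_genotypes = x$n_genotypes,
    n_phenotypes = nrow(x$phenotypes),
    max_neutral_set = max(x$phenotypes$n_genotypes),
    median_neutral_set = stats::median(x$phenotypes$n_genotypes),
    n_gt10 = sum(x$phenotypes$n_genotypes > 10)
  )
}

map_keys <- function(map) {
  if (is.null(map$keys)) {
    stop("this gp_map was merged from shards and has no per-genotype keys; ",
         "rebuild with build_gp_map() for genotype-level statistics",
         call. = FALSE)
  }
  map$keys
}

# neighbor enumeration indices, n x 18 (NA where the mutation leaves the range)
neighbor_index_matrix <- function(ranges, n = n_genotypes(ranges)) {
  sizes <- range_sizes(ranges)
  strides <- gene_strides(ranges)
  idx0 <- seq_len(n) - 1
  out <- matrix(NA_real_, nrow = n, ncol = 18L)
  for (g in 1:9) {
    digit <- (idx0 %/% strides[g]) %% sizes[g]
    dn <- digit > 0
    up <- digit < sizes[g] - 1L
    out[dn, 2L * g - 1L] <- idx0[dn] - strides[g] + 1
    out[up, 2L * g] <- idx0[up] + strides[g] + 1
  }
  out
}

#' Neutral set size rank curve
#'
#' For each phenotype the rank r is the number of phenotypes with greater
#' or equal neutral set size; ties share a rank. Plotting `n_genotypes`
#' against `rank` on log-log axes gives the Zipf-like curve characteristic
#' of strong phenotype bias.
#'
#' @param table A `gp_map` or its phenotype tibble (needs `n_genotypes`).
#' @return The table with a `rank` column, sorted by rank.
#' @export
rank_curve <- function(table) {
  tbl <- if (inherits(table, "gp_map")) table$phenotypes else table
  sizes <- sort(unique(tbl$n_genotypes), decreasing = TRUE)
  cnt <- as.integer(table(factor(tbl$n_genotypes, levels = sizes)))
  cum <- cumsum(cnt)
  tbl$rank <- cum[match(tbl$n_genotypes, sizes)]
  dplyr::arrange(tbl, .data$rank, .data$phenotype)
}

#' Robustness of a single genotype
#'
#' Fraction of available point mutations that leave the phenotype
#' unchanged. The denominator is the number of mutations that actually
#' exist at this genotype (18 in the interior, fewer at range boundaries).
#' Computed directly from [phenotype_of()] on every neighbor; for bulk
#' computation over a whole map use [gp_genotype_stats()].
#'
#' @inheritParams validate_genotype
#' @param config A [raster_config()].
#' @return A fraction in \[0, 1\].
#' @export
genotype_robustness <- function(genotype, ranges = gene_ranges(),
                                config = raster_config()) {
  g <- validate_genotype(genotype, ranges)
  nb <- mutational_neighbors(g, ranges)
  k0 <- phenotype_of(g, config)
  mean(phenotype_keys(nb, config) == k0)
}

#' Evolvability of a single genotype
#'
#' Number of distinct phenotypes (other than its own) reachable by a
#' single point mutation.
#'
#' @inheritParams genotype_robustness
#' @return A non-negative count.
#' @export
genotype_evolvability <- function(genotype, ranges = gene_ranges(),
                                  config = raster_config()) {
  g <- validate_genotype(genotype, ranges)
  nb <- mutational_neighbors(g, ranges)
  k0 <- phenotype_of(g, config)
  length(setdiff(unique(phenotype_keys(nb, config)), k0))
}

#' Per-genotype robustness and evolvability over a whole map
#'
#' @param map A `gp_map` built with [build_gp_map()].
#' @return A tibble with one row per genotype (enumeration order): `index`,
#'   `phenotype`, `n_neighbors`, `robustness`, `evolvability`.
#' @export
gp_genotype_stats <- function(map) {
  keys <- map_keys(map)
  nm <- neighbor_index_matrix(map$ranges, map$n_genotypes)
  nk <- matrix(keys[nm], nrow = nrow(nm))
  avail <- !is.na(nm)
  neutral <- nk == keys          # column-wise recycling over the n rows
  n_nb <- rowSums(avail)
  n_neutral <- rowSums(neutral, na.rm = TRUE)
  evo <- integer(nrow(nm))
  for (i in seq_len(nrow(nm))) {
    r <- nk[i, avail[i, ]]
    evo[i] <- length(unique(r[r != keys[i]]))
  }
  tibble(index = seq_len(nrow(nm)),
         phenotype = keys,
         n_neighbors = n_nb,
         robustness = n_neutral / n_nb,
         evolvability = evo)
}

# long table of mutation events (from phenotype id, to phenotype id)
mutation_events <- function(map) {
  keys <- map_keys(map)
  uk <- map$phenotypes$phenotype
  id <- match(keys, uk)
  nm <- neighbor_index_matrix(map$ranges, map$n_genotypes)
  from <- rep(id, times = ncol(nm))
  to_idx <- as.vector(nm)
  ok <- !is.na(to_idx)
  list(from = from[ok], to = id[to_idx[ok]], uk = uk)
}

#' Per-phenotype statistics: robustness, evolvability, rank
#'
#' Phenotype robustness is the mean genotype robustness over the neutral
#' set; phenotype evolvability is the number of distinct other phenotypes
#' reachable by one mutation from anywhere in the neutral set.
#'
#' @inheritParams gp_genotype_stats
#' @return The map's phenotype tibble with added columns `rank`,
#'   `robustness`, `evolvability`.
#' @export
gp_phenotype_stats <- function(map) {
  gs <- gp_genotype_stats(map)
  uk <- map$phenotypes$phenotype
  id <- match(gs$phenotype, uk)
  rho <- vapply(split(gs$robustness, id), mean, numeric(1))
  rho_full <- numeric(length(uk))
  rho_full[as.integer(names(rho))] <- rho
  ev <- mutation_events(map)
  nonneutral <- ev$from != ev$to
  pair <- ev$from[nonneutral] * (length(uk) + 1) + ev$to[nonneutral]
  upair <- unique(pair)
  from_u <- upair %/% (length(uk) + 1)
  eps <- tabulate(from_u, nbins = length(uk))
  out <- rank_curve(map$phenotypes)
  out$robustness <- rho_full[match(out$phenotype, uk)]
  out$evolvability <- eps[match(out$phenotype, uk)]
  out
}

#' Phenotype mutation probabilities from a source phenotype
#'
#' phi_pq is the probability that a random mutation on a random genotype of
#' the source set lands on phenotype p. The source may be a phenotype key
#' (its full neutral set) or a [neutral_component()]. The denominator is
#' the number of available mutation events from the set, matching the
#' robustness denominator, so rho_q + sum_p phi_pq = 1 exactly.
#'
#' @param q A phenotype key present in the map, or a `neutral_component`.
#' @inheritParams gp_genotype_stats
#' @return A tibble with columns `phenotype`, `events`, `phi` for every
#'   target reached (the neutral target q itself is excluded); the neutral
#'   fraction is attached as attribute `rho` and the source as `q`.
#' @export
phi_from <- function(q, map) {
  keys <- map_keys(map)
  if (inherits(q, "neutral_component")) {
    members <- attr(q, "indices")
    q_key <- attr(q, "phenotype")
  } else {
    q_key <- q
    members <- which(keys == q_key)
    if (length(members) == 0L) stop("phenotype not found in map", call. = FALSE)
  }
  nm <- neighbor_index_matrix(map$ranges, map$n_genotypes)[members, , drop = FALSE]
  to_idx <- as.vector(nm)
  to_idx <- to_idx[!is.na(to_idx)]
  to_key <- keys[to_idx]
  total <- length(to_key)
  neutral <- to_key == q_key
  tab <- table(to_key[!neutral])
  out <- tibble(phenotype = names(tab),
                events = as.integer(tab),
                phi = as.integer(tab) / total)
  out <- dplyr::arrange(out, dplyr::desc(.data$phi), .data$phenotype)
  attr(out, "rho") <- sum(neutral) / total
  attr(out, "q") <- q_key
  out
}

#' Full sparse mutation matrix
#'
#' All non-neutral phenotype transition probabilities phi_pq of the map.
#'
#' @inheritParams gp_genotype_stats
#' @return A tibble with columns `from`, `to`, `events`, `phi` (and the
#'   per-source neutral probability `rho` repeated on each row).
#' @export
mutation_matrix <- function(map) {
  ev <- mutation_events(map)
  uk <- ev$uk
  P1 <- length(uk) + 1
  tot <- tabulate(ev$from, nbins = length(uk))
  pair <- ev$from * P1 + ev$to
  upair <- sort(unique(pair))
  cnt <- tabulate(match(pair, upair), nbins = length(upair))
  from <- as.integer(upair %/% P1)
  to <- as.integer(upair %% P1)
  neutral <- from == to
  neutral_events <- integer(length(uk))
  neutral_events[from[neutral]] <- cnt[neutral]
  from_nn <- from[!neutral]
  tibble(from = uk[from_nn],
         to = uk[to[!neutral]],
         events = cnt[!neutral],
         phi = cnt[!neutral] / tot[from_nn],
         rho = neutral_events[from_nn] / tot[from_nn])
}

#' Null-model expectations for robustness and mutation probabilities
#'
#' Under the uncorrelated null model (neutral set sizes kept, genotype
#' assignments randomized) both the expected phenotype robustness and the
#' expected mutation probability toward p equal the frequency f_p.
#'
#' @param table A `gp_map` or phenotype tibble with an `f` column.
#' @return A tibble with columns `phenotype`, `rho_null`, `phi_null`.
#' @export
null_model_expectations <- function(table) {
  tbl <- if (inherits(table, "gp_map")) table$phenotypes else table
  tibble(phenotype = tbl$phenotype, rho_null = tbl$f, phi_null = tbl$f)
}

#' Neutral component containing a genotype
#'
#' The set of genotypes reachable from `genotype` by neutral point
#' mutations (breadth-first closure). With a prebuilt `gp_map` the search
#' uses the cached key vector; without one, phenotypes are computed on
#' demand (usable on the full default range, where the component is tiny
#' compared to genotype space).
#'
#' @inheritParams validate_genotype
#' @param map Optional `gp_map` over the same ranges/config.
#' @param config A [raster_config()] (used when `map` is NULL).
#' @return A tibble of member genotypes (`g1`..`g9`) of class
#'   `neutral_component`, with attributes `phenotype` (shared key) and
#'   `indices` (enumeration indices).
#' @export
neutral_component <- function(genotype, ranges = gene_ranges(),
                              config = raster_config(), map = NULL) {
  g <- validate_genotype(genotype, ranges)
  if (!is.null(map)) {
    keys <- map_keys(map)
    nm <- neighbor_index_matrix(ranges, map$n_genotypes)
    start <- genotype_index(g, ranges)
    key0 <- keys[start]
    seen <- logical(map$n_genotypes)
    seen[start] <- TRUE
    frontier <- start
    while (length(frontier)) {
      nb <- unique(as.vector(nm[frontier, , drop = FALSE]))
      nb <- nb[!is.na(nb)]
      nb <- nb[!seen[nb]]
      nb <- nb[keys[nb] == key0]
      seen[nb] <- TRUE
      frontier <- nb
    }
    idx <- which(seen)
  } else {
    key0 <- phenotype_of(g, config)
    strides <- gene_strides(ranges)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    start <- genotype_index(g, ranges)
    assign(as.character(start), TRUE, envir = seen)
    members <- start
    frontier <- matrix(g, nrow = 1)
    while (nrow(frontier)) {
      nb_list <- lapply(seq_len(nrow(frontier)), function(i) {
        as.matrix(mutational_neighbors(frontier[i, ], ranges)[, 1:9])
      })
      nb <- unique(do.call(rbind, nb_list))
      nb_idx <- as.numeric(nb %*% strides) -
        sum(ranges$mins * strides) + 1
      new <- !vapply(as.character(nb_idx), exists, logical(1), envir = seen)
      nb <- nb[new, , drop = FALSE]; nb_idx <- nb_idx[new]
      if (!nrow(nb)) break
      nbt <- as_tibble(as.data.frame(nb))
      names(nbt) <- paste0("g", 1:9)
      is_neutral <- phenotype_keys(nbt, config) == key0
      for (ii in as.character(nb_idx)) assign(ii, TRUE, envir = seen)
      keep <- which(is_neutral)
      members <- c(members, nb_idx[keep])
      frontier <- nb[keep, , drop = FALSE]
    }
    idx <- sort(members)
  }
  out <- genotype_at(idx, ranges)
  structure(out, class = c("neutral_component", class(out)),
            phenotype = key0, indices = idx)
}

# --- sharded building for large ranges -------------------------------------

#' Build one shard of a large GP map
#'
#' Counts phenotypes over the sub-hyper-rectangle with `g1` and `g9` fixed.
#' The full default range factors into 7 x 8 = 56 such shards of 7^7 =
#' 823,543 genotypes each; no shard holds more than one prefix's counts.
#' Shard tables from all (g1, g9) prefixes merge losslessly with
#' [merge_gp_shards()].
#'
#' @inheritParams build_gp_map
#' @param g1,g9 The fixed values of genes 1 and 9 for this shard.
#' @return A tibble with columns `phenotype`, `n_genotypes`,
#'   `example_index` (global enumeration index of the first member).
#' @export
gp_map_shard <- function(ranges, config, g1, g9) {
  stopifnot(g1 >= ranges$vector_min, g1 <= ranges$vector_max,
            g9 >= ranges$g9_min, g9 <= ranges$g9_max)
  vals <- lapply(1:9, function(j) ranges$mins[j]:ranges$maxs[j])
  vals[[1]] <- as.integer(g1); vals[[9]] <- as.integer(g9)
  grid <- rev(do.call(expand.grid, rev(vals)))  # g1 slowest, g9 fastest
  names(grid) <- paste0("g", 1:9)
  keys <- phenotype_keys(grid, config)
  strides <- gene_strides(ranges)
  gidx <- as.numeric(as.matrix(grid) %*% strides) -
    sum(ranges$mins * strides) + 1
  first <- !duplicated(keys)
  uk <- keys[first]
  counts <- tabulate(match(keys, uk), nbins = length(uk))
  tibble(phenotype = uk, n_genotypes = counts,
         example_index = gidx[first])
}

#' Merge GP-map shards
#'
#' @param shards A list of shard tibbles from [gp_map_shard()] (or a
#'   directory containing them as CSV files).
#' @inheritParams build_gp_map
#' @return A `gp_map` without the per-genotype key vector (table-level
#'   statistics and [rank_curve()] work; genotype-level statistics require
#'   [build_gp_map()]).
#' @export
merge_gp_shards <- function(shards, ranges, config = raster_config()) {
  if (is.character(shards)) {
    files <- list.files(shards, pattern = "\\.csv$", full.names = TRUE)
    shards <- lapply(files, function(f) as_tibble(read.csv(f)))
  }
  all <- dplyr::bind_rows(shards)
  phen <- all |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(n_genotypes = sum(.data$n_genotypes),
                     example_index = min(.data$example_index),
                     .groups = "drop")
  n <- n_genotypes(ranges)
  phen$f <- phen$n_genotypes / n
  phen$example <- genotype_strings(genotype_at(phen$example_index, ranges))
  phen <- phen[, c("phenotype", "n_genotypes", "f", "example_index", "example")]
  structure(list(ranges = ranges, config = config, n_genotypes = n,
                 keys = NULL, phenotypes = phen),
            class = "gp_map")
}
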