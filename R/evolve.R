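#' Fitness landscapes over phenotypes
#'
#' Fitness is assigned per phenotype key, with a default for unlisted
#' phenotypes. `flat_landscape()` gives every phenotype fitness 1 (pure
#' drift). `two_peak_landscape()` gives the source phenotype p0 fitness 1
#' and the two adaptive phenotypes fitnesses 1 + s1 and 1 + s2; every
#' other phenotype is unviable (fitness 0).
#'
#' @param values Tibble with columns `phenotype`, `fitness`.
#' @param default Fitness for phenotypes not listed.
#' @return An object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(values = tibble(phenotype = character(),
                                              fitness = numeric()),
                              default = 1) {
  stopifnot(all(values$fitness >= 0), default >= 0)
  structure(list(values = values, default = default),
            class = "fitness_landscape")
}

#' @rdname fitness_landscape
#' @export
flat_landscape <- function() fitness_landscape(default = 1)

#' @rdname fitness_landscape
#' @param p0,p1,p2 Phenotype keys of the source and the two adaptive
#'   phenotypes.
#' @param s1,s2 Selection coefficients of p1 and p2.
#' @export
two_peak_landscape <- function(p0, p1, p2, s1, s2) {
  fitness_landscape(tibble(phenotype = c(p0, p1, p2),
                           fitness = c(1, 1 + s1, 1 + s2)),
                    default = 0)
}

#' Fitness of phenotype keys under a landscape
#' @param keys Character vector of phenotype keys.
#' @param landscape A [fitness_landscape()].
#' @return Numeric fitness vector.
#' @export
fitness_of <- function(keys, landscape) {
  i <- match(keys, landscape$values$phenotype)
  out <- landscape$values$fitness[i]
  out[is.na(i)] <- landscape$default
  out
}

#' Wright-Fisher simulation configuration
#'
#' @param N Population size.
#' @param mu Per-site mutation probability per generation.
#' @param generations Measured generations (after burn-in).
#' @param ranges A [gene_ranges()].
#' @param raster A [raster_config()].
#' @param burn_in Burn-in generations before measurement; fixed at 10 N.
#' @param fixation_threshold Population share above which a phenotype
#'   counts as fixed (default 0.70).
#' @param max_generations Safety cap for run-to-fixation simulations.
#' @return An object of class `wf_config`.
#' @export
wright_fisher_config <- function(N, mu, generations = 0L,
                                 ranges = gene_ranges(),
                                 raster = raster_config(),
                                 burn_in = 10L * N,
                                 fixation_threshold = 0.70,
                                 max_generations = 2e5) {
  stopifnot(N >= 1, mu >= 0, mu <= 1, burn_in == 10L * N,
            fixation_threshold > 0, fixation_threshold < 1)
  structure(list(N = as.integer(N), mu = mu,
                 generations = as.integer(generations),
                 ranges = ranges, raster = raster,
                 burn_in = as.integer(burn_in),
                 fixation_threshold = fixation_threshold,
                 max_generations = max_generations),
            class = "wf_config")
}

# mutate a population matrix in place (per-site Bernoulli(mu); a boundary
# gene mutates inward with the full per-site probability)
mutate_population <- function(m, mu, ranges) {
  N <- nrow(m)
  nmut <- rbinom(1L, N * 9L, mu)
  if (nmut == 0L) return(list(m = m, changed = integer(0)))
  slots <- sample.int(N * 9L, nmut)
  i <- (slots - 1L) %% N + 1L
  j <- (slots - 1L) %/% N + 1L
  cur <- m[cbind(i, j)]
  dn_ok <- cur > ranges$mins[j]
  up_ok <- cur < ranges$maxs[j]
  delta <- integer(nmut)
  both <- dn_ok & up_ok
  delta[both] <- sample(c(-1L, 1L), sum(both), replace = TRUE)
  delta[!both & up_ok] <- 1L
  delta[!both & dn_ok] <- -1L
  m[cbind(i, j)] <- cur + delta
  list(m = m, changed = unique(i))
}

#' One Wright-Fisher generation
#'
#' N offspring are drawn with replacement with probability proportional to
#' parental fitness (fitness of the phenotype of each genotype under
#' `landscape`), then every site of every offspring mutates by one integer
#' step with probability `mu`; at a range boundary the step direction is
#' drawn from the in-range options only, keeping the per-site mutation
#' rate exactly `mu` everywhere. At most one step per site per generation.
#'
#' @param pop Tibble (or matrix) of genotypes, one row per individual.
#' @param landscape A [fitness_landscape()].
#' @param config A [wright_fisher_config()] (supplies mu, ranges, raster).
#' @return A tibble of genotypes of the same size.
#' @export
wright_fisher_step <- function(pop, landscape, config) {
  m <- as.matrix(as.data.frame(pop)[, paste0("g", 1:9)])
  storage.mode(m) <- "integer"
  keys <- phenotype_keys(as.data.frame(m) |> stats::setNames(paste0("g", 1:9)),
                         config$raster)
  fit <- fitness_of(keys, landscape)
  if (all(fit == 0)) {
    stop("entire population has zero fitness (extinction); check the ",
         "landscape/initialization", call. = FALSE)
  }
  parents <- sample.int(nrow(m), nrow(m), replace = TRUE, prob = fit)
  m <- m[parents, , drop = FALSE]
  m <- mutate_population(m, config$mu, config$ranges)$m
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("g", 1:9)
  out
}

#' Random genotype drawn uniformly from a range
#' @inheritParams n_genotypes
#' @return An integer genotype.
#' @export
random_genotype <- function(ranges) {
  g <- ranges$mins + vapply(range_sizes(ranges), function(s) {
    sample.int(s, 1L) - 1L
  }, integer(1))
  as_genotype(g)
}

#' Scenario 1: neutral drift on a flat fitness landscape
#'
#' All phenotypes are equally fit; the population drifts from a random
#' initial genotype. After a 10 N generation burn-in, the run records how
#' often every phenotype appears in the population (individual-generations,
#' normalized to sum 1) and, optionally, a per-generation time series for
#' focal phenotypes. Under neutrality the appearance frequency of a
#' phenotype tracks its global frequency f_p.
#'
#' @param config A [wright_fisher_config()] (the range must be small
#'   enough for [build_gp_map()] unless `map` is supplied).
#' @param map A prebuilt `gp_map` over the same range/raster.
#' @param focal_phenotypes Character vector of phenotype keys to track
#'   per generation.
#' @return An object of class `flat_scenario`: list with `appearance`
#'   (tibble: phenotype, occurrences, appearance_freq, f), `focal_series`
#'   (tibble: generation, phenotype, count), and the config.
#' @export
run_flat_scenario <- function(config, map = NULL, focal_phenotypes = NULL) {
  if (is.null(map)) map <- build_gp_map(config$ranges, config$raster)
  keys <- map_keys(map)
  uk <- map$phenotypes$phenotype
  id <- match(keys, uk)
  strides <- gene_strides(config$ranges)
  offset <- sum(config$ranges$mins * strides) - 1
  N <- config$N
  m <- matrix(rep(random_genotype(config$ranges), each = N), nrow = N)
  gens <- config$generations
  focal_id <- match(focal_phenotypes, uk)
  occ <- numeric(nrow(map$phenotypes))
  focal_counts <- if (length(focal_id)) {
    matrix(0L, nrow = gens, ncol = length(focal_id))
  }
  total_gens <- config$burn_in + gens
  for (t in seq_len(total_gens)) {
    parents <- sample.int(N, N, replace = TRUE)  # flat fitness: uniform
    m <- m[parents, , drop = FALSE]
    m <- mutate_population(m, config$mu, config$ranges)$m
    if (t > config$burn_in) {
      idx <- as.numeric(m %*% strides) - offset
      tg <- t - config$burn_in
      tab <- tabulate(id[idx], nbins = length(uk))
      occ <- occ + tab
      if (length(focal_id)) focal_counts[tg, ] <- tab[focal_id]
    }
  }
  appearance <- tibble(phenotype = uk,
                       occurrences = occ,
                       appearance_freq = occ / sum(occ),
                       f = map$phenotypes$f)
  focal_series <- if (length(focal_id)) {
    tibble(generation = rep(seq_len(gens), times = length(focal_id)),
           phenotype = rep(focal_phenotypes, each = gens),
           count = as.integer(focal_counts))
  } else {
    tibble(generation = integer(), phenotype = character(), count = integer())
  }
  structure(list(appearance = appearance, focal_series = focal_series,
                 config = config),
            class = "flat_scenario")
}

#' @export
print.flat_scenario <- function(x, ...) {
  cat("<flat_scenario> N =", x$config$N, ", mu =", x$config$mu,
      ",", x$config$generations, "measured generations;",
      sum(x$appearance$occurrences > 0), "phenotypes appeared\n")
  invisible(x)
}

#' @rdname run_flat_scenario
#' @param x,object A `flat_scenario`.
#' @param ... Unused.
#' @export
tidy.flat_scenario <- function(x, ...) {
  dplyr::arrange(x$appearance, dplyr::desc(.data$appearance_freq))
}

#' @rdname run_flat_scenario
#' @export
glance.flat_scenario <- function(x, ...) {
  seen <- x$appearance$occurrences > 0
  tibble(
    n_phenotypes_seen = sum(seen),
    spearman_f = stats::cor(x$appearance$appearance_freq[seen],
                            x$appearance$f[seen], method = "spearman"),
    N = x$config$N, mu = x$config$mu, generations = x$config$generations
  )
}

#' List adaptive candidates around a neutral component
#'
#' All phenotypes reachable by one mutation from a neutral component,
#' with their mutation probabilities phi from the NC. Used to choose the
#' two adaptive phenotypes of the two-peak scenario: a frequent one (high
#' phi) and a rare one (low phi).
#'
#' @param nc A [neutral_component()].
#' @param ranges,config Range and raster settings matching the NC.
#' @return A tibble with columns `phenotype`, `events`, `phi`, sorted by
#'   decreasing phi; neutral fraction as attribute `rho`.
#' @export
nc_phi_spectrum <- function(nc, ranges = gene_ranges(),
                            config = raster_config()) {
  key0 <- attr(nc, "phenotype")
  nb <- lapply(seq_len(nrow(nc)), function(i) {
    mutational_neighbors(as_genotype(nc[i, ]), ranges)[, 1:9]
  })
  nb <- dplyr::bind_rows(nb)
  keys <- phenotype_keys(nb, config)
  total <- length(keys)
  neutral <- keys == key0
  tab <- sort(table(keys[!neutral]), decreasing = TRUE)
  out <- tibble(phenotype = names(tab), events = as.integer(tab),
                phi = as.integer(tab) / total)
  attr(out, "rho") <- sum(neutral) / total
  attr(out, "q") <- key0
  out
}

#' Choose the frequent and the rare adaptive phenotype
#'
#' p1 is the most mutationally accessible phenotype from the NC; p2 is the
#' accessible phenotype whose phi is closest to `ratio` times phi(p1)
#' (default 0.02, a ~fifty-fold accessibility contrast).
#'
#' @param spectrum Output of [nc_phi_spectrum()].
#' @param ratio Target phi(p2) / phi(p1).
#' @return A list with `p1`, `p2`, `phi1`, `phi2`.
#' @export
pick_two_peak_targets <- function(spectrum, ratio = 0.02) {
  stopifnot(nrow(spectrum) >= 2)
  phi1 <- spectrum$phi[1L]
  rest <- spectrum[-1L, ]
  j <- which.min(abs(rest$phi / phi1 - ratio))
  list(p1 = spectrum$phenotype[1L], p2 = rest$phenotype[j],
       phi1 = phi1, phi2 = rest$phi[j])
}

# classify keys into 1 = p0, 2 = p1, 3 = p2, 4 = other
classify_keys <- function(keys, key0, key1, key2) {
  out <- rep.int(4L, length(keys))
  out[keys == key0] <- 1L
  out[keys == key1] <- 2L
  out[keys == key2] <- 3L
  out
}

#' Scenario 2: two-peak fitness landscape (arrival of the frequent)
#'
#' The population starts on a neutral component (NC) of a source phenotype
#' p0, burns in for 10 N generations of neutral drift on p0 (only p0
#' viable), then evolves on a landscape where p0 has fitness 1, p1 fitness
#' 1 + s1, p2 fitness 1 + s2 and everything else is unviable. Each
#' repetition runs to the first fixation event (share of p1 or p2 above
#' the fixation threshold) and records whether the rarer phenotype p2
#' appeared at all before it and which phenotype fixed. The (s1, s2) grid
#' shares burn-in states and measurement seeds across cells (common random
#' numbers), so comparisons across cells are paired.
#'
#' @param nc A [neutral_component()] of the source phenotype.
#' @param p1,p2 Phenotype keys of the two adaptive phenotypes (see
#'   [pick_two_peak_targets()]).
#' @param s1,s2 Numeric vectors of selection coefficients; the scenario is
#'   run for every (s1, s2) pair (expanded grid).
#' @param config A [wright_fisher_config()].
#' @param repetitions Repetitions per (s1, s2) cell.
#' @param seed Integer seed; every repetition and cell derives its RNG
#'   stream from it.
#' @return An object of class `two_peak_result`: tibble with one row per
#'   (s1, s2) cell: `p2_appeared` (probability p2 appeared before the
#'   first fixation), `p2_fixed_first`, `p1_fixed_first`, `no_fixation`,
#'   binomial standard errors, and `repetitions`.
#' @export
run_two_peak_scenario <- function(nc, p1, p2, s1, s2, config,
                                  repetitions = 100L, seed = 1L) {
  key0 <- attr(nc, "phenotype")
  stopifnot(!is.null(key0), p1 != key0, p2 != key0, p1 != p2)
  N <- config$N
  ranges <- config$ranges
  nc_m <- as.matrix(as.data.frame(nc)[, paste0("g", 1:9)])
  storage.mode(nc_m) <- "integer"
  key_cache <- new.env(hash = TRUE, parent = emptyenv())
  key_of_row <- function(g) {
    id <- paste(g, collapse = ",")
    k <- key_cache[[id]]
    if (is.null(k)) {
      k <- cpp_phenotype_key(as.integer(g), config$raster$grid_size,
                             config$raster$margin_pct,
                             config$raster$fill_threshold,
                             config$raster$length_rounding)
      key_cache[[id]] <- k
    }
    k
  }
  step <- function(m, cls, fit_by_class) {
    fit <- fit_by_class[cls]
    if (all(fit == 0)) stop("population extinct", call. = FALSE)
    parents <- sample.int(N, N, replace = TRUE, prob = fit)
    m <- m[parents, , drop = FALSE]
    cls <- cls[parents]
    res <- mutate_population(m, config$mu, ranges)
    for (i in res$changed) {
      cls[i] <- classify_keys(key_of_row(res$m[i, ]), key0, p1, p2)
    }
    list(m = res$m, cls = cls)
  }

  # burn-in endpoints, shared across the (s1, s2) grid
  burnt <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(seed + r)
    g0 <- nc_m[sample.int(nrow(nc_m), 1L), ]
    m <- matrix(rep(g0, each = N), nrow = N)
    cls <- rep.int(1L, N)
    for (t in seq_len(config$burn_in)) {
      st <- step(m, cls, c(1, 0, 0, 0))
      m <- st$m; cls <- st$cls
    }
    burnt[[r]] <- list(m = m, cls = cls)
  }

  cells <- tidyr::expand_grid(s1 = s1, s2 = s2)
  thr <- config$fixation_threshold * N
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    fit_by_class <- c(1, 1 + cells$s1[ci], 1 + cells$s2[ci], 0)
    appeared <- fixed1 <- fixed2 <- none <- logical(repetitions)
    for (r in seq_len(repetitions)) {
      set.seed(seed + 1000003L * r)  # common random numbers across cells
      m <- burnt[[r]]$m; cls <- burnt[[r]]$cls
      p2_seen <- FALSE
      t <- 0L
      repeat {
        t <- t + 1L
        st <- step(m, cls, fit_by_class)
        m <- st$m; cls <- st$cls
        n2 <- sum(cls == 3L)
        if (n2 > 0L) p2_seen <- TRUE
        n1 <- sum(cls == 2L)
        if (n1 > thr) { fixed1[r] <- TRUE; break }
        if (n2 > thr) { fixed2[r] <- TRUE; break }
        if (t >= config$max_generations) { none[r] <- TRUE; break }
      }
      appeared[r] <- p2_seen
    }
    se <- function(p) sqrt(p * (1 - p) / repetitions)
    out[[ci]] <- tibble(
      s1 = cells$s1[ci], s2 = cells$s2[ci],
      p2_appeared = mean(appeared), p2_appeared_se = se(mean(appeared)),
      p1_fixed_first = mean(fixed1), p2_fixed_first = mean(fixed2),
      p2_fixed_first_se = se(mean(fixed2)),
      no_fixation = mean(none), repetitions = repetitions
    )
  }
  structure(dplyr::bind_rows(out),
            class = c("two_peak_result", class(tibble())),
            seed = seed, p1 = p1, p2 = p2, p0 = key0)
}
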