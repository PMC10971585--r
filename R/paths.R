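#' Minimal-mutation path between two genotypes
#'
#' Point mutations change one gene by one step, so the shortest path
#' length is the Manhattan distance between the genotypes in gene space.
#' Ties are broken deterministically: gene 1 is adjusted to its target
#' value first, then gene 2, and so on.
#'
#' @param a,b Genotypes (anything [as_genotype()] accepts).
#' @param ranges A [gene_ranges()] both endpoints must satisfy.
#' @param config Optional [raster_config()]; when supplied, the phenotype
#'   key of every step is recorded and phenotype changes counted.
#' @return An object of class `genotype_path`: tibble with one row per
#'   visited genotype (`step`, `g1`..`g9`, and with a config `phenotype`,
#'   `phenotype_changed`), with attributes `n_steps` and `n_changes`.
#' @examples
#' p <- min_mutation_path(c(0,0,0,0,0,0,0,0,1), c(1,0,0,2,0,0,0,0,2),
#'                        gene_ranges())
#' attr(p, "n_steps")  # 4
#' @export
min_mutation_path <- function(a, b, ranges = gene_ranges(), config = NULL) {
  ga <- validate_genotype(a, ranges)
  gb <- validate_genotype(b, ranges)
  steps <- list(ga)
  cur <- ga
  for (gene in 1:9) {
    while (cur[gene] != gb[gene]) {
      cur[gene] <- cur[gene] + sign(gb[gene] - cur[gene])
      steps[[length(steps) + 1L]] <- cur
    }
  }
  build_genotype_path(steps, config)
}

build_genotype_path <- function(steps, config = NULL) {
  m <- do.call(rbind, steps)
  out <- as_tibble(as.data.frame(m))
  names(out) <- paste0("g", 1:9)
  out <- dplyr::bind_cols(tibble(step = seq_len(nrow(out)) - 1L), out)
  n_changes <- NA_integer_
  if (!is.null(config)) {
    keys <- phenotype_keys(out, config)
    out$phenotype <- keys
    out$phenotype_changed <- c(FALSE, keys[-1L] != keys[-length(keys)])
    n_changes <- sum(out$phenotype_changed)
  }
  structure(out, class = c("genotype_path", class(tibble())),
            n_steps = nrow(out) - 1L, n_changes = n_changes)
}

#' Probability of following one specific mutational path
#'
#' Under the interior-genotype idealization each step must pick the one
#' correct mutation out of 18, so a path of n mutations has probability
#' (1/18)^n. Boundary genotypes have fewer than 18 options, making this a
#' slight underestimate there; it is the standard back-of-envelope figure
#' for how unlikely a specific long path is.
#'
#' @param path A `genotype_path` (or an integer step count).
#' @return A probability.
#' @examples
#' path_probability(13)  # ~5e-17
#' @export
path_probability <- function(path) {
  n <- if (is.numeric(path)) path else attr(path, "n_steps")
  (1 / 18)^n
}

#' Path with the fewest phenotype changes to a target phenotype
#'
#' Searches the genotype graph (edges = point mutations) for a path from
#' `a` to any genotype of the target phenotype that minimizes the number
#' of phenotype transitions; neutral mutations are free. Among
#' equal-transition paths the one with fewest mutations is returned, with
#' remaining ties broken by enumeration order. Implemented as a Dijkstra
#' search with combined integer weights (transitions are worth more than
#' any possible number of single mutations), which is exact for 0/1-style
#' weights. Requires a `gp_map` so phenotypes are available for the whole
#' range.
#'
#' @param a Starting genotype.
#' @param target A phenotype key present in the map.
#' @param map A `gp_map` from [build_gp_map()].
#' @return A `genotype_path` as in [min_mutation_path()] (with phenotype
#'   annotations), or `NULL` invisibly with a message if the target is
#'   unreachable.
#' @export
min_phenotype_change_path <- function(a, target, map) {
  ranges <- map$ranges
  keys <- map_keys(map)
  ga <- validate_genotype(a, ranges)
  start <- genotype_index(ga, ranges)
  if (!any(keys == target)) {
    stop("target phenotype not present in the map", call. = FALSE)
  }
  n <- map$n_genotypes
  nm <- neighbor_index_matrix(ranges, n)
  big <- n + 1  # one transition outweighs any mutation count
  dist <- rep(Inf, n)
  pred <- rep(NA_real_, n)
  visited <- logical(n)
  dist[start] <- 0
  # simple binary heap keyed by (dist, node)
  heap_n <- 0L
  heap_d <- numeric(1024L); heap_v <- numeric(1024L)
  push <- function(d, v) {
    heap_n <<- heap_n + 1L
    if (heap_n > length(heap_d)) {
      heap_d <<- c(heap_d, numeric(length(heap_d)))
      heap_v <<- c(heap_v, numeric(length(heap_v)))
    }
    heap_d[heap_n] <<- d; heap_v[heap_n] <<- v
    i <- heap_n
    while (i > 1L) {
      p <- i %/% 2L
      if (heap_d[p] > heap_d[i] ||
          (heap_d[p] == heap_d[i] && heap_v[p] > heap_v[i])) {
        td <- heap_d[p]; heap_d[p] <<- heap_d[i]; heap_d[i] <<- td
        tv <- heap_v[p]; heap_v[p] <<- heap_v[i]; heap_v[i] <<- tv
        i <- p
      } else break
    }
  }
  pop <- function() {
    d <- heap_d[1L]; v <- heap_v[1L]
    heap_d[1L] <<- heap_d[heap_n]; heap_v[1L] <<- heap_v[heap_n]
    heap_n <<- heap_n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= heap_n && (heap_d[l] < heap_d[s] ||
          (heap_d[l] == heap_d[s] && heap_v[l] < heap_v[s]))) s <- l
      if (r <= heap_n && (heap_d[r] < heap_d[s] ||
          (heap_d[r] == heap_d[s] && heap_v[r] < heap_v[s]))) s <- r
      if (s == i) break
      td <- heap_d[s]; heap_d[s] <<- heap_d[i]; heap_d[i] <<- td
      tv <- heap_v[s]; heap_v[s] <<- heap_v[i]; heap_v[i] <<- tv
      i <- s
    }
    c(d, v)
  }
  push(0, start)
  goal <- NA_real_
  while (heap_n > 0L) {
    dv <- pop()
    v <- dv[2L]
    if (visited[v]) next
    visited[v] <- TRUE
    if (keys[v] == target) { goal <- v; break }
    nbrs <- nm[v, ]
    nbrs <- nbrs[!is.na(nbrs)]
    for (w in nbrs) {
      if (visited[w]) next
      wgt <- 1 + big * (keys[w] != keys[v])
      nd <- dv[1L] + wgt
      if (nd < dist[w] || (nd == dist[w] && v < pred[w] %||% Inf)) {
        dist[w] <- nd
        pred[w] <- v
        push(nd, w)
      }
    }
  }
  if (is.na(goal)) {
    message("target phenotype unreachable from the start within the range")
    return(invisible(NULL))
  }
  idx <- goal
  chain <- goal
  while (idx != start) {
    idx <- pred[idx]
    chain <- c(idx, chain)
  }
  steps <- lapply(chain, function(i) {
    as.integer(genotype_at(i, ranges)[1L, ])
  })
  build_genotype_path(steps, map$config)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x
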