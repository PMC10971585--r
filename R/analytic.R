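#' Parameters of the analytic constrained/unconstrained model
#'
#' The analytic model separates the genotype into constrained positions
#' (any change alters the phenotype) and unconstrained positions (no change
#' ever does). For biomorphs the unconstrained positions are the vector
#' genes whose vectors are never used because development stops after `g9`
#' stages. The model is exact for an (overly) fine-grained phenotype
#' definition and complements the raster coarse-graining.
#'
#' @param k Number of allowed values per vector gene (default 7,
#'   i.e. genes in \[-3, 3\]).
#' @param g9_min,g9_max Range of the recursion gene (default 1..8).
#' @param mutations_per_genotype Fixed mutation count per genotype used by
#'   the analytic formulas (default 18; boundary effects are ignored by
#'   design, unlike the computational statistics).
#' @return An object of class `analytic_params`.
#' @export
analytic_params <- function(k = 7L, g9_min = 1L, g9_max = 8L,
                            mutations_per_genotype = 18L) {
  k <- as.integer(k)
  stopifnot(k >= 2L, g9_min >= 1L, g9_min <= g9_max)
  structure(list(k = k, n_vector_genes = 8L,
                 g9_min = as.integer(g9_min), g9_max = as.integer(g9_max),
                 n_g9 = as.integer(g9_max - g9_min + 1L),
                 mutations_per_genotype = as.integer(mutations_per_genotype)),
            class = "analytic_params")
}

# vector indices used within the first g9 recursion stages:
# stage 1 uses index 4; each stage maps i -> {i-1, i+1} with wrap 0->8, 9->1
used_vector_indices <- function(g9) {
  used <- integer(0)
  frontier <- 4L
  for (s in seq_len(g9)) {
    frontier <- ifelse(frontier == 0L, 8L, ifelse(frontier == 9L, 1L, frontier))
    used <- union(used, frontier)
    frontier <- unique(c(frontier - 1L, frontier + 1L))
  }
  sort(used)
}

# genes feeding each vector index (x and y components)
genes_of_vector <- list(
  `1` = c(3L, 7L), `2` = c(2L, 6L), `3` = c(1L, 5L), `4` = 4L,
  `5` = c(1L, 5L), `6` = c(2L, 6L), `7` = c(3L, 7L), `8` = 8L
)

#' Constrained genotype positions for a given recursion depth
#'
#' Genes feeding any vector used within the first `g9` recursion stages are
#' constrained, plus gene 9 itself; all others are unconstrained (their
#' vectors are never drawn). From depth 5 onward every vector is in use.
#'
#' @param g9 Recursion gene value (>= 1).
#' @return Sorted integer vector of constrained gene indices (subset of 1..9).
#' @examples
#' constrained_sites(1)  # only g4 (and g9)
#' constrained_sites(4)  # all but g8
#' @export
constrained_sites <- function(g9) {
  stopifnot(g9 >= 1)
  used <- used_vector_indices(g9)
  genes <- sort(unique(unlist(genes_of_vector[as.character(used)])))
  sort(unique(c(genes, 9L)))
}

n_unconstrained_vector_genes <- function(g9) {
  8L - (length(constrained_sites(g9)) - 1L)
}

#' Analytic neutral set size
#'
#' Each unconstrained vector gene multiplies the neutral set by k, and the
#' mirror identification contributes a factor 2:
#' N_p(g9) ~ 2 k^(9 - 2 g9) for 1 <= g9 <= 4 and 2 otherwise.
#'
#' @inheritParams constrained_sites
#' @param params An [analytic_params()].
#' @return The approximate neutral set size (a double).
#' @examples
#' analytic_neutral_set_size(4)  # 2 * 7 = 14
#' @export
analytic_neutral_set_size <- function(g9, params = analytic_params()) {
  u <- vapply(g9, n_unconstrained_vector_genes, integer(1))
  2 * as.numeric(params$k)^u
}

#' Analytic phenotype frequency for a recursion-depth class
#' @inheritParams analytic_neutral_set_size
#' @return N_p divided by the total number of genotypes.
#' @export
analytic_frequency <- function(g9, params = analytic_params()) {
  analytic_neutral_set_size(g9, params) /
    (as.numeric(params$k)^8 * params$n_g9)
}

#' Analytic neutral-set-size rank
#'
#' r ~ k^8 / N_p for N_p > 2 and 2 k^8 for N_p = 2. The approximation
#' keeps only the largest term of a sum over g9, so it deliberately
#' underestimates true ranks and is non-integer in general.
#'
#' @param n_p Neutral set size(s).
#' @inheritParams analytic_neutral_set_size
#' @return The approximate rank (a double).
#' @export
analytic_rank <- function(n_p, params = analytic_params()) {
  k8 <- as.numeric(params$k)^8
  ifelse(n_p > 2, k8 / n_p, 2 * k8)
}

#' Analytic phenotype robustness from frequency
#'
#' rho_p ~ (1/9) log_k(k^8 * n9 * f_p / 2), clamped at zero. On the
#' model's own classes this evaluates exactly to the allowed values
#' rho_p = 0 and (1 + 2n)/9 for n = 0..3 (i.e. u/9 with u the number of
#' unconstrained vector genes).
#'
#' @param f_p Phenotype frequency (or frequencies).
#' @inheritParams analytic_neutral_set_size
#' @return Robustness value(s) in \[0, 1\].
#' @export
analytic_robustness <- function(f_p, params = analytic_params()) {
  k <- as.numeric(params$k)
  val <- log(k^8 * params$n_g9 * f_p / 2, base = k) / 9
  pmax(val, 0)
}

#' Analytic genotype evolvability
#'
#' In the analytic model every non-neutral mutation reaches a distinct
#' phenotype, so evolvability and robustness trade off exactly:
#' e_g = 18 (1 - rho_g).
#'
#' @param rho_g Genotype robustness value(s).
#' @inheritParams analytic_neutral_set_size
#' @return Count(s) of distinct alternative phenotypes.
#' @export
analytic_genotype_evolvability <- function(rho_g, params = analytic_params()) {
  params$mutations_per_genotype * (1 - rho_g)
}

#' Analytic phenotype evolvability
#'
#' Piecewise in phenotype robustness:
#' 18 if rho_p = 0; 15 + k if rho_p = 1/9;
#' 18 (1 - rho_p) - 1 + k^2 if rho_p >= 2/9.
#' Branches are evaluated in this order, so rho_p = 0 never falls through
#' to the third form.
#'
#' @param rho_p Phenotype robustness value(s).
#' @inheritParams analytic_neutral_set_size
#' @return Count(s) of distinct alternative phenotypes.
#' @examples
#' analytic_phenotype_evolvability(1 / 3)  # 60 at k = 7
#' @export
analytic_phenotype_evolvability <- function(rho_p, params = analytic_params()) {
  k <- as.numeric(params$k)
  m <- as.numeric(params$mutations_per_genotype)
  out <- numeric(length(rho_p))
  eps <- 1e-12
  zero <- abs(rho_p) < eps
  ninth <- abs(rho_p - 1 / 9) < eps
  rest <- !zero & !ninth
  out[zero] <- m
  out[ninth] <- (m - 3) + k
  out[rest] <- m * (1 - rho_p[rest]) - 1 + k^2
  out
}

#' Analytic upper bound on neutral set size from description length
#'
#' The description length of an analytic phenotype is taken as 3 bits per
#' constrained site (K = 3 c). Fewer constrained sites mean exponentially
#' more genotypes, giving the simplicity-bias envelope
#' N_p <= 2 k^(9 - K/3), a monotone log-linear bound that every analytic
#' class attains with equality.
#'
#' @param k_tilde Description length(s) in bits.
#' @inheritParams analytic_neutral_set_size
#' @return Neutral-set-size bound(s).
#' @export
analytic_complexity_bound <- function(k_tilde, params = analytic_params()) {
  2 * as.numeric(params$k)^(9 - k_tilde / 3)
}

# negation-closed value set of size k used for orbit counting
analytic_value_set <- function(k) {
  if (k %% 2L == 1L) {
    h <- (k - 1L) %/% 2L
    seq.int(-h, h)
  } else {
    h <- k %/% 2L
    setdiff(seq.int(-h, h), 0L)
  }
}

# the involution identifying mirror-equivalent constrained assignments:
# negate the constrained x-genes (g1..g3); for g9 = 1 none is constrained
# and the identification is g4 <-> -g4 (the drawn line is the same image
# up to translation)
mirror_active_genes <- function(g9) {
  cs <- setdiff(constrained_sites(g9), 9L)
  act <- intersect(cs, 1:3)
  if (length(act) == 0L) act <- intersect(cs, 4L)
  act
}

#' Number of distinct analytic phenotype classes
#'
#' Counts, for every g9 value, the distinct assignments of values to the
#' constrained vector genes, identifying each assignment with its mirror
#' image (the identification behind the factor 2 in the neutral-set-size
#' formula). `method = "closed_form"` uses orbit counting
#' ((k^c + k^(c-m)) / 2 with m mirror-active genes, the fixed-point term
#' present only when 0 is an allowed value); `method = "enumerate"`
#' explicitly enumerates value tuples (tiny k only) and is the independent
#' check.
#'
#' @inheritParams analytic_neutral_set_size
#' @param method `"closed_form"` or `"enumerate"`.
#' @return Total phenotype-class count (a double).
#' @examples
#' analytic_phenotype_count()  # ~1.2e7 at defaults
#' @export
analytic_phenotype_count <- function(params = analytic_params(),
                                     method = c("closed_form", "enumerate")) {
  method <- match.arg(method)
  k <- as.numeric(params$k)
  has_zero <- params$k %% 2L == 1L
  total <- 0
  for (v in params$g9_min:params$g9_max) {
    cs <- setdiff(constrained_sites(v), 9L)
    cc <- length(cs)
    act <- mirror_active_genes(v)
    m <- length(act)
    if (method == "closed_form") {
      fixed <- if (has_zero) k^(cc - m) else 0
      total <- total + (k^cc + fixed) / 2
    } else {
      vals <- analytic_value_set(params$k)
      if (cc == 0L) { total <- total + 1; next }
      grid <- as.matrix(do.call(expand.grid, rep(list(vals), cc)))
      mir <- grid
      flip <- match(act, cs)
      mir[, flip] <- -mir[, flip]
      key <- apply(grid, 1L, paste, collapse = ",")
      mkey <- apply(mir, 1L, paste, collapse = ",")
      total <- total + length(unique(pmin(key, mkey)))
    }
  }
  total
}

#' Per-class analytic table
#'
#' One row per g9 value with the class's constrained sites, neutral set
#' size, frequency, robustness, evolvability, description length and rank.
#'
#' @inheritParams analytic_neutral_set_size
#' @return A tibble.
#' @export
analytic_class_table <- function(params = analytic_params()) {
  g9 <- params$g9_min:params$g9_max
  cs <- lapply(g9, constrained_sites)
  u <- vapply(g9, n_unconstrained_vector_genes, integer(1))
  n_p <- analytic_neutral_set_size(g9, params)
  f <- analytic_frequency(g9, params)
  rho <- u / 9
  tibble(
    g9 = g9,
    constrained = vapply(cs, function(x) paste(x, collapse = ","), ""),
    n_constrained = lengths(cs),
    n_unconstrained = u,
    n_p = n_p,
    f = f,
    rho = rho,
    evolvability = analytic_phenotype_evolvability(rho, params),
    k_tilde = 3 * lengths(cs),
    rank = analytic_rank(n_p, params)
  )
}

#' Analytic mutation-probability curve from a source class
#'
#' Within the analytic model, mutations from the neutral set of a class
#' with recursion depth `g9` partition into: neutral mutations at
#' unconstrained sites; mutations at constrained vector genes or to
#' `g9 - 1` (every genotype of the set reaches the same target, so
#' phi = 1/18 per target, and the target frequency is at least the source
#' frequency); and mutations to `g9 + 1`, which newly constrain `delta`
#' sites and scatter the set over k^delta targets, so phi = (1/18) k^-delta
#' with target frequency smaller by the same factor structure. The result
#' is linear (phi proportional to f_p) below the source frequency and a
#' plateau at 1/18 at or above it:
#' phi(f_p) = (1/18) min(1, f_p / f_q).
#'
#' @param g9 Recursion gene of the source class.
#' @inheritParams analytic_neutral_set_size
#' @return A tibble with columns `transition`, `target_g9`, `f_p`, `phi`,
#'   `n_targets`; source frequency attached as attribute `f_q`.
#' @export
analytic_phi_curve <- function(g9, params = analytic_params()) {
  stopifnot(g9 >= params$g9_min, g9 <= params$g9_max)
  m <- as.numeric(params$mutations_per_genotype)
  k <- as.numeric(params$k)
  f_q <- analytic_frequency(g9, params)
  cc <- function(v) length(constrained_sites(v)) - 1L
  rows <- list()
  n_con <- cc(g9)
  if (n_con > 0) {
    rows[[length(rows) + 1]] <- tibble(
      transition = "constrained_site", target_g9 = as.integer(g9),
      f_p = f_q, phi = 1 / m, n_targets = 2L * n_con)
  }
  if (g9 - 1 >= params$g9_min) {
    rows[[length(rows) + 1]] <- tibble(
      transition = "g9_down", target_g9 = g9 - 1L,
      f_p = analytic_frequency(g9 - 1, params), phi = 1 / m, n_targets = 1L)
  }
  if (g9 + 1 <= params$g9_max) {
    delta <- cc(g9 + 1) - cc(g9)
    rows[[length(rows) + 1]] <- tibble(
      transition = "g9_up", target_g9 = g9 + 1L,
      f_p = analytic_frequency(g9 + 1, params),
      phi = (1 / m) * k^(-delta), n_targets = as.integer(k^delta))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "f_q") <- f_q
  out
}

#' @rdname analytic_phi_curve
#' @param f_p Target phenotype frequency (vectorized).
#' @param f_q Source phenotype frequency.
#' @export
analytic_phi <- function(f_p, f_q, params = analytic_params()) {
  pmin(1, f_p / f_q) / params$mutations_per_genotype
}
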