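---
title: "The biomorph genotype-phenotype map: model, statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The biomorph genotype-phenotype map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomorphr)
```

## The developmental model

A biomorph genotype is nine integers $(g_1, \dots, g_9)$. The first eight
define eight 2D vectors

$$\vec v_1 = (-g_3, g_7),\; \vec v_2 = (-g_2, g_6),\; \vec v_3 = (-g_1, g_5),\;
\vec v_4 = (0, g_4),$$
$$\vec v_5 = (g_1, g_5),\; \vec v_6 = (g_2, g_6),\; \vec v_7 = (g_3, g_7),\;
\vec v_8 = (0, g_8),$$

so that $\vec v_{5..7}$ mirror $\vec v_{3..1}$ across the y-axis. Development
is a binary recursion: starting at the origin with vector index $i = 4$ and
$c = g_9$ stages remaining, each call draws a line of $c \cdot \vec v_i$ from
the current point and, while $c > 1$, recurses to indices $i - 1$ and $i + 1$
(index 0 wraps to 8 and 9 to 1) with $c - 1$. A genotype with recursion gene
$g_9$ therefore draws exactly $2^{g_9} - 1$ segments, and the figure is
mirror-symmetric about the y-axis by construction. Only vectors reachable
within $g_9$ stages are ever used: stage $s$ touches indices $4 \pm (s-1)$,
so $\vec v_8$ (reached only by wrap from index 1) first appears at stage
five.

All coordinates are exact integers from drawing through merging. Floating
point enters only at rasterization, and even there pixel-boundary incidence
is decided in integer arithmetic (next section). This avoids spurious
phenotype splits from rounding.

Mutation is a $\pm 1$ step at a single gene. Genes are restricted to finite
ranges — by default $g_{1..8} \in [-3, 3]$ ($k = 7$ values) and
$g_9 \in [1, 8]$, spanning $7^8 \times 8 = 46{,}118{,}408$ genotypes — and a
step that would leave the range simply does not exist (no clamping or
wrapping), so an interior genotype has 18 mutations and boundary genotypes
fewer.

## The discrete phenotype

Two figures count as the same phenotype when they look the same at limited
resolution. `phenotype_of()` composes:

1. **Merge** (`merge_coincident_segments()`): segments are grouped by their
   supporting line and unioned as 1D intervals, so strokes drawn multiple
   times contribute once; zero-length segments are dropped.
2. **Rasterize** (`rasterize()`): the full figure is centered on a
   $30 \times 30$ grid whose physical size is 5% larger than the figure's
   longer bounding-box dimension. Per pixel, the total clipped segment
   length (in pixel-side units) is rounded to the nearest $10^{-3}$; the
   pixel is set iff that length is at least 20% of the pixel side. A segment
   lying exactly on a pixel boundary contributes half its length to each
   side.
3. **Key**: the 900-bit grid is bit-packed row-major (row 1 = top of the
   figure) into a lowercase hex string; equal keys iff identical grids.

Design notes worth knowing:

* *Exact boundary tests.* With margin restricted to whole percents, the map
  from integer coordinates to grid units is rational with integer
  denominator, so "lies on a pixel boundary" is an exact integer test, and
  numerator/denominator are reduced by their gcd before any floating
  division. Consequently the raster is bit-identical under integer rescaling
  of all coordinates — the property the tests assert — rather than merely
  approximately stable.
* *The mirror axis.* The grid side is even and the figure is centered, so a
  zero-width figure (a pure vertical line) lies exactly on the boundary
  between the two middle columns and sets both of them via the
  half-contribution rule. Any single-column convention would break the
  raster's mirror symmetry.
* *Dots.* A genotype whose used vectors are all zero draws only zero-length
  segments. Its phenotype is defined as a single set pixel at the grid
  center, so paths "from a dot" are representable.
* *Half figures.* `half_figure()` clips a drawing at $x = 0$; because the
  stored grid covers the full symmetric figure, the half-figure is an
  optimization and a complexity input, not part of the phenotype pipeline.

Coarse-graining parameters (`raster_config()`): `grid_size` (30),
`margin_factor` (0.05), `fill_threshold` (0.20 of the pixel side),
`length_rounding` ($10^{-3}$). Changing resolution or threshold changes
phenotype counts but not the qualitative structure; all are exposed for
parameter scans.

## Exhaustive GP-map statistics

`build_gp_map()` enumerates a range in odometer order (gene 1 slowest,
gene 9 fastest — the order that defines each phenotype's deterministic
example genotype) and retains the per-genotype key vector, so every
downstream statistic reduces to index arithmetic:

* neutral set size $N_p$ and frequency $f_p = N_p / |G|$;
* rank $r(p) = |\{p' : N_{p'} \ge N_p\}|$ (ties share a rank);
* genotype robustness $\tilde\rho_g$ = fraction of *available* mutations
  that are neutral (boundary-aware denominator), phenotype robustness
  $\rho_p$ = mean over the neutral set;
* genotype/phenotype evolvability $\tilde\epsilon_g$, $\epsilon_p$ =
  distinct non-self phenotypes reachable by one mutation from the genotype /
  from anywhere in the neutral set;
* mutation probabilities $\phi_{pq}$ = mutation events from the neutral set
  of $q$ landing on $p$, over all events from the set. Because the $\phi$
  denominator matches the robustness denominator,
  $\rho_q + \sum_p \phi_{pq} = 1$ holds exactly and the tests assert it at
  machine precision.
* neutral components (`neutral_component()`): breadth-first closure under
  neutral mutations, usable with a prebuilt map or with phenotypes computed
  on demand (the full default range, where the component is tiny compared to
  genotype space).

The uncorrelated null model keeps neutral set sizes but randomizes genotype
assignments; it predicts $\rho_p = f_p$ and $\phi_{pq} = f_p$
(`null_model_expectations()`). The fixture analyses show the hallmark
deviations: $\rho_p \gg f_p$ with $\rho_p$ growing linearly in $\log f_p$,
a negative $\tilde\epsilon_g$–$\tilde\rho_g$ association, and a positive
$\epsilon_p$–$\rho_p$ association.

Ranges too large for memory are processed shard-wise (`gp_map_shard()`,
one $(g_1, g_9)$ prefix at a time — 56 shards of $7^7$ genotypes for the
default range — merged by `merge_gp_shards()`). The full-range enumeration
is a deliberate long-running opt-in; everything in the test suite runs at
fixture scale.

## The analytic constrained/unconstrained model

If development stops after $g_9$ stages, the genes feeding unused vectors
cannot affect the phenotype: they are *unconstrained*. The analytic model
assumes every other position is fully constrained. With $u(g_9)$
unconstrained vector genes ($u = 7, 5, 3, 1, 0$ for $g_9 = 1, 2, 3, 4,
\ge 5$), each unconstrained site multiplies the neutral set by $k$ and a
factor 2 comes from mirror identification:

$$N_p(g_9) \approx 2k^{\,9 - 2 g_9} \ (1 \le g_9 \le 4), \qquad
N_p \approx 2 \text{ otherwise},$$

with rank $r \approx k^8 / N_p$ for $N_p > 2$ and $2k^8$ at the floor —
five distinct $(N_p, r)$ points over the default $g_9$ range. Robustness
follows by counting neutral directions, $\rho_p = u/9$, equivalently
$\rho_p \approx \tfrac19 \log_k (k^8 \cdot 8 \cdot f_p / 2)$, taking only
the values $0$ and $(1 + 2n)/9$, $0 \le n \le 3$. Genotype evolvability
trades off exactly, $\tilde\epsilon_g = 18(1 - \rho_g)$, while phenotype
evolvability is piecewise
($18$; $15 + k$; $18(1-\rho_p) - 1 + k^2$ for $\rho_p = 0$; $1/9$;
$\ge 2/9$) — evaluated in that order so the $\rho_p = 0$ case never falls
through. With the description length $\tilde K = 3$ bits per constrained
site, $N_p \le 2k^{\,9 - \tilde K / 3}$ is the log-linear simplicity-bias
envelope, attained with equality by every class.

Two quantities needed re-derivation inside the model:

* **Phenotype count.** For each $g_9$, analytic phenotypes are assignments
  of values to the constrained vector genes, identified with their mirror
  image. The identification negates the constrained genes among
  $g_1..g_3$; for $g_9 = 1$ none is constrained and the pairing is
  $g_4 \leftrightarrow -g_4$ (the same drawn line up to translation).
  Counting orbits (Burnside: $(k^c + k^{c-m})/2$ with $m$ mirror-active
  genes, the fixed-point term present only when 0 is an allowed value)
  gives 11,984,963 $\approx 1.2 \times 10^7$ at defaults; an explicit
  enumeration over value tuples checks the closed form at toy $k$.
* **$\phi$ curve.** From a class with $c$ constrained vector genes, every
  mutation at a constrained site or to $g_9 - 1$ maps the whole neutral set
  onto one target, so $\phi = 1/18$, and those targets have $f_p \ge f_q$.
  A mutation to $g_9 + 1$ newly constrains $\Delta$ sites and scatters the
  set over $k^\Delta$ targets, each with $\phi = k^{-\Delta}/18$ and
  frequency smaller by the same factor. Hence
  $\phi(f_p) = \tfrac{1}{18}\min(1, f_p / f_q)$: linear below the source
  frequency, a plateau at and above it.

## Complexity estimators

Complexity is a phenotype property, computed from one example grid (all
genotypes of a neutral set render the identical grid). Because biomorphs are
axially symmetric, both grid-based estimators see the $x \ge 0$ half of the
grid (15 columns at default settings):

* **Block decomposition** (`bdm_complexity()`): cut the array into small
  blocks, sum block complexity plus $\log_2$ multiplicity over distinct
  blocks; the sliding-window boundary option (stride 1) keeps edge pixels in
  play. Published small-block algorithmic-probability tables come from
  Turing-machine enumerations that are not reproducible here, so the
  package's default table is **synthetic**: a coding-theorem-style
  enumeration of all 256 elementary cellular automaton rules on all 3-cell
  seeds, each run emitting a $3\times3$ block; block complexity is
  $-\log_2$ of the add-one-smoothed output frequency. It is deterministic
  and ordinal comparisons against it are meaningful; its absolute values are
  in bits of this machine class and are never compared to published CTM
  numbers. Any table keyed by row-major block bit strings can be supplied
  instead; a missing table is a configuration error, never a silent
  fallback.
* **Lempel–Ziv** (`lz_complexity()`): LZ76 phrase count of the row-major
  flattened half grid. The mirror-redundant half of the full grid adds
  phrase structure without information, which measurably distorts the
  complexity–frequency relationship at fixture scale, so the pipeline never
  feeds it the full grid.
* **Line count** (`line_count_complexity()`): segments after merging.

The headline relationship — the per-complexity-bin maximum of $N_p$ decays
with complexity — is checked with six equal-width bins at fixture scale so
each bin holds on the order of a hundred phenotypes; a max statistic over
sparser bins is dominated by sampling noise, and one bin of slack absorbs
estimator roughness.

## Evolutionary scenarios

`wright_fisher_step()` draws $N$ offspring with probability proportional to
parental fitness (fitness attaches to the phenotype via a
`fitness_landscape`), then mutates each of the nine sites of each offspring
independently with probability $\mu$ — at most one $\pm1$ step per site per
generation, and a boundary gene mutates inward with the full per-site
probability, keeping the rate exactly $\mu$ everywhere. Burn-in is fixed at
$10N$ generations.

*Scenario 1 (flat landscape).* All phenotypes equally fit; after burn-in the
run tallies how often each phenotype appears (individual-generations,
normalized). At the package's reduced scale ($N = 200$, $\mu = 0.1$/site,
$10^4$ measured generations on the 26,244-genotype fixture) appearance
frequency tracks $f_p$ with a strongly positive rank correlation — the
fixture-scale analogue of neutral arrival rates being set by phenotype
frequency.

*Scenario 2 (two peaks).* The population starts on a neutral component (NC)
of a source phenotype $p_0$; two phenotypes reachable from the NC get
fitnesses $1 + s_1$ (frequent, $p_1$) and $1 + s_2$ (rare, $p_2 $, with
$s_2 \ge s_1$), everything else is unviable. Each repetition runs to the
first fixation (population share above 0.70) and records whether $p_2$
appeared at all before it. The paper-scale parameters ($N = 500$,
$\mu = 10^{-4}$, so $9\mu N = 0.45$) sit in the strong-selection
weak-mutation regime. Two readings this package had to fix:

* "Evolve neutrally for $10N$ generations" before the measurement is
  implemented as burn-in on a landscape where only $p_0$ is viable. Under a
  genuinely flat landscape at these parameters the population would drift
  off $p_0$ entirely during burn-in, contradicting the stated initial
  condition of the measurement phase.
* The two adaptive phenotypes are figure-defined in the source material and
  not printed; `nc_phi_spectrum()` lists every phenotype reachable from the
  NC with its $\phi$, and `pick_two_peak_targets()` selects the most
  accessible one and a rare one at a requested accessibility ratio
  (default 0.02). Any two keys can be substituted.

Common random numbers: burn-in endpoints are computed once per repetition
and shared across the $(s_1, s_2)$ grid, and the measurement phase reseeds
per repetition, so cells are paired and the monotonicity of
$P(p_2 \text{ appears})$ in $s_1$ is checked without between-cell noise.
Runs that reach `max_generations` without fixation are reported in a
`no_fixation` column rather than silently dropped.

*Scenario 3 (paths).* `min_mutation_path()` realizes the Manhattan-distance
path (deterministic tie-break: gene 1 first), with
$(1/18)^{\text{steps}}$ as the interior-genotype idealization of one
specific path's probability. `min_phenotype_change_path()` minimizes
phenotype transitions with neutral mutations free — a Dijkstra search with
combined integer weights (one transition outweighs any number of
mutations), so among equal-transition paths the fewest-mutation one is
returned, with remaining ties broken by enumeration index. On the fixtures
there exist start/target pairs where this strictly beats the direct path's
transition count — the reason neutral exploration makes monotone fitness
paths easier to construct.

## What the fixtures do and do not show

The desk-scale profiles (`fixture_profile()`) shrink the gene ranges
(genes 1–8 in $[-1,1]$, $g_9 \le 3$ or 4), keeping every pipeline stage
identical while making exhaustive enumeration and brute-force
re-computation cheap: 26,244 genotypes map onto 784 phenotypes at default
coarse-graining. The fixture reproduces the full-scale map's *structure* —
multi-order-of-magnitude bias, log-linear robustness, the
evolvability correlations, the complexity envelope, arrival of the frequent
— but not its *scale*: fixture neutral sets span four orders of magnitude,
not six-plus, and fixture-scale correlations are noisier. Passing tests
certify the machinery and the qualitative phenomena, not the full-range
headline counts, which require the sharded multi-hour enumeration.

## Known limitations

* The raster phenotype depends on coarse-graining parameters by design;
  keys from different `raster_config()`s are incomparable.
* The synthetic block table is a stand-in for published CTM tables; only
  ordinal use is supported.
* `min_phenotype_change_path()` and map-level statistics need the
  in-memory key vector; shard-merged maps support only table-level
  statistics.
* The analytic model deliberately over-counts phenotype distinctions
  (every rescaling or line-multiplicity change is a "different" phenotype),
  so its absolute counts bracket, rather than match, the computational
  ones.
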