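#' Raster coarse-graining configuration
#'
#' Drawings are projected onto a `grid_size` x `grid_size` binary pixel grid
#' whose physical size is `(1 + margin_factor)` times the longer dimension
#' of the full figure, with the figure centered. Within each pixel the total
#' clipped segment length (in pixel-side units, rounded to the nearest
#' `length_rounding`) is compared against `fill_threshold` of the pixel side:
#' the pixel is 1 iff length >= threshold. Segments lying exactly on a pixel
#' boundary contribute half their length to the pixel on either side; this
#' incidence is decided by exact integer arithmetic, which is why
#' `margin_factor` must be a whole number of percent.
#'
#' @param grid_size Pixels per side (default 30).
#' @param margin_factor Fractional margin added to the longer dimension
#'   (default 0.05, i.e. the grid is 5% larger than the figure).
#' @param fill_threshold Fraction of the pixel side length required to set a
#'   pixel (default 0.20).
#' @param length_rounding Quantum to which per-pixel lengths are rounded
#'   before thresholding (default 1e-3).
#' @return An object of class `raster_config`.
#' @export
raster_config <- function(grid_size = 30L, margin_factor = 0.05,
                          fill_threshold = 0.20, length_rounding = 1e-3) {
  grid_size <- as.integer(grid_size)
  stopifnot(grid_size >= 1L, fill_threshold >= 0, fill_threshold <= 1,
            margin_factor >= 0, length_rounding > 0)
  margin_pct <- margin_factor * 100
  if (abs(margin_pct - round(margin_pct)) > 1e-9) {
    stop("margin_factor must be a whole number of percent ",
         "(exact pixel-boundary tests require a rational scale)",
         call. = FALSE)
  }
  structure(list(grid_size = grid_size, margin_factor = margin_factor,
                 margin_pct = as.integer(round(margin_pct)),
                 fill_threshold = fill_threshold,
                 length_rounding = length_rounding),
            class = "raster_config")
}

#' @export
print.raster_config <- function(x, ...) {
  cat("<raster_config> ", x$grid_size, "x", x$grid_size,
      " grid, margin ", x$margin_factor * 100, "%, fill threshold ",
      x$fill_threshold, ", length quantum ", x$length_rounding, "\n", sep = "")
  invisible(x)
}

#' Merge coincident and overlapping collinear segments
#'
#' If an identical piece of line is drawn more than once (e.g. as part of
#' two longer strokes), only one instance is kept: segments are grouped by
#' their supporting line and unioned as 1D intervals, so the covered point
#' set is unchanged while no two output segments overlap over positive
#' length. Zero-length segments (from zero vectors) cover no length and are
#' removed.
#'
#' @param drawing A drawing tibble (columns `x0`, `y0`, `x1`, `y1`).
#' @return A merged drawing tibble.
#' @export
merge_coincident_segments <- function(drawing) {
  m <- cpp_merge(drawing_matrix(drawing))
  new_drawing(as_tibble(m), genotype = attr(drawing, "genotype"))
}

#' Total drawn length of a drawing
#'
#' Sum of segment lengths; on a merged drawing this is the measure of the
#' covered point set.
#' @inheritParams merge_coincident_segments
#' @return A double.
#' @export
drawing_length <- function(drawing) {
  sum(sqrt((drawing$x1 - drawing$x0)^2 + (drawing$y1 - drawing$y0)^2))
}

#' Keep the x >= 0 half of a mirror-symmetric drawing
#'
#' Every biomorph is mirror-symmetric about the y-axis, so one half carries
#' all the information. Segments crossing the axis are clipped at x = 0
#' (clipped endpoints may be non-integer); segments lying on the axis are
#' retained once. Asymmetric input is a contract violation and errors.
#'
#' @inheritParams merge_coincident_segments
#' @return A drawing tibble (numeric coordinates) covering x >= 0.
#' @export
half_figure <- function(drawing) {
  d <- as.data.frame(drawing)[, c("x0", "y0", "x1", "y1")]
  if (!is_mirror_symmetric(d)) {
    stop("drawing is not mirror-symmetric about x = 0", call. = FALSE)
  }
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    s <- as.numeric(d[i, ])
    x0 <- s[1]; y0 <- s[2]; x1 <- s[3]; y1 <- s[4]
    if (x0 > x1 || (x0 == x1 && y0 > y1)) { # orient toward +x for clipping
      tmp <- c(x1, y1, x0, y0); x0 <- tmp[1]; y0 <- tmp[2]; x1 <- tmp[3]; y1 <- tmp[4]
    }
    if (x1 < 0) next                       # entirely in the x < 0 half
    if (x0 < 0) {                          # crosses the axis: clip
      t <- -x0 / (x1 - x0)
      y0 <- y0 + t * (y1 - y0)
      x0 <- 0
    }
    out[[i]] <- c(x0, y0, x1, y1)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- matrix(numeric(0), ncol = 4)
  colnames(out) <- c("x0", "y0", "x1", "y1")
  new_drawing(as_tibble(as.data.frame(out)), genotype = attr(drawing, "genotype"))
}

is_mirror_symmetric <- function(d) {
  canon <- function(x0, y0, x1, y1) {
    sw <- x0 > x1 | (x0 == x1 & y0 > y1)
    paste(ifelse(sw, x1, x0), ifelse(sw, y1, y0),
          ifelse(sw, x0, x1), ifelse(sw, y0, y1))
  }
  a <- sort(canon(d$x0, d$y0, d$x1, d$y1))
  b <- sort(canon(-d$x0, d$y0, -d$x1, d$y1))
  identical(a, b)
}

#' Rasterize a merged drawing to a binary phenotype grid
#'
#' Projects the full (merged) drawing onto the configured grid. The grid's
#' physical size is `(1 + margin_factor)` times the longer bounding-box
#' dimension of the figure, the figure is centered, per-pixel clipped
#' lengths are rounded to the configured quantum, and each pixel is set iff
#' its length reaches `fill_threshold` of the pixel side. A degenerate
#' zero-extent drawing ("dot") maps to a single set pixel at the grid
#' center; an empty drawing maps to the all-zero grid.
#'
#' Storage convention: row-major with row 1 at the top of the figure
#' (decreasing mathematical y), columns increasing with x. This convention
#' is fixed so phenotype keys are bit-stable.
#'
#' @param drawing A drawing tibble; pass it through
#'   [merge_coincident_segments()] first so duplicated strokes do not count
#'   twice.
#' @param config A [raster_config()].
#' @return An integer matrix of 0/1 with class `phenotype_grid`.
#' @export
rasterize <- function(drawing, config = raster_config()) {
  m <- cpp_rasterize(drawing_matrix(drawing), config$grid_size,
                     config$margin_pct, config$fill_threshold,
                     config$length_rounding)
  new_phenotype_grid(m, config)
}

new_phenotype_grid <- function(m, config) {
  structure(m, class = c("phenotype_grid", "matrix", "array"), config = config)
}

#' @export
print.phenotype_grid <- function(x, ...) {
  cat("<phenotype_grid> ", nrow(x), "x", ncol(x), ", ",
      sum(x), " set pixels\n", sep = "")
  chars <- ifelse(unclass(x) == 1L, "#", ".")
  apply(chars, 1L, function(r) cat(paste(r, collapse = ""), "\n"))
  invisible(x)
}

#' Per-pixel clipped lengths (diagnostic)
#'
#' The raw per-pixel total segment lengths (pixel-side units, before
#' rounding and thresholding) that [rasterize()] thresholds.
#' @inheritParams rasterize
#' @return A numeric `grid_size` x `grid_size` matrix.
#' @export
raster_lengths <- function(drawing, config = raster_config()) {
  cpp_raster_lengths(drawing_matrix(drawing), config$grid_size,
                     config$margin_pct)
}

#' Phenotype of a genotype
#'
#' The deterministic composition draw -> merge -> rasterize -> key. Two
#' genotypes share a phenotype iff their keys are equal.
#'
#' @inheritParams validate_genotype
#' @param config A [raster_config()].
#' @return `phenotype_of()` returns the phenotype key (lowercase hex digest
#'   of the bit-packed row-major grid; equal keys iff identical grids).
#'   `phenotype_grid_of()` returns the grid itself.
#' @examples
#' phenotype_of(c(0, 0, 0, 1, 1, 0, 0, 0, 2))
#' @export
phenotype_of <- function(genotype, config = raster_config()) {
  g <- as_genotype(genotype)
  cpp_phenotype_key(g, config$grid_size, config$margin_pct,
                    config$fill_threshold, config$length_rounding)
}

#' @rdname phenotype_of
#' @export
phenotype_grid_of <- function(genotype, config = raster_config()) {
  g <- as_genotype(genotype)
  d0 <- draw_biomorph(g)
  d <- merge_coincident_segments(d0)
  if (nrow(d) == 0L && nrow(d0) > 0L) d <- d0  # all-zero vectors: a dot
  rasterize(d, config)
}

#' Phenotype keys for many genotypes
#'
#' Vectorized over the rows of a genotype table; the workhorse behind
#' exhaustive enumeration.
#'
#' @param genotypes Data frame with columns `g1`..`g9`.
#' @inheritParams phenotype_of
#' @return Character vector of phenotype keys, one per row.
#' @export
phenotype_keys <- function(genotypes, config = raster_config()) {
  m <- as.matrix(as.data.frame(genotypes)[, paste0("g", 1:9)])
  storage.mode(m) <- "integer"
  cpp_phenotype_keys(m, config$grid_size, config$margin_pct,
                     config$fill_threshold, config$length_rounding)
}

#' Convert between phenotype grids and keys
#'
#' @param grid A `phenotype_grid` (or plain 0/1 matrix).
#' @param key A phenotype key string.
#' @param config A [raster_config()] (supplies the grid size for decoding).
#' @return `phenotype_key()` returns the hex key; `key_to_grid()` the grid.
#' @export
phenotype_key <- function(grid) {
  m <- unclass(grid)
  storage.mode(m) <- "integer"
  cpp_grid_key(m)
}

#' @rdname phenotype_key
#' @export
key_to_grid <- function(key, config = raster_config()) {
  new_phenotype_grid(cpp_key_to_grid(key, config$grid_size), config)
}

# --- I/O -------------------------------------------------------------------

#' Write a phenotype grid to disk
#'
#' `write_grid_text()` writes rows of 0/1 characters; `write_grid_pbm()`
#' writes portable-bitmap (P1) readable by standard image tools;
#' `write_grid_png()` requires the `png` package.
#'
#' @param grid A `phenotype_grid`.
#' @param path File path.
#' @param config A [raster_config()] attached to grids read back in.
#' @export
write_grid_text <- function(grid, path) {
  writeLines(apply(unclass(grid), 1L, paste, collapse = ""), path)
  invisible(path)
}

#' @rdname write_grid_text
#' @export
read_grid_text <- function(path, config = raster_config()) {
  lines <- readLines(path)
  m <- do.call(rbind, lapply(lines, function(l) {
    as.integer(strsplit(l, "")[[1L]])
  }))
  new_phenotype_grid(m, config)
}

#' @rdname write_grid_text
#' @export
write_grid_pbm <- function(grid, path) {
  m <- unclass(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(m), nrow(m))), con)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_grid_text
#' @export
write_grid_png <- function(grid, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(1 - unclass(grid), path)  # set pixels drawn black
  invisible(path)
}

#' Export a drawing as CSV of segments
#'
#' @inheritParams merge_coincident_segments
#' @param path Output file path.
#' @export
write_drawing_csv <- function(drawing, path) {
  write.csv(as.data.frame(drawing)[, c("x0", "y0", "x1", "y1")], path,
            row.names = FALSE)
  invisible(path)
}
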