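#' Region specifications for the tissue simulator
#'
#' A region couples a geometry (background rectangle, disk, annulus, or
#' axis-aligned band), a homogeneous cell density, and a Dirichlet
#' concentration vector over the type vocabulary from which the region's
#' realized cell-type mixture is drawn.  Regions are applied in list order and
#' later regions override earlier ones where they overlap, so a cell sitting
#' inside both the tumor nodule and the BST core carries the core's label.
#'
#' @param name region name (becomes the ground-truth label).
#' @param geometry one of [geom_background()], [geom_disk()],
#'   [geom_annulus()], [geom_band()].
#' @param density expected cells per square pixel (> 0).
#' @param concentration Dirichlet concentration vector, one entry per
#'   vocabulary type (all > 0); large values for a type make the region's
#'   realized mixture concentrate on it.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, geometry, density, concentration) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(geometry, "region_geometry")) stop("geometry must be a region geometry")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (any(concentration <= 0)) stop("Dirichlet concentrations must be > 0")
  structure(list(name = name, geometry = geometry, density = density,
                 concentration = as.numeric(concentration)),
            class = "region_spec")
}

#' Region geometries
#'
#' Primitive shapes on the image canvas (pixels; origin top-left, y downward).
#' `geom_background()` covers the whole canvas; `geom_band()` is the
#' axis-aligned slab `lo <= coord < hi` along `"x"` or `"y"`.
#'
#' @param cx,cy,r,r_inner,r_outer disk/annulus center and radii in pixels.
#' @param axis `"x"` or `"y"`; `lo`,`hi` band limits in pixels.
#' @return A `region_geometry` object.
#' @name region_geometry
NULL

#' @rdname region_geometry
#' @export
geom_background <- function() structure(list(kind = "background"), class = "region_geometry")

#' @rdname region_geometry
#' @export
geom_disk <- function(cx, cy, r) {
  stopifnot(r > 0)
  structure(list(kind = "disk", cx = cx, cy = cy, r = r), class = "region_geometry")
}

#' @rdname region_geometry
#' @export
geom_annulus <- function(cx, cy, r_inner, r_outer) {
  stopifnot(r_outer > r_inner, r_inner >= 0)
  structure(list(kind = "annulus", cx = cx, cy = cy,
                 r_inner = r_inner, r_outer = r_outer), class = "region_geometry")
}

#' @rdname region_geometry
#' @export
geom_band <- function(axis = c("y", "x"), lo, hi) {
  axis <- match.arg(axis)
  stopifnot(hi > lo)
  structure(list(kind = "band", axis = axis, lo = lo, hi = hi),
            class = "region_geometry")
}

# area of a geometry clipped to the canvas; disks/annuli/bands in the presets
# lie inside the canvas, so only bands are clipped explicitly
.geom_area <- function(g, canvas) {
  switch(g$kind,
    background = canvas[1L] * canvas[2L],
    disk = pi * g$r^2,
    annulus = pi * (g$r_outer^2 - g$r_inner^2),
    band = if (g$axis == "y") {
      (min(g$hi, canvas[2L]) - max(g$lo, 0)) * canvas[1L]
    } else {
      (min(g$hi, canvas[1L]) - max(g$lo, 0)) * canvas[2L]
    })
}

.geom_contains <- function(g, x, y) {
  switch(g$kind,
    background = rep(TRUE, length(x)),
    disk = (x - g$cx)^2 + (y - g$cy)^2 <= g$r^2,
    annulus = {
      d2 <- (x - g$cx)^2 + (y - g$cy)^2
      d2 <= g$r_outer^2 & d2 > g$r_inner^2
    },
    band = if (g$axis == "y") y >= g$lo & y < g$hi else x >= g$lo & x < g$hi)
}

# uniform points inside a geometry (rejection from bounding box for disks)
.geom_sample <- function(g, n, canvas) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  switch(g$kind,
    background = cbind(x = runif(n, 0, canvas[1L]), y = runif(n, 0, canvas[2L])),
    band = if (g$axis == "y") {
      cbind(x = runif(n, 0, canvas[1L]),
            y = runif(n, max(g$lo, 0), min(g$hi, canvas[2L])))
    } else {
      cbind(x = runif(n, max(g$lo, 0), min(g$hi, canvas[1L])),
            y = runif(n, 0, canvas[2L]))
    },
    disk = ,
    annulus = {
      r_out <- if (g$kind == "disk") g$r else g$r_outer
      pts <- matrix(numeric(0), 0L, 2L)
      while (nrow(pts) < n) {
        m <- max(2L * (n - nrow(pts)), 16L)
        cand <- cbind(runif(m, g$cx - r_out, g$cx + r_out),
                      runif(m, g$cy - r_out, g$cy + r_out))
        keep <- .geom_contains(g, cand[, 1L], cand[, 2L])
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      colnames(pts) <- c("x", "y")
      pts[seq_len(n), , drop = FALSE]
    })
}

# label each point with the last region whose geometry contains it
.region_of <- function(regions, x, y) {
  lab <- rep(1L, length(x))
  if (length(regions) > 1L)
    for (i in 2L:length(regions)) {
      inside <- .geom_contains(regions[[i]]$geometry, x, y)
      lab[inside] <- i
    }
  lab
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic tissue with planted niches
#'
#' Cells are placed by a homogeneous Poisson process per region (a region's
#' realized count is Poisson with mean density x geometry area); points of an
#' earlier region that fall inside a later region are discarded, so overlaps
#' carry the later region's density and mixture.  Each region draws one
#' mixture from its Dirichlet concentration and cells sample their type
#' i.i.d. from it.  Fully reproducible given `seed`.
#'
#' @param regions non-empty list of [region_spec()]; the first must be a
#'   background region covering the canvas.
#' @param canvas numeric `c(width, height)` in pixels.
#' @param vocabulary the `type_vocabulary` the concentration vectors index.
#' @param seed integer RNG seed.
#' @param sample_id sample identifier stamped on every cell.
#' @return A list with `cells` (a [cell_table()]), and `truth`: a list with
#'   `region` (per-cell region name) and `mixtures` (region x type matrix of
#'   realized mixture proportions).
#' @export
generate_tissue <- function(regions, canvas = c(2000, 2000),
                            vocabulary = default_type_vocabulary(),
                            seed = 1L, sample_id = "synthetic") {
  if (length(regions) == 0L) stop("regions must be non-empty")
  if (regions[[1L]]$geometry$kind != "background")
    stop("first region must be a background covering the canvas")
  if (any(canvas <= 0)) stop("empty canvas")
  n_types <- length(vocabulary$types)
  for (r in regions)
    if (length(r$concentration) != n_types)
      stop("region \"", r$name, "\": concentration length ",
           length(r$concentration), " != vocabulary size ", n_types)

  set.seed(seed)
  mixtures <- t(vapply(regions, function(r) .rdirichlet1(r$concentration),
                       numeric(n_types)))
  dimnames(mixtures) <- list(vapply(regions, `[[`, "", "name"), vocabulary$types)

  xs <- ys <- numeric(0)
  gen <- integer(0)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    n_i <- rpois(1L, r$density * .geom_area(r$geometry, canvas))
    pts <- .geom_sample(r$geometry, n_i, canvas)
    xs <- c(xs, pts[, 1L]); ys <- c(ys, pts[, 2L])
    gen <- c(gen, rep(i, n_i))
  }
  if (length(xs) == 0L) stop("zero cells generated: densities too low")
  owner <- .region_of(regions, xs, ys)
  keep <- owner == gen       # later regions override earlier ones
  xs <- xs[keep]; ys <- ys[keep]; owner <- owner[keep]

  types <- character(length(xs))
  for (i in seq_along(regions)) {
    sel <- owner == i
    if (any(sel))
      types[sel] <- sample(vocabulary$types, sum(sel), replace = TRUE,
                           prob = mixtures[i, ])
  }
  ord <- order(ys, xs)       # stable spatial order, independent of region list
  xs <- xs[ord]; ys <- ys[ord]; owner <- owner[ord]; types <- types[ord]
  cells <- cell_table(sample_id = rep(sample_id, length(xs)),
                      cell_id = sprintf("c%06d", seq_along(xs)),
                      x_px = xs, y_px = ys, cell_type = types,
                      vocabulary = vocabulary)
  list(cells = cells,
       truth = list(region = rownames(mixtures)[owner], mixtures = mixtures))
}

#' The five-region basal-cell-carcinoma preset
#'
#' The canvas (2000 x 2000 px at ~0.005 cells/px^2, about 20,000 cells)
#' plants the architecture the pipeline is designed to detect: background
#' stroma; a large tumor nodule; a stroma-deplete BST-like core inside the
#' nodule; a myeloid-rich strip along the top edge; and a BIT-like tumor band
#' directly abutting the strip.  By construction every BIT-band cell is
#' closer to the myeloid strip than any BST-core cell.  Concentrations are
#' strongly peaked so regions have well-separated compositions.
#'
#' @param vocabulary a `type_vocabulary`; the default 17-type vocabulary.
#' @param density background cell density in cells per square pixel.
#' @return A list of five [region_spec()] objects, in override order.
#' @export
bcc_preset_regions <- function(vocabulary = default_type_vocabulary(),
                               density = 0.005) {
  tv <- vocabulary$types
  conc <- function(..., rest = 0.05) {
    a <- setNames(rep(rest, length(tv)), tv)
    w <- c(...)
    a[names(w)] <- w
    a
  }
  # rest = 0.01 inside the tumor nests: solid tumor nests and the
  # stroma-deplete BST core essentially exclude unlisted populations, so the
  # planted geometry (not stray type draws) determines myeloid distances
  list(
    region_spec("stroma", geom_background(), density,
                conc("Fibroblast" = 40, "T cell" = 12, "Endothelium" = 12,
                     "Myofibroblast" = 8, "B cell" = 4, "Unknown" = 2)),
    region_spec("tumor", geom_disk(1000, 1250, 600), density,
                conc("Tumor" = 55, "TREM2 myeloid" = 8, "Fibroblast" = 6,
                     "Endothelium" = 4, "T cell" = 3, rest = 0.01)),
    region_spec("bst_core", geom_disk(1000, 1350, 300), density,
                conc("BST tumor" = 70, "Tumor" = 6, "Unknown" = 2,
                     rest = 0.01)),
    region_spec("myeloid_strip", geom_band("y", 0, 250), density,
                conc("Macrophage" = 28, "Neutrophil" = 18, "TREM1 myeloid" = 22,
                     "Dendritic cell" = 6, "T cell" = 3)),
    region_spec("bit_band", geom_band("y", 250, 500), density,
                conc("BIT tumor" = 50, "TREM1 myeloid" = 10, "Macrophage" = 7,
                     "Neutrophil" = 5, "Fibroblast" = 2))
  )
}

#' Generate a spatially unstructured null tissue
#'
#' Cells at uniform random positions with i.i.d. type draws: the calibration
#' fixture on which every community enrichment score should be ~1.
#'
#' @param n_cells number of cells.
#' @param type_frequencies named numeric vector summing to 1 over (a subset
#'   of) the vocabulary types.
#' @param canvas `c(width, height)` in pixels.
#' @param vocabulary a `type_vocabulary`; defaults to one built from the
#'   frequency names.
#' @param seed integer RNG seed.
#' @param sample_id sample identifier.
#' @return A `cell_table` (empty when `n_cells = 0`).
#' @export
generate_null_tissue <- function(n_cells, type_frequencies,
                                 canvas = c(2000, 2000), vocabulary = NULL,
                                 seed = 1L, sample_id = "null") {
  if (abs(sum(type_frequencies) - 1) > 1e-8)
    stop("type frequencies must sum to 1")
  if (is.null(vocabulary)) vocabulary <- type_vocabulary(names(type_frequencies))
  set.seed(seed)
  n_cells <- as.integer(n_cells)
  types <- if (n_cells > 0L)
    sample(names(type_frequencies), n_cells, replace = TRUE,
           prob = type_frequencies) else character(0)
  cell_table(sample_id = rep(sample_id, n_cells),
             cell_id = if (n_cells) sprintf("c%06d", seq_len(n_cells)) else character(0),
             x_px = runif(n_cells, 0, canvas[1L]),
             y_px = runif(n_cells, 0, canvas[2L]),
             cell_type = types, vocabulary = vocabulary)
}

#' Spot-generation specification
#'
#' @param pitch grid pitch in micrometers (default 100, the Visium spot
#'   spacing convention).
#' @param diameter spot diameter in micrometers (default 55); must not exceed
#'   `pitch`.
#' @param n_genes total gene count.
#' @param signature character vector of signature gene names (must be a
#'   subset of the generated gene names `g0001..`, or supplied names).
#' @param n_signature number of signature genes when `signature` is `NULL`
#'   (default 16, mirroring a 16-gene myeloid signature).
#' @param baseline_mean,dispersion negative-binomial mean and dispersion
#'   (variance = mu + dispersion * mu^2) shared by all genes outside the
#'   uplifted region.
#' @param delta log-fold uplift applied to signature-gene means inside the
#'   designated region (signature mean becomes `baseline_mean * exp(delta)`).
#' @param uplift_region name of the region receiving the uplift.
#' @return An object of class `spot_gen_spec`.
#' @export
spot_gen_spec <- function(pitch = 100, diameter = 55, n_genes = 200,
                          signature = NULL, n_signature = 16,
                          baseline_mean = 5, dispersion = 0.5,
                          delta = 2, uplift_region = "bit_band") {
  if (pitch < diameter) stop("pitch must be >= spot diameter")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(signature)) signature <- genes[seq_len(n_signature)]
  if (!all(signature %in% genes)) stop("signature must be a subset of the gene set")
  if (!is.finite(delta)) stop("delta must be finite")
  structure(list(pitch = pitch, diameter = diameter, genes = genes,
                 signature = signature, baseline_mean = baseline_mean,
                 dispersion = dispersion, delta = delta,
                 uplift_region = uplift_region),
            class = "spot_gen_spec")
}

#' Generate a synthetic spot matrix on a regular grid
#'
#' Spots sit on a regular grid at the requested pitch; each spot's cluster
#' label is the region of its center under the same override rule as
#' [generate_tissue()].  Counts are negative-binomial with a shared
#' dispersion; signature genes have their mean multiplied by `exp(delta)`
#' inside the uplift region.
#'
#' @param spec a [spot_gen_spec()].
#' @param regions list of [region_spec()] defining the region map (geometry
#'   and names only; densities/concentrations are ignored here).
#' @param canvas `c(width, height)` in pixels.
#' @param px_per_um pixel-to-micrometer calibration used to lay the
#'   micrometer-pitch grid on the pixel canvas (default 2.65).
#' @param seed integer RNG seed.
#' @param n_rows,n_cols optional explicit grid shape; by default the grid
#'   fills the canvas.
#' @return A `spot_matrix` whose `cluster` field holds the region labels.
#' @export
generate_spots <- function(spec, regions, canvas = c(2000, 2000),
                           px_per_um = 2.65, seed = 1L,
                           n_rows = NULL, n_cols = NULL) {
  stopifnot(inherits(spec, "spot_gen_spec"))
  set.seed(seed)
  pitch_px <- spec$pitch * px_per_um
  if (is.null(n_cols)) n_cols <- max(1L, floor(canvas[1L] / pitch_px))
  if (is.null(n_rows)) n_rows <- max(1L, floor(canvas[2L] / pitch_px))
  gx <- (seq_len(n_cols) - 0.5) * pitch_px
  gy <- (seq_len(n_rows) - 0.5) * pitch_px
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  n_spots <- nrow(grid)
  region_idx <- .region_of(regions, grid$x, grid$y)
  region_names <- vapply(regions, `[[`, "", "name")
  labels <- region_names[region_idx]

  n_genes <- length(spec$genes)
  is_sig <- spec$genes %in% spec$signature
  uplifted <- labels == spec$uplift_region
  mu <- matrix(spec$baseline_mean, n_spots, n_genes)
  mu[uplifted, is_sig] <- spec$baseline_mean * exp(spec$delta)
  size <- 1 / spec$dispersion
  counts <- matrix(rnbinom(n_spots * n_genes, mu = mu, size = size),
                   n_spots, n_genes)
  dimnames(counts) <- list(sprintf("spot%04d", seq_len(n_spots)), spec$genes)
  spot_matrix(counts, x_px = grid$x, y_px = grid$y, cluster = labels)
}
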