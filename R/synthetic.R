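#' @importFrom stats rnorm runif dist
NULL

#' Anticlinal and periclinal wall type vocabularies
#'
#' The seven anticlinal undulation types and five periclinal sculpture types
#' used to label testa surface patterns. Anticlinal walls are the boundaries
#' between neighbouring testa cells; their undulation ranges from straight
#' through S- and U-shaped waves to strongly re-entrant omega lobes, plus two
#' irregular forms. Periclinal walls are the outward-facing cell surfaces,
#' sculptured with granules or verrucae (wart-like protuberances) of varying
#' size and placement.
#'
#' @format Character vectors of the valid enum levels.
#' @export
ANTICLINAL_TYPES <- c("irregular_curved", "irregular_to_straight", "straight",
                      "S", "U", "U_to_omega", "omega")

#' @rdname ANTICLINAL_TYPES
#' @export
PERICLINAL_TYPES <- c("granule", "small_verrucae", "large_verrucae",
                      "marginal_verrucae", "verrucate_verrucae")

#' Construct a wall-class label
#'
#' @param anticlinal One of [ANTICLINAL_TYPES].
#' @param periclinal One of [PERICLINAL_TYPES].
#' @return A `wall_class` object (list with `anticlinal`, `periclinal`).
#' @export
wall_class <- function(anticlinal, periclinal) {
  if (!is.character(anticlinal) || length(anticlinal) != 1L ||
      !(anticlinal %in% ANTICLINAL_TYPES))
    stop("`anticlinal` must be one of: ",
         paste(ANTICLINAL_TYPES, collapse = ", "), call. = FALSE)
  if (!is.character(periclinal) || length(periclinal) != 1L ||
      !(periclinal %in% PERICLINAL_TYPES))
    stop("`periclinal` must be one of: ",
         paste(PERICLINAL_TYPES, collapse = ", "), call. = FALSE)
  structure(list(anticlinal = anticlinal, periclinal = periclinal),
            class = "wall_class")
}

#' Texture-generation parameters
#'
#' Controls the geometry of the synthetic testa patch: cell tessellation
#' density, wall undulation, periclinal bump placement, and the SEM-like
#' degradation (blur then additive noise).
#'
#' @param cell_count Number of Voronoi seed cells in the 250x250 patch.
#' @param undulation_amplitude Peak wall displacement, pixels. Must stay below
#'   half the mean cell spacing so neighbouring walls cannot cross.
#' @param undulation_frequency Undulation cycles per wall edge.
#' @param lobe_reentrance In `[0, 1]`; 0 gives open U-like waves, values
#'   >= 0.6 fold the wave into re-entrant omega-like lobes.
#' @param verruca_count Number of periclinal bumps to place.
#' @param verruca_radius Bump radius, pixels.
#' @param verruca_placement `"uniform"`, `"marginal"` (beside walls) or
#'   `"dense"` (tighter packing).
#' @param noise_sd Additive Gaussian noise SD, gray-level units.
#' @param blur_sigma Gaussian blur SD, pixels.
#' @param seed Integer RNG seed; generation is deterministic given it.
#' @return A validated `texture_params` list.
#' @export
texture_params <- function(cell_count = 12L, undulation_amplitude = 0,
                           undulation_frequency = 0, lobe_reentrance = 0,
                           verruca_count = 0L, verruca_radius = 3,
                           verruca_placement = "uniform",
                           noise_sd = 0.03, blur_sigma = 1, seed = 1L) {
  .check_scalar(cell_count, "cell_count", 1)
  .check_scalar(undulation_amplitude, "undulation_amplitude", 0)
  .check_scalar(undulation_frequency, "undulation_frequency", 0)
  .check_scalar(lobe_reentrance, "lobe_reentrance", 0, 1)
  .check_scalar(verruca_count, "verruca_count", 0)
  .check_scalar(verruca_radius, "verruca_radius", 0)
  .check_scalar(noise_sd, "noise_sd", 0)
  .check_scalar(blur_sigma, "blur_sigma", 0)
  .check_scalar(seed, "seed")
  if (!verruca_placement %in% c("uniform", "marginal", "dense"))
    stop("`verruca_placement` must be uniform, marginal or dense",
         call. = FALSE)
  spacing <- 250 / sqrt(cell_count)
  if (undulation_amplitude >= spacing / 2)
    stop("undulation_amplitude must be below half the cell spacing (",
         round(spacing / 2, 1), " px for cell_count ", cell_count, ")",
         call. = FALSE)
  structure(list(cell_count = as.integer(cell_count),
                 undulation_amplitude = undulation_amplitude,
                 undulation_frequency = undulation_frequency,
                 lobe_reentrance = lobe_reentrance,
                 verruca_count = as.integer(verruca_count),
                 verruca_radius = verruca_radius,
                 verruca_placement = verruca_placement,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "texture_params")
}

# per-class default geometry; tests pin this table, so changes are versioned
.anticlinal_defaults <- list(
  straight              = list(undulation_amplitude = 0,  undulation_frequency = 0,   lobe_reentrance = 0,   jitter = FALSE),
  irregular_to_straight = list(undulation_amplitude = 3,  undulation_frequency = 1,   lobe_reentrance = 0,   jitter = TRUE),
  irregular_curved      = list(undulation_amplitude = 6,  undulation_frequency = 1.5, lobe_reentrance = 0,   jitter = TRUE),
  S                     = list(undulation_amplitude = 6,  undulation_frequency = 1,   lobe_reentrance = 0,   jitter = FALSE),
  U                     = list(undulation_amplitude = 10, undulation_frequency = 2,   lobe_reentrance = 0,   jitter = FALSE),
  U_to_omega            = list(undulation_amplitude = 12, undulation_frequency = 2,   lobe_reentrance = 0.6, jitter = FALSE),
  omega                 = list(undulation_amplitude = 14, undulation_frequency = 2,   lobe_reentrance = 0.9, jitter = FALSE)
)

.periclinal_defaults <- list(
  granule            = list(verruca_count = 80L, verruca_radius = 2, verruca_placement = "uniform"),
  small_verrucae     = list(verruca_count = 50L, verruca_radius = 3, verruca_placement = "uniform"),
  large_verrucae     = list(verruca_count = 12L, verruca_radius = 8, verruca_placement = "uniform"),
  marginal_verrucae  = list(verruca_count = 40L, verruca_radius = 3, verruca_placement = "marginal"),
  verrucate_verrucae = list(verruca_count = 30L, verruca_radius = 5, verruca_placement = "dense")
)

#' Default texture parameters for a wall class
#'
#' Looks up the versioned per-class parameter table (wall undulation geometry
#' from the anticlinal type, bump layout from the periclinal type) and returns
#' a full [texture_params] object. `...` overrides individual fields.
#'
#' @param class A [wall_class].
#' @param ... Overrides passed to [texture_params] (e.g. `seed`, `cell_count`).
#' @return A `texture_params` object.
#' @export
default_texture_params <- function(class, ...) {
  stopifnot(inherits(class, "wall_class"))
  a <- .anticlinal_defaults[[class$anticlinal]]
  p <- .periclinal_defaults[[class$periclinal]]
  base <- c(a[setdiff(names(a), "jitter")], p)
  over <- list(...)
  args <- utils::modifyList(base, over)
  tp <- do.call(texture_params, args)
  attr(tp, "jitter") <- a$jitter
  tp
}

#' Arc-length to chord-length ratio of a polyline
#'
#' A tortuosity of 1 means a straight wall; undulating anticlinal walls score
#' higher. Used to validate that generated walls reflect their class.
#'
#' @param polyline Numeric matrix with columns x, y; ordered points (>= 2).
#' @return Tortuosity ratio >= 1.
#' @export
boundary_tortuosity <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 points", call. = FALSE)
  d <- diff(polyline)
  arc <- sum(sqrt(rowSums(d^2)))
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1L, ])^2))
  if (chord < 1e-9) stop("coincident endpoints: chord undefined", call. = FALSE)
  max(arc / chord, 1)
}

# --- internal geometry -------------------------------------------------------

# dart-throwing Poisson-disk sample of n points in [lo, hi]^2
.poisson_disk <- function(n, lo, hi, min_dist, max_tries = 60L * n) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries) {
    cand <- runif(2, lo, hi)
    if (nrow(pts) == 0L ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_dist^2)
      pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  while (nrow(pts) < n)   # degenerate fallback: fill unconstrained
    pts <- rbind(pts, runif(2, lo, hi))
  dimnames(pts) <- NULL
  pts
}

# brute-force Delaunay triangulation (point counts here are small); returns
# list(triangles = m x 3 index matrix, centers = m x 2 circumcenters)
.delaunay <- function(pts) {
  m <- nrow(pts)
  tri <- t(utils::combn(m, 3L))
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-9
  tri <- tri[ok, , drop = FALSE]
  ax <- ax[ok]; ay <- ay[ok]; bx <- bx[ok]; by <- by[ok]
  cx <- cx[ok]; cy <- cy[ok]; d <- d[ok]
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # a triangle is Delaunay iff no point lies strictly inside its circumcircle
  # (its own vertices sit on the circle and are excluded by the tolerance)
  dx2 <- outer(ux, pts[, 1], "-")^2 + outer(uy, pts[, 2], "-")^2
  keep <- rowSums(dx2 < r2 - 1e-7) == 0L
  list(triangles = tri[keep, , drop = FALSE],
       centers = cbind(ux, uy)[keep, , drop = FALSE])
}

# Voronoi edges between the first n_orig points: for each Delaunay edge shared
# by two triangles, the segment joining their circumcenters
.voronoi_edges <- function(pts, n_orig) {
  dt <- .delaunay(pts)
  tri <- dt$triangles
  if (nrow(tri) == 0L) return(list())
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
  tri_id <- rep(seq_len(nrow(tri)), 3L)
  keys <- pair_key(edges[, 1], edges[, 2])
  out <- list()
  for (k in unique(keys[edges[, 1] <= n_orig & edges[, 2] <= n_orig])) {
    ids <- tri_id[keys == k]
    if (length(ids) != 2L) next
    ij <- as.integer(strsplit(k, " ")[[1]])
    out[[length(out) + 1L]] <- list(
      cells = ij,
      v1 = dt$centers[ids[1], ], v2 = dt$centers[ids[2], ])
  }
  out
}

# displaced polyline for one wall edge
.wall_polyline <- function(v1, v2, amp, freq, reent, jitter) {
  L <- sqrt(sum((v2 - v1)^2))
  if (L < 2) return(rbind(v1, v2))
  if (jitter) {
    amp <- amp * runif(1, 0.3, 1.3)
    freq <- max(freq * runif(1, 0.5, 1.5), 0.25)
  }
  amp <- min(amp, 0.35 * L)
  npts <- max(16L, ceiling(4 * L))
  s <- seq(0, 1, length.out = npts)
  tg <- (v2 - v1) / L
  nrm <- c(-tg[2], tg[1])
  phase <- runif(1, 0, 2 * pi)
  w <- sin(pi * s)
  dN <- amp * sin(2 * pi * freq * s + phase) * w
  dT <- reent * amp * 0.8 * cos(2 * pi * freq * s + phase) * w
  base <- cbind(v1[1] + s * (v2[1] - v1[1]), v1[2] + s * (v2[2] - v1[2]))
  cbind(base[, 1] + nrm[1] * dN + tg[1] * dT,
        base[, 2] + nrm[2] * dN + tg[2] * dT)
}

# densify a polyline so consecutive samples are < 0.7 px apart
.densify <- function(p) {
  d <- sqrt(rowSums(diff(p)^2))
  out <- list(p[1, , drop = FALSE])
  for (i in seq_along(d)) {
    k <- max(2L, ceiling(d[i] / 0.7) + 1L)
    seg <- cbind(seq(p[i, 1], p[i + 1, 1], length.out = k),
                 seq(p[i, 2], p[i + 1, 2], length.out = k))
    out[[i + 1L]] <- seg[-1, , drop = FALSE]
  }
  do.call(rbind, out)
}

# stamp discs of given radius at polyline samples into a logical mask
.stamp <- function(mask, xy, radius) {
  side <- dim(mask)[1]
  off <- expand.grid(dx = -ceiling(radius):ceiling(radius),
                     dy = -ceiling(radius):ceiling(radius))
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  cx <- round(xy[, 1]); cy <- round(xy[, 2])
  px <- rep(cx, each = nrow(off)) + rep(off$dx, times = length(cx))
  py <- rep(cy, each = nrow(off)) + rep(off$dy, times = length(cy))
  ok <- px >= 1 & px <= side & py >= 1 & py <= side
  mask[cbind(py[ok], px[ok])] <- TRUE   # row = y, col = x
  mask
}

# place bump centers with a minimum separation; returns k x 2 matrix
.place_bumps <- function(n, side, radius, placement, polylines) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  sep <- if (placement == "dense") 1.6 * radius else 2 * radius + 2
  lo <- radius + 2; hi <- side - radius - 1
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  all_wall <- if (length(polylines)) do.call(rbind, polylines) else NULL
  while (nrow(pts) < n && tries < 400L * n) {
    tries <- tries + 1L
    if (placement == "marginal" && !is.null(all_wall)) {
      base <- all_wall[sample.int(nrow(all_wall), 1L), ]
      ang <- runif(1, 0, 2 * pi)
      cand <- base + (radius + 2.5) * c(cos(ang), sin(ang))
      if (any(cand < lo) || any(cand > hi)) next
    } else {
      cand <- runif(2, lo, hi)
    }
    if (nrow(pts) == 0L ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= sep^2)
      pts <- rbind(pts, cand)
  }
  dimnames(pts) <- NULL
  pts
}

#' Generate one synthetic seed-coat patch
#'
#' Builds a Poisson-disk-seeded Voronoi cell mesh, draws the anticlinal walls
#' as sinusoidally displaced cell edges (with re-entrant lobes for omega-like
#' classes and per-edge jitter for the irregular classes), adds bright
#' periclinal bumps, then applies Gaussian blur and additive noise to emulate
#' an SEM micrograph. Deterministic for a fixed `(wall_class, params)`.
#'
#' @param class A [wall_class].
#' @param params A [texture_params]; use [default_texture_params] for the
#'   class-typical geometry.
#' @param id Image identifier string.
#' @return A `seed_image`: list with `id`, `raster` (250x250 matrix in
#'   `[0, 1]`), `truth` (the wall class) and `provenance = "synthetic"`.
#'   Attributes `boundaries` (list of wall polylines), `bump_centers` and
#'   `bump_layer` expose the pre-noise vector geometry for validation.
#' @export
generate_image <- function(class, params = default_texture_params(class),
                           id = "synthetic") {
  stopifnot(inherits(class, "wall_class"), inherits(params, "texture_params"))
  side <- 250L
  jitter <- isTRUE(attr(params, "jitter")) ||
    class$anticlinal %in% c("irregular_curved", "irregular_to_straight")
  withr::with_seed(params$seed, {
    spacing <- side / sqrt(params$cell_count)
    seeds <- .poisson_disk(params$cell_count, 4, side - 4, 0.75 * spacing)
    # mirror border-near points across each side so border cells are bounded
    near <- 0.8 * spacing
    mir <- rbind(
      cbind(-seeds[seeds[, 1] < near, 1], seeds[seeds[, 1] < near, 2]),
      cbind(2 * side - seeds[seeds[, 1] > side - near, 1],
            seeds[seeds[, 1] > side - near, 2]),
      cbind(seeds[seeds[, 2] < near, 1], -seeds[seeds[, 2] < near, 2]),
      cbind(seeds[seeds[, 2] > side - near, 1],
            2 * side - seeds[seeds[, 2] > side - near, 2]))
    all_pts <- rbind(seeds, mir)
    edges <- .voronoi_edges(all_pts, nrow(seeds))
    polylines <- lapply(edges, function(e)
      .wall_polyline(e$v1, e$v2, params$undulation_amplitude,
                     params$undulation_frequency, params$lobe_reentrance,
                     jitter))
    # per-cell base brightness: nearest-seed assignment
    gx <- rep(seq_len(side), times = side)       # col index = x
    gy <- rep(seq_len(side), each = side)        # row index = y  (column-major)
    d2 <- matrix(Inf, side * side, 1)
    cell <- integer(side * side)
    best <- rep(Inf, side * side)
    for (i in seq_len(nrow(seeds))) {
      di <- (gx - seeds[i, 1])^2 + (gy - seeds[i, 2])^2
      upd <- di < best
      cell[upd] <- i
      best[upd] <- di[upd]
    }
    shade <- runif(nrow(seeds), 0.74, 0.78)
    raster <- matrix(shade[cell], side, side)    # [row=y, col=x] column-major ok
    raster <- t(raster)                          # arrange as [y, x]
    # walls
    wall_mask <- matrix(FALSE, side, side)
    for (p in polylines) wall_mask <- .stamp(wall_mask, .densify(p), 1.4)
    raster[wall_mask] <- 0.08
    # periclinal bumps
    centers <- .place_bumps(params$verruca_count, side, params$verruca_radius,
                            params$verruca_placement, polylines)
    bump <- matrix(0, side, side)
    if (nrow(centers) > 0) {
      sg <- max(params$verruca_radius / 1.6, 0.8)
      w <- ceiling(2.2 * sg)
      prof <- outer(-w:w, -w:w, function(a, b) 0.35 * exp(-(a^2 + b^2) / (2 * sg^2)))
      for (i in seq_len(nrow(centers))) {
        cxr <- round(centers[i, 2]); cxc <- round(centers[i, 1])  # row=y col=x
        rr <- (cxr - w):(cxr + w); cc <- (cxc - w):(cxc + w)
        okr <- rr >= 1 & rr <= side; okc <- cc >= 1 & cc <= side
        bump[rr[okr], cc[okc]] <- pmax(bump[rr[okr], cc[okc]],
                                       prof[okr, okc])
      }
    }
    img <- pmin(pmax(raster + bump, 0), 1)
    if (params$blur_sigma > 0)
      img <- .as_matrix(EBImage::gblur(img, sigma = params$blur_sigma))
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(side * side, 0, params$noise_sd), side, side)
    img <- pmin(pmax(img, 0), 1)
    structure(list(id = id, raster = img, truth = class,
                   provenance = "synthetic"),
              class = "seed_image",
              boundaries = polylines, bump_centers = centers,
              bump_layer = bump)
  })
}

#' Generate a labeled synthetic dataset
#'
#' @param class_spec List of entries `list(class = wall_class, count = n)`.
#' @param base_params Named list of [texture_params] overrides applied on top
#'   of each class's defaults (e.g. `list(noise_sd = 0.05)`).
#' @param seed Master seed; per-image seeds are derived from it.
#' @return List of `seed_image` objects with truth labels.
#' @export
generate_dataset <- function(class_spec, base_params = list(), seed = 1L) {
  if (length(class_spec) == 0L) stop("empty class_spec", call. = FALSE)
  for (e in class_spec) {
    stopifnot(inherits(e$class, "wall_class"))
    if (is.null(e$count) || e$count < 1) stop("counts must be >= 1", call. = FALSE)
  }
  out <- list()
  idx <- 0L
  for (ci in seq_along(class_spec)) {
    e <- class_spec[[ci]]
    over <- utils::modifyList(as.list(base_params),
                              as.list(e$params %||% list()))
    for (j in seq_len(e$count)) {
      idx <- idx + 1L
      img_seed <- derive_seed(seed, sprintf("image-%d-%d", ci, j))
      pp <- do.call(default_texture_params,
                    c(list(class = e$class), over, list(seed = img_seed)))
      id <- sprintf("img%03d_%s_%s", idx, e$class$anticlinal, e$class$periclinal)
      out[[idx]] <- generate_image(e$class, pp, id = id)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three well-separated demonstration classes
#'
#' A class specification used throughout the examples and the planted-truth
#' validation: three wall classes chosen so their cell density, wall
#' undulation and bump load differ strongly, giving clearly separated texture
#' statistics.
#'
#' @param n_per_class Images per class.
#' @return A class_spec list for [generate_dataset].
#' @export
separated_class_spec <- function(n_per_class = 20L) {
  list(
    list(class = wall_class("straight", "granule"),
         count = n_per_class, params = list(cell_count = 15L)),
    list(class = wall_class("U_to_omega", "small_verrucae"),
         count = n_per_class, params = list(cell_count = 30L)),
    list(class = wall_class("omega", "verrucate_verrucae"),
         count = n_per_class, params = list(cell_count = 50L)))
}
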