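#' Preprocessing configuration
#'
#' @param crop_size Output patch side, pixels.
#' @param threshold Global gray-level threshold in `[0, 1]`; pixels `>=`
#'   threshold become foreground. The default 0.6 separates bright periclinal
#'   surfaces from dark anticlinal walls.
#' @param connectivity 4 or 8; neighbourhood used for component labeling.
#' @param downsample_side Side of the downsampled raster used as the
#'   clustering feature vector.
#' @param adaptive If `TRUE`, threshold each pixel against the local mean in a
#'   `adaptive_window` neighbourhood instead of the global value.
#' @param adaptive_window Window side for the local-mean threshold, pixels.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(crop_size = 250L, threshold = 0.6,
                              connectivity = 8L, downsample_side = 64L,
                              adaptive = FALSE, adaptive_window = 35L) {
  .check_scalar(crop_size, "crop_size", 1)
  .check_scalar(threshold, "threshold", 0, 1)
  .check_scalar(downsample_side, "downsample_side", 1)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(crop_size = as.integer(crop_size), threshold = threshold,
                 connectivity = as.integer(connectivity),
                 downsample_side = as.integer(downsample_side),
                 adaptive = isTRUE(adaptive),
                 adaptive_window = as.integer(adaptive_window)),
            class = "preprocess_config")
}

#' Convert a 3-channel raster to grayscale
#'
#' Uses ITU-R 601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param raster Numeric array `H x W x 3` with values in `[0, 1]`.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
to_grayscale <- function(raster) {
  if (length(dim(raster)) != 3L || dim(raster)[3] != 3L)
    stop("`raster` must have exactly 3 channels", call. = FALSE)
  if (min(raster) < 0 || max(raster) > 1)
    stop("channel values must lie in [0, 1]", call. = FALSE)
  matrix(0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3],
         dim(raster)[1], dim(raster)[2])
}

#' Threshold a grayscale image to binary
#'
#' Pixels at or above the threshold become foreground (1), the rest
#' background (0).
#'
#' @param gray Matrix in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`.
#' @return Integer matrix over `{0, 1}`.
#' @export
binarize <- function(gray, threshold = 0.6) {
  .check_scalar(threshold, "threshold", 0, 1)
  if (min(gray) < 0 || max(gray) > 1)
    stop("gray values must lie in [0, 1]", call. = FALSE)
  m <- matrix(as.integer(gray >= threshold), nrow(gray), ncol(gray))
  m
}

# area-average (block-mean) downsample to ds x ds; unlike interpolation this
# pools every pixel, so the features summarize texture density, not layout
.block_mean <- function(m, ds) {
  if (nrow(m) == ds && ncol(m) == ds) return(m)
  ri <- ceiling(seq_len(nrow(m)) / nrow(m) * ds)
  ci <- ceiling(seq_len(ncol(m)) / ncol(m) * ds)
  s <- t(rowsum(t(rowsum(m, ri)), ci))
  s / outer(tabulate(ri, ds), tabulate(ci, ds))
}

# local-mean threshold: pixel >= mean of its window
.binarize_adaptive <- function(gray, window) {
  k <- matrix(1 / (window * window), window, window)
  local_mean <- .as_matrix(EBImage::filter2(gray, k))
  matrix(as.integer(gray >= local_mean), nrow(gray), ncol(gray))
}

#' Label connected foreground components
#'
#' Builds the pixel-adjacency graph of the foreground under the requested
#' connectivity and labels its connected components 1..L in order of first
#' (row-major) pixel occurrence; background stays 0.
#'
#' @param binary Matrix over `{0, 1}`.
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix) and `n` (component count L).
#' @export
label_components <- function(binary, connectivity = 8L) {
  if (!all(binary %in% c(0L, 1L)))
    stop("`binary` must contain only 0 and 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(binary); nc <- ncol(binary)
  fg <- which(binary == 1L)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(list(labels = labels, n = 0L))
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  edge_pairs <- function(dr, dc) {
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) return(NULL)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    sel <- binary[nb] == 1L
    if (!any(sel)) return(NULL)
    cbind(idx[fg[ok]][sel], idx[nb][sel])
  }
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel components by first row-major pixel occurrence for determinism
  rm_order <- order(((fg - 1L) %% nr) * nc + ((fg - 1L) %/% nr))
  relab <- integer(max(memb))
  nxt <- 0L
  for (i in rm_order) {
    m <- memb[i]
    if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
  }
  labels[fg] <- relab[memb]
  list(labels = labels, n = nxt)
}

#' Measure per-component region properties
#'
#' @param labels Integer label matrix (0 = background).
#' @return Data frame with one row per label: `area`, half-open bounding box
#'   (`bbox_r0`, `bbox_c0`, `bbox_r1`, `bbox_c1`; 0-based), centroid,
#'   `perimeter` (count of exposed 4-neighbour pixel edges) and ellipse
#'   `eccentricity` from second central moments.
#' @export
measure_regions <- function(labels) {
  L <- max(labels)
  empty <- data.frame(label = integer(0), area = integer(0),
                      bbox_r0 = integer(0), bbox_c0 = integer(0),
                      bbox_r1 = integer(0), bbox_c1 = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      perimeter = numeric(0), eccentricity = numeric(0))
  if (L == 0L) return(empty)
  nr <- nrow(labels); nc <- ncol(labels)
  fg <- which(labels > 0L)
  lab <- labels[fg]
  r <- ((fg - 1L) %% nr)          # 0-based row
  c <- ((fg - 1L) %/% nr)         # 0-based col
  area <- tabulate(lab, L)
  # perimeter: 4-neighbour edges facing a different label or the image border
  per <- numeric(L)
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- r + s[1]; c2 <- c + s[2]
    outside <- r2 < 0L | r2 >= nr | c2 < 0L | c2 >= nc
    nbv <- integer(length(fg))
    nbv[!outside] <- labels[cbind(r2[!outside] + 1L, c2[!outside] + 1L)]
    exposed <- outside | nbv != lab
    per <- per + tabulate(lab[exposed], L)
  }
  cen_r <- tapply(r, lab, mean)
  cen_c <- tapply(c, lab, mean)
  ecc <- vapply(seq_len(L), function(k) {
    rk <- r[lab == k]; ck <- c[lab == k]
    mu20 <- mean((rk - mean(rk))^2) + 1 / 12   # pixel-extent correction
    mu02 <- mean((ck - mean(ck))^2) + 1 / 12
    mu11 <- mean((rk - mean(rk)) * (ck - mean(ck)))
    tr <- mu20 + mu02
    det <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
    l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
    if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  }, numeric(1))
  data.frame(label = seq_len(L), area = area,
             bbox_r0 = as.integer(tapply(r, lab, min)),
             bbox_c0 = as.integer(tapply(c, lab, min)),
             bbox_r1 = as.integer(tapply(r, lab, max)) + 1L,
             bbox_c1 = as.integer(tapply(c, lab, max)) + 1L,
             centroid_r = as.numeric(cen_r), centroid_c = as.numeric(cen_c),
             perimeter = per, eccentricity = ecc, row.names = NULL)
}

#' Assign a distinct color to each labeled component
#'
#' @param labels Integer label matrix.
#' @param seed RNG seed; the palette is deterministic per seed.
#' @return `H x W x 3` array; background black, each label one distinct color.
#' @export
colorize_labels <- function(labels, seed = 1L) {
  L <- max(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  out <- array(0, dim = c(nr, nc, 3L))
  if (L == 0L) return(out)
  withr::with_seed(seed, {
    hues <- (seq_len(L) - 1) / L
    hues <- ((hues + runif(1)) %% 1)[sample.int(L)]
    cols <- grDevices::hsv(hues, s = runif(L, 0.65, 1), v = runif(L, 0.7, 1))
  })
  rgb <- grDevices::col2rgb(cols) / 255
  fg <- which(labels > 0L)
  lab <- labels[fg]
  for (ch in 1:3) {
    plane <- matrix(0, nr, nc)
    plane[fg] <- rgb[ch, lab]
    out[, , ch] <- plane
  }
  out
}

#' Compute the three clustering representations of one image
#'
#' Derives the grayscale, binary-threshold and colored-component
#' representations plus the per-component region table.
#'
#' @param image A `seed_image`, grayscale matrix, or 3-channel array.
#' @param config A [preprocess_config].
#' @param color_seed Seed for the label palette.
#' @return A `representation_set`: `image_id`, `grayscale`, `binary`,
#'   `labels`, `n_components`, `colored`, `region_table`.
#' @export
compute_representations <- function(image, config = preprocess_config(),
                                    color_seed = 1L) {
  id <- if (inherits(image, "seed_image")) image$id else "image"
  gray <- .as_gray(image)
  binary <- if (config$adaptive)
    .binarize_adaptive(gray, config$adaptive_window)
  else binarize(gray, config$threshold)
  lc <- label_components(binary, config$connectivity)
  structure(list(image_id = id, grayscale = gray, binary = binary,
                 labels = lc$labels, n_components = lc$n,
                 colored = colorize_labels(lc$labels, color_seed),
                 region_table = measure_regions(lc$labels)),
            class = "representation_set")
}

.as_gray <- function(image) {
  if (inherits(image, "seed_image")) return(image$raster)
  if (length(dim(image)) == 3L) return(to_grayscale(image))
  if (is.matrix(image)) return(image)
  stop("unsupported image input", call. = FALSE)
}

#' Extract a normalized square patch around the dominant bright structure
#'
#' Thresholds the image, finds the largest connected foreground component,
#' crops its (squared) bounding box and rescales to
#' `config$crop_size x config$crop_size`.
#'
#' @param image Grayscale matrix, 3-channel array, or `seed_image`.
#' @param config A [preprocess_config].
#' @return A `seed_image` with `provenance = "external"`.
#' @export
extract_patch <- function(image, config = preprocess_config()) {
  gray <- .as_gray(image)
  binary <- binarize(gray, config$threshold)
  lc <- label_components(binary, config$connectivity)
  if (lc$n == 0L) stop("no foreground component: empty patch", call. = FALSE)
  tab <- measure_regions(lc$labels)
  big <- tab[which.max(tab$area), ]
  r0 <- big$bbox_r0 + 1L; r1 <- big$bbox_r1
  c0 <- big$bbox_c0 + 1L; c1 <- big$bbox_c1
  # square up the box (centered, clamped to the frame)
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  side <- max(h, w)
  r0 <- max(1L, min(r0 - (side - h) %/% 2L, nrow(gray) - side + 1L))
  c0 <- max(1L, min(c0 - (side - w) %/% 2L, ncol(gray) - side + 1L))
  side <- min(side, nrow(gray) - r0 + 1L, ncol(gray) - c0 + 1L)
  patch <- gray[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
  if (side != config$crop_size)
    patch <- .as_matrix(EBImage::resize(patch, w = config$crop_size,
                                        h = config$crop_size))
  patch <- pmin(pmax(patch, 0), 1)
  structure(list(id = "patch", raster = patch, truth = NULL,
                 provenance = "external"),
            class = "seed_image")
}

#' Augmentation configuration
#'
#' @param max_rotation_deg Maximum absolute rotation, degrees (default 5).
#' @param shift_fraction Maximum shift as a fraction of the image side
#'   (default 0.01, i.e. 2.5 px at side 250).
#' @param seed RNG seed.
#' @return An `augment_config` list.
#' @export
augment_config <- function(max_rotation_deg = 5, shift_fraction = 0.01,
                           seed = 1L) {
  .check_scalar(max_rotation_deg, "max_rotation_deg", 0)
  if (shift_fraction < 0 || shift_fraction >= 1)
    stop("`shift_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(max_rotation_deg = max_rotation_deg,
                 shift_fraction = shift_fraction, seed = as.integer(seed)),
            class = "augment_config")
}

#' Randomly rotate and shift an image
#'
#' Draws a rotation angle uniformly in `[-max_rotation_deg, +max_rotation_deg]`
#' and horizontal/vertical shifts uniformly within `shift_fraction` of the
#' side, then applies one bilinear affine warp about the image center.
#' Output dimensions are preserved; deterministic per config seed.
#'
#' @param image A `seed_image` or grayscale matrix.
#' @param config An [augment_config].
#' @return A `seed_image`; attributes `angle_deg`, `shift_px` record the draw.
#' @export
augment <- function(image, config = augment_config()) {
  gray <- .as_gray(image)
  nr <- nrow(gray); nc <- ncol(gray)
  withr::with_seed(config$seed, {
    ang <- runif(1, -config$max_rotation_deg, config$max_rotation_deg)
    sh <- runif(2, -config$shift_fraction, config$shift_fraction) * c(nr, nc)
  })
  th <- ang * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  ctr <- c(nr, nc) / 2
  off <- ctr - ctr %*% R + sh
  m <- rbind(R, off)   # maps input (row, col, 1) to output coordinates
  out <- .as_matrix(EBImage::affine(gray, m, output.dim = c(nr, nc)))
  out <- pmin(pmax(out, 0), 1)
  res <- structure(list(id = if (inherits(image, "seed_image"))
                          paste0(image$id, "_aug") else "aug",
                        raster = out,
                        truth = if (inherits(image, "seed_image")) image$truth else NULL,
                        provenance = "synthetic"),
                   class = "seed_image")
  attr(res, "angle_deg") <- ang
  attr(res, "shift_px") <- sh
  res
}

#' Shuffle a dataset and split into train and test
#'
#' @param images List of images (any objects).
#' @param train_fraction In (0, 1); train size is `floor(n * train_fraction)`.
#' @param seed RNG seed.
#' @return List with `train` and `test` lists.
#' @export
shuffle_split <- function(images, train_fraction = 0.8, seed = 1L) {
  n <- length(images)
  if (n < 2L) stop("need at least 2 images to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(n * train_fraction)
  list(train = images[perm[seq_len(n_train)]],
       test = images[perm[(n_train + 1L):n]])
}

#' Turn a representation into a feature vector
#'
#' Grayscale and threshold representations are downsampled to
#' `downsample_side^2` pixels and flattened; the colored-component
#' representation is summarized by a fixed 10-element region-statistics
#' vector (component count; area mean/sd; perimeter mean/sd; eccentricity
#' mean/sd; foreground fraction; largest-component fraction; components per
#' pixel), since the label colors themselves are arbitrary.
#'
#' @param rep A `representation_set`.
#' @param which `"grayscale"`, `"threshold"` or `"colored"`.
#' @param config A [preprocess_config].
#' @return Numeric feature vector; length depends only on `(which, config)`.
#' @export
vectorize <- function(rep, which = c("grayscale", "threshold", "colored"),
                      config = preprocess_config()) {
  which <- match.arg(which)
  if (!inherits(rep, "representation_set"))
    stop("`rep` must be a representation_set", call. = FALSE)
  ds <- config$downsample_side
  if (which == "grayscale")
    return(as.numeric(.block_mean(rep$grayscale, ds)))
  if (which == "threshold")
    return(as.numeric(.block_mean(rep$binary * 1.0, ds)))
  tab <- rep$region_table
  npix <- length(rep$binary)
  side <- sqrt(npix)
  if (nrow(tab) == 0L) return(numeric(10))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  # dimensionless units (fractions of the image; log-scaled count) so no one
  # raw scale dominates the Euclidean geometry
  c(log1p(nrow(tab)),
    mean(tab$area) / npix, sd0(tab$area) / npix,
    mean(tab$perimeter) / (4 * side), sd0(tab$perimeter) / (4 * side),
    mean(tab$eccentricity), sd0(tab$eccentricity),
    sum(tab$area) / npix,
    max(tab$area) / sum(tab$area),
    nrow(tab) / npix)
}
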