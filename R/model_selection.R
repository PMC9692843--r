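# coerce a list of equal-length vectors or a matrix to a points matrix (rows)
.as_points <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.vector(vectors) && is.numeric(vectors)) vectors <- cbind(vectors)
  if (!is.matrix(vectors) || !is.numeric(vectors) || any(!is.finite(vectors)))
    stop("vectors must be finite numerics", call. = FALSE)
  unname(vectors)
}

# scan a k grid with best-of-restarts k-means; each k is additionally
# warm-started from the previous k's solution with its widest centroid split,
# which makes the best SSE non-increasing in k
.kmeans_scan <- function(points, k_grid, restarts, seed) {
  out <- vector("list", length(k_grid))
  prev <- NULL
  for (gi in seq_along(k_grid)) {
    k <- k_grid[gi]
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(points, k, seed = derive_seed(seed, sprintf("scan-%d-%d", k, r)))
      fit <- kmeans_lloyd(points, k, init)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
    if (!is.null(prev) && k == prev$k + 1L) {
      split_i <- which.max(vapply(seq_len(prev$k), function(j) {
        pts <- points[prev$labels == j, , drop = FALSE]
        if (nrow(pts) < 2L) return(-Inf)
        sum(sweep(pts, 2, colMeans(pts))^2)
      }, numeric(1)))
      pts <- points[prev$labels == split_i, , drop = FALSE]
      far <- which.max(rowSums(sweep(pts, 2, prev$centers[split_i, ])^2))
      warm <- rbind(prev$centers, pts[far, , drop = FALSE])
      fit <- kmeans_lloyd(points, k, warm)
      if (fit$sse < best$sse) best <- fit
    }
    best$k <- k
    out[[gi]] <- best
    prev <- best
  }
  out
}

#' Per-k sum of squared distances (elbow curve)
#'
#' For each k in the grid, fits k-means (best of `restarts` seeded
#' initializations, warm-started across k) and records the total
#' within-cluster sum of squared Euclidean distances.
#'
#' @param vectors Points as a matrix (rows) or list of numeric vectors.
#' @param k_grid Increasing integer vector of cluster counts (default 2..10).
#' @param restarts Restarts per k.
#' @param seed RNG seed.
#' @return Numeric vector of SSE values, one per k.
#' @export
sse_curve <- function(vectors, k_grid = 2:10, restarts = 10L, seed = 1L) {
  points <- .as_points(vectors)
  if (max(k_grid) > nrow(points))
    stop("k exceeds the number of points", call. = FALSE)
  vapply(.kmeans_scan(points, k_grid, restarts, seed), `[[`, numeric(1), "sse")
}

#' Locate the elbow of an SSE curve
#'
#' Returns the interior k whose `(k, sse)` point lies farthest (perpendicular
#' distance) from the chord joining the first and last grid points; ties break
#' toward smaller k.
#'
#' @param k_grid Increasing integer grid (>= 3 points).
#' @param sse Finite SSE values, one per k.
#' @return The elbow k.
#' @export
detect_elbow <- function(k_grid, sse) {
  if (length(k_grid) < 3L || length(sse) != length(k_grid))
    stop("need >= 3 grid points with matching sse", call. = FALSE)
  if (any(!is.finite(sse))) stop("sse must be finite", call. = FALSE)
  p1 <- c(k_grid[1], sse[1])
  p2 <- c(k_grid[length(k_grid)], sse[length(sse)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  d <- abs(v[2] * (k_grid - p1[1]) - v[1] * (sse - p1[2])) /
    if (nv > 0) nv else 1
  interior <- 2:(length(k_grid) - 1L)
  k_grid[interior[which.max(d[interior])]]   # which.max takes the first = smaller k
}

#' Mean silhouette coefficient of a labeling
#'
#' Per point, `s = (b - a) / max(a, b)` where `a` is the mean distance to the
#' point's own cluster and `b` the smallest mean distance to another cluster;
#' singleton clusters contribute 0. Euclidean distances.
#'
#' @param vectors Points as matrix or list.
#' @param labels Cluster assignment (any label type; >= 2 distinct values).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(vectors, labels) {
  points <- .as_points(vectors)
  labs <- as.integer(factor(labels))
  if (length(labs) != nrow(points))
    stop("labels length must match points", call. = FALSE)
  if (length(unique(labs)) < 2L)
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  if (length(unique(labs)) == length(labs)) return(0)   # all singletons
  sil <- cluster::silhouette(labs, dist(points))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by elbow and silhouette
#'
#' Scans the k grid once with seeded k-means, then chooses `k_elbow` by
#' [detect_elbow] on the SSE curve and `k_silhouette` as the argmax of the
#' per-k mean silhouette (ties toward smaller k).
#'
#' @param vectors Points as matrix or list.
#' @param k_grid Integer grid (default 2..10).
#' @param restarts Restarts per k.
#' @param seed RNG seed.
#' @param representation Optional tag recorded in the result.
#' @return A `k_selection` list: `representation`, `k_grid`, `sse`,
#'   `silhouette`, `k_elbow`, `k_silhouette`.
#' @export
choose_k <- function(vectors, k_grid = 2:10, restarts = 10L, seed = 1L,
                     representation = NA_character_) {
  points <- .as_points(vectors)
  if (max(k_grid) > nrow(points))
    stop("k exceeds the number of points", call. = FALSE)
  fits <- .kmeans_scan(points, k_grid, restarts, seed)
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  sil <- vapply(fits, function(f) {
    if (length(unique(f$labels)) < 2L) return(-1)
    mean_silhouette(points, f$labels)
  }, numeric(1))
  structure(list(representation = representation, k_grid = k_grid,
                 sse = sse, silhouette = sil,
                 k_elbow = detect_elbow(k_grid, sse),
                 k_silhouette = k_grid[which.max(sil)]),
            class = "k_selection")
}
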