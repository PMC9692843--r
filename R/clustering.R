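#' Battery configuration for the five-method clustering stage
#'
#' @param restarts Restarts for the k-means family.
#' @param batch_size Minibatch size.
#' @param birch_branching CF-tree branching factor.
#' @param birch_threshold CF-entry radius threshold, in standardized feature
#'   units.
#' @param rbf_gamma RBF affinity scale for spectral clustering; `NULL` means
#'   `1 / (dimension x mean feature variance)`.
#' @param methods_representation Representation fed to the M1..M5 method runs.
#' @param methods_criterion Which selected k the M1..M5 runs use.
#' @param master_seed Master seed; per-run seeds are derived from it.
#' @return A `battery_config` list.
#' @export
battery_config <- function(restarts = 10L, batch_size = 32L,
                           birch_branching = 50L, birch_threshold = 0.5,
                           rbf_gamma = NULL,
                           methods_representation = "grayscale",
                           methods_criterion = "elbow",
                           master_seed = 1L) {
  .check_scalar(restarts, "restarts", 1)
  .check_scalar(batch_size, "batch_size", 1)
  .check_scalar(birch_branching, "birch_branching", 2)
  .check_scalar(birch_threshold, "birch_threshold", 0)
  structure(list(restarts = as.integer(restarts),
                 batch_size = as.integer(batch_size),
                 birch_branching = as.integer(birch_branching),
                 birch_threshold = birch_threshold, rbf_gamma = rbf_gamma,
                 methods_representation = methods_representation,
                 methods_criterion = methods_criterion,
                 master_seed = as.integer(master_seed)),
            class = "battery_config")
}

# one labeling of the image set; labels are 0-based cluster indices so that
# cluster i carries the display name C(i+1)
clustering_run <- function(code, method, representation, k, labels0, ids,
                           seed = NA_integer_, criterion = NA_character_) {
  stopifnot(length(labels0) == length(ids), all(labels0 >= 0L), all(labels0 < k))
  structure(list(code = code, method = method,
                 representation = representation, criterion = criterion,
                 k = as.integer(k), labels = as.integer(labels0),
                 ids = ids, seed = seed),
            class = "clustering_run")
}

# squared Euclidean distances between rows of x and rows of centers
.dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

# D^2 sampling probabilities for the next k-means++ centroid
.kmeanspp_probs <- function(points, centers) {
  d2 <- .dist2(points, centers)
  mins <- apply(d2, 1, min)
  if (sum(mins) == 0) rep(1 / length(mins), length(mins)) else mins / sum(mins)
}

#' k-means++ centroid initialization
#'
#' First centroid uniform over the points; each next centroid drawn with
#' probability proportional to the squared distance to its nearest already
#' chosen centroid.
#'
#' @param vectors Points as matrix or list.
#' @param k Number of centroids (<= number of points).
#' @param seed RNG seed.
#' @return `k x d` centroid matrix.
#' @export
kmeanspp_init <- function(vectors, k, seed = 1L) {
  points <- .as_points(vectors)
  if (k > nrow(points)) stop("k exceeds the number of points", call. = FALSE)
  withr::with_seed(seed, {
    centers <- points[sample.int(nrow(points), 1L), , drop = FALSE]
    while (nrow(centers) < k) {
      p <- .kmeanspp_probs(points, centers)
      centers <- rbind(centers, points[sample.int(nrow(points), 1L, prob = p), ])
    }
  })
  unname(centers)
}

#' Lloyd k-means from explicit initial centroids
#'
#' Alternates nearest-centroid assignment and mean updates until assignments
#' stabilize or `max_iter` is reached. A cluster left empty is re-seeded with
#' the point farthest from its assigned centroid.
#'
#' @param vectors Points as matrix or list.
#' @param k Number of clusters.
#' @param init `k x d` initial centroid matrix (default: k-means++ with seed 1).
#' @param max_iter Iteration cap.
#' @return List: `labels` (1..k), `centers`, `sse`, `iterations`.
#' @export
kmeans_lloyd <- function(vectors, k, init = NULL, max_iter = 300L) {
  points <- .as_points(vectors)
  if (k < 1L || k > nrow(points)) stop("k must be in 1..n", call. = FALSE)
  centers <- if (is.null(init)) kmeanspp_init(points, k) else .as_points(init)
  stopifnot(nrow(centers) == k)
  labels <- rep(0L, nrow(points))
  n <- nrow(points)
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(points, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the farthest point whose donor cluster
    # keeps at least one member
    repeat {
      sizes <- tabulate(new_labels, k)
      empt <- which(sizes == 0L)
      if (length(empt) == 0L) break
      ord <- order(-d2[cbind(seq_len(n), new_labels)])
      cand <- ord[sizes[new_labels[ord]] > 1L][1]
      if (is.na(cand)) break
      centers[empt[1], ] <- points[cand, ]
      new_labels[cand] <- empt[1]
      d2 <- .dist2(points, centers)
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k))
      if (any(labels == j))
        centers[j, ] <- colMeans(points[labels == j, , drop = FALSE])
  }
  d2 <- .dist2(points, centers)
  list(labels = labels, centers = centers,
       sse = sum(d2[cbind(seq_along(labels), labels)]), iterations = it)
}

#' Minibatch k-means
#'
#' k-means++ initialization, then per-iteration random batches with streaming
#' per-centroid mean updates at learning rate `1 / count`; final labels by
#' nearest centroid.
#'
#' @param vectors Points as matrix or list.
#' @param k Number of clusters.
#' @param batch_size Batch size (<= n).
#' @param iterations Number of batch updates per restart.
#' @param seed RNG seed.
#' @param restarts Independent restarts; the solution with the lowest final
#'   assignment SSE is kept.
#' @return List: `labels` (1..k), `centers`, `sse`.
#' @export
minibatch_kmeans <- function(vectors, k, batch_size = 32L, iterations = 100L,
                             seed = 1L, restarts = 5L) {
  points <- .as_points(vectors)
  n <- nrow(points)
  if (batch_size > n) stop("batch_size exceeds n", call. = FALSE)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  best <- NULL
  for (rs in seq_len(restarts)) {
    centers <- kmeanspp_init(points, k, seed = derive_seed(seed, sprintf("mb-init-%d", rs)))
    counts <- rep(0, k)
    withr::with_seed(derive_seed(seed, sprintf("mb-batches-%d", rs)), {
      for (it in seq_len(iterations)) {
        batch <- points[sample.int(n, batch_size), , drop = FALSE]
        a <- max.col(-.dist2(batch, centers), ties.method = "first")
        for (i in seq_len(nrow(batch))) {
          j <- a[i]
          counts[j] <- counts[j] + 1
          centers[j, ] <- centers[j, ] + (batch[i, ] - centers[j, ]) / counts[j]
        }
      }
    })
    labels <- max.col(-.dist2(points, centers), ties.method = "first")
    # guarantee no empty cluster in the final assignment
    for (j in which(tabulate(labels, k) == 0L)) {
      d2 <- .dist2(points, centers)
      far <- which.max(d2[cbind(seq_len(n), labels)])
      centers[j, ] <- points[far, ]
      labels[far] <- j
    }
    sse <- sum(.dist2(points, centers)[cbind(seq_len(n), labels)])
    if (is.null(best) || sse < best$sse)
      best <- list(labels = labels, centers = centers, sse = sse)
  }
  best
}

# spectral embedding + k-means on a given affinity matrix
.spectral_from_affinity <- function(A, k, seed = 1L, restarts = 10L) {
  diag(A) <- 0
  dvec <- rowSums(A)
  dvec[dvec == 0] <- 1e-12
  M <- A / sqrt(dvec) / rep(sqrt(dvec), each = nrow(A))
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]   # top of M = bottom of Laplacian
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- kmeans_lloyd(U, k, kmeanspp_init(U, k, seed = derive_seed(seed, sprintf("spec-%d", r))))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best$labels
}

#' Spectral clustering with an RBF affinity
#'
#' Builds `A_ij = exp(-gamma ||x_i - x_j||^2)`, forms the symmetric normalized
#' Laplacian, embeds the points in the k leading eigenvectors (row-normalized)
#' and clusters the embedding with k-means.
#'
#' @param vectors Points as matrix or list.
#' @param k Number of clusters (>= 2).
#' @param rbf_gamma Affinity scale; `NULL` gives `1 / (d x mean variance)`.
#' @param seed RNG seed.
#' @return List: `labels` (1..k), `gamma`.
#' @export
spectral_cluster <- function(vectors, k, rbf_gamma = NULL, seed = 1L) {
  points <- .as_points(vectors)
  if (k < 2L || k > nrow(points)) stop("need n >= k >= 2", call. = FALSE)
  if (is.null(rbf_gamma)) {
    v <- mean(apply(points, 2, stats::var))
    rbf_gamma <- 1 / (ncol(points) * max(v, 1e-12))
  }
  A <- exp(-rbf_gamma * .dist2(points, points))
  labels <- .spectral_from_affinity(A, k, seed = seed)
  list(labels = labels, gamma = rbf_gamma)
}

# --- Birch CF-tree -----------------------------------------------------------
# clustering features are (n, linear sum, squared sum); a leaf entry absorbs a
# point only if the resulting radius stays within the threshold

.cf_radius <- function(n, ls, ss) {
  mu <- ls / n
  sqrt(max(ss / n - sum(mu^2), 0))
}

#' Birch clustering
#'
#' One-pass CF-tree build: each point descends to the closest leaf entry and
#' is absorbed if the entry's radius stays within `radius_threshold`,
#' otherwise it opens a new entry; leaves split at the branching limit by
#' farthest-pair seeding. Leaf entries are then merged to k clusters by
#' agglomerative centroid linkage and points inherit their entry's cluster.
#'
#' @param vectors Points as matrix or list.
#' @param k Target cluster count.
#' @param branching Maximum entries per leaf / children per node (>= 2).
#' @param radius_threshold Absorption radius.
#' @return List: `labels` (1..k_eff), `n_entries`, `entry_of_point`.
#' @export
birch_cluster <- function(vectors, k, branching = 50L, radius_threshold = 0.5) {
  points <- .as_points(vectors)
  if (branching < 2L) stop("branching must be >= 2", call. = FALSE)
  n <- nrow(points); d <- ncol(points)
  # flat store of leaf entries; the tree is a recursive grouping of entry ids
  ent_n <- numeric(0); ent_ls <- NULL; ent_ss <- numeric(0)
  entry_of_point <- integer(n)
  # leaves: list of integer vectors (entry ids); descend by closest leaf centroid
  leaves <- list(integer(0))
  for (i in seq_len(n)) {
    x <- points[i, ]
    # choose leaf whose entries' closest centroid is nearest
    if (length(ent_n) == 0L) {
      li <- 1L; ei <- 0L
    } else {
      cents <- ent_ls / ent_n
      d2 <- colSums((t(cents) - x)^2)
      ei_global <- which.min(d2)
      li <- which(vapply(leaves, function(v) ei_global %in% v, logical(1)))[1]
      ei <- ei_global
    }
    absorbed <- FALSE
    if (ei > 0L) {
      nn <- ent_n[ei] + 1
      nls <- ent_ls[ei, ] + x
      nss <- ent_ss[ei] + sum(x^2)
      if (.cf_radius(nn, nls, nss) <= radius_threshold) {
        ent_n[ei] <- nn; ent_ls[ei, ] <- nls; ent_ss[ei] <- nss
        entry_of_point[i] <- ei
        absorbed <- TRUE
      }
    }
    if (!absorbed) {
      ent_n <- c(ent_n, 1)
      ent_ls <- rbind(ent_ls, x)
      ent_ss <- c(ent_ss, sum(x^2))
      new_id <- length(ent_n)
      entry_of_point[i] <- new_id
      leaves[[li]] <- c(leaves[[li]], new_id)
      if (length(leaves[[li]]) > branching) {
        # split by farthest-pair seeding
        ids <- leaves[[li]]
        cents <- ent_ls[ids, , drop = FALSE] / ent_n[ids]
        dd <- as.matrix(dist(cents))
        far <- arrayInd(which.max(dd), dim(dd))
        s1 <- far[1]; s2 <- far[2]
        grp1 <- dd[, s1] <= dd[, s2]
        leaves[[li]] <- ids[grp1]
        leaves[[length(leaves) + 1L]] <- ids[!grp1]
      }
    }
  }
  n_entries <- length(ent_n)
  k_eff <- min(k, n_entries)
  if (n_entries == 1L) {
    entry_cluster <- 1L
  } else {
    cents <- ent_ls / ent_n
    hc <- stats::hclust(dist(cents)^2, method = "centroid")
    entry_cluster <- stats::cutree(hc, k = k_eff)
  }
  labels <- entry_cluster[entry_of_point]
  # contiguous labels 1..k_eff in first-appearance order
  labels <- as.integer(factor(labels, levels = unique(labels)))
  list(labels = labels, n_entries = n_entries,
       entry_of_point = entry_of_point)
}

# z-score standardization; constant dimensions are left centered only
.standardize <- function(points) {
  mu <- colMeans(points)
  sdv <- apply(points, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  sweep(sweep(points, 2, mu), 2, sdv, "/")
}

# best-of-restarts k-means++ labels (the engine behind the EG..SC runs)
.kmeans_best <- function(points, k, restarts, seed) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- kmeans_lloyd(points, k,
                        kmeanspp_init(points, k, seed = derive_seed(seed, sprintf("r%d", r))))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}

#' Build per-representation feature matrices for a set of images
#'
#' @param images List of `seed_image` objects.
#' @param config A [preprocess_config].
#' @param color_seed Palette seed for the colored representation.
#' @return List: `ids`, matrices `grayscale`, `threshold`, `colored` (rows =
#'   images), and `representations` (the per-image representation sets).
#' @export
build_features <- function(images, config = preprocess_config(),
                           color_seed = 1L) {
  reps <- lapply(images, compute_representations, config = config,
                 color_seed = color_seed)
  list(ids = vapply(images, `[[`, character(1), "id"),
       grayscale = do.call(rbind, lapply(reps, vectorize, which = "grayscale", config = config)),
       threshold = do.call(rbind, lapply(reps, vectorize, which = "threshold", config = config)),
       colored = do.call(rbind, lapply(reps, vectorize, which = "colored", config = config)),
       representations = reps)
}

#' Run the five-method battery and the six proposed runs
#'
#' Produces (a) method runs M1..M5 — k-means with random-point initialization,
#' k-means++, minibatch k-means, spectral and Birch — on one representation at
#' one selected k, used for the human-comparison analyses, and (b) the six
#' proposed runs EG, SG, ET, ST, EC, SC: for each representation (grayscale,
#' threshold, colored) and each selection criterion (elbow, silhouette) a
#' k-means++ run at that criterion's selected k. Features are z-scored before
#' spectral and Birch; the k-means family sees the raw features. Fully
#' reproducible from `config$master_seed`.
#'
#' @param features Output of [build_features].
#' @param config A [battery_config].
#' @param selection Named list of [choose_k] results, one per representation.
#' @return List of `clustering_run` objects keyed by code.
#' @export
run_battery <- function(features, config = battery_config(), selection) {
  reps <- c("grayscale", "threshold", "colored")
  for (rp in reps)
    if (is.null(selection[[rp]]))
      stop("missing k selection for representation: ", rp, call. = FALSE)
  ids <- features$ids
  ms <- config$master_seed
  runs <- list()

  # --- method runs M1..M5 on the configured representation -----------------
  X <- features[[config$methods_representation]]
  kM <- if (config$methods_criterion == "elbow")
    selection[[config$methods_representation]]$k_elbow
  else selection[[config$methods_representation]]$k_silhouette
  Xz <- .standardize(X)
  add_run <- function(code, method, representation, k, labels1, seed,
                      criterion = NA_character_) {
    runs[[code]] <<- clustering_run(code, method, representation, k,
                                    labels1 - 1L, ids, seed, criterion)
  }
  # M1: Lloyd from random-point initialization
  s1 <- derive_seed(ms, "M1")
  best <- NULL
  for (r in seq_len(config$restarts)) {
    init <- withr::with_seed(derive_seed(s1, sprintf("r%d", r)),
                             X[sample.int(nrow(X), kM), , drop = FALSE])
    fit <- kmeans_lloyd(X, kM, init)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  add_run("M1", "kmeans", config$methods_representation, kM, best$labels, s1)
  # M2: k-means++
  s2 <- derive_seed(ms, "M2")
  add_run("M2", "kmeanspp", config$methods_representation, kM,
          .kmeans_best(X, kM, config$restarts, s2)$labels, s2)
  # M3: minibatch
  s3 <- derive_seed(ms, "M3")
  fit <- minibatch_kmeans(X, kM, batch_size = min(config$batch_size, nrow(X)),
                          iterations = 100L, seed = s3,
                          restarts = config$restarts)
  add_run("M3", "minibatch", config$methods_representation, kM, fit$labels, s3)
  # M4: spectral (standardized features)
  s4 <- derive_seed(ms, "M4")
  fit <- spectral_cluster(Xz, kM, rbf_gamma = config$rbf_gamma, seed = s4)
  add_run("M4", "spectral", config$methods_representation, kM, fit$labels, s4)
  # M5: birch (standardized features)
  s5 <- derive_seed(ms, "M5")
  fit <- birch_cluster(Xz, kM, branching = config$birch_branching,
                       radius_threshold = config$birch_threshold)
  kB <- length(unique(fit$labels))
  add_run("M5", "birch", config$methods_representation, kB, fit$labels, s5)

  # --- proposed runs EG SG ET ST EC SC -------------------------------------
  code_map <- list(elbow = c(grayscale = "EG", threshold = "ET", colored = "EC"),
                   silhouette = c(grayscale = "SG", threshold = "ST", colored = "SC"))
  for (crit in c("elbow", "silhouette")) {
    for (rp in reps) {
      code <- code_map[[crit]][[rp]]
      k <- if (crit == "elbow") selection[[rp]]$k_elbow
           else selection[[rp]]$k_silhouette
      sd <- derive_seed(ms, code)
      fit <- .kmeans_best(features[[rp]], k, config$restarts, sd)
      add_run(code, "kmeanspp", rp, k, fit$labels, sd, criterion = crit)
    }
  }
  runs
}
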