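test_that("k-means++ D-squared sampling probabilities are exact", {
  pts <- cbind(c(0, 1, 10))
  probs <- testaclust:::.kmeanspp_probs(pts, cbind(0))
  expect_equal(probs[3], 100 / 101, tolerance = 1e-12)
  expect_equal(probs[1], 0)        # a point equal to a centroid can't be drawn
  cents <- kmeanspp_init(pts, 3, seed = 2L)
  expect_setequal(as.vector(cents), c(0, 1, 10))   # k = n -> a permutation
  expect_error(kmeanspp_init(pts, 4), "exceeds")
})

test_that("Lloyd k-means solves the worked micro-instance", {
  fit <- kmeans_lloyd(cbind(c(1, 2, 10, 11)), 2, init = cbind(c(1, 10)))
  expect_equal(fit$sse, 1.0)
  expect_identical(fit$labels[1], fit$labels[2])
  expect_identical(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
  # k distinct points -> zero SSE
  fit0 <- kmeans_lloyd(cbind(c(3, 7, 9)), 3, init = cbind(c(3, 7, 9)))
  expect_lt(fit0$sse, 1e-12)
  # final SSE never exceeds the SSE of the initial assignment
  pts <- withr::with_seed(4L, matrix(rnorm(60), 30, 2))
  init <- pts[1:4, ]
  d2 <- testaclust:::.dist2(pts, init)
  sse_init <- sum(d2[cbind(1:30, max.col(-d2))])
  expect_lte(kmeans_lloyd(pts, 4, init)$sse, sse_init + 1e-9)
})

test_that("k-means attains the exhaustive optimum on small instances", {
  hits <- 0L
  for (i in 1:30) {
    x <- withr::with_seed(2000 + i, rnorm(sample(4:8, 1)))
    fit <- testaclust:::.kmeans_best(cbind(x), 2, 20, i)
    if (fit$sse <= exhaustive_min_sse2(x) + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
})

test_that("no cluster is left empty after reseeding", {
  # adversarial init: two centroids on the same far point
  pts <- cbind(c(0, 0.1, 0.2, 50))
  fit <- kmeans_lloyd(pts, 3, init = cbind(c(50, 50, 50)))
  expect_setequal(unique(fit$labels), 1:3)
})

test_that("minibatch k-means finds the separated pairs", {
  x <- cbind(c(0, 0.1, 10, 10.1))
  mb <- minibatch_kmeans(x, 2, batch_size = 2L, iterations = 200L, seed = 5L)
  km <- kmeans_lloyd(x, 2, init = cbind(c(0, 10)))
  expect_identical(adjusted_rand_index(mb$labels, km$labels), 1)
  expect_identical(minibatch_kmeans(x, 1, batch_size = 2L, seed = 1L)$labels,
                   rep(1L, 4))
  expect_identical(minibatch_kmeans(x, 2, batch_size = 2L, seed = 3L)$labels,
                   minibatch_kmeans(x, 2, batch_size = 2L, seed = 3L)$labels)
  expect_error(minibatch_kmeans(x, 2, batch_size = 10L), "batch_size")
})

test_that("spectral clustering recovers exact blocks and far groups", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1
  lab <- testaclust:::.spectral_from_affinity(A, 2, seed = 1L)
  expect_identical(adjusted_rand_index(lab, c(1, 1, 1, 2, 2, 2)), 1)
  pts <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, 20, sd = 0.1), 10, 2))
  sp <- spectral_cluster(pts, 2, seed = 2L)
  expect_identical(adjusted_rand_index(sp$labels, rep(1:2, each = 10)), 1)
  expect_error(spectral_cluster(pts, 1), "k >= 2")
})

test_that("spectral agrees with an independent implementation on blobs", {
  pts <- blob_points(6L, n_per = 15L, sd = 0.5)
  sp <- spectral_cluster(pts, 4, seed = 3L)
  ref <- withr::with_seed(3L, kernlab::specc(pts, centers = 4))
  expect_gte(adjusted_rand_index(sp$labels, ref@.Data), 0.95)
})

test_that("birch CF-tree honors its radius threshold", {
  x <- cbind(c(0, 0.1, 10, 10.1))
  expect_identical(birch_cluster(x, 2, radius_threshold = 100)$n_entries, 1L)
  expect_identical(birch_cluster(x, 2, radius_threshold = 1e-9)$n_entries, 4L)
  fit <- birch_cluster(x, 2, radius_threshold = 0.5)
  km <- kmeans_lloyd(x, 2, init = cbind(c(0, 10)))
  expect_identical(adjusted_rand_index(fit$labels, km$labels), 1)
  expect_error(birch_cluster(x, 2, branching = 1), "branching")
})

test_that("birch splits leaves and still labels every point", {
  pts <- withr::with_seed(9L, matrix(rnorm(300), 150, 2))
  fit <- birch_cluster(pts, 3, branching = 4L, radius_threshold = 0.3)
  expect_length(fit$labels, 150L)
  expect_lte(max(fit$labels), 3L)
  expect_setequal(unique(fit$labels), seq_len(max(fit$labels)))
})

test_that("all five methods agree on linearly separable planted data", {
  pts <- blob_points(12L, n_per = 15L, sd = 0.4)
  truth <- rep(1:4, each = 15)
  best_random_init <- function(points, k, restarts, seed) {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- withr::with_seed(seed + r, points[sample.int(nrow(points), k), ])
      fit <- kmeans_lloyd(points, k, init)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
    best
  }
  labs <- list(
    m1 = best_random_init(pts, 4, 10L, 1L)$labels,
    m2 = testaclust:::.kmeans_best(pts, 4, 10, 2L)$labels,
    m3 = minibatch_kmeans(pts, 4, batch_size = 20L, iterations = 150L, seed = 3L)$labels,
    m4 = spectral_cluster(testaclust:::.standardize(pts), 4, seed = 4L)$labels,
    m5 = birch_cluster(testaclust:::.standardize(pts), 4)$labels)
  for (a in seq_along(labs)) for (b in seq_along(labs))
    if (a < b)
      expect_gte(adjusted_rand_index(labs[[a]], labs[[b]]), 0.9)
  for (l in labs) expect_gte(adjusted_rand_index(l, truth), 0.9)
})

test_that("the battery is a pure function of its inputs", {
  feats <- list(ids = sprintf("i%02d", 1:30),
                grayscale = blob_points(21L, n_per = 10L)[1:30, ],
                threshold = blob_points(22L, n_per = 10L)[1:30, ],
                colored = blob_points(23L, n_per = 10L)[1:30, ])
  sel <- list()
  for (rp in c("grayscale", "threshold", "colored"))
    sel[[rp]] <- choose_k(feats[[rp]], 2:5, restarts = 5L, seed = 1L,
                          representation = rp)
  cfg <- battery_config(master_seed = 77L)
  r1 <- run_battery(feats, cfg, sel)
  r2 <- run_battery(feats, cfg, sel)
  expect_identical(lapply(r1, `[[`, "labels"), lapply(r2, `[[`, "labels"))
  expect_setequal(names(r1), c(paste0("M", 1:5),
                               "EG", "SG", "ET", "ST", "EC", "SC"))
  for (r in r1) {
    expect_true(all(r$labels >= 0L & r$labels < r$k))
    expect_length(unique(r$labels), r$k)   # every cluster inhabited
  }
  expect_error(run_battery(feats, cfg, sel["grayscale"]), "missing")
})
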