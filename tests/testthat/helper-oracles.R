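# Independent oracles used across the suite. These deliberately use brute
# force / closed forms, never the package's own code paths.

# exhaustive minimum 2-cluster SSE over all bipartitions of a 1-d sample
exhaustive_min_sse2 <- function(x) {
  n <- length(x)
  best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {
    a <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    if (any(a) && any(!a)) {
      s <- sum((x[a] - mean(x[a]))^2) + sum((x[!a] - mean(x[!a]))^2)
      best <- min(best, s)
    }
  }
  best
}

# hand silhouette: mean of (b - a)/max(a, b), singletons contribute 0
hand_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive agreement level: largest subset of runs whose mates sets for
# image i are pairwise identical
brute_agreement_level <- function(run_labels, i) {
  n_runs <- length(run_labels)
  mates <- lapply(run_labels, function(l) {
    m <- which(l == l[i])
    sort(setdiff(m, i))
  })
  best <- 1L
  for (m in 1:(2^n_runs - 1)) {
    sel <- which(as.logical(bitwAnd(m, 2^(0:(n_runs - 1)))))
    if (length(sel) <= best) next
    ok <- TRUE
    for (a in sel) for (b in sel)
      if (!identical(mates[[a]], mates[[b]])) { ok <- FALSE; break }
    if (ok) best <- length(sel)
  }
  best
}

# quick builder for clustering_run objects in consensus tests
make_run <- function(labels0, k, code = "A",
                     ids = sprintf("img%03d", seq_along(labels0))) {
  testaclust:::clustering_run(code, "kmeanspp", "grayscale", k,
                              as.integer(labels0), ids)
}

# 4 planted Gaussian blobs in 2-d (the k-selection recovery fixture)
blob_points <- function(seed, n_per = 50L, sd = 1) {
  withr::with_seed(seed, {
    ctr <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
    do.call(rbind, lapply(1:4, function(j)
      sweep(matrix(rnorm(2 * n_per, sd = sd), n_per, 2), 2, ctr[j, ], "+")))
  })
}
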