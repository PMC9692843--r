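test_that("grayscale conversion uses ITU-R 601 weights", {
  px <- array(0, dim = c(1, 1, 3))
  expect_equal(to_grayscale(px)[1, 1], 0)
  px[1, 1, ] <- 1
  expect_equal(to_grayscale(px)[1, 1], 1)
  px[1, 1, ] <- c(1, 0, 0)
  expect_equal(to_grayscale(px)[1, 1], 0.299)
  expect_error(to_grayscale(matrix(0, 2, 2)), "3 channels")
})

test_that("binarize applies the >= rule at the 0.6 default", {
  g <- matrix(c(0.59, 0.60, 0, 1), 2, 2)
  b <- binarize(g, 0.6)
  expect_identical(sort(unique(as.vector(b))), c(0L, 1L))
  expect_identical(b[1, 1], 0L)   # 0.59 below
  expect_identical(b[2, 1], 1L)   # 0.60 at threshold -> foreground
  expect_true(all(binarize(matrix(0, 3, 3), 0.6) == 0L))
  # idempotent on binary input at threshold 0.5
  expect_identical(binarize(b * 1.0, 0.5), b)
  expect_error(binarize(g, 1.2), "threshold")
  expect_error(binarize(matrix(2, 2, 2), 0.5), "\\[0, 1\\]")
})

test_that("corner-touching pixels merge under 8- but not 4-connectivity", {
  b <- matrix(0L, 5, 5)
  b[2, 2] <- 1L; b[3, 3] <- 1L
  expect_identical(label_components(b, 8L)$n, 1L)
  expect_identical(label_components(b, 4L)$n, 2L)
  expect_identical(label_components(matrix(0L, 4, 4), 8L)$n, 0L)
  expect_error(label_components(matrix(2L, 2, 2), 8L), "0 and 1")
})

test_that("two disjoint blocks give two components with correct areas", {
  b <- matrix(0L, 5, 5)
  b[1:2, 1:2] <- 1L
  b[4:5, 4:5] <- 1L
  lc <- label_components(b, 8L)
  expect_identical(lc$n, 2L)
  tab <- measure_regions(lc$labels)
  expect_identical(tab$area, c(4L, 4L))
  expect_identical(c(tab$bbox_r0[1], tab$bbox_c0[1], tab$bbox_r1[1], tab$bbox_c1[1]),
                   c(0L, 0L, 2L, 2L))
})

test_that("8-connected count never exceeds 4-connected count", {
  for (s in 1:20) {
    b <- withr::with_seed(s, matrix(rbinom(400, 1, 0.35), 20, 20))
    expect_lte(label_components(b, 8L)$n, label_components(b, 4L)$n)
  }
})

test_that("region areas always sum to the foreground pixel count", {
  for (s in 1:10) {
    b <- withr::with_seed(100 + s, matrix(rbinom(900, 1, 0.4), 30, 30))
    lc <- label_components(b, 8L)
    tab <- measure_regions(lc$labels)
    expect_identical(sum(tab$area), sum(b))
    expect_true(all(tab$eccentricity >= 0 & tab$eccentricity <= 1))
  }
  expect_identical(nrow(measure_regions(matrix(0L, 3, 3))), 0L)
})

test_that("region table reports areas of mixed-size blocks", {
  b <- matrix(0L, 10, 10)
  b[1:2, 1:2] <- 1L
  b[5:7, 5:7] <- 1L
  tab <- measure_regions(label_components(b, 8L)$labels)
  expect_setequal(tab$area, c(4L, 9L))
  # a thin line is far more eccentric than a square
  line <- matrix(0L, 12, 12); line[6, 2:11] <- 1L
  sq <- matrix(0L, 12, 12); sq[4:9, 4:9] <- 1L
  e_line <- measure_regions(label_components(line, 8L)$labels)$eccentricity
  e_sq <- measure_regions(label_components(sq, 8L)$labels)$eccentricity
  expect_gt(e_line, 0.95)
  expect_lt(e_sq, 0.3)
})

test_that("colorize assigns one distinct color per label, deterministically", {
  b <- matrix(0L, 9, 9)
  for (i in 0:6) b[1 + 2 * (i %% 4), 1 + 2 * (i %/% 4)] <- 1L
  lc <- label_components(b, 8L)
  expect_identical(lc$n, 7L)
  col <- colorize_labels(lc$labels, seed = 3L)
  fg <- which(lc$labels > 0)
  cols <- apply(cbind(col[, , 1][fg], col[, , 2][fg], col[, , 3][fg]), 1,
                paste, collapse = ",")
  expect_length(unique(cols), 7L)
  expect_identical(col, colorize_labels(lc$labels, seed = 3L))
  expect_true(all(colorize_labels(matrix(0L, 4, 4)) == 0))
})

test_that("extract_patch crops the dominant component to the target size", {
  big <- matrix(0, 600, 600)
  big[150:449, 160:459] <- 0.9
  p <- extract_patch(big, preprocess_config())
  expect_identical(dim(p$raster), c(250L, 250L))
  expect_gt(mean(p$raster), 0.85)
  full <- matrix(0.8, 250, 250)
  expect_equal(extract_patch(full)$raster, full, tolerance = 1e-6)
  expect_error(extract_patch(matrix(0, 100, 100)), "empty patch")
})

test_that("augmentation respects the rotation and shift bounds", {
  img <- structure(list(id = "x", raster = matrix(0.5, 250, 250),
                        truth = NULL, provenance = "synthetic"),
                   class = "seed_image")
  draws <- t(vapply(1:1000, function(s) {
    a <- augment(img, augment_config(seed = s))
    c(attr(a, "angle_deg"), attr(a, "shift_px"))
  }, numeric(3)))
  expect_true(all(abs(draws[, 1]) <= 5))
  expect_true(all(abs(draws[, 2:3]) <= 2.5))
  a1 <- augment(img, augment_config(seed = 9L))
  a2 <- augment(img, augment_config(seed = 9L))
  expect_identical(a1$raster, a2$raster)
})

test_that("augment really moves the image by the drawn shift", {
  g <- matrix(0, 100, 100)
  g[40:60, 40:60] <- 1
  img <- structure(list(id = "x", raster = g, truth = NULL,
                        provenance = "synthetic"), class = "seed_image")
  a <- augment(img, augment_config(max_rotation_deg = 0,
                                   shift_fraction = 0.1, seed = 2L))
  sh <- attr(a, "shift_px")
  cm <- function(m) {
    fg <- which(m > 0.5)
    c(mean((fg - 1) %% 100), mean((fg - 1) %/% 100))
  }
  expect_equal(cm(a$raster) - cm(g), sh, tolerance = 0.2)
})

test_that("shuffle_split preserves the multiset and uses the floor rule", {
  ids <- sprintf("i%03d", 1:100)
  sp <- shuffle_split(ids, 0.8, seed = 6L)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- shuffle_split(ids, 0.8, seed = 6L)
  expect_identical(sp, sp2)
  expect_error(shuffle_split(list(1), 0.5), "at least 2")
  expect_error(shuffle_split(ids, 1.2), "train_fraction")
})

test_that("vectorize length depends only on representation and config", {
  wc <- wall_class("U", "granule")
  rep1 <- compute_representations(generate_image(wc, default_texture_params(wc, seed = 1L)))
  rep2 <- compute_representations(generate_image(wc, default_texture_params(wc, seed = 2L)))
  cfg64 <- preprocess_config(downsample_side = 64)
  expect_length(vectorize(rep1, "grayscale", cfg64), 4096L)
  expect_length(vectorize(rep2, "grayscale", cfg64), 4096L)
  expect_length(vectorize(rep1, "colored", cfg64), 10L)
  # constant raster -> constant vector; no components -> all-zero summary
  flat <- structure(list(image_id = "flat", grayscale = matrix(0.4, 250, 250),
                         binary = matrix(0L, 250, 250),
                         labels = matrix(0L, 250, 250), n_components = 0L,
                         colored = array(0, c(250, 250, 3)),
                         region_table = measure_regions(matrix(0L, 250, 250))),
                    class = "representation_set")
  expect_equal(vectorize(flat, "grayscale", cfg64), rep(0.4, 4096),
               tolerance = 1e-12)
  expect_identical(vectorize(flat, "colored", cfg64), numeric(10))
})
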