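test_that("contingency table matches the hand count and its marginals", {
  ra <- make_run(c(0, 0, 1, 1), 2, "A")
  rb <- make_run(c(0, 1, 1, 1), 2, "B")
  tab <- contingency_table(ra, rb)
  expect_identical(unname(tab), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  # identical partitions -> diagonal up to permutation
  tab2 <- contingency_table(ra, ra)
  expect_identical(unname(sort(diag(tab2))), sort(as.integer(rowSums(tab2))))
  expect_error(contingency_table(ra, make_run(c(0, 1), 2, "C", ids = c("a", "b"))),
               "same image set")
})

test_that("contingency marginal identities hold on random partitions", {
  for (s in 1:30) {
    n <- withr::with_seed(s, sample(8:20, 1))
    la <- withr::with_seed(s + 40, sample(0:2, n, replace = TRUE))
    lb <- withr::with_seed(s + 80, sample(0:3, n, replace = TRUE))
    ra <- make_run(la, 3, "A"); rb <- make_run(lb, 4, "B")
    tab <- contingency_table(ra, rb)
    expect_identical(sum(tab), n)
    expect_identical(as.integer(rowSums(tab)), as.integer(tabulate(la + 1L, 3)))
    expect_identical(as.integer(colSums(tab)), as.integer(tabulate(lb + 1L, 4)))
  }
})

test_that("jaccard categories follow the documented thresholds", {
  cfg <- overlap_config(report_floor = 0L)
  tab <- matrix(c(95L, 5L, 5L, 0L), 2, 2)   # sizes 100/100, overlap 95
  rel <- classify_relations(tab, cfg, "A", "B")
  r11 <- rel[rel$cluster_a == 0 & rel$cluster_b == 0, ]
  expect_equal(r11$jaccard, 95 / 105, tolerance = 1e-12)
  expect_identical(r11$category, "identical")
  tab2 <- matrix(c(80L, 20L, 20L, 0L), 2, 2)   # overlap 80 of 100/100
  r2 <- classify_relations(tab2, cfg, "A", "B")
  expect_identical(r2$category[r2$cluster_a == 0 & r2$cluster_b == 0], "related")
  tab3 <- matrix(c(60L, 40L, 40L, 0L), 2, 2)   # overlap 60 of 100/100
  r3 <- classify_relations(tab3, cfg, "A", "B")
  expect_identical(r3$category[r3$cluster_a == 0 & r3$cluster_b == 0], "none")
  # perfect identity
  expect_identical(classify_relations(diag(c(10L, 10L)), cfg)$category,
                   c("identical", "identical"))
})

test_that("separation ranks overlaps in descending count", {
  tab <- matrix(c(50L, 0L, 30L, 0L, 0L, 10L), 2, 3)
  rel <- classify_relations(tab, overlap_config(report_floor = 0L), "A", "B")
  a0 <- rel[rel$cluster_a == 0, ]
  expect_identical(a0$separation[order(a0$cluster_b)], c(1L, 2L))
})

test_that("relations are symmetric and monotone under config changes", {
  for (s in 1:20) {
    n <- 40L
    la <- withr::with_seed(s, sample(0:2, n, replace = TRUE))
    lb <- withr::with_seed(s + 99, sample(0:2, n, replace = TRUE))
    ra <- make_run(la, 3, "A"); rb <- make_run(lb, 3, "B")
    cfg <- overlap_config(tau_identical = 0.8, tau_related = 0.3,
                          report_floor = 0L)
    fwd <- classify_relations(contingency_table(ra, rb), cfg, "A", "B")
    bwd <- classify_relations(contingency_table(rb, ra), cfg, "B", "A")
    key_f <- paste(fwd$cluster_a, fwd$cluster_b)
    key_b <- paste(bwd$cluster_b, bwd$cluster_a)
    expect_setequal(key_f, key_b)
    m <- match(key_f, key_b)
    expect_equal(fwd$jaccard, bwd$jaccard[m])
    expect_identical(fwd$category, bwd$category[m])
    # raising tau_identical only demotes, never promotes
    stricter <- classify_relations(contingency_table(ra, rb),
                                   overlap_config(0.95, 0.3, 0L), "A", "B")
    was_none <- fwd$category == "none"
    expect_true(all(stricter$category[was_none] == "none"))
    # raising the floor only removes rows
    floored <- classify_relations(contingency_table(ra, rb),
                                  overlap_config(0.8, 0.3, 5L), "A", "B")
    expect_true(all(paste(floored$cluster_a, floored$cluster_b) %in% key_f))
  }
})

test_that("threads require three distinct runs and chain through relations", {
  rel <- data.frame(
    run_a = c("EG", "EC"), cluster_a = c(0L, 0L),
    run_b = c("EC", "SC"), cluster_b = c(0L, 0L),
    overlap = c(10L, 10L), size_a = c(10L, 10L), size_b = c(10L, 10L),
    jaccard = c(1, 1), separation = c(1L, 1L),
    category = c("identical", "identical"))
  th <- find_threads(rel)
  expect_length(th, 1L)
  expect_identical(th[[1]]$runs_spanned, 3L)
  expect_identical(nrow(th[[1]]$nodes), 3L)
  expect_setequal(th[[1]]$nodes$run, c("EG", "EC", "SC"))
  expect_length(find_threads(rel[0, ]), 0L)
  # relations confined to two runs never form a thread
  rel2 <- rel[1, ]
  expect_length(find_threads(rel2), 0L)
  # category "none" edges don't count
  rel3 <- rel; rel3$category <- "none"
  expect_length(find_threads(rel3), 0L)
})

test_that("agreement grouping handles the canonical edge cases", {
  n <- 9L
  base <- rep(0:2, each = 3)
  six_same <- lapply(1:6, function(i) make_run(base, 3, paste0("R", i)))
  ag <- agreement_grouping(six_same)
  expect_true(all(ag$assignment == "SI"))
  expect_identical(unname(ag$counts["SI"]), n)
  expect_identical(sum(ag$counts), n)
  # five identical runs plus an all-singletons run -> everyone at SS
  five_plus <- c(six_same[1:5],
                 list(make_run(0:(n - 1), n, "R6")))
  ag2 <- agreement_grouping(five_plus)
  expect_true(all(ag2$assignment == "SS"))
  expect_error(agreement_grouping(six_same[1:5]), "exactly 6")
})

test_that("agreement levels equal the exhaustive subset oracle", {
  for (s in 1:35) {
    n <- withr::with_seed(s, sample(6:12, 1))
    run_labels <- withr::with_seed(s + 300, lapply(1:6, function(i)
      sample(0:2, n, replace = TRUE)))
    runs <- lapply(1:6, function(i) make_run(run_labels[[i]], 3, paste0("R", i),
                                             ids = sprintf("im%02d", 1:n)))
    ag <- agreement_grouping(runs)
    for (i in seq_len(n))
      expect_identical(ag$level[i], brute_agreement_level(run_labels, i))
    expect_identical(sum(ag$counts), n)
  }
})

test_that("perturbing runs never increases the SI count", {
  n <- 30L
  base <- rep(0:2, each = 10)
  for (s in 1:5) {
    prev_si <- n
    for (frac in c(0, 0.1, 0.3, 0.6)) {
      runs <- lapply(1:6, function(i) {
        lab <- base
        n_flip <- round(frac * n)
        if (n_flip > 0) {
          idx <- withr::with_seed(s * 100 + i, sample.int(n, n_flip))
          lab[idx] <- withr::with_seed(s * 100 + i + 50,
                                       sample(0:2, n_flip, replace = TRUE))
        }
        make_run(lab, 3, paste0("R", i), ids = sprintf("im%02d", 1:n))
      })
      si <- agreement_grouping(runs)$counts[["SI"]]
      expect_lte(si, prev_si)
      prev_si <- si
    }
  }
})

test_that("combination counts follow the closed form", {
  expect_identical(combination_count(6, 2), 15)
  expect_identical(combination_count(5, 2), 10)
  expect_identical(combination_count(7, 7), 1)
  expect_identical(combination_count(4, 0), 1)
  expect_error(combination_count(3, 5), "k <= n")
  expect_error(combination_count(-1, 0), "k <= n")
})

test_that("adjusted Rand index matches the reference implementation", {
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  for (s in 1:20) {
    a <- withr::with_seed(s, sample(1:4, 25, replace = TRUE))
    b <- withr::with_seed(s + 77, sample(1:3, 25, replace = TRUE))
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("pairwise_relations emits C(m,2) tables", {
  runs <- lapply(1:4, function(i)
    make_run(withr::with_seed(i, sample(0:1, 12, replace = TRUE)), 2,
             paste0("R", i), ids = sprintf("im%02d", 1:12)))
  names(runs) <- paste0("R", 1:4)
  pw <- pairwise_relations(runs, overlap_config(report_floor = 0L))
  expect_length(pw$tables, combination_count(4, 2))
})

test_that("compare_to_human mirrors a perfectly recovered axis", {
  n <- 24L
  truth <- c(lapply(1:12, function(i) wall_class("straight", "granule")),
             lapply(1:12, function(i) wall_class("omega", "small_verrucae")))
  machine <- make_run(rep(c(0L, 1L), each = 12), 2, "EG",
                      ids = sprintf("im%02d", 1:n))
  out <- compare_to_human(list(EG = machine), truth,
                          overlap_config(report_floor = 0L))
  ant <- out$anticlinal$relations
  expect_true(all(ant$jaccard[ant$overlap == 12] == 1))
  expect_true(all(ant$category[ant$overlap == 12] == "identical"))
  expect_true(all(c("truth_class", "separation", "category") %in% names(ant)))
  # random labels over balanced truth produce no identical relations
  rnd <- make_run(withr::with_seed(5L, sample(0:1, n, replace = TRUE)), 2,
                  "EG", ids = sprintf("im%02d", 1:n))
  out2 <- compare_to_human(list(EG = rnd), truth, overlap_config(report_floor = 0L))
  expect_false(any(out2$anticlinal$relations$category == "identical"))
})
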