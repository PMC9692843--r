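#' Overlap-analysis configuration
#'
#' "Identical" and "related" cluster pairs are operationalized by Jaccard
#' thresholds on the shared-image overlap; `report_floor` is the minimum
#' overlap count worth reporting (higher tiers such as 1000-2000 or >2000 are
#' report filters applied downstream, not algorithm changes).
#'
#' @param tau_identical Jaccard at or above which a pair is `identical`.
#' @param tau_related Jaccard at or above which (but below `tau_identical`)
#'   a pair is `related`.
#' @param report_floor Minimum overlap image count for a relation to be
#'   reported (default 500).
#' @return An `overlap_config` list.
#' @export
overlap_config <- function(tau_identical = 0.9, tau_related = 0.5,
                           report_floor = 500L) {
  if (!(tau_related > 0 && tau_related < tau_identical && tau_identical <= 1))
    stop("need 0 < tau_related < tau_identical <= 1", call. = FALSE)
  .check_scalar(report_floor, "report_floor", 0)
  structure(list(tau_identical = tau_identical, tau_related = tau_related,
                 report_floor = as.integer(report_floor)),
            class = "overlap_config")
}

#' Cluster-by-cluster overlap table of two runs
#'
#' @param run_a,run_b `clustering_run` objects over the same image set.
#' @return `kA x kB` integer matrix; cell `(i, j)` counts the images in
#'   cluster `i-1` of A and cluster `j-1` of B. Row/column sums equal the
#'   cluster sizes and the total equals n.
#' @export
contingency_table <- function(run_a, run_b) {
  if (!identical(run_a$ids, run_b$ids))
    stop("runs must label the same image set", call. = FALSE)
  tab <- table(factor(run_a$labels, levels = 0:(run_a$k - 1L)),
               factor(run_b$labels, levels = 0:(run_b$k - 1L)))
  m <- matrix(as.integer(tab), run_a$k, run_b$k)
  dimnames(m) <- list(paste0("C", seq_len(run_a$k)),
                      paste0("C", seq_len(run_b$k)))
  m
}

#' Classify cluster-pair overlap relations
#'
#' For every cell of the contingency table with overlap at or above the
#' report floor, computes the Jaccard similarity
#' `overlap / (size_a + size_b - overlap)` and categorizes the pair:
#' `identical` at or above `tau_identical`, `related` between `tau_related`
#' and `tau_identical`, otherwise `none`. The separation index ranks each
#' cluster's reported overlaps in descending count (ties by ascending partner
#' cluster index), mirroring the method/cluster/separation naming of the
#' relation notation.
#'
#' @param tab Contingency table from [contingency_table].
#' @param config An [overlap_config].
#' @param code_a,code_b Run codes used in the output.
#' @return Data frame: `run_a`, `cluster_a`, `run_b`, `cluster_b`, `overlap`,
#'   `size_a`, `size_b`, `jaccard`, `separation`, `category`. Cluster indices
#'   are 0-based.
#' @export
classify_relations <- function(tab, config = overlap_config(),
                               code_a = "A", code_b = "B") {
  size_a <- rowSums(tab); size_b <- colSums(tab)
  cells <- which(tab > 0 & tab >= config$report_floor, arr.ind = TRUE)
  if (nrow(cells) == 0L)
    return(data.frame(run_a = character(0), cluster_a = integer(0),
                      run_b = character(0), cluster_b = integer(0),
                      overlap = integer(0), size_a = integer(0),
                      size_b = integer(0), jaccard = numeric(0),
                      separation = integer(0), category = character(0)))
  ov <- tab[cells]
  sa <- size_a[cells[, 1]]; sb <- size_b[cells[, 2]]
  jac <- ov / (sa + sb - ov)
  category <- ifelse(jac >= config$tau_identical, "identical",
                     ifelse(jac >= config$tau_related, "related", "none"))
  out <- data.frame(run_a = code_a, cluster_a = cells[, 1] - 1L,
                    run_b = code_b, cluster_b = cells[, 2] - 1L,
                    overlap = as.integer(ov), size_a = as.integer(sa),
                    size_b = as.integer(sb), jaccard = jac,
                    separation = NA_integer_, category = category,
                    row.names = NULL)
  # separation: rank of the cell among its A-cluster's reported overlaps
  for (i in unique(out$cluster_a)) {
    sel <- out$cluster_a == i
    o <- order(-out$overlap[sel], out$cluster_b[sel])
    out$separation[sel][o] <- seq_len(sum(sel))
  }
  out
}

#' All pairwise overlap tables and relations for a set of runs
#'
#' @param runs Named list of `clustering_run` objects.
#' @param config An [overlap_config].
#' @return List with `tables` (one contingency table per unordered run pair,
#'   `combination_count(m, 2)` of them), and `relations` (row-bound
#'   classification of every pair).
#' @export
pairwise_relations <- function(runs, config = overlap_config()) {
  codes <- names(runs)
  tables <- list()
  rel <- list()
  if (length(codes) >= 2L) {
    for (i in seq_len(length(codes) - 1L)) {
      for (j in (i + 1L):length(codes)) {
        tab <- contingency_table(runs[[i]], runs[[j]])
        key <- paste(codes[i], codes[j], sep = "_")
        tables[[key]] <- tab
        rel[[key]] <- classify_relations(tab, config, codes[i], codes[j])
      }
    }
  }
  list(tables = tables, relations = do.call(rbind, c(rel, list(make.row.names = FALSE))))
}

#' Find threads: relation chains spanning three or more runs
#'
#' Builds the graph whose nodes are `(run, cluster)` pairs and whose edges
#' are the relations with category other than `none`, then enumerates maximal
#' simple paths whose nodes all come from distinct runs and that span at
#' least 3 runs. Each thread is reported once, endpoints in canonical order.
#'
#' @param relations Relation data frame from [classify_relations] /
#'   [pairwise_relations].
#' @return List of threads; each has `nodes` (data frame `run`, `cluster`)
#'   and `runs_spanned`.
#' @export
find_threads <- function(relations) {
  rel <- relations[relations$category != "none", , drop = FALSE]
  if (is.null(rel) || nrow(rel) == 0L) return(list())
  node_key <- function(run, cl) paste0(run, "-C", cl + 1L)
  a <- node_key(rel$run_a, rel$cluster_a)
  b <- node_key(rel$run_b, rel$cluster_b)
  nodes <- sort(unique(c(a, b)))
  run_of <- c(stats::setNames(rel$run_a, a), stats::setNames(rel$run_b, b))
  run_of <- run_of[nodes]
  adj <- lapply(stats::setNames(nodes, nodes), function(nd)
    sort(unique(c(b[a == nd], a[b == nd]))))
  threads <- new.env()
  seen <- new.env()   # states keyed by (sorted node set, unordered endpoints):
                      # possible extensions depend only on that state
  extend <- function(path) {
    ends <- sort(c(path[1], path[length(path)]))
    state <- paste(c(sort(path), "|", ends), collapse = "&")
    if (!is.null(seen[[state]])) return(invisible())
    seen[[state]] <- TRUE
    used_runs <- run_of[path]
    nxt <- setdiff(adj[[path[length(path)]]], path)
    nxt <- nxt[!(run_of[nxt] %in% used_runs)]
    front <- setdiff(adj[[path[1]]], path)
    front <- front[!(run_of[front] %in% used_runs)]
    if (length(nxt) == 0L && length(front) == 0L) {
      if (length(unique(used_runs)) >= 3L) {
        canon <- if (path[1] <= path[length(path)]) path else rev(path)
        key <- paste(sort(path), collapse = "|")   # one thread per node set
        if (is.null(threads[[key]])) threads[[key]] <- canon
      }
      return(invisible())
    }
    for (v in nxt) extend(c(path, v))
    for (v in front) extend(c(v, path))
  }
  for (nd in nodes) extend(nd)
  out <- lapply(sort(ls(threads)), function(k) {
    p <- threads[[k]]
    parts <- regmatches(p, regexec("^(.*)-C([0-9]+)$", p))
    data <- data.frame(run = vapply(parts, `[`, character(1), 2),
                       cluster = as.integer(vapply(parts, `[`, character(1), 3)) - 1L)
    list(nodes = data, runs_spanned = length(unique(data$run)))
  })
  out
}

#' Six-level agreement grouping across the proposed runs
#'
#' For image i and run r let `mates_r(i)` be the set of images sharing i's
#' cluster in r (excluding i itself). The agreement level of i is the size of
#' the largest set of runs whose mates sets for i are pairwise identical
#' (set equality is transitive, so this is the largest multiplicity among the
#' six mates sets). Levels map to groups: 6 = SI (strongly identical),
#' 5 = SS, 4 = SM, 3 = NS, 2 = PS, 1 = PD (possibly different).
#'
#' @param runs Exactly six `clustering_run` objects over the same images.
#' @return An `agreement_partition`: `assignment` (per-image group),
#'   `level` (per-image 1..6), `counts` (named SI..PD, summing to n), `ids`.
#' @export
agreement_grouping <- function(runs) {
  if (length(runs) != 6L)
    stop("agreement grouping needs exactly 6 runs", call. = FALSE)
  ids <- runs[[1]]$ids
  for (r in runs)
    if (!identical(r$ids, ids))
      stop("runs must label the same image set", call. = FALSE)
  n <- length(ids)
  group_names <- c("PD", "PS", "NS", "SM", "SS", "SI")   # level 1..6
  keys <- matrix("", n, 6L)
  for (j in seq_len(6L)) {
    labs <- runs[[j]]$labels
    members <- split(seq_len(n), labs)
    for (mem in members) {
      all_key <- paste(mem, collapse = ",")
      for (i in mem) {
        keys[i, j] <- if (length(mem) == 1L) ""   # empty mates set
          else paste(setdiff(mem, i), collapse = ",")
      }
    }
  }
  level <- vapply(seq_len(n), function(i) max(table(keys[i, ])), integer(1))
  group <- group_names[level]
  counts <- stats::setNames(integer(6), c("SI", "SS", "SM", "NS", "PS", "PD"))
  tb <- table(group)
  counts[names(tb)] <- as.integer(tb)
  structure(list(assignment = group, level = as.integer(level),
                 counts = counts, ids = ids),
            class = "agreement_partition")
}

#' Number of unordered selections (binomial coefficient)
#'
#' `C(n, k) = n! / (k! (n - k)!)`; with k = 2 this is the number of pairwise
#' comparison tables for n runs.
#'
#' @param n Set size (>= 0).
#' @param k Selection size, `0 <= k <= n`.
#' @return The count as a numeric scalar.
#' @export
combination_count <- function(n, k) {
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  round(choose(n, k))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table of the two partitions.
#'
#' @param labels_a,labels_b Equal-length cluster assignments.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Compare machine runs against the human annotation axes
#'
#' Treats each annotation axis (anticlinal wall type; periclinal wall type)
#' as a reference partition and runs the overlap analysis — contingency
#' table, relation classification, thread search — of every machine run
#' against it.
#'
#' @param runs Named list of `clustering_run` objects.
#' @param truth List of [wall_class] objects, one per image (in run order).
#' @param config An [overlap_config].
#' @return List with one element per axis, each holding `relations` (one row
#'   per truth class / run / cluster / separation) and `threads`.
#' @export
compare_to_human <- function(runs, truth, config = overlap_config()) {
  if (length(truth) != length(runs[[1]]$ids))
    stop("truth labels must cover every image", call. = FALSE)
  ids <- runs[[1]]$ids
  out <- list()
  for (axis in c("anticlinal", "periclinal")) {
    cls <- vapply(truth, `[[`, character(1), axis)
    lv <- unique(cls)
    ref <- clustering_run(paste0("H_", axis), "human", axis, length(lv),
                          as.integer(factor(cls, levels = lv)) - 1L, ids)
    rel <- list()
    for (code in names(runs)) {
      tab <- contingency_table(ref, runs[[code]])
      rownames(tab) <- lv
      r <- classify_relations(tab, config, paste0("H_", axis), code)
      r$truth_class <- lv[r$cluster_a + 1L]
      rel[[code]] <- r
    }
    relations <- do.call(rbind, c(rel, list(make.row.names = FALSE)))
    out[[axis]] <- list(relations = relations,
                        threads = find_threads(relations))
  }
  out
}
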