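#' Pipeline configuration
#'
#' Exactly one dataset source: `class_spec` (synthetic generation) or
#' `image_dir` (PNG ingestion, patches extracted and normalized to 250x250).
#'
#' @param class_spec Synthetic class specification for [generate_dataset].
#' @param image_dir Directory of PNG images to ingest instead.
#' @param preprocess A [preprocess_config].
#' @param augment An [augment_config].
#' @param battery A [battery_config].
#' @param overlap An [overlap_config].
#' @param k_grid Cluster-count grid scanned per representation.
#' @param train_fraction Recorded shuffle split fraction.
#' @param master_seed Master seed; every stochastic stage derives its own
#'   seed from it by stable stage-name hashing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(class_spec = NULL, image_dir = NULL,
                            preprocess = preprocess_config(),
                            augment = augment_config(),
                            battery = battery_config(),
                            overlap = overlap_config(),
                            k_grid = 2:10, train_fraction = 0.8,
                            master_seed = 1L) {
  if (is.null(class_spec) == is.null(image_dir))
    stop("provide exactly one of `class_spec` or `image_dir`", call. = FALSE)
  structure(list(class_spec = class_spec, image_dir = image_dir,
                 preprocess = preprocess, augment = augment,
                 battery = battery, overlap = overlap, k_grid = k_grid,
                 train_fraction = train_fraction,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate or ingest -> preprocess into three representations -> select k by
#' elbow and silhouette per representation -> run the five-method battery and
#' the six proposed runs -> pairwise overlap analysis, threads and agreement
#' grouping -> report. Bit-reproducible for a fixed `master_seed`.
#'
#' @param config A [pipeline_config].
#' @return A `run_report` list: `images`, `features`, `selection`, `runs`,
#'   `consensus` (tables, relations, threads, agreement), `human` (if truth
#'   labels exist), `split_ids`, `n_tables`, `config`, `version`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ms <- config$master_seed
  log <- character(0)
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%s] %s", stage, msg))
  }

  # 1. dataset
  if (!is.null(config$class_spec)) {
    images <- generate_dataset(config$class_spec, seed = derive_seed(ms, "generate"))
    note("generate", sprintf("generated %d synthetic images", length(images)))
  } else {
    images <- read_images(config$image_dir, config$preprocess)
    note("ingest", sprintf("read %d images from %s", length(images), config$image_dir))
  }
  ids <- vapply(images, `[[`, character(1), "id")

  # 2. representations + features
  features <- build_features(images, config$preprocess,
                             color_seed = derive_seed(ms, "colorize"))
  note("preprocess", sprintf("3 representations over %d images", length(images)))

  # 3. recorded shuffle split (consensus runs on the full original set)
  split <- shuffle_split(ids, config$train_fraction, derive_seed(ms, "shuffle"))
  note("shuffle", sprintf("train %d / test %d", length(split$train), length(split$test)))

  # 4. k selection per representation
  selection <- list()
  for (rp in c("grayscale", "threshold", "colored")) {
    selection[[rp]] <- choose_k(features[[rp]], k_grid = config$k_grid,
                                restarts = config$battery$restarts,
                                seed = derive_seed(ms, paste0("select-", rp)),
                                representation = rp)
    note("select-k", sprintf("%s: k_elbow=%d k_silhouette=%d", rp,
                             selection[[rp]]$k_elbow, selection[[rp]]$k_silhouette))
  }

  # 5. battery
  bat <- config$battery
  bat$master_seed <- derive_seed(ms, "battery")
  runs <- run_battery(features, bat, selection)
  note("cluster", sprintf("%d runs: %s", length(runs),
                          paste(names(runs), collapse = " ")))

  # 6. consensus over the six proposed runs
  proposed <- runs[c("EG", "SG", "ET", "ST", "EC", "SC")]
  pw <- pairwise_relations(proposed, config$overlap)
  threads <- find_threads(pw$relations)
  agreement <- agreement_grouping(proposed)
  note("consensus", sprintf("%d tables, %d relations, %d threads",
                            length(pw$tables),
                            if (is.null(pw$relations)) 0L else nrow(pw$relations),
                            length(threads)))

  # 7. comparison with human annotation, when truth labels exist
  truth <- lapply(images, `[[`, "truth")
  human <- NULL
  if (!any(vapply(truth, is.null, logical(1)))) {
    human <- compare_to_human(runs, truth, config$overlap)
    note("human", "compared runs against anticlinal and periclinal axes")
  }

  structure(list(images = images, features = features, selection = selection,
                 runs = runs,
                 consensus = list(tables = pw$tables, relations = pw$relations,
                                  threads = threads, agreement = agreement),
                 human = human, split_ids = split,
                 n_tables = length(pw$tables),
                 config = config,
                 version = as.character(utils::packageVersion("testaclust")),
                 log = log),
            class = "run_report")
}

#' Write a pipeline report to disk
#'
#' Emits machine-readable CSV tables (k-selection curves, run manifest and
#' labels, relations, agreement partition), a JSON summary with the six-group
#' agreement counts and the run-code manifest, and a per-stage log.
#' Idempotent: re-writing the same report produces identical files.
#'
#' @param report A `run_report` from [run_pipeline].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create ", output_dir, call. = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  curves <- do.call(rbind, lapply(report$selection, function(s)
    data.frame(representation = s$representation, k = s$k_grid,
               sse = s$sse, silhouette = s$silhouette)))
  wr(curves, "k_selection_curves.csv")
  manifest <- do.call(rbind, lapply(report$runs, function(r)
    data.frame(code = r$code, method = r$method,
               representation = r$representation,
               criterion = r$criterion, k = r$k, seed = r$seed)))
  wr(manifest, "run_manifest.csv")
  labels <- do.call(rbind, lapply(report$runs, function(r)
    data.frame(image_id = r$ids, code = r$code, label = r$labels)))
  wr(labels, "run_labels.csv")
  rel <- report$consensus$relations
  if (is.null(rel)) rel <- data.frame()
  wr(rel, "relations.csv")
  ag <- report$consensus$agreement
  wr(data.frame(image_id = ag$ids, level = ag$level, group = ag$assignment),
     "agreement_partition.csv")
  threads_js <- lapply(report$consensus$threads, function(th)
    list(runs_spanned = th$runs_spanned,
         nodes = sprintf("%s-C%d", th$nodes$run, th$nodes$cluster + 1L)))
  summary <- list(
    n_images = length(report$images),
    group_counts = as.list(ag$counts),
    run_codes = names(report$runs),
    selected_k = lapply(report$selection, function(s)
      list(elbow = s$k_elbow, silhouette = s$k_silhouette)),
    n_tables = report$n_tables,
    threads = threads_js,
    version = report$version,
    master_seed = report$config$master_seed,
    overlap = unclass(report$config$overlap))
  p <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(output_dir, "pipeline.log")
  writeLines(report$log, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write seed images as 8-bit grayscale PNGs plus a label CSV
#'
#' @param images List of `seed_image` objects.
#' @param dir Output directory.
#' @return Invisibly, the label data frame (id, anticlinal, periclinal).
#' @export
write_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- data.frame(id = character(0), anticlinal = character(0),
                     periclinal = character(0))
  for (im in images) {
    png::writePNG(im$raster, file.path(dir, paste0(im$id, ".png")))
    tr <- im$truth
    labs <- rbind(labs, data.frame(
      id = im$id,
      anticlinal = if (is.null(tr)) NA_character_ else tr$anticlinal,
      periclinal = if (is.null(tr)) NA_character_ else tr$periclinal))
  }
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(labs)
}

#' Read a directory of PNG images as normalized seed patches
#'
#' Each image is converted to grayscale if needed; images not already at
#' `crop_size` are passed through [extract_patch]. If a `labels.csv` with
#' columns id, anticlinal, periclinal is present, truth labels are attached.
#'
#' @param dir Directory containing `.png` files.
#' @param config A [preprocess_config].
#' @return List of `seed_image` objects.
#' @export
read_images <- function(dir, config = preprocess_config()) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG images in ", dir, call. = FALSE)
  labs <- NULL
  labfile <- file.path(dir, "labels.csv")
  if (file.exists(labfile)) labs <- utils::read.csv(labfile)
  lapply(files, function(f) {
    raw <- png::readPNG(f)
    gray <- if (length(dim(raw)) == 3L) to_grayscale(raw[, , 1:3]) else raw
    id <- sub("\\.png$", "", basename(f))
    if (!all(dim(gray) == config$crop_size)) {
      im <- extract_patch(gray, config)
    } else {
      im <- structure(list(id = id, raster = gray, truth = NULL,
                           provenance = "external"), class = "seed_image")
    }
    im$id <- id
    if (!is.null(labs) && id %in% labs$id) {
      row <- labs[labs$id == id, ]
      if (!is.na(row$anticlinal[1]))
        im$truth <- wall_class(row$anticlinal[1], row$periclinal[1])
    }
    im
  })
}
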