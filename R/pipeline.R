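#' Default run configuration for the end-to-end pipeline
#'
#' One nested configuration with per-stage namespaces (simulate, windows,
#' model, train, evaluate, features) and a single global seed from which
#' every stage seed is derived deterministically. Defaults are the published
#' operating point scaled to the synthetic stated world: 10 kb resolution,
#' 64-bin windows (auto stride window_bins/16), batch 128, learning rate
#' 0.01.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return nested config list.
#' @export
defaultRunConfig <- function(seed = 1L, out_dir = "siamesehic_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_bins = 1000L, resolution = 10000, alpha = 1,
                    depth = 1e6, replicates = 2L,
                    conditions = c("A", "B"), planted = TRUE),
    windows = list(window_bins = 64L, stride_bp = NULL),
    model = list(mask_bins = 3L, embed_dim = 8L),
    train = list(lr = 0.01, batch_size = 128L, margin = 1,
                 loss_weights = c(2, 1), min_epochs = 5L, stop_rise = 0.10,
                 max_epochs = 30L),
    evaluate = list(eval_split = "test"),
    features = list(pct = 95, k = 10L, min_span = 5e4, max_span = 2.56e6)
  )
}

#' Read / merge a JSON run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. The merged config round-trips through JSON unchanged.
#'
#' @param path JSON config path (\code{NULL} = pure defaults).
#' @param seed seed overriding the config's.
#' @return nested config list.
#' @export
readRunConfig <- function(path = NULL, seed = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

runManifest <- function(cfg, stage, inputs = character(0)) {
  list(stage = stage, seed = cfg$seed,
       config = cfg[setdiff(names(cfg), "out_dir")],
       inputs = lapply(inputs, function(p) {
         list(path = p, size = file.info(p)$size)
       }),
       package_version = as.character(utils::packageVersion("SiameseHiC")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Pipeline stage: simulate a synthetic experiment to disk
#'
#' Writes one dense-text contact matrix per condition/replicate/chromosome
#' plus \code{truth_table.json} and a stage manifest.
#'
#' @param cfg run config from \code{\link{readRunConfig}}.
#' @return the generated experiment, invisibly.
#' @export
runSimulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$simulate
  n <- as.integer(sc$n_bins)
  syn <- syntheticConfig(
    chroms = c(chr1 = n, chr18 = n, chr2 = n),
    resolution = sc$resolution, alpha = sc$alpha, depth = sc$depth,
    diff_features = if (isTRUE(sc$planted)) NULL else list(),
    seed = cfg$seed)
  exp <- generateExperiment(syn, conditions = sc$conditions,
                            replicates = sc$replicates)
  for (cond in names(exp$matrices)) {
    for (r in names(exp$matrices[[cond]])) {
      for (ch in names(exp$matrices[[cond]][[r]])) {
        writeContactMatrix(exp$matrices[[cond]][[r]][[ch]],
                           file.path(cfg$out_dir,
                                     sprintf("%s_%s_%s.matrix.tsv",
                                             cond, r, ch)))
      }
    }
  }
  jsonlite::write_json(exp$truth, file.path(cfg$out_dir, "truth_table.json"),
                       digits = NA)
  writeManifest(runManifest(cfg, "simulate"),
                file.path(cfg$out_dir, "simulate.manifest.json"))
  invisible(exp)
}

#' Pipeline stage: extract, filter, clean and pair windows
#'
#' Reads every simulated matrix from the run directory, windows it, and
#' writes the pooled pair set (\code{pairs.rds}) with a JSON manifest
#' listing pair counts per split.
#'
#' @param cfg run config.
#' @return the \code{\link{WindowPairs}}, invisibly.
#' @export
runExtract <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "\\.matrix\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no matrices in ", cfg$out_dir, "; run the simulate stage first")
  }
  parts <- list()
  for (f in files) {
    nm <- sub("\\.matrix\\.tsv$", "", basename(f))
    bits <- strsplit(nm, "_")[[1]]
    cm <- readContactMatrix(f)
    w <- extractWindows(cm, window_bins = cfg$windows$window_bins,
                        stride_bp = cfg$windows$stride_bp,
                        condition = bits[1], replicate = bits[2])
    parts[[length(parts) + 1L]] <- cleanWindows(filterWindows(w))
  }
  windows <- do.call(c, parts)
  pairs <- makePairs(windows)
  saveRDS(pairs, file.path(cfg$out_dir, "pairs.rds"))
  counts <- table(split = pairs@split, label = pairs@label)
  man <- runManifest(cfg, "extract", files)
  man$pair_counts <- as.list(as.data.frame(counts))
  writeManifest(man, file.path(cfg$out_dir, "extract.manifest.json"))
  invisible(pairs)
}

#' Pipeline stage: train the twin network
#'
#' @param cfg run config.
#' @return list(model, history), invisibly; writes \code{checkpoint.rds}
#'   and \code{history.tsv}.
#' @export
runTrain <- function(cfg) {
  ppath <- file.path(cfg$out_dir, "pairs.rds")
  if (!file.exists(ppath)) {
    stop("no pair set in ", cfg$out_dir, "; run the extract stage first")
  }
  pairs <- readRDS(ppath)
  mcfg <- modelConfig(window_bins = pairs@windows@windowBins,
                      mask_bins = cfg$model$mask_bins,
                      embed_dim = cfg$model$embed_dim)
  tcfg <- do.call(trainConfig, c(cfg$train, list(seed = cfg$seed)))
  fit <- trainSiamese(pairs, mcfg, tcfg)
  saveCheckpoint(fit$model, file.path(cfg$out_dir, "checkpoint.rds"))
  utils::write.table(fit$history, file.path(cfg$out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeManifest(runManifest(cfg, "train", ppath),
                file.path(cfg$out_dir, "train.manifest.json"))
  invisible(fit)
}

#' Pipeline stage: evaluate separation on the held-out split
#'
#' @param cfg run config.
#' @return the \code{\link{SeparationReport}}, invisibly; writes
#'   \code{separation_report.json} and the test distance track.
#' @export
runEvaluate <- function(cfg) {
  pairs <- readRDS(file.path(cfg$out_dir, "pairs.rds"))
  model <- loadCheckpoint(file.path(cfg$out_dir, "checkpoint.rds"))
  report <- separationReport(model, pairs,
                             eval_split = cfg$evaluate$eval_split)
  writeSeparationReport(report,
                        file.path(cfg$out_dir, "separation_report.json"))
  d <- embeddingDistances(model, pairs, cfg$evaluate$eval_split)
  track <- buildDistanceTrack(d, seed = cfg$seed)
  span <- pairs@windows@windowBins * pairs@windows@resolution
  writeDistanceTrack(track, file.path(cfg$out_dir, "distance_track"), span)
  writeManifest(runManifest(cfg, "evaluate"),
                file.path(cfg$out_dir, "evaluate.manifest.json"))
  invisible(report)
}

#' Pipeline stage: extract differential features on the test chromosome
#'
#' @param cfg run config.
#' @return the feature list, invisibly; writes \code{features.bedpe} and
#'   cluster mean images.
#' @export
runFeatures <- function(cfg) {
  pairs <- readRDS(file.path(cfg$out_dir, "pairs.rds"))
  model <- loadCheckpoint(file.path(cfg$out_dir, "checkpoint.rds"))
  test_pairs <- pairsForSplit(pairs, cfg$evaluate$eval_split)
  fx <- extractDifferentialFeatures(
    model, test_pairs, pct = cfg$features$pct, k = cfg$features$k,
    min_span = cfg$features$min_span, max_span = cfg$features$max_span,
    seed = cfg$seed)
  writeFeaturesBEDPE(fx$features, file.path(cfg$out_dir, "features.bedpe"))
  if (!is.null(fx$cluster)) {
    writeClusterMeans(fx$cluster, file.path(cfg$out_dir, "features"))
  }
  man <- runManifest(cfg, "features")
  man$n_features <- nrow(fx$features)
  man$conv_stage <- "stage2 (post-GeLU, post-pool)"
  writeManifest(man, file.path(cfg$out_dir, "features.manifest.json"))
  invisible(fx)
}

#' Run the whole pipeline on synthetic data
#'
#' Chains simulate, extract, train, evaluate and features; with an identical
#' config and seed the run is byte-reproducible.
#'
#' @param cfg run config.
#' @return list with the separation report and features, invisibly.
#' @export
runAll <- function(cfg) {
  runSimulate(cfg)
  runExtract(cfg)
  runTrain(cfg)
  report <- runEvaluate(cfg)
  fx <- runFeatures(cfg)
  invisible(list(report = report, features = fx))
}
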