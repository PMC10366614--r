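#' Default hyper-parameter grids
#'
#' The exploration space used by [runPipeline()]: three distance metrics;
#' neighborhood sizes 5..200 in steps of 5 (40 values) for LE and UMAP;
#' perplexities 5..100 in steps of 5 plus 150, 175, 200; method-specific
#' dimension and learning-rate grids; minimum distance fixed at 0.8.
#'
#' @return named list of grids.
#' @export
defaultGrids <- function() {
  list(metrics = c("euclidean", "correlation", "cosine"),
       knn = seq(5L, 200L, by = 5L),
       perplexity = c(seq(5L, 100L, by = 5L), 150L, 175L, 200L),
       dimsLe = c(2L, 3L, 5L, 10L, 15L, 20L, 25L, 30L),
       dimsTsne = c(2L, 3L, 10L, 15L),
       dimsUmap = c(2L, 3L, 5L, 10L, 15L, 20L, 25L, 30L),
       lrTsne = c(10, 50, 75, 100, 200, 500, 1000),
       lrUmap = c(0.01, 0.1, 1.0),
       minDist = 0.8)
}

#' Pipeline configuration
#'
#' Bundles everything [runPipeline()] needs: the synthetic-dataset
#' configuration, the window specification, the embedding grids, the null
#' models to run, and one master seed from which every stochastic stage
#' derives a named substream.
#'
#' @param syntheticCfg a [syntheticConfig()] (its seed is overridden by
#'   the master seed).
#' @param window a [WindowSpec-class].
#' @param grids hyper-parameter grids as in [defaultGrids()]. The full
#'   default grid is large; trim it for interactive runs.
#' @param methods manifold learners to sweep (subset of LE, TSNE, UMAP).
#' @param nullModels null models to generate ("connectivity", "phase", or
#'   none).
#' @param seed master seed.
#' @param outputDir artifact directory.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(syntheticCfg = syntheticConfig(),
                           window = WindowSpec(),
                           grids = defaultGrids(),
                           methods = c("LE"),
                           nullModels = character(0),
                           seed = 1L,
                           outputDir = tempfile("manifoldFC_run_")) {
  stopifnot(all(methods %in% c("LE", "TSNE", "UMAP")),
            all(nullModels %in% c("connectivity", "phase")),
            all(lengths(grids) > 0L))
  syntheticCfg$seed <- as.integer(seed)
  structure(list(syntheticCfg = syntheticCfg, window = window,
                 grids = grids, methods = methods, nullModels = nullModels,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "PipelineConfig")
}

# named substreams: every stochastic stage gets a fixed offset from the
# master seed (kept < 2^31)
stageSeed <- function(seed, stage) {
  offs <- c(simulate = 0L, connectivity = 101L, phase = 211L, embed = 307L)
  as.integer(seed + offs[[stage]])
}

# expand the per-method grid into a run table
planRuns <- function(config, nScans) {
  g <- config$grids
  plans <- list()
  if ("LE" %in% config$methods)
    plans$LE <- expand.grid(method = "LE", metric = g$metrics, k = g$knn,
                            m = g$dimsLe, lr = NA_real_,
                            stringsAsFactors = FALSE)
  if ("TSNE" %in% config$methods)
    plans$TSNE <- expand.grid(method = "TSNE", metric = g$metrics,
                              k = g$perplexity, m = g$dimsTsne, lr = g$lrTsne,
                              stringsAsFactors = FALSE)
  if ("UMAP" %in% config$methods)
    plans$UMAP <- expand.grid(method = "UMAP", metric = g$metrics, k = g$knn,
                              m = g$dimsUmap, lr = g$lrUmap,
                              stringsAsFactors = FALSE)
  plan <- do.call(rbind, plans)
  plan <- plan[rep(seq_len(nrow(plan)), nScans), , drop = FALSE]
  plan$scan <- rep(seq_len(nScans), each = nrow(plan) / nScans)
  rownames(plan) <- NULL
  plan
}

writeSidecar <- function(path, record) {
  jsonlite::write_json(record, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Run the simulate -> tvfc -> null -> id -> embed -> evaluate pipeline
#'
#' Executes the stages in dependency order on a synthetic dataset, writes
#' every artifact with a JSON provenance sidecar (inputs, parameters,
#' seed, package version), expands the configured grids into
#' per-combination embedding runs, and returns a manifest of the produced
#' files (with md5 hashes) plus the per-combination silhouette results.
#' With `dryRun = TRUE` nothing is executed; the planned run table is
#' returned.
#'
#' @param config a [pipelineConfig()].
#' @param dryRun plan only.
#' @return For a dry run, the planned grid data.frame (one row per
#'   embedding combination per scan). Otherwise a list with `manifest`
#'   (file, md5) and `results` (per-combination task silhouettes).
#' @export
runPipeline <- function(config, dryRun = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  nScans <- config$syntheticCfg$nSubjects
  plan <- planRuns(config, nScans)
  if (dryRun) return(plan)

  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outputDir, paste0(...))
  version <- as.character(utils::packageVersion("manifoldFC"))
  manifest <- character(0)

  # simulate
  cfg <- config$syntheticCfg
  cfg$seed <- stageSeed(config$seed, "simulate")
  ds <- generateDataset(cfg)
  writeEvents(ds[[1L]]$schedule, out("events.tsv"), tr = cfg$tr)
  manifest <- c(manifest, out("events.tsv"))
  for (s in seq_along(ds)) {
    p <- out(sprintf("sub%02d_timeseries.tsv", s))
    writeRoiTimeseries(ds[[s]]$ts, p)
    writeGroundTruth(ds[[s]]$groundTruth, out(sprintf("sub%02d_truth.json", s)))
    writeSidecar(p, list(stage = "simulate", seed = cfg$seed,
                         version = version))
    manifest <- c(manifest, p, out(sprintf("sub%02d_truth.json", s)))
  }

  # tvfc
  tvfcs <- lapply(ds, function(d)
    computeTvfc(d$ts, config$window, schedule = d$schedule))
  for (s in seq_along(tvfcs)) {
    p <- out(sprintf("sub%02d_tvfc", s))
    writeTvfc(tvfcs[[s]], p)
    writeSidecar(paste0(p, ".tsv"),
                 list(stage = "tvfc", w = wDuration(config$window),
                      step = wStep(config$window), version = version))
    manifest <- c(manifest, paste0(p, c(".tsv", ".json")))
  }

  # null models (first scan)
  for (nm in config$nullModels) {
    nseed <- stageSeed(config$seed, nm)
    surrogate <- if (nm == "connectivity")
      randomizeConnectivity(tvfcs[[1L]], seed = nseed)
    else
      computeTvfc(phaseRandomize(ds[[1L]]$ts, seed = nseed), config$window,
                  schedule = ds[[1L]]$schedule)
    p <- out(sprintf("null_%s_tvfc", nm))
    writeTvfc(surrogate, p)
    writeSidecar(paste0(p, ".tsv"), list(stage = "null", model = nm,
                                         seed = nseed, version = version))
    manifest <- c(manifest, paste0(p, c(".tsv", ".json")))
  }

  # intrinsic dimension (first scan)
  idg <- estimateId(tvfcs[[1L]], "twoNN", "global")
  idTab <- data.frame(estimator = "twoNN", scope = "global",
                      value = idValue(idg), n = idg@nSamples)
  write.table(idTab, out("id_estimates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- c(manifest, out("id_estimates.tsv"))

  # embed + evaluate over the grid (first scan)
  results <- plan[plan$method %in% config$methods, , drop = FALSE]
  results <- results[!duplicated(results[, c("method", "metric", "k", "m", "lr")]), ]
  results$si_task <- NA_real_
  eseed <- stageSeed(config$seed, "embed")
  for (r in seq_len(nrow(results))) {
    params <- switch(results$method[r],
      LE = leParams(k = results$k[r], m = results$m[r]),
      TSNE = tsneParams(perplexity = results$k[r], m = results$m[r],
                        learningRate = results$lr[r], seed = eseed + r),
      UMAP = umapParams(k = results$k[r], m = results$m[r],
                        learningRate = results$lr[r], seed = eseed + r))
    emb <- tryCatch(embedTvfc(tvfcs[[1L]], params, metric = results$metric[r]),
                    error = function(e) NULL)
    if (!is.null(emb))
      results$si_task[r] <- tryCatch(silhouetteIndex(emb, "task")$value,
                                     error = function(e) NA_real_)
  }
  write.table(results, out("embedding_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSidecar(out("embedding_results.tsv"),
               list(stage = "evaluate", seed = eseed, version = version))
  manifest <- c(manifest, out("embedding_results.tsv"))

  md5 <- tools::md5sum(manifest)
  list(manifest = data.frame(file = basename(manifest), md5 = unname(md5)),
       results = results)
}
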