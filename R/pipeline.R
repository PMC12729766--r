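#' Save / load a repair-model checkpoint
#'
#' A checkpoint is a single file holding the model kind, its configuration
#' and all parameter matrices; loading restores a model that reproduces the
#' saved model's outputs exactly.
#'
#' @param model a \linkS4class{RepairModel}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{saveRepairModel}: \code{path} invisibly;
#'   \code{loadRepairModel}: the restored \linkS4class{RepairModel}.
#' @export
saveRepairModel <- function(model, path) {
  stopifnot(is(model, "RepairModel"))
  saveRDS(list(kind = model@kind, config = model@config,
               nGenes = model@nGenes, params = model@params), path)
  invisible(path)
}

#' @rdname saveRepairModel
#' @export
loadRepairModel <- function(path) {
  x <- readRDS(path)
  new("RepairModel", kind = x$kind, config = x$config, nGenes = x$nGenes,
      params = x$params, mode = "eval")
}

# deterministic fan-out of one global seed into per-stage substreams by
# stable string hashing, so adding a stage never reshuffles the others
.stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((h + (as.double(seed) %% 1e9) * 97) %% 2147480009)
}

.log_stage <- function(quiet, ...) {
  if (!quiet)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [screpair] ", ...)
}

#' Default end-to-end pipeline configuration
#'
#' Nested configuration for [runPipeline()] covering every stage:
#' synthetic-data generation, QC, normalisation and HVG selection,
#' degradation, splitting, model and training settings, evaluation, and the
#' optional orthogonal protein-panel validation. Stage seeds are derived
#' from the single global \code{seed}.
#'
#' @param seed global integer seed.
#' @param outDir artifact directory.
#' @return nested list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = tempfile("screpair_")) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    quiet = FALSE,
    synth = list(nCells = 2000L, nGenes = 500L, nTypes = 4L,
                 markersPerType = 10L, markerLogFC = log(4), baseMean = 2,
                 dispersion = 0.3, lengthLogMean = log(2000),
                 lengthLogSD = 0.7),
    qc = list(minGenesPerCell = 1, maxGenesPerCell = Inf,
              maxMitoFraction = 1, minCellsPerGene = 3),
    hvg = list(nTop = 500L),
    degrade = list(alpha = 0.5, dropoutRate = 0.3, noiseSD = 0.2),
    split = list(fractions = c(0.8, 0.1, 0.1), stratify = TRUE),
    model = list(embedDim = 64L, numHeads = 4L, numLayers = 2L,
                 ffnDim = 256L, dropout = 0, tokenSize = 25L),
    train = list(batchSize = 16L, learningRate = 5e-3,
                 plateauPatience = 10L, plateauFactor = 0.5,
                 maxEpochs = 30L, earlyStopPatience = 25L),
    evaluate = list(topK = 50L, threshold = 0.1, nPCs = 50L),
    protein = list(enabled = TRUE, nPairs = 6L, noiseSD = 0.3)
  )
}

#' Run the full repair pipeline
#'
#' Executes the stages in order: synthesise ground truth, preprocess (QC,
#' CP10k/log1p, HVG selection), simulate degradation, split cells, train
#' the Transformer repair model, repair the held-out test cells, and
#' evaluate repaired and degraded profiles against the originals. Every
#' intermediate artifact and a resolved-config snapshot (including the
#' derived per-stage seed chain) are persisted under \code{out_dir};
#' rerunning with the same configuration reproduces the metrics exactly.
#'
#' @param config nested list as produced by [defaultPipelineConfig()].
#' @return list with the trained model, the degraded pair, the split, the
#'   test-cell \linkS4class{MetricsReport}s for repaired and degraded data,
#'   the training history, optional protein validation, and the artifact
#'   directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  quiet <- isTRUE(config$quiet)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(
    synth = .stage_seed(config$seed, "synth"),
    degrade = .stage_seed(config$seed, "degrade"),
    split = .stage_seed(config$seed, "split"),
    model = .stage_seed(config$seed, "model"),
    train = .stage_seed(config$seed, "train"),
    protein = .stage_seed(config$seed, "protein"))
  snapshot <- config
  snapshot$derived_seeds <- seeds
  jsonlite::write_json(snapshot, file.path(out, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  stage <- "synth"
  result <- tryCatch({
    .log_stage(quiet, "stage synth")
    spec <- do.call(SyntheticSpec, c(config$synth, list(seed = seeds$synth)))
    truth <- generateTruth(spec)
    writeExpressionMatrix(truth, file.path(out, "truth_mtx"), "mtx_dir")
    utils::write.table(markerTable(truth), file.path(out, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "preprocess"
    .log_stage(quiet, "stage preprocess")
    thr <- do.call(QCThresholds, config$qc)
    filtered <- qcFilter(truth, thr)
    norm <- normalizeLog(filtered)
    hvg <- selectHVG(norm, nTop = config$hvg$nTop)

    stage <- "simulate"
    .log_stage(quiet, "stage simulate")
    params <- DegradationParams(alpha = config$degrade$alpha,
                                dropoutRate = config$degrade$dropoutRate,
                                noiseSD = config$degrade$noiseSD,
                                seed = seeds$degrade)
    pair <- degrade(hvg, params)

    stage <- "split"
    split <- splitDataset(ncol(pair), fractions = config$split$fractions,
                          labels = if (isTRUE(config$split$stratify))
                                     cellTypes(pair) else NULL,
                          seed = seeds$split)

    stage <- "train"
    .log_stage(quiet, "stage train")
    mcfg <- do.call(RepairModelConfig,
                    c(list(nGenes = nrow(pair)), config$model,
                      list(seed = seeds$model)))
    tcfg <- do.call(TrainConfig,
                    c(config$train, list(seed = seeds$train)))
    fit <- trainRepairModel(buildRepairModel(mcfg), pair, split, tcfg)
    saveRepairModel(fit$model, file.path(out, "checkpoint.rds"))
    utils::write.csv(fit$history@history, file.path(out, "history.csv"),
                     row.names = FALSE)

    stage <- "repair"
    .log_stage(quiet, "stage repair")
    Xdeg <- t(degradedMatrix(pair))[split@testIdx, , drop = FALSE]
    Xorig <- t(originalMatrix(pair))[split@testIdx, , drop = FALSE]
    Xrep <- repairExpression(fit$model, Xdeg)

    stage <- "evaluate"
    .log_stage(quiet, "stage evaluate")
    labels <- cellTypes(pair)[split@testIdx]
    markers <- intersect(markerTable(truth)$gene, rownames(pair))
    ev <- config$evaluate
    repReport <- evaluateRepair(Xrep, Xorig, labels, markers,
                                topK = ev$topK, threshold = ev$threshold,
                                nPCs = ev$nPCs)
    degReport <- evaluateRepair(Xdeg, Xorig, labels, markers,
                                topK = ev$topK, threshold = ev$threshold,
                                nPCs = ev$nPCs)
    metrics <- list(repaired = as.list(metricsAsVector(repReport)),
                    degraded = as.list(metricsAsVector(degReport)))
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)

    protein <- NULL
    if (isTRUE(config$protein$enabled)) {
      stage <- "protein"
      .log_stage(quiet, "stage protein")
      mk <- utils::head(markers, config$protein$nPairs)
      pairs <- data.frame(protein = paste0("prot_", mk), gene = mk)
      panel <- generateProteinPanel(truth, pairs,
                                    noiseSD = config$protein$noiseSD,
                                    seed = seeds$protein)
      pv <- proteinValues(panel)[colnames(pair)[split@testIdx], ,
                                 drop = FALSE]
      panelTest <- new("ProteinPanel", values = pv, pairs = pairs)
      protein <- orthogonalProteinValidation(Xorig, Xdeg, Xrep, panelTest)
    }

    list(model = fit$model, history = fit$history, pair = pair,
         split = split, repaired = repReport, degraded = degReport,
         protein = protein, truth = truth, hvg = hvg, outDir = out)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial artifacts in %s)",
                 stage, conditionMessage(e), out), call. = FALSE)
  })
  .log_stage(quiet, "done")
  result
}
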