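#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.SCALE_TAGS <- c("counts", "cp10k_log1p")

#' RepairDataSet: the expression carrier
#'
#' A \linkS4class{SingleCellExperiment} subclass holding a genes x cells
#' expression matrix together with the metadata the degradation and repair
#' machinery needs: per-gene transcript lengths (\code{rowData} column
#' \code{gene_length}), optional cell-type labels (\code{colData} column
#' \code{cell_type}), and a scale tag recording whether the values are raw
#' counts or counts-per-10k log1p-transformed expression.
#'
#' @slot scaleTag character(1), one of \code{"counts"} (nonnegative raw
#'   counts) or \code{"cp10k_log1p"} (per-cell CP10k normalised, log1p).
#'
#' @seealso [RepairDataSet()] for the constructor, [normalizeLog()],
#'   [qcFilter()], [selectHVG()].
#' @export
setClass("RepairDataSet",
  contains = "SingleCellExperiment",
  slots = c(scaleTag = "character")
)

setValidity("RepairDataSet", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% .SCALE_TAGS)
    msg <- c(msg, sprintf("scaleTag must be one of: %s",
                          paste(.SCALE_TAGS, collapse = ", ")))
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene ids (rownames) and cell ids (colnames) are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "gene ids must be unique")
  }
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    msg <- c(msg, "at least one assay is required")
  else {
    v <- SummarizedExperiment::assay(object, 1L)
    if (identical(object@scaleTag, "counts") && length(v) && min(v) < 0)
      msg <- c(msg, "values must be >= 0 when scaleTag is 'counts'")
  }
  rd <- SummarizedExperiment::rowData(object)
  if ("gene_length" %in% colnames(rd)) {
    len <- rd$gene_length
    if (anyNA(len) || any(len <= 0))
      msg <- c(msg, "gene_length must be all > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RepairDataSet
#'
#' @param values numeric matrix, genes x cells (dense or sparse). Raw counts
#'   unless \code{scaleTag = "cp10k_log1p"}.
#' @param geneIds,cellIds character vectors of unique gene / cell
#'   identifiers; default to the dimnames of \code{values}.
#' @param geneLengths optional positive numeric vector of transcript lengths
#'   in bases, aligned to \code{geneIds}.
#' @param cellTypes optional character/factor vector of per-cell labels.
#' @param scaleTag \code{"counts"} (default) or \code{"cp10k_log1p"}.
#'
#' @return A \linkS4class{RepairDataSet}.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' rds <- RepairDataSet(m)
#' scaleTag(rds)
#' @export
RepairDataSet <- function(values, geneIds = rownames(values),
                          cellIds = colnames(values), geneLengths = NULL,
                          cellTypes = NULL, scaleTag = "counts") {
  values <- as.matrix(values)
  if (is.null(geneIds) || is.null(cellIds))
    stop("geneIds and cellIds are required (or supply dimnames on 'values')")
  dimnames(values) <- list(as.character(geneIds), as.character(cellIds))
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(geneLengths)) {
    if (length(geneLengths) != nrow(values))
      stop("geneLengths must have one entry per gene")
    rd$gene_length <- as.numeric(geneLengths)
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(cellTypes)) {
    if (length(cellTypes) != ncol(values))
      stop("cellTypes must have one entry per cell")
    cd$cell_type <- as.character(cellTypes)
  }
  assays <- stats::setNames(
    list(values), if (identical(scaleTag, "counts")) "counts" else "logcounts")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays, rowData = rd, colData = cd)
  new("RepairDataSet", sce, scaleTag = scaleTag)
}

#' Degradation parameters
#'
#' The three knobs of the pseudo-degradation model: 3'-bias intensity
#' \code{alpha}, dropout probability \code{dropoutRate} and additive
#' Gaussian noise SD \code{noiseSD}, plus the seed that makes the stochastic
#' corruption reproducible.
#'
#' @slot alpha nonnegative numeric(1); 0 disables length-dependent bias.
#' @slot dropoutRate numeric(1) in [0, 1]; per-entry Bernoulli zeroing
#'   probability.
#' @slot noiseSD nonnegative numeric(1); SD of additive Gaussian noise on
#'   the log-normalised scale.
#' @slot seed integer(1).
#' @export
setClass("DegradationParams",
  slots = c(alpha = "numeric", dropoutRate = "numeric",
            noiseSD = "numeric", seed = "integer"),
  prototype = list(alpha = 0.5, dropoutRate = 0.3, noiseSD = 0.2, seed = 1L)
)

setValidity("DegradationParams", function(object) {
  msg <- character()
  for (s in c("alpha", "dropoutRate", "noiseSD", "seed"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a non-missing scalar", s))
  if (!length(msg)) {
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@dropoutRate < 0 || object@dropoutRate > 1)
      msg <- c(msg, "dropoutRate must be in [0, 1]")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname DegradationParams-class
#' @param alpha,dropoutRate,noiseSD,seed see slots.
#' @return A \code{DegradationParams} object.
#' @export
DegradationParams <- function(alpha = 0.5, dropoutRate = 0.3, noiseSD = 0.2,
                              seed = 1L) {
  new("DegradationParams", alpha = as.numeric(alpha),
      dropoutRate = as.numeric(dropoutRate), noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Aligned original / degraded expression pair
#'
#' A \linkS4class{SingleCellExperiment} subclass with three aligned assays:
#' \code{original} (the clean log-normalised profile), \code{degraded} (the
#' corrupted profile) and \code{dropoutMask} (the realised binary mask; 0 =
#' entry zeroed by dropout). The realised per-gene bias factors, the
#' parameters used and a summary of the realised noise draw are kept for
#' audit.
#'
#' @slot params the \linkS4class{DegradationParams} used.
#' @slot biasFactors numeric, one factor in (0, 1] per gene.
#' @slot noiseSummary named numeric(2): mean and SD of the realised noise.
#' @export
setClass("DegradedPair",
  contains = "SingleCellExperiment",
  slots = c(params = "DegradationParams", biasFactors = "numeric",
            noiseSummary = "numeric")
)

setValidity("DegradedPair", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("original", "degraded", "dropoutMask")
  if (!all(need %in% an))
    msg <- c(msg, paste("assays must include:", paste(need, collapse = ", ")))
  else {
    if (min(SummarizedExperiment::assay(object, "degraded")) < 0)
      msg <- c(msg, "degraded values must be >= 0 (clamp contract)")
  }
  if (length(object@biasFactors) != nrow(object))
    msg <- c(msg, "biasFactors must have one entry per gene")
  else if (any(object@biasFactors <= 0 | object@biasFactors > 1))
    msg <- c(msg, "biasFactors must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Transformer repair model configuration
#'
#' Architecture hyperparameters of the one-step Transformer repair network.
#' Defaults follow the full-size configuration (model dimension 256, 8
#' heads, 4 encoder layers, feed-forward dimension 1024, dropout 0.1); the
#' gene-chunk token size is a design knob of this implementation.
#'
#' @slot nGenes integer(1), input/output dimensionality.
#' @slot embedDim integer(1), model (embedding) dimension.
#' @slot numHeads integer(1); must divide \code{embedDim}.
#' @slot numLayers integer(1), encoder depth.
#' @slot ffnDim integer(1), feed-forward hidden width.
#' @slot dropout numeric(1) in [0, 1), applied during training only.
#' @slot tokenSize integer(1), genes per token chunk.
#' @slot noiseAugment logical(1); if TRUE, Gaussian noise of SD
#'   \code{noiseAugmentSD} is added to the conditioning input during
#'   training (off by default; inference is always noise-free).
#' @slot noiseAugmentSD numeric(1).
#' @slot predictResidual logical(1); if TRUE (default) the network output
#'   is added to the conditioning input, so the model predicts the
#'   degradation correction (the "noise component") rather than the full
#'   profile — the denoising parameterisation of a one-step repair map.
#' @slot seed integer(1), parameter-initialisation seed.
#' @export
setClass("RepairModelConfig",
  slots = c(nGenes = "integer", embedDim = "integer", numHeads = "integer",
            numLayers = "integer", ffnDim = "integer", dropout = "numeric",
            tokenSize = "integer", noiseAugment = "logical",
            noiseAugmentSD = "numeric", predictResidual = "logical",
            seed = "integer")
)

setValidity("RepairModelConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@tokenSize < 1L) msg <- c(msg, "tokenSize must be >= 1")
  if (object@embedDim < 1L || object@embedDim %% object@numHeads != 0L)
    msg <- c(msg, "embedDim must be a positive multiple of numHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@numLayers < 1L) msg <- c(msg, "numLayers must be >= 1")
  if (object@ffnDim < 1L) msg <- c(msg, "ffnDim must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname RepairModelConfig-class
#' @param nGenes,embedDim,numHeads,numLayers,ffnDim,dropout,tokenSize,seed
#'   see slots.
#' @param noiseAugment,noiseAugmentSD optional training-time input noise
#'   augmentation.
#' @param predictResidual predict the correction to the input (default)
#'   rather than the full profile.
#' @return A \code{RepairModelConfig}.
#' @export
RepairModelConfig <- function(nGenes, embedDim = 256L, numHeads = 8L,
                              numLayers = 4L, ffnDim = 1024L, dropout = 0.1,
                              tokenSize = 50L, noiseAugment = FALSE,
                              noiseAugmentSD = 0.1, predictResidual = TRUE,
                              seed = 1L) {
  new("RepairModelConfig", nGenes = as.integer(nGenes),
      embedDim = as.integer(embedDim), numHeads = as.integer(numHeads),
      numLayers = as.integer(numLayers), ffnDim = as.integer(ffnDim),
      dropout = as.numeric(dropout), tokenSize = as.integer(tokenSize),
      noiseAugment = isTRUE(noiseAugment),
      noiseAugmentSD = as.numeric(noiseAugmentSD),
      predictResidual = isTRUE(predictResidual), seed = as.integer(seed))
}

#' Baseline autoencoder configuration
#'
#' Configuration of the MLP denoising autoencoder (\code{kind = "dae"}) and
#' variational autoencoder (\code{kind = "vae"}) baselines. Both consume the
#' degraded profile and regress the original; the VAE adds a diagonal
#' Gaussian latent with a KL penalty of weight \code{klWeight}.
#'
#' @slot kind "dae" or "vae".
#' @slot hiddenDims integer vector, encoder widths (decoder mirrors them).
#' @slot latentDim integer(1) >= 1.
#' @slot dropout numeric(1) in [0, 1).
#' @slot klWeight numeric(1), VAE KL weight (beta); ignored for the DAE.
#' @slot seed integer(1).
#' @export
setClass("BaselineConfig",
  slots = c(kind = "character", hiddenDims = "integer", latentDim = "integer",
            dropout = "numeric", klWeight = "numeric", seed = "integer")
)

setValidity("BaselineConfig", function(object) {
  msg <- character()
  if (!object@kind %in% c("dae", "vae"))
    msg <- c(msg, "kind must be 'dae' or 'vae'")
  if (length(object@hiddenDims) < 1L || any(object@hiddenDims < 1L))
    msg <- c(msg, "hiddenDims must be a nonempty vector of positive widths")
  if (object@latentDim < 1L) msg <- c(msg, "latentDim must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@klWeight < 0) msg <- c(msg, "klWeight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BaselineConfig-class
#' @param kind,hiddenDims,latentDim,dropout,klWeight,seed see slots.
#' @return A \code{BaselineConfig}.
#' @export
BaselineConfig <- function(kind = c("dae", "vae"), hiddenDims = c(256L, 128L),
                           latentDim = 32L, dropout = 0.1, klWeight = 1e-3,
                           seed = 1L) {
  kind <- match.arg(kind)
  new("BaselineConfig", kind = kind, hiddenDims = as.integer(hiddenDims),
      latentDim = as.integer(latentDim), dropout = as.numeric(dropout),
      klWeight = as.numeric(klWeight), seed = as.integer(seed))
}

#' A repair model (Transformer or autoencoder baseline)
#'
#' Opaque learned state plus its configuration. Built by
#' [buildRepairModel()] / [buildBaseline()], trained by
#' [trainRepairModel()], applied by [repairExpression()]. In \code{"eval"}
#' mode inference is a single deterministic forward pass.
#'
#' @slot kind "transformer", "dae" or "vae".
#' @slot config the building configuration object.
#' @slot nGenes integer(1), input/output dimensionality.
#' @slot params named list of parameter matrices/vectors.
#' @slot mode "train" or "eval".
#' @export
setClass("RepairModel",
  slots = c(kind = "character", config = "ANY", nGenes = "integer",
            params = "list", mode = "character")
)

setValidity("RepairModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("transformer", "dae", "vae"))
    msg <- c(msg, "kind must be 'transformer', 'dae' or 'vae'")
  if (!object@mode %in% c("train", "eval"))
    msg <- c(msg, "mode must be 'train' or 'eval'")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Optimisation hyperparameters for [trainRepairModel()]: Adam with an
#' initial learning rate of 2e-4 and batch size 64 by default, a
#' reduce-on-plateau schedule that halves the learning rate after
#' \code{plateauPatience} epochs without relative validation-loss
#' improvement beyond \code{plateauRelTol}, and early stopping.
#'
#' @slot batchSize integer(1) >= 1.
#' @slot learningRate positive numeric(1).
#' @slot optimizer "adam".
#' @slot plateauPatience integer(1), epochs of no improvement before halving.
#' @slot plateauFactor numeric(1) in (0, 1).
#' @slot plateauRelTol numeric(1), relative improvement threshold.
#' @slot maxEpochs integer(1).
#' @slot earlyStopPatience integer(1).
#' @slot emaDecay numeric(1) in [0, 1): per-step exponential moving average
#'   of the parameters; validation and the returned model use the averaged
#'   weights (the standard stabiliser for one-step denoising models).
#'   0 disables averaging.
#' @slot seed integer(1).
#' @export
setClass("TrainConfig",
  slots = c(batchSize = "integer", learningRate = "numeric",
            optimizer = "character", plateauPatience = "integer",
            plateauFactor = "numeric", plateauRelTol = "numeric",
            maxEpochs = "integer", earlyStopPatience = "integer",
            emaDecay = "numeric", seed = "integer")
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (!identical(object@optimizer, "adam"))
    msg <- c(msg, "optimizer must be 'adam'")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    msg <- c(msg, "plateauFactor must be in (0, 1)")
  if (object@emaDecay < 0 || object@emaDecay >= 1)
    msg <- c(msg, "emaDecay must be in [0, 1)")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param batchSize,learningRate,optimizer,plateauPatience,plateauFactor,plateauRelTol,maxEpochs,earlyStopPatience,emaDecay,seed
#'   see slots.
#' @return A \code{TrainConfig}.
#' @export
TrainConfig <- function(batchSize = 64L, learningRate = 2e-4,
                        optimizer = "adam", plateauPatience = 10L,
                        plateauFactor = 0.5, plateauRelTol = 1e-4,
                        maxEpochs = 100L, earlyStopPatience = 25L,
                        emaDecay = 0.99, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), optimizer = optimizer,
      plateauPatience = as.integer(plateauPatience),
      plateauFactor = as.numeric(plateauFactor),
      plateauRelTol = as.numeric(plateauRelTol),
      maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      emaDecay = as.numeric(emaDecay), seed = as.integer(seed))
}

#' Cell-level train/validation/test split
#'
#' Disjoint index sets covering all cells, optionally stratified by label so
#' each stratum is represented at the target fractions to within one cell.
#'
#' @slot trainIdx,valIdx,testIdx integer vectors (1-based cell indices).
#' @slot fractions numeric(3) summing to 1.
#' @slot stratified logical(1).
#' @slot seed integer(1).
#' @export
setClass("SplitAssignment",
  slots = c(trainIdx = "integer", valIdx = "integer", testIdx = "integer",
            fractions = "numeric", stratified = "logical", seed = "integer")
)

setValidity("SplitAssignment", function(object) {
  idx <- c(object@trainIdx, object@valIdx, object@testIdx)
  msg <- character()
  if (anyDuplicated(idx)) msg <- c(msg, "split indices must be disjoint")
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "fractions must be 3 values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Training history
#'
#' Per-epoch record of the realised training objective: train loss,
#' validation loss and learning rate, plus the best-validation epoch whose
#' parameters the trained model carries. The cell indices that entered
#' gradient steps and scheduler decisions are recorded so the test-set
#' firewall can be audited.
#'
#' @slot history data.frame with columns epoch, train_loss, val_loss, lr.
#' @slot bestEpoch integer(1).
#' @slot usedIdx list with elements \code{gradient} and \code{scheduler}:
#'   sorted unique cell indices that influenced each.
#' @export
setClass("TrainHistory",
  slots = c(history = "data.frame", bestEpoch = "integer", usedIdx = "list")
)

setValidity("TrainHistory", function(object) {
  h <- object@history
  msg <- character()
  need <- c("epoch", "train_loss", "val_loss", "lr")
  if (!all(need %in% names(h)))
    msg <- c(msg, paste("history must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(h) && is.unsorted(-h$lr))
    msg <- c(msg, "learning-rate sequence must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Technical + biological evaluation scorecard
#'
#' Technical block: MSE, Pearson correlation over all entries, PR-AUC and F1
#' for the expressed-vs-unexpressed task. Biological block (0-100 scales):
#' silhouette cell-type separation, differential-expression preservation and
#' marker-gene recovery; \code{overallBiological} is their arithmetic mean.
#'
#' @slot mse,pearson,prAuc,f1 numeric(1) technical metrics (may be NA when
#'   a metric is undefined, e.g. Pearson on constant input).
#' @slot cellTypeSeparation,degPreservation,markerRecovery,overallBiological
#'   numeric(1) scores in [0, 100].
#' @export
setClass("MetricsReport",
  slots = c(mse = "numeric", pearson = "numeric", prAuc = "numeric",
            f1 = "numeric", cellTypeSeparation = "numeric",
            degPreservation = "numeric", markerRecovery = "numeric",
            overallBiological = "numeric")
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  chk01 <- function(x, lo, hi, nm) {
    if (!is.na(x) && (x < lo || x > hi))
      sprintf("%s must be in [%g, %g]", nm, lo, hi) else character()
  }
  msg <- c(msg,
    chk01(object@pearson, -1, 1, "pearson"),
    chk01(object@prAuc, 0, 1, "prAuc"),
    chk01(object@f1, 0, 1, "f1"),
    chk01(object@cellTypeSeparation, 0, 100, "cellTypeSeparation"),
    chk01(object@degPreservation, 0, 100, "degPreservation"),
    chk01(object@markerRecovery, 0, 100, "markerRecovery"),
    chk01(object@overallBiological, 0, 100, "overallBiological"))
  if (!is.na(object@mse) && object@mse < 0)
    msg <- c(msg, "mse must be >= 0")
  bio <- c(object@cellTypeSeparation, object@degPreservation,
           object@markerRecovery)
  if (!anyNA(bio) && !is.na(object@overallBiological) &&
      abs(object@overallBiological - mean(bio)) > 5e-4)
    msg <- c(msg, "overallBiological must equal the mean of the three biological scores")
  if (length(msg)) msg else TRUE
})

#' Paired surface-protein panel
#'
#' Per-cell protein measurements paired with RNA through a protein-to-gene
#' map, used for orthogonal validation of degradation and repair: protein
#' abundance is unaffected by RNA degradation, so the RNA-protein Spearman
#' correlation should drop under degradation and recover after repair.
#'
#' @slot values numeric matrix, cells x proteins.
#' @slot pairs data.frame with columns \code{protein} and \code{gene}.
#' @export
setClass("ProteinPanel",
  slots = c(values = "matrix", pairs = "data.frame")
)

setValidity("ProteinPanel", function(object) {
  msg <- character()
  if (!all(c("protein", "gene") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns 'protein' and 'gene'")
  else if (nrow(object@pairs) != ncol(object@values))
    msg <- c(msg, "one pair row per protein column is required")
  if (length(msg)) msg else TRUE
})

#' Paired test result
#'
#' Result of a two-sided paired t-test with its paired Cohen's d effect
#' size (mean of paired differences over their SD, n-1 denominator).
#'
#' @slot pValue numeric(1) in [0, 1].
#' @slot cohenD numeric(1); sign matches \code{meanDiff}.
#' @slot n integer(1), number of pairs.
#' @slot meanDiff numeric(1).
#' @slot degenerate logical(1); TRUE when all differences were zero, in
#'   which case p = 1 and d = 0 by convention.
#' @export
setClass("PairedTestResult",
  slots = c(pValue = "numeric", cohenD = "numeric", n = "integer",
            meanDiff = "numeric", degenerate = "logical")
)

setValidity("PairedTestResult", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  if (!is.na(object@cohenD) && !is.na(object@meanDiff) &&
      object@cohenD * object@meanDiff < 0)
    msg <- c(msg, "sign of cohenD must match sign of meanDiff")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset specification
#'
#' Parameters of the clustered negative-binomial single-cell generator:
#' cells, genes, equally sized cell types, planted marker genes whose mean
#' is multiplied by \code{exp(markerLogFC)} inside their own type,
#' gamma-Poisson (negative binomial) counts with overdispersion
#' \code{dispersion}, and log-normal transcript lengths.
#'
#' @slot nCells,nGenes,nTypes,markersPerType integer(1) counts.
#' @slot markerLogFC positive numeric(1), log-scale marker effect size.
#' @slot baseMean positive numeric(1), median per-gene baseline mean count.
#' @slot dispersion positive numeric(1), NB overdispersion (size = 1/disp).
#' @slot lengthLogMean numeric(1), mean of log transcript length (bases).
#' @slot lengthLogSD positive numeric(1).
#' @slot seed integer(1).
#' @export
setClass("SyntheticSpec",
  slots = c(nCells = "integer", nGenes = "integer", nTypes = "integer",
            markersPerType = "integer", markerLogFC = "numeric",
            baseMean = "numeric", dispersion = "numeric",
            lengthLogMean = "numeric", lengthLogSD = "numeric",
            seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nTypes < 1L) msg <- c(msg, "nTypes must be >= 1")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@markersPerType * object@nTypes > object@nGenes)
    msg <- c(msg, "markersPerType * nTypes must not exceed nGenes")
  for (s in c("markerLogFC", "baseMean", "dispersion", "lengthLogSD"))
    if (slot(object, s) <= 0)
      msg <- c(msg, sprintf("%s must be > 0", s))
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nCells,nGenes,nTypes,markersPerType,markerLogFC,baseMean,dispersion,lengthLogMean,lengthLogSD,seed
#'   see slots.
#' @return A \code{SyntheticSpec}.
#' @export
SyntheticSpec <- function(nCells = 2000L, nGenes = 500L, nTypes = 4L,
                          markersPerType = 10L, markerLogFC = log(4),
                          baseMean = 2, dispersion = 0.3,
                          lengthLogMean = log(2000), lengthLogSD = 0.7,
                          seed = 1L) {
  new("SyntheticSpec", nCells = as.integer(nCells),
      nGenes = as.integer(nGenes), nTypes = as.integer(nTypes),
      markersPerType = as.integer(markersPerType),
      markerLogFC = as.numeric(markerLogFC), baseMean = as.numeric(baseMean),
      dispersion = as.numeric(dispersion),
      lengthLogMean = as.numeric(lengthLogMean),
      lengthLogSD = as.numeric(lengthLogSD), seed = as.integer(seed))
}

#' Quality-control thresholds
#'
#' Cell- and gene-level filters applied by [qcFilter()]: cells must express
#' between \code{minGenesPerCell} and \code{maxGenesPerCell} genes and have
#' a mitochondrial fraction at most \code{maxMitoFraction} (mitochondrial
#' genes identified by id prefix); genes must be expressed in at least
#' \code{minCellsPerGene} surviving cells. Defaults are permissive; real
#' analyses should set thresholds appropriate to the platform.
#'
#' @slot minGenesPerCell,maxGenesPerCell numeric(1) (max may be Inf).
#' @slot maxMitoFraction numeric(1) in [0, 1].
#' @slot minCellsPerGene numeric(1).
#' @slot mitoPrefix character(1), default \code{"MT-"}.
#' @export
setClass("QCThresholds",
  slots = c(minGenesPerCell = "numeric", maxGenesPerCell = "numeric",
            maxMitoFraction = "numeric", minCellsPerGene = "numeric",
            mitoPrefix = "character")
)

setValidity("QCThresholds", function(object) {
  msg <- character()
  if (object@minGenesPerCell > object@maxGenesPerCell)
    msg <- c(msg, "minGenesPerCell must be <= maxGenesPerCell")
  if (object@maxMitoFraction < 0 || object@maxMitoFraction > 1)
    msg <- c(msg, "maxMitoFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname QCThresholds-class
#' @param minGenesPerCell,maxGenesPerCell,maxMitoFraction,minCellsPerGene,mitoPrefix
#'   see slots.
#' @return A \code{QCThresholds}.
#' @export
QCThresholds <- function(minGenesPerCell = 1, maxGenesPerCell = Inf,
                         maxMitoFraction = 1, minCellsPerGene = 1,
                         mitoPrefix = "MT-") {
  new("QCThresholds", minGenesPerCell = as.numeric(minGenesPerCell),
      maxGenesPerCell = as.numeric(maxGenesPerCell),
      maxMitoFraction = as.numeric(maxMitoFraction),
      minCellsPerGene = as.numeric(minCellsPerGene),
      mitoPrefix = mitoPrefix)
}
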