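#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Accessors for RepairDataSet and friends
#'
#' \code{exprValues} returns the primary genes x cells matrix;
#' \code{scaleTag} the scale it is on; \code{geneLengths} the per-gene
#' transcript lengths (or NULL); \code{cellTypes} the per-cell labels (or
#' NULL); \code{markerTable} the planted marker table of a synthetic
#' dataset (or NULL).
#'
#' @param x a \linkS4class{RepairDataSet} (or \linkS4class{DegradedPair}
#'   where noted).
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("exprValues", "RepairDataSet", function(x) assay(x, 1L))

#' @rdname accessors
#' @export
setMethod("scaleTag", "RepairDataSet", function(x) x@scaleTag)

#' @rdname accessors
#' @export
setMethod("geneLengths", "SummarizedExperiment", function(x) {
  rd <- rowData(x)
  if ("gene_length" %in% colnames(rd)) as.numeric(rd$gene_length) else NULL
})

#' @rdname accessors
#' @export
setMethod("cellTypes", "SummarizedExperiment", function(x) {
  cd <- colData(x)
  if ("cell_type" %in% colnames(cd)) as.character(cd$cell_type) else NULL
})

#' @rdname accessors
#' @export
setMethod("markerTable", "SummarizedExperiment", function(x)
  metadata(x)$marker_table)

#' @rdname accessors
#' @export
setMethod("degradationParams", "DegradedPair", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("biasFactorsOf", "DegradedPair", function(x) x@biasFactors)

#' Original / degraded assays of a DegradedPair
#' @param x a \linkS4class{DegradedPair}.
#' @return genes x cells numeric matrix.
#' @export
originalMatrix <- function(x) assay(x, "original")

#' @rdname originalMatrix
#' @export
degradedMatrix <- function(x) assay(x, "degraded")

#' @rdname originalMatrix
#' @export
dropoutMask <- function(x) assay(x, "dropoutMask")

setMethod("show", "RepairDataSet", function(object) {
  cat(sprintf("RepairDataSet: %d genes x %d cells [scale: %s]\n",
              nrow(object), ncol(object), object@scaleTag))
  if (!is.null(geneLengths(object))) cat("  gene lengths: present\n")
  ct <- cellTypes(object)
  if (!is.null(ct))
    cat(sprintf("  cell types: %d (%s)\n", length(unique(ct)),
                paste(utils::head(unique(ct), 4), collapse = ", ")))
  invisible(object)
})

setMethod("show", "DegradedPair", function(object) {
  p <- object@params
  cat(sprintf(
    "DegradedPair: %d genes x %d cells (alpha=%.3g, dropout=%.3g, noiseSD=%.3g, seed=%d)\n",
    nrow(object), ncol(object), p@alpha, p@dropoutRate, p@noiseSD, p@seed))
  cat(sprintf("  realized dropout fraction: %.4f\n",
              mean(assay(object, "dropoutMask") == 0)))
  invisible(object)
})

setMethod("show", "DegradationParams", function(object) {
  cat(sprintf("DegradationParams(alpha=%.3g, dropoutRate=%.3g, noiseSD=%.3g, seed=%d)\n",
              object@alpha, object@dropoutRate, object@noiseSD, object@seed))
  invisible(object)
})

setMethod("show", "RepairModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("RepairModel<%s>: %d genes, %d parameters, mode=%s\n",
              object@kind, object@nGenes, np, object@mode))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  technical : MSE=%.4g  Pearson=%.4g  PR-AUC=%.4g  F1=%.4g\n",
              object@mse, object@pearson, object@prAuc, object@f1))
  cat(sprintf("  biological: separation=%.3f  DEG=%.3f  marker=%.3f  overall=%.3f\n",
              object@cellTypeSeparation, object@degPreservation,
              object@markerRecovery, object@overallBiological))
  invisible(object)
})

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment: train=%d val=%d test=%d (stratified=%s, seed=%d)\n",
              length(object@trainIdx), length(object@valIdx),
              length(object@testIdx), object@stratified, object@seed))
  invisible(object)
})

setMethod("show", "TrainHistory", function(object) {
  h <- object@history
  cat(sprintf("TrainHistory: %d epochs, best epoch %d (val loss %.5g)\n",
              nrow(h), object@bestEpoch, h$val_loss[object@bestEpoch]))
  invisible(object)
})

setMethod("show", "ProteinPanel", function(object) {
  cat(sprintf("ProteinPanel: %d cells x %d proteins\n",
              nrow(object@values), ncol(object@values)))
  if (nrow(object@pairs))
    cat("  pairs:", paste(sprintf("%s->%s", object@pairs$protein,
                                  object@pairs$gene), collapse = ", "), "\n")
  invisible(object)
})

#' Panel accessors
#' @param x a \linkS4class{ProteinPanel}.
#' @return \code{proteinValues}: cells x proteins matrix;
#'   \code{proteinPairs}: the protein-to-gene map.
#' @export
proteinValues <- function(x) x@values

#' @rdname proteinValues
#' @export
proteinPairs <- function(x) x@pairs

# internal: coerce any supported carrier to a cells x genes dense matrix
# (the sample-major orientation the model and metric code work in)
.cells_by_genes <- function(x) {
  if (is(x, "SummarizedExperiment")) t(as.matrix(assay(x, 1L)))
  else if (is.matrix(x)) x
  else as.matrix(x)
}
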