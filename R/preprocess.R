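#' Quality-control filtering
#'
#' Removes cells expressing too few or too many genes or with a high
#' mitochondrial fraction, then (after the cell filter) genes expressed in
#' fewer than \code{minCellsPerGene} surviving cells. A per-entity report of
#' what was removed and why is attached to the result's metadata as
#' \code{qc_report}.
#'
#' @param x a \linkS4class{RepairDataSet} of raw counts.
#' @param thresholds a \linkS4class{QCThresholds}.
#' @return The filtered \linkS4class{RepairDataSet};
#'   \code{metadata(result)$qc_report} holds data.frames
#'   \code{cells_removed} and \code{genes_removed} (columns id, reason) and
#'   removal counts.
#' @export
qcFilter <- function(x, thresholds = QCThresholds()) {
  stopifnot(is(x, "RepairDataSet"), is(thresholds, "QCThresholds"))
  if (!identical(scaleTag(x), "counts"))
    stop("qcFilter requires raw counts (scaleTag 'counts')")
  validObject(thresholds)
  counts <- exprValues(x)
  detected <- colSums(counts > 0)
  mito <- startsWith(rownames(x), thresholds@mitoPrefix)
  tot <- colSums(counts)
  mito_frac <- ifelse(tot > 0, colSums(counts[mito, , drop = FALSE]) / tot, 0)
  reasons <- character(ncol(x))
  reasons[detected < thresholds@minGenesPerCell] <- "too_few_genes"
  reasons[detected > thresholds@maxGenesPerCell] <- "too_many_genes"
  high_mito <- mito_frac > thresholds@maxMitoFraction
  reasons[high_mito] <- ifelse(nzchar(reasons[high_mito]),
                               paste0(reasons[high_mito], ";high_mito"),
                               "high_mito")
  keep_cells <- !nzchar(reasons)
  if (!any(keep_cells))
    stop("QC removed every cell; relax the thresholds")
  sub <- counts[, keep_cells, drop = FALSE]
  gene_cells <- rowSums(sub > 0)
  keep_genes <- gene_cells >= thresholds@minCellsPerGene
  if (!any(keep_genes))
    stop("QC removed every gene; relax minCellsPerGene")
  out <- x[keep_genes, keep_cells]
  metadata(out)$qc_report <- list(
    cells_removed = data.frame(
      id = colnames(x)[!keep_cells], reason = reasons[!keep_cells],
      stringsAsFactors = FALSE),
    genes_removed = data.frame(
      id = rownames(x)[!keep_genes], reason = rep("low_cell_count",
                                                  sum(!keep_genes)),
      stringsAsFactors = FALSE),
    n_cells_removed = sum(!keep_cells),
    n_genes_removed = sum(!keep_genes))
  out
}

#' CP10k + log1p normalisation
#'
#' Scales each cell's counts to a total of 10,000 (counts per 10k) and
#' applies \code{log1p}. This is the working scale of the degradation
#' simulator and the repair model. The transform is per-cell
#' scale-invariant: multiplying a cell's counts by any positive constant
#' leaves its normalised vector unchanged.
#'
#' @param x a \linkS4class{RepairDataSet} of raw counts with every cell
#'   total positive (run [qcFilter()] first).
#' @return A \linkS4class{RepairDataSet} with
#'   \code{scaleTag = "cp10k_log1p"}.
#' @export
normalizeLog <- function(x) {
  stopifnot(is(x, "RepairDataSet"))
  if (!identical(scaleTag(x), "counts"))
    stop("normalizeLog expects raw counts (scaleTag 'counts')")
  counts <- exprValues(x)
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("cell(s) with zero total counts: run qcFilter before normalizeLog")
  v <- log1p(counts * rep(1e4 / tot, each = nrow(counts)))
  out <- x
  SummarizedExperiment::assays(out) <- list(logcounts = v)
  out@scaleTag <- "cp10k_log1p"
  validObject(out)
  out
}

#' Highly variable gene selection
#'
#' Keeps the \code{nTop} genes with the largest variance of log-normalised
#' expression across cells. Ties are broken by higher mean expression and
#' then lexicographic gene id, so selection is fully deterministic. The
#' original gene order is preserved among the selected genes, and the
#' selection is nested: the top-k set is a subset of the top-k' set for
#' k <= k'.
#'
#' @param x a \linkS4class{RepairDataSet} on the \code{"cp10k_log1p"} scale.
#' @param nTop number of genes to keep (capped at the gene count).
#' @return The column-subset \linkS4class{RepairDataSet}.
#' @export
selectHVG <- function(x, nTop = 5000) {
  stopifnot(is(x, "RepairDataSet"))
  if (!identical(scaleTag(x), "cp10k_log1p"))
    stop("selectHVG expects log-normalised data: run normalizeLog first")
  if (nTop < 1) stop("nTop must be >= 1")
  v <- exprValues(x)
  mu <- rowMeans(v)
  ss <- rowSums((v - mu)^2) / (ncol(v) - 1L)
  rank_order <- order(-ss, -mu, rownames(x))
  sel <- sort(rank_order[seq_len(min(nTop, nrow(x)))])
  x[sel, ]
}
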