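#' Generate a clustered synthetic single-cell dataset
#'
#' Draws a ground-truth counts matrix from a gamma-Poisson (negative
#' binomial) model with equally sized cell types and planted marker genes:
#' per-gene baseline means are log-normally dispersed around
#' \code{baseMean}, and each marker gene's mean is multiplied by
#' \code{exp(markerLogFC)} in cells of its own type. Transcript lengths are
#' drawn log-normal, giving the 3'-bias simulator meaningful variation.
#' With a single cell type no markers are planted (there is no "rest" to be
#' differential against).
#'
#' Generation is fully reproducible given \code{spec@seed} and leaves the
#' caller's RNG state untouched.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{RepairDataSet} of raw counts with cell-type
#'   labels, gene lengths, and the planted marker table available via
#'   [markerTable()] (a data.frame with columns \code{gene} and
#'   \code{cell_type}; empty when \code{nTypes == 1}).
#' @examples
#' truth <- generateTruth(SyntheticSpec(nCells = 100, nGenes = 50,
#'                                      nTypes = 2, markersPerType = 5))
#' table(cellTypes(truth))
#' head(markerTable(truth))
#' @export
generateTruth <- function(spec) {
  validObject(spec)
  G <- spec@nGenes; C <- spec@nCells; K <- spec@nTypes
  geneIds <- sprintf("gene%04d", seq_len(G))
  cellIds <- sprintf("cell%05d", seq_len(C))
  types <- sprintf("type%d", rep_len(seq_len(K), C))
  .with_seed(spec@seed, {
    lengths <- stats::rlnorm(G, spec@lengthLogMean, spec@lengthLogSD)
    # gene-level baseline variation so variance ranking is non-trivial
    mu <- spec@baseMean * exp(stats::rnorm(G, 0, 0.5))
    if (K >= 2L && spec@markersPerType > 0L) {
      midx <- sample.int(G, spec@markersPerType * K)
      mtype <- sprintf("type%d", rep(seq_len(K), each = spec@markersPerType))
    } else {
      midx <- integer(); mtype <- character()
    }
    Mu <- matrix(mu, G, C)
    if (length(midx)) {
      fc <- exp(spec@markerLogFC)
      for (k in seq_len(K)) {
        rows <- midx[mtype == sprintf("type%d", k)]
        Mu[rows, types == sprintf("type%d", k)] <-
          Mu[rows, types == sprintf("type%d", k)] * fc
      }
    }
    counts <- matrix(stats::rnbinom(G * C, mu = as.vector(Mu),
                                    size = 1 / spec@dispersion), G, C)
    rds <- RepairDataSet(counts, geneIds = geneIds, cellIds = cellIds,
                         geneLengths = lengths, cellTypes = types,
                         scaleTag = "counts")
    metadata(rds)$marker_table <- data.frame(
      gene = geneIds[midx], cell_type = mtype, stringsAsFactors = FALSE)
    metadata(rds)$synthetic_spec <- spec
    rds
  })
}

#' Generate a paired surface-protein panel
#'
#' Emulates a CITE-seq-style readout: for each (protein, gene) pair the
#' protein value per cell is a monotone (affine) transform of the paired
#' gene's log-normalised expression plus Gaussian noise of SD
#' \code{noiseSD}. With \code{noiseSD = 0} the protein is a strictly
#' monotone function of the gene's expression, so their Spearman
#' correlation is exactly 1.
#'
#' @param truth a \linkS4class{RepairDataSet}; raw counts are log-normalised
#'   internally, \code{"cp10k_log1p"} data are used as-is.
#' @param pairs data.frame with columns \code{protein} and \code{gene}, or a
#'   list of length-2 character vectors. May be empty.
#' @param noiseSD nonnegative numeric(1).
#' @param seed integer(1).
#' @return A \linkS4class{ProteinPanel} with one column per pair.
#' @export
generateProteinPanel <- function(truth, pairs, noiseSD = 0.3, seed = 1L) {
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- data.frame(protein = vapply(pairs, `[`, "", 1L),
                        gene = vapply(pairs, `[`, "", 2L))
  if (!nrow(pairs)) {
    return(new("ProteinPanel",
               values = matrix(numeric(), nrow = ncol(truth), ncol = 0L,
                               dimnames = list(colnames(truth), NULL)),
               pairs = data.frame(protein = character(),
                                  gene = character())))
  }
  missing <- setdiff(pairs$gene, rownames(truth))
  if (length(missing))
    stop("paired gene id(s) not found in dataset: ",
         paste(missing, collapse = ", "))
  x <- if (identical(scaleTag(truth), "counts")) normalizeLog(truth) else truth
  expr <- exprValues(x)[pairs$gene, , drop = FALSE]   # pairs x cells
  .with_seed(seed, {
    noise <- matrix(stats::rnorm(length(expr), 0, noiseSD),
                    nrow(expr), ncol(expr))
    vals <- t(0.5 + 1.0 * expr + noise)               # cells x proteins
  })
  colnames(vals) <- pairs$protein
  rownames(vals) <- colnames(truth)
  new("ProteinPanel", values = vals,
      pairs = data.frame(protein = as.character(pairs$protein),
                         gene = as.character(pairs$gene),
                         stringsAsFactors = FALSE))
}
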