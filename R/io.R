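#' Read an expression matrix
#'
#' Reads either a 10x-style Matrix Market directory (\code{matrix.mtx} plus
#' \code{features.tsv}/\code{genes.tsv} and \code{barcodes.tsv}, plain or
#' gzipped) or a dense CSV/TSV with a header row of gene ids and one row
#' per cell (cell ids in the first column). On-disk Matrix Market data are
#' conventionally genes x cells; orientation is detected from the id files
#' and normalised, so the returned object is always genes x cells in the
#' container with the ids attached.
#'
#' @param path directory (for \code{"mtx_dir"}) or file (for \code{"csv"}).
#' @param format \code{"mtx_dir"} or \code{"csv"}.
#' @return A \linkS4class{RepairDataSet} with \code{scaleTag = "counts"}.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") .read_mtx_dir(path) else .read_csv(path)
}

.find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

.read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  mtx <- .find_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("matrix.mtx not found in ", path)
  feat <- .find_file(path, c("features.tsv", "features.tsv.gz",
                             "genes.tsv", "genes.tsv.gz"))
  if (is.null(feat)) stop("features.tsv / genes.tsv not found in ", path)
  bc <- .find_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bc)) stop("barcodes.tsv not found in ", path)
  m <- as.matrix(Matrix::readMM(mtx))
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)
  geneIds <- as.character(features[[1L]])
  cellIds <- as.character(barcodes[[1L]])
  if (nrow(m) == length(geneIds) && ncol(m) == length(cellIds)) {
    # canonical 10x orientation: genes x cells
  } else if (nrow(m) == length(cellIds) && ncol(m) == length(geneIds)) {
    m <- t(m)
  } else {
    stop(sprintf(
      "dimension mismatch: matrix.mtx is %d x %d but %s has %d rows and %s has %d rows",
      nrow(m), ncol(m), basename(feat), length(geneIds), basename(bc),
      length(cellIds)))
  }
  RepairDataSet(m, geneIds = geneIds, cellIds = cellIds, scaleTag = "counts")
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)   # cells x genes on disk
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  RepairDataSet(t(m), geneIds = colnames(m), cellIds = rownames(m),
                scaleTag = "counts")
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix()]: \code{"mtx_dir"} writes
#' \code{matrix.mtx} (genes x cells), \code{features.tsv} and
#' \code{barcodes.tsv} into \code{path}; \code{"csv"} writes a dense
#' cells x genes table with gene ids as header and cell ids as row names.
#'
#' @param x a \linkS4class{RepairDataSet} (or any SummarizedExperiment).
#' @param path output directory (mtx_dir) or file (csv).
#' @param format \code{"mtx_dir"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  v <- as.matrix(SummarizedExperiment::assay(x, 1L))
  if (format == "mtx_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(rownames(v), rownames(v)),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(colnames(v)),
                       file.path(path, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.csv(t(v), path, quote = FALSE)
  }
  invisible(path)
}
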