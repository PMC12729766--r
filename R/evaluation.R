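#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision over all distinct score thresholds:
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} with precision and recall
#' evaluated at each distinct threshold, tied scores handled as one block.
#'
#' @param scores numeric vector.
#' @param positives logical vector, same length: the true positive class.
#' @return numeric(1) in [0, 1], or NA (with a warning) when there are no
#'   positives.
#' @export
averagePrecision <- function(scores, positives) {
  if (length(scores) != length(positives)) stop("length mismatch")
  P <- sum(positives)
  if (P == 0L) {
    warning("no positive examples: average precision undefined")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  y <- as.numeric(positives[o])
  s <- scores[o]
  ends <- c(which(diff(s) != 0), length(s))   # last index of each tie block
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Technical repair metrics
#'
#' Computes the technical scorecard comparing a repaired (or degraded)
#' matrix against the original: MSE and Pearson correlation over all
#' flattened entries, and PR-AUC plus F1 for the expressed-vs-unexpressed
#' task, in which an entry is truly positive when the original value is
#' strictly positive and the reconstructed value is used as score (F1 after
#' binarising at \code{threshold}).
#'
#' @param xHat,xOrig cells x genes matrices (or SummarizedExperiment, first
#'   assay) of identical shape.
#' @param threshold binarisation threshold for F1 on the log-normalised
#'   scale (default 0.1).
#' @return list with elements \code{mse}, \code{pearson}, \code{prAuc},
#'   \code{f1}. Pearson is NA with a warning when either input is constant.
#' @export
technicalMetrics <- function(xHat, xOrig, threshold = 0.1) {
  xHat <- .cells_by_genes(xHat)
  xOrig <- .cells_by_genes(xOrig)
  if (!identical(dim(xHat), dim(xOrig)))
    stop("shape mismatch between xHat and xOrig")
  h <- as.vector(xHat)
  o <- as.vector(xOrig)
  mse <- mean((h - o)^2)
  pearson <- if (stats::sd(h) == 0 || stats::sd(o) == 0) {
    warning("constant input: Pearson correlation undefined")
    NA_real_
  } else stats::cor(h, o)
  pos <- o > 0
  prAuc <- averagePrecision(h, pos)
  predpos <- h > threshold
  tp <- sum(predpos & pos)
  f1 <- if (2 * tp + sum(predpos & !pos) + sum(!predpos & pos) == 0) 0
        else 2 * tp / (2 * tp + sum(predpos & !pos) + sum(!predpos & pos))
  list(mse = mse, pearson = pearson, prAuc = prAuc, f1 = f1)
}

#' Cell-type separation score
#'
#' Mean silhouette width of the labelled cell types, computed with
#' Euclidean distance in the space of the top principal components of the
#' expression matrix (at most \code{nPCs}), rescaled from [-1, 1] to
#' [0, 100] via \eqn{(s + 1)/2 \times 100}.
#'
#' @param x cells x genes matrix (or SummarizedExperiment).
#' @param labels per-cell labels; at least 2 distinct labels with at least
#'   2 cells each.
#' @param nPCs number of principal components (default 50, capped by the
#'   data dimensions).
#' @return numeric(1) in [0, 100].
#' @export
cellTypeSeparation <- function(x, labels, nPCs = 50) {
  x <- .cells_by_genes(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("labels must have one entry per cell")
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("cell-type separation is undefined for a single label")
  if (any(tab < 2L))
    stop("every label needs at least 2 cells")
  k <- min(nPCs, ncol(x), nrow(x) - 1L)
  pcs <- stats::prcomp(x, rank. = k, center = TRUE, scale. = FALSE)$x
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(pcs))
  s <- mean(sil[, "sil_width"])
  (s + 1) / 2 * 100
}

# vectorised one-vs-rest Wilcoxon rank-sum (Mann-Whitney) statistics:
# normal approximation with tie correction, no continuity correction
.ranksum_one_vs_rest <- function(X, ingrp) {
  n1 <- sum(ingrp); n2 <- sum(!ingrp); n <- n1 + n2
  R <- apply(X, 2L, rank)
  W <- colSums(R[ingrp, , drop = FALSE]) - n1 * (n1 + 1) / 2
  tiesum <- apply(X, 2L, function(col) {
    t <- tabulate(match(col, unique(col)))
    sum(t^3 - t)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (W - n1 * n2 / 2) / sqrt(sig2), 0)
  p <- ifelse(sig2 > 0, 2 * stats::pnorm(-abs(z)), 1)
  lfc <- colMeans(X[ingrp, , drop = FALSE]) -
         colMeans(X[!ingrp, , drop = FALSE])
  data.frame(gene = colnames(X), p = p, lfc = lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest rank-sum differential expression
#'
#' For each label, tests every gene with a two-sided Wilcoxon rank-sum test
#' of that label's cells against all others (normal approximation with tie
#' correction) and reports the p-value and the difference of means on the
#' current scale (log fold change for log-normalised input).
#'
#' @param x cells x genes matrix (or SummarizedExperiment) with gene ids as
#'   column names.
#' @param labels per-cell labels (at least 2 distinct).
#' @return Named list (one element per label) of data.frames with columns
#'   \code{gene}, \code{p}, \code{lfc}, in the input gene order.
#' @seealso [topDEGs()], [degPreservation()]
#' @export
rankSumDEG <- function(x, labels) {
  X <- .cells_by_genes(x)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("gene%04d", seq_len(ncol(X)))
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("labels must have one entry per cell")
  ulab <- sort(unique(labels))
  if (length(ulab) < 2L) stop("at least 2 labels are required")
  stats::setNames(lapply(ulab, function(l)
    .ranksum_one_vs_rest(X, labels == l)), ulab)
}

# deterministic ranking: smallest p, then largest |lfc|, then gene id
.top_genes <- function(df, topK) {
  o <- order(df$p, -abs(df$lfc), df$gene)
  df$gene[o[seq_len(topK)]]
}

#' Top differentially expressed genes per label
#'
#' @inheritParams rankSumDEG
#' @param topK number of genes per label; ties in p-value are broken by
#'   larger absolute log fold change, then gene id.
#' @return Named list of character vectors of gene ids.
#' @export
topDEGs <- function(x, labels, topK = 50) {
  deg <- rankSumDEG(x, labels)
  ng <- nrow(deg[[1L]])
  if (topK > ng) stop("topK exceeds the number of genes")
  lapply(deg, .top_genes, topK = topK)
}

#' Differential-expression preservation score
#'
#' Quantifies how well repair preserves the top differential-expression
#' structure: for each label, the top-\code{topK} one-vs-rest DEG sets are
#' computed independently from the original and reconstructed matrices and
#' compared by Jaccard index and F1 (set-overlap) score, averaged over
#' labels. The score is \code{mean(jaccard, f1) * 100}.
#'
#' @param xHat,xOrig cells x genes matrices (or SummarizedExperiment).
#' @param labels per-cell labels.
#' @param topK DEG set size per label (default 50).
#' @return list with \code{jaccard}, \code{f1} (both in [0, 1]) and
#'   \code{score} in [0, 100].
#' @export
degPreservation <- function(xHat, xOrig, labels, topK = 50) {
  setsHat <- topDEGs(xHat, labels, topK = topK)
  setsOrig <- topDEGs(xOrig, labels, topK = topK)
  jac <- f1 <- numeric(length(setsOrig))
  for (i in seq_along(setsOrig)) {
    a <- setsOrig[[i]]; b <- setsHat[[i]]
    inter <- length(intersect(a, b))
    jac[i] <- inter / length(union(a, b))
    f1[i] <- 2 * inter / (length(a) + length(b))
  }
  list(jaccard = mean(jac), f1 = mean(f1),
       score = mean(c(mean(jac), mean(f1))) * 100)
}

#' Marker-gene recovery score
#'
#' Mean (over marker genes) Spearman correlation across cells between the
#' reconstructed and original expression of each marker, negatively
#' correlated markers clipped to 0 ("no recovery"), scaled to [0, 100].
#'
#' @param xHat,xOrig cells x genes matrices (or SummarizedExperiment) with
#'   gene ids as column names.
#' @param markerGenes character vector of gene ids present in both.
#' @return numeric(1) in [0, 100].
#' @export
markerRecovery <- function(xHat, xOrig, markerGenes) {
  H <- .cells_by_genes(xHat)
  O <- .cells_by_genes(xOrig)
  markerGenes <- as.character(markerGenes)
  missing <- c(setdiff(markerGenes, colnames(H)),
               setdiff(markerGenes, colnames(O)))
  if (length(missing))
    stop("marker gene(s) absent: ", paste(unique(missing), collapse = ", "))
  rho <- vapply(markerGenes, function(g) {
    r <- suppressWarnings(
      stats::cor(H[, g], O[, g], method = "spearman"))
    if (is.na(r)) 0 else r
  }, numeric(1))
  mean(pmax(rho, 0)) * 100
}

#' Overall biological score
#'
#' The arithmetic mean of the three biological metrics (cell-type
#' separation, differential-expression preservation, marker recovery),
#' reported to 3 decimals.
#'
#' @param separation,deg,marker scores in [0, 100].
#' @return numeric(1) in [0, 100].
#' @examples
#' overallBiological(65.210, 57.410, 66.450)  # 63.023
#' @export
overallBiological <- function(separation, deg, marker) {
  vals <- c(separation, deg, marker)
  if (anyNA(vals) || any(vals < 0 | vals > 100))
    stop("all three scores must lie in [0, 100]")
  round(mean(vals), 3)
}

#' Paired significance test with effect size
#'
#' Two-sided paired t-test of per-cell (or per-pair) metric values under
#' two conditions, with the paired Cohen's d effect size: mean of the
#' differences over their standard deviation (n-1 denominator). When all
#' differences are exactly zero the t statistic is undefined; p = 1 and
#' d = 0 are returned with the degenerate flag set.
#'
#' @param a,b numeric vectors of equal length n >= 2 (condition A and B per
#'   unit); differences are a - b.
#' @return A \linkS4class{PairedTestResult}.
#' @examples
#' pairedSignificance(c(2, 3, 4), c(1, 1, 1))  # mean diff 2, d = 2
#' @export
pairedSignificance <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- a - b
  if (all(d == 0)) {
    return(new("PairedTestResult", pValue = 1, cohenD = 0, n = as.integer(n),
               meanDiff = 0, degenerate = TRUE))
  }
  sdd <- stats::sd(d)
  cohen <- if (sdd > 0) mean(d) / sdd else Inf * sign(mean(d))
  p <- if (sdd > 0) stats::t.test(a, b, paired = TRUE)$p.value else 0
  new("PairedTestResult", pValue = p, cohenD = cohen, n = as.integer(n),
      meanDiff = mean(d), degenerate = FALSE)
}

#' Orthogonal RNA-protein validation
#'
#' Uses a paired surface-protein panel as an RNA-independent readout.
#' Degradation of the RNA should lower, and repair restore, the per-pair
#' Spearman correlation between each protein and its paired gene. The
#' recovered share of the lost correlation is summarised as
#' \deqn{(mean_{rep} - mean_{deg}) / (mean_{orig} - mean_{deg})}
#' and repaired-vs-degraded per-pair correlations are compared with a
#' paired t-test.
#'
#' @param rnaOrig,rnaDeg,rnaRep cells x genes matrices (or
#'   SummarizedExperiment) aligned with the panel's cells.
#' @param panel a \linkS4class{ProteinPanel}.
#' @return list with \code{perPair} (data.frame of per-pair correlations in
#'   the three conditions), \code{summary} (mean and SD per condition),
#'   \code{recoveryFraction} (NA with a warning when original and degraded
#'   means coincide) and \code{pairedTest}.
#' @export
orthogonalProteinValidation <- function(rnaOrig, rnaDeg, rnaRep, panel) {
  stopifnot(is(panel, "ProteinPanel"))
  O <- .cells_by_genes(rnaOrig)
  D <- .cells_by_genes(rnaDeg)
  R <- .cells_by_genes(rnaRep)
  pv <- proteinValues(panel)
  pairs <- proteinPairs(panel)
  if (nrow(pv) != nrow(O))
    stop("panel cells are not aligned with the RNA matrices")
  if (!nrow(pairs)) stop("empty protein panel")
  rho <- function(M, i) suppressWarnings(
    stats::cor(pv[, i], M[, pairs$gene[i]], method = "spearman"))
  perPair <- data.frame(
    protein = pairs$protein, gene = pairs$gene,
    rho_orig = vapply(seq_len(nrow(pairs)), function(i) rho(O, i), 1),
    rho_deg = vapply(seq_len(nrow(pairs)), function(i) rho(D, i), 1),
    rho_rep = vapply(seq_len(nrow(pairs)), function(i) rho(R, i), 1),
    stringsAsFactors = FALSE)
  summ <- data.frame(
    condition = c("original", "degraded", "repaired"),
    mean = c(mean(perPair$rho_orig), mean(perPair$rho_deg),
             mean(perPair$rho_rep)),
    sd = c(stats::sd(perPair$rho_orig), stats::sd(perPair$rho_deg),
           stats::sd(perPair$rho_rep)))
  denom <- summ$mean[1L] - summ$mean[2L]
  recovery <- if (abs(denom) < 1e-12) {
    warning("original and degraded mean correlations coincide: recovery fraction undefined")
    NA_real_
  } else (summ$mean[3L] - summ$mean[2L]) / denom
  list(perPair = perPair, summary = summ, recoveryFraction = recovery,
       pairedTest = pairedSignificance(perPair$rho_rep, perPair$rho_deg))
}

#' Cross-validated cell-type classification check
#'
#' Stratified k-fold cross-validation of a multinomial logistic-regression
#' classifier predicting cell types from expression, as a downstream
#' usability check of repaired data.
#'
#' @param x cells x genes matrix (or SummarizedExperiment).
#' @param labels per-cell labels; every class needs at least \code{folds}
#'   members.
#' @param folds number of folds (default 5).
#' @param seed integer(1).
#' @return list with \code{foldAccuracy} (numeric vector of length
#'   \code{folds}) and \code{meanAccuracy}.
#' @export
classifierValidation <- function(x, labels, folds = 5L, seed = 1L) {
  X <- .cells_by_genes(x)
  y <- factor(labels)
  if (length(y) != nrow(X)) stop("labels must have one entry per cell")
  tab <- table(y)
  if (any(tab < folds))
    stop("class(es) smaller than the number of folds: ",
         paste(names(tab)[tab < folds], collapse = ", "))
  fold_id <- integer(length(y))
  .with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  df <- data.frame(y = y, X)
  acc <- vapply(seq_len(folds), function(f) {
    fit <- nnet::multinom(y ~ ., data = df[fold_id != f, , drop = FALSE],
                          trace = FALSE, MaxNWts = 100000L)
    pred <- stats::predict(fit, newdata = df[fold_id == f, , drop = FALSE])
    mean(pred == y[fold_id == f])
  }, numeric(1))
  list(foldAccuracy = acc, meanAccuracy = mean(acc))
}

#' Full evaluation scorecard
#'
#' Composes the technical and biological metrics into a
#' \linkS4class{MetricsReport}.
#'
#' @param xHat,xOrig cells x genes matrices (or SummarizedExperiment).
#' @param labels per-cell cell-type labels.
#' @param markerGenes character vector of marker gene ids.
#' @param topK DEG set size (default 50).
#' @param threshold F1 binarisation threshold (default 0.1).
#' @param nPCs principal components for the separation score (default 50).
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateRepair <- function(xHat, xOrig, labels, markerGenes, topK = 50,
                           threshold = 0.1, nPCs = 50) {
  tech <- technicalMetrics(xHat, xOrig, threshold = threshold)
  sep <- cellTypeSeparation(xHat, labels, nPCs = nPCs)
  deg <- degPreservation(xHat, xOrig, labels, topK = topK)
  mark <- markerRecovery(xHat, xOrig, markerGenes)
  new("MetricsReport", mse = tech$mse, pearson = tech$pearson,
      prAuc = tech$prAuc, f1 = tech$f1, cellTypeSeparation = sep,
      degPreservation = deg$score, markerRecovery = mark,
      overallBiological = overallBiological(sep, deg$score, mark))
}

#' Flatten a MetricsReport to a named numeric vector
#' @param report a \linkS4class{MetricsReport}.
#' @return named numeric vector of the eight metrics.
#' @export
metricsAsVector <- function(report) {
  c(mse = report@mse, pearson = report@pearson, pr_auc = report@prAuc,
    f1 = report@f1, cell_type_separation = report@cellTypeSeparation,
    deg_preservation = report@degPreservation,
    marker_recovery = report@markerRecovery,
    overall_biological = report@overallBiological)
}
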