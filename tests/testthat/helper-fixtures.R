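# Shared fixture builders. Everything is generated in code at test time;
# no data files are read.

metadata <- S4Vectors::metadata

# small clustered ground-truth dataset
tiny_truth <- function(nCells = 120, nGenes = 40, nTypes = 2,
                       markersPerType = 4, seed = 7) {
  generateTruth(SyntheticSpec(nCells = nCells, nGenes = nGenes,
                              nTypes = nTypes,
                              markersPerType = markersPerType, seed = seed))
}

# log-normalised dataset straight from the generator (QC skipped: the
# generator cannot produce zero-total cells at the default base mean)
tiny_norm <- function(...) normalizeLog(tiny_truth(...))

# a RepairDataSet on the log scale built from an explicit matrix
# (genes x cells), with equal gene lengths unless given
norm_rds <- function(v, lengths = rep(1000, nrow(v))) {
  dimnames(v) <- list(sprintf("g%03d", seq_len(nrow(v))),
                      sprintf("c%03d", seq_len(ncol(v))))
  RepairDataSet(v, geneLengths = lengths, scaleTag = "cp10k_log1p")
}

# an aligned degraded pair on a small dataset
tiny_pair <- function(alpha = 0.5, dropoutRate = 0.3, noiseSD = 0.2,
                      seed = 7, ...) {
  degrade(tiny_norm(...),
          DegradationParams(alpha, dropoutRate, noiseSD, seed = seed))
}

# brute-force average precision by explicit threshold enumeration
# (independent of the package's cumulative-sum implementation)
ap_oracle <- function(scores, positives) {
  P <- sum(positives)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & positives)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# brute-force one-vs-rest rank-sum top-k sets via stats::wilcox.test,
# normal approximation without continuity correction (the package's
# analytic path is an independent vectorised implementation)
topk_oracle <- function(X, labels, topK) {
  out <- list()
  for (l in sort(unique(labels))) {
    ingrp <- labels == l
    p <- lfc <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      p[j] <- suppressWarnings(
        stats::wilcox.test(X[ingrp, j], X[!ingrp, j], exact = FALSE,
                           correct = FALSE)$p.value)
      if (is.na(p[j])) p[j] <- 1
      lfc[j] <- mean(X[ingrp, j]) - mean(X[!ingrp, j])
    }
    o <- order(p, -abs(lfc), colnames(X))
    out[[l]] <- colnames(X)[o[seq_len(topK)]]
  }
  out
}
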