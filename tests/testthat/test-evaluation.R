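test_that("technical metrics have exact identity and anti-identity limits", {
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  tm <- technicalMetrics(X, X)
  expect_equal(tm$mse, 0)
  expect_equal(tm$pearson, 1)

  anti <- technicalMetrics(-X, X)   # X is (near) zero-mean by construction
  expect_equal(anti$pearson, -1, tolerance = 1e-12)

  expect_warning(technicalMetrics(matrix(1, 5, 2), matrix(1:10, 5, 2)),
                 "constant")
  expect_error(technicalMetrics(X, X[1:3, ]), "shape")
})

test_that("average precision equals the threshold-enumeration oracle", {
  # worked 6-entry example: positives at entries 1 and 3
  scores <- c(0.9, 0.8, 0.7, 0.1, 0.05, 0.01)
  pos <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(averagePrecision(scores, pos), ap_oracle(scores, pos))
  expect_equal(averagePrecision(scores, pos), (1 + 2 / 3) / 2)

  # randomized instances, with ties, against the brute-force oracle
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:1000, 1)
    sc <- sample(round(runif(n), 2))      # coarse grid forces tied scores
    ps <- runif(n) < 0.3
    if (!any(ps)) ps[1] <- TRUE
    expect_equal(averagePrecision(sc, ps), ap_oracle(sc, ps),
                 tolerance = 1e-12)
  }
  expect_warning(averagePrecision(1:3, rep(FALSE, 3)), "no positive")
})

test_that("F1 uses the configured binarisation threshold", {
  orig <- matrix(c(2, 0, 1, 0), 1)   # positives at entries 1 and 3
  hat <- matrix(c(0.5, 0.3, 0.05, 0.01), 1)
  # at tau = 0.1: predictions {1,2}; tp=1, fp=1, fn=1 -> F1 = 0.5
  expect_equal(technicalMetrics(hat, orig)$f1, 0.5)
  # at tau = 0.4: predictions {1}; tp=1, fp=0, fn=1 -> F1 = 2/3
  expect_equal(technicalMetrics(hat, orig, threshold = 0.4)$f1, 2 / 3)
})

test_that("cell-type separation maps silhouette onto [0, 100] as decided", {
  # two tight clusters far apart: every silhouette width is 1 -> score 100
  X <- rbind(matrix(0, 3, 2), matrix(100, 3, 2)) +
    matrix(rnorm(12, 0, 1e-9), 6, 2)
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(cellTypeSeparation(X, lab), 100, tolerance = 1e-6)

  # equidistant points (scaled identity): a = b for every cell -> s = 0
  # -> score exactly 50 under the affine map (s+1)/2 * 100
  expect_equal(cellTypeSeparation(diag(4) * 10, c("a", "a", "b", "b")), 50,
               tolerance = 1e-9)

  expect_error(cellTypeSeparation(X, rep("a", 6)), "single label")
  expect_error(cellTypeSeparation(X, c("a", rep("b", 5))), "at least 2")
})

test_that("shuffled labels cannot beat the true clustering", {
  norm <- tiny_norm(nCells = 150, nGenes = 40, nTypes = 3,
                    markersPerType = 6, seed = 51)
  X <- t(exprValues(norm))
  lab <- cellTypes(norm)
  real <- cellTypeSeparation(X, lab)
  set.seed(99)
  shuffled <- mean(replicate(5, cellTypeSeparation(X, sample(lab))))
  expect_gt(real, shuffled)
})

test_that("DEG sets match a brute-force rank-sum oracle on a 20-gene toy", {
  set.seed(12)
  n <- 60
  lab <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  planted <- c(1, 4, 7, 11, 18)
  X[lab == "a", planted] <- X[lab == "a", planted] + 1.5
  tops <- topDEGs(X, lab, topK = 5)
  oracle <- topk_oracle(X, lab, topK = 5)
  expect_identical(tops, oracle)
  expect_setequal(tops$a, colnames(X)[planted])
})

test_that("DEG preservation is 100 on identity and near chance on permutation", {
  norm <- tiny_norm(nCells = 200, nGenes = 300, nTypes = 2,
                    markersPerType = 10, seed = 53)
  X <- t(exprValues(norm))
  lab <- cellTypes(norm)
  idp <- degPreservation(X, X, lab, topK = 20)
  expect_equal(idp$jaccard, 1)
  expect_equal(idp$f1, 1)
  expect_equal(idp$score, 100)

  set.seed(7)
  Xperm <- X[, sample(ncol(X))]
  colnames(Xperm) <- colnames(X)   # break the gene correspondence
  perm <- degPreservation(Xperm, X, lab, topK = 20)
  expect_lt(perm$score, 30)   # chance scale ~ 2*topK/nGenes

  expect_error(degPreservation(X, X, lab, topK = 1000), "topK")
})

test_that("marker recovery follows Spearman with clipping at zero", {
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2,
              dimnames = list(NULL, c("m1", "m2")))
  expect_equal(markerRecovery(X, X, c("m1", "m2")), 100)

  rev <- X[4:1, ]
  expect_equal(markerRecovery(rev, X, c("m1", "m2")), 0)

  # hand-computed Spearman: ranks (2,1,4,3) vs (1,2,3,4) -> rho = 0.6
  Y <- X
  Y[, 1] <- c(2, 1, 4, 3)
  expect_equal(markerRecovery(Y, X, "m1"), 60)

  expect_error(markerRecovery(X, X, "absent"), "absent")
})

test_that("the overall biological score is the exact 3-decimal mean", {
  expect_equal(overallBiological(0, 0, 0), 0)
  expect_equal(overallBiological(30, 60, 90), 60)
  expect_error(overallBiological(101, 50, 50), "\\[0, 100\\]")
  expect_error(overallBiological(-1, 50, 50), "\\[0, 100\\]")
})

test_that("paired significance matches hand arithmetic and conventions", {
  r <- pairedSignificance(c(2, 3, 4), c(1, 1, 1))   # diffs 1, 2, 3
  expect_equal(r@meanDiff, 2)
  expect_equal(r@cohenD, 2)
  expect_equal(r@n, 3L)
  # t = mean/ (sd/sqrt(n)) = 2 * sqrt(3); two-sided p with 2 df
  expect_equal(r@pValue, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_false(r@degenerate)

  same <- pairedSignificance(c(1, 2, 3), c(1, 2, 3))
  expect_true(same@degenerate)
  expect_equal(same@pValue, 1)
  expect_equal(same@cohenD, 0)

  # sign convention: d and the mean difference agree
  neg <- pairedSignificance(c(1, 1, 1), c(2, 3, 4))
  expect_lt(neg@cohenD, 0)
  expect_lt(neg@meanDiff, 0)

  expect_error(pairedSignificance(1:3, 1:2), "equal length")
  expect_error(pairedSignificance(1, 1), "at least 2")
})

test_that("the paired test holds its nominal type-I error under the null", {
  set.seed(31)
  reps <- 2000
  rej <- mean(replicate(reps, {
    a <- rnorm(50); b <- rnorm(50)
    pairedSignificance(a, b)@pValue < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("orthogonal protein validation has exact recovery limits", {
  norm <- tiny_norm(nCells = 150, nGenes = 40, seed = 61)
  mk <- markerTable(tiny_truth(nCells = 150, nGenes = 40, seed = 61))$gene[1:4]
  pairs <- data.frame(protein = paste0("p", mk), gene = mk)
  panel <- generateProteinPanel(tiny_truth(nCells = 150, nGenes = 40,
                                           seed = 61),
                                pairs, noiseSD = 0.3, seed = 2)
  X <- t(exprValues(norm))
  pairD <- degrade(norm, DegradationParams(0, 0.5, 0.3, seed = 3))
  Xdeg <- t(degradedMatrix(pairD))

  full <- orthogonalProteinValidation(X, Xdeg, X, panel)
  expect_equal(full$recoveryFraction, 1)
  none <- orthogonalProteinValidation(X, Xdeg, Xdeg, panel)
  expect_equal(none$recoveryFraction, 0)

  expect_warning(orthogonalProteinValidation(X, X, X, panel), "coincide")
})

test_that("classifier validation is exact on separable data, chance on noise", {
  set.seed(71)
  X <- rbind(matrix(rnorm(50 * 5, 0), 50, 5),
             matrix(rnorm(50 * 5, 10), 50, 5))
  lab <- rep(c("a", "b"), each = 50)
  cv <- classifierValidation(X, lab, folds = 5, seed = 1)
  expect_length(cv$foldAccuracy, 5)
  expect_gte(cv$meanAccuracy, 0.99)

  # labels shuffled over 4 balanced classes: chance is 0.25
  lab4 <- sample(rep(c("a", "b", "c", "d"), 25))
  Xn <- matrix(rnorm(100 * 5), 100, 5)
  cvn <- classifierValidation(Xn, lab4, folds = 5, seed = 2)
  expect_gt(cvn$meanAccuracy, 0.05)
  expect_lt(cvn$meanAccuracy, 0.45)

  expect_error(classifierValidation(X, c(rep("a", 98), "b", "b"), folds = 5),
               "smaller than")
})

test_that("evaluateRepair composes a consistent MetricsReport", {
  norm <- tiny_norm(nCells = 120, nGenes = 40, nTypes = 2,
                    markersPerType = 4, seed = 81)
  truth <- tiny_truth(nCells = 120, nGenes = 40, nTypes = 2,
                      markersPerType = 4, seed = 81)
  X <- t(exprValues(norm))
  pair <- degrade(norm, DegradationParams(0.3, 0.3, 0.2, seed = 5))
  Xdeg <- t(degradedMatrix(pair))
  mk <- markerTable(truth)$gene
  rep <- evaluateRepair(Xdeg, X, cellTypes(norm), mk, topK = 10)
  expect_s4_class(rep, "MetricsReport")
  v <- metricsAsVector(rep)
  expect_true(all(v[c("pr_auc", "f1")] >= 0 & v[c("pr_auc", "f1")] <= 1))
  expect_true(all(v[5:8] >= 0 & v[5:8] <= 100))
  expect_equal(unname(v["overall_biological"]),
               round(mean(v[5:7]), 3), tolerance = 1e-9)
})
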