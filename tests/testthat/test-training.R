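test_that("splits are disjoint covers at the target fractions", {
  s <- splitDataset(100, seed = 5)
  expect_length(s@trainIdx, 80)
  expect_length(s@valIdx, 10)
  expect_length(s@testIdx, 10)
  allidx <- c(s@trainIdx, s@valIdx, s@testIdx)
  expect_equal(sort(allidx), 1:100)

  # partition contract holds for awkward sizes too
  for (n in c(10, 37, 101)) {
    s2 <- splitDataset(n, seed = n)
    idx <- c(s2@trainIdx, s2@valIdx, s2@testIdx)
    expect_equal(sort(idx), seq_len(n))
    expect_equal(anyDuplicated(idx), 0L)
  }

  expect_error(splitDataset(10, fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("stratified splits represent every label to within one cell", {
  labels <- rep(c("a", "b", "c", "d"), each = 100)
  s <- splitDataset(400, labels = labels, seed = 2)
  for (set in list(s@trainIdx, s@valIdx, s@testIdx)) {
    tab <- table(labels[set])
    expect_true(all(abs(tab - length(set) / 4) <= 1))
  }
  expect_error(splitDataset(5, labels = c("a", "a", "a", "b", "b")),
               "stratum")
  # deterministic given seed
  expect_identical(splitDataset(400, labels = labels, seed = 2)@trainIdx,
                   s@trainIdx)
})

test_that("plateau schedule halves the rate after the patience window", {
  # constant (never-improving after the first epoch) validation trace:
  # the first epoch sets the best, epochs 2..11 accumulate 10 waits,
  # so the rate halves when the scheduler sees epoch 11
  tr <- replayPlateauSchedule(rep(1, 13), lr0 = 2e-4)
  expect_equal(tr$lr_used[1:11], rep(2e-4, 11))
  expect_equal(tr$lr_after[11], 1e-4)
  expect_equal(tr$lr_used[12], 1e-4)

  # a steadily improving trace never triggers
  tr2 <- replayPlateauSchedule(exp(-(1:30)), lr0 = 1e-3)
  expect_equal(unique(tr2$lr_after), 1e-3)

  # improvements below the relative threshold do not reset the counter
  v <- 1 - cumsum(rep(1e-7, 12))
  tr3 <- replayPlateauSchedule(v, lr0 = 1e-3, relTol = 1e-4)
  expect_equal(tr3$lr_after[11], 5e-4)
})

test_that("training learns the identity task and selects the best epoch", {
  norm <- tiny_norm(nCells = 120, nGenes = 20, seed = 31)
  pair <- degrade(norm, DegradationParams(0, 0, 0, seed = 1))
  split <- splitDataset(ncol(pair), seed = 1)
  cfg <- RepairModelConfig(nGenes = 20, embedDim = 16, numHeads = 2,
                           numLayers = 1, ffnDim = 32, tokenSize = 5,
                           dropout = 0, seed = 2)
  model <- buildRepairModel(cfg)
  Xva <- t(degradedMatrix(pair))[split@valIdx, ]
  before <- mseLoss(repairExpression(model, Xva),
                    t(originalMatrix(pair))[split@valIdx, ])
  fit <- trainRepairModel(model, pair, split,
                          TrainConfig(batchSize = 32, learningRate = 1e-2,
                                      maxEpochs = 60, seed = 3))
  h <- fit$history@history
  expect_lt(min(h$val_loss), before)
  expect_lt(min(h$val_loss), 0.1)
  expect_equal(fit$history@bestEpoch, which.min(h$val_loss))
  expect_equal(modelMode(fit$model), "eval")

  # the realized learning-rate trace replays exactly from the loss trace
  replay <- replayPlateauSchedule(h$val_loss, lr0 = 1e-2)
  expect_equal(h$lr, replay$lr_used)

  # test-set firewall: no test index entered gradients or scheduling
  expect_length(intersect(fit$history@usedIdx$gradient, split@testIdx), 0)
  expect_length(intersect(fit$history@usedIdx$scheduler, split@testIdx), 0)
  expect_setequal(fit$history@usedIdx$gradient, split@trainIdx)
})

test_that("training is bitwise reproducible under a fixed seed", {
  pair <- tiny_pair(nCells = 80, nGenes = 15, seed = 21)
  split <- splitDataset(ncol(pair), seed = 4)
  cfg <- RepairModelConfig(nGenes = 15, embedDim = 8, numHeads = 2,
                           numLayers = 1, ffnDim = 16, tokenSize = 5,
                           seed = 5)
  tc <- TrainConfig(maxEpochs = 4, seed = 6)
  f1 <- trainRepairModel(buildRepairModel(cfg), pair, split, tc)
  f2 <- trainRepairModel(buildRepairModel(cfg), pair, split, tc)
  expect_identical(f1$history@history, f2$history@history)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("training rejects invalid splits", {
  pair <- tiny_pair(nCells = 50, nGenes = 10, seed = 22)
  empty <- new("SplitAssignment", trainIdx = integer(),
               valIdx = 1:5, testIdx = 6:10,
               fractions = c(0.8, 0.1, 0.1), stratified = FALSE, seed = 1L)
  cfg <- RepairModelConfig(nGenes = 10, embedDim = 8, numHeads = 2,
                           numLayers = 1, ffnDim = 16, tokenSize = 5)
  expect_error(trainRepairModel(buildRepairModel(cfg), pair, empty),
               "empty training split")
})

test_that("the grid runner reproduces single runs and survives failures", {
  pair <- tiny_pair(nCells = 80, nGenes = 16, seed = 25)
  split <- splitDataset(ncol(pair), seed = 7)
  tc <- TrainConfig(maxEpochs = 3, seed = 8)
  mk <- function(ed, nl) RepairModelConfig(
    nGenes = 16, embedDim = ed, numHeads = 2, numLayers = nl,
    ffnDim = 2L * ed, tokenSize = 8, seed = 9)

  # singleton grid equals a direct train + evaluate
  g1 <- gridRunner(pair, split, tc, list(mk(8L, 1L)))
  fit <- trainRepairModel(buildRepairModel(mk(8L, 1L)), pair, split, tc)
  Xte <- t(degradedMatrix(pair))[split@testIdx, ]
  Yte <- t(originalMatrix(pair))[split@testIdx, ]
  expect_equal(g1$test_mse, mseLoss(repairExpression(fit$model, Xte), Yte))
  expect_equal(g1$status, "ok")

  # duplicated config -> identical rows; 2x2 grid -> finite metrics
  g2 <- gridRunner(pair, split, tc,
                   list(mk(8L, 1L), mk(8L, 1L), mk(8L, 2L), mk(16L, 2L)))
  expect_equal(g2$test_mse[1], g2$test_mse[2])
  expect_true(all(is.finite(g2$test_mse)))
  expect_true(all(is.finite(g2$test_pearson)))
  expect_equal(nrow(g2), 4)

  expect_error(gridRunner(pair, split, tc, list()), "nonempty")
})
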