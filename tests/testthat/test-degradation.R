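test_that("bias factors follow the exponential length model", {
  # closed form at alpha = 0.5, median length 1000
  expect_equal(biasFactors(c(500, 1000, 2000), 0.5),
               exp(c(-0.25, -0.5, -1.0)), tolerance = 1e-12)
  # no-bias limit
  expect_identical(biasFactors(c(100, 5000, 123), 0), rep(1, 3))
  # monotone non-increasing in length
  f <- biasFactors(c(500, 2000), 1)
  expect_gt(f[1], f[2])
  lens <- sort(exp(rnorm(50, 7, 1)))
  expect_true(all(diff(biasFactors(lens, 0.7)) <= 0))
  expect_true(all(biasFactors(lens, 0.7) > 0 & biasFactors(lens, 0.7) <= 1))

  expect_error(biasFactors(c(100, -5), 1), "> 0")
  expect_error(biasFactors(c(100, 200), -0.1), "nonnegative")
})

test_that("degradation has exact identity and full-dropout limits", {
  norm <- tiny_norm(seed = 15)
  idp <- degrade(norm, DegradationParams(0, 0, 0, seed = 1))
  expect_identical(degradedMatrix(idp), originalMatrix(idp))
  expect_identical(originalMatrix(idp), exprValues(norm))

  gone <- degrade(norm, DegradationParams(0, 1, 0, seed = 1))
  expect_true(all(degradedMatrix(gone) == 0))
})

test_that("realized dropout rate matches the Bernoulli parameter", {
  # all-positive entries so zeros can only come from the mask
  set.seed(2)
  v <- matrix(runif(500 * 200, 1, 5), nrow = 500)
  rds <- norm_rds(v)
  pair <- degrade(rds, DegradationParams(0, 0.5, 0, seed = 33))
  frac <- mean(degradedMatrix(pair) == 0)
  se <- sqrt(0.25 / (500 * 200))
  expect_lt(abs(frac - 0.5), 4 * se)
  # the returned mask is the realized corruption
  expect_identical(degradedMatrix(pair) == 0, dropoutMask(pair) == 0)
})

test_that("realized noise SD matches sigma where clamping is inactive", {
  set.seed(3)
  v <- matrix(runif(400 * 250, 2, 6), nrow = 400)  # entries >= 2
  rds <- norm_rds(v)
  pair <- degrade(rds, DegradationParams(0, 0, 0.3, seed = 5))
  resid <- degradedMatrix(pair) - originalMatrix(pair)
  expect_lt(abs(sd(resid) - 0.3) / 0.3, 0.02)
  expect_equal(unname(pair@noiseSummary["sd"]), sd(resid), tolerance = 1e-6)
})

test_that("degraded values are clamped at zero and never negative", {
  norm <- tiny_norm(seed = 16)
  pair <- degrade(norm, DegradationParams(0.5, 0.2, 1.5, seed = 9))
  expect_gte(min(degradedMatrix(pair)), 0)
})

test_that("degradation is seeded and requires lengths only when biased", {
  norm <- tiny_norm(seed = 17)
  p <- DegradationParams(0.3, 0.4, 0.1, seed = 77)
  expect_identical(degradedMatrix(degrade(norm, p)),
                   degradedMatrix(degrade(norm, p)))
  p2 <- DegradationParams(0.3, 0.4, 0.1, seed = 78)
  expect_false(identical(degradedMatrix(degrade(norm, p)),
                         degradedMatrix(degrade(norm, p2))))

  nolen <- RepairDataSet(exprValues(norm), scaleTag = "cp10k_log1p")
  expect_error(degrade(nolen, DegradationParams(alpha = 0.5)),
               "gene lengths")
  # but alpha = 0 needs no lengths
  expect_s4_class(degrade(nolen, DegradationParams(0, 0.1, 0.1)),
                  "DegradedPair")
})

test_that("signal retention decreases with gene length under 3' bias", {
  norm <- tiny_norm(nCells = 300, nGenes = 100, seed = 19)
  pair <- degrade(norm, DegradationParams(0.8, 0, 0, seed = 4))
  retention <- rowMeans(degradedMatrix(pair)) /
               pmax(rowMeans(originalMatrix(pair)), 1e-12)
  expect_lt(cor(geneLengths(norm), retention, method = "spearman"), 0)
})

test_that("grid degradation is deterministic and monotone in dropout", {
  norm <- tiny_norm(nCells = 200, nGenes = 60, seed = 23)
  grid <- list(DegradationParams(0, 0.1, 0.05),
               DegradationParams(0, 0.3, 0.05),
               DegradationParams(0, 0.6, 0.05))
  res <- degradeDataset(norm, grid, baseSeed = 11)
  res2 <- degradeDataset(norm, grid, baseSeed = 11)
  expect_identical(lapply(res, degradedMatrix), lapply(res2, degradedMatrix))
  means <- vapply(res, function(p) mean(degradedMatrix(p)), numeric(1))
  expect_true(all(diff(means) <= 0))

  # identity grid entry reproduces the input
  one <- degradeDataset(norm, list(DegradationParams(0, 0, 0)), baseSeed = 1)
  expect_identical(degradedMatrix(one[[1]]), exprValues(norm))

  expect_error(degradeDataset(norm, list()), "nonempty")
})

test_that("degradation parameter bounds are enforced", {
  expect_error(DegradationParams(dropoutRate = 1.2), "\\[0, 1\\]")
  expect_error(DegradationParams(alpha = -1), ">= 0")
  expect_error(DegradationParams(noiseSD = -0.1), ">= 0")
  expect_error(degrade(tiny_truth(), DegradationParams()), "normalizeLog")
})
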