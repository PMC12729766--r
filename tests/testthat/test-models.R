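test_that("tokenizer arithmetic and truncation contracts hold", {
  expect_equal(numTokens(RepairModelConfig(nGenes = 5000)), 100)
  expect_equal(numTokens(RepairModelConfig(nGenes = 7, tokenSize = 3,
                                           embedDim = 8, numHeads = 2)), 3)

  cfg <- RepairModelConfig(nGenes = 7, tokenSize = 3, embedDim = 8,
                           numHeads = 2, numLayers = 1, ffnDim = 16)
  model <- buildRepairModel(cfg)
  out <- repairExpression(model, matrix(rnorm(4 * 7), 4, 7))
  expect_equal(dim(out), c(4, 7))
})

test_that("model building is bitwise reproducible from the seed", {
  cfg <- RepairModelConfig(nGenes = 30, embedDim = 16, numHeads = 4,
                           numLayers = 2, ffnDim = 32, tokenSize = 10,
                           seed = 99)
  expect_identical(buildRepairModel(cfg)@params, buildRepairModel(cfg)@params)
  cfg2 <- RepairModelConfig(nGenes = 30, embedDim = 16, numHeads = 4,
                            numLayers = 2, ffnDim = 32, tokenSize = 10,
                            seed = 100)
  expect_false(identical(buildRepairModel(cfg)@params,
                         buildRepairModel(cfg2)@params))
})

test_that("invalid architecture configurations are rejected", {
  expect_error(RepairModelConfig(nGenes = 10, embedDim = 10, numHeads = 3),
               "multiple of numHeads")
  expect_error(RepairModelConfig(nGenes = 10, dropout = 1), "\\[0, 1\\)")
  expect_error(BaselineConfig("dae", hiddenDims = integer()), "nonempty")
})

test_that("inference is a deterministic per-cell map", {
  cfg <- RepairModelConfig(nGenes = 20, embedDim = 16, numHeads = 2,
                           numLayers = 2, ffnDim = 32, tokenSize = 5,
                           dropout = 0.5, seed = 3)
  model <- buildRepairModel(cfg)
  X <- matrix(rnorm(6 * 20), 6, 20)
  # same input twice: identical output despite nonzero dropout config
  expect_identical(repairExpression(model, X), repairExpression(model, X))
  # permuting cells permutes outputs identically (cells are independent)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(repairExpression(model, X[perm, ]),
               repairExpression(model, X)[perm, ], tolerance = 1e-12)
  # single forward pass: inference equals one call into the network
  direct <- screpair:::.model_forward(model, X)$out
  expect_equal(unname(repairExpression(model, X)), direct)

  expect_error(repairExpression(model, matrix(0, 2, 19)), "mismatch")
})

test_that("the MSE objective matches its closed forms", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(mseLoss(X, X), 0)
  expect_equal(mseLoss(X + 0.3, X), 0.09, tolerance = 1e-12)
  expect_equal(mseLoss(matrix(c(1, 3, 2, 4), 2), matrix(c(1, 0, 0, 4), 2)),
               3.25)
  expect_error(mseLoss(X, matrix(0, 2, 2)), "shape")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- RepairModelConfig(nGenes = 7, embedDim = 8, numHeads = 2,
                           numLayers = 2, ffnDim = 12, dropout = 0,
                           tokenSize = 3, seed = 42)
  sh <- screpair:::.tf_shapes(cfg)
  p <- screpair:::.tf_init(cfg)
  set.seed(1)
  X <- matrix(rnorm(5 * 7), 5, 7)
  Y <- matrix(rnorm(5 * 7), 5, 7)
  fw <- screpair:::.tf_forward(p, X, sh, cache = TRUE)
  g <- screpair:::.tf_backward(p, fw$cache, 2 * (fw$out - Y) / length(Y), sh)
  loss <- function(pp) mean((screpair:::.tf_forward(pp, X, sh)$out - Y)^2)
  eps <- 1e-6
  for (nm in names(p)) {
    n <- length(p[[nm]])
    for (i in unique(round(seq(1, n, length.out = min(4, n))))) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- loss(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- loss(pp)
      fd <- (up - dn) / (2 * eps)
      an <- g[[nm]][i]
      # below ~1e-6 the central difference is dominated by float noise
      # (e.g. key biases, whose gradient is exactly 0 by softmax shift
      # invariance)
      if (abs(fd) < 1e-6 && abs(an) < 1e-6) next
      expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("autoencoder baselines honour their latent contracts", {
  # KL closed forms
  expect_equal(screpair:::.vae_kl(matrix(0, 1, 1), matrix(0, 1, 1)), 0)
  expect_equal(screpair:::.vae_kl(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  # batch mean, sum over dims: two samples, two dims
  mu <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(screpair:::.vae_kl(mu, matrix(0, 2, 2)), 0.5)

  dae <- buildBaseline(BaselineConfig("dae", hiddenDims = c(16L, 8L),
                                      latentDim = 4L, seed = 5), 20)
  vae <- buildBaseline(BaselineConfig("vae", hiddenDims = c(16L),
                                      latentDim = 4L, seed = 5), 20)
  X <- matrix(rnorm(7 * 20), 7, 20)
  for (m in list(dae, vae)) {
    out <- repairExpression(m, X)
    expect_equal(dim(out), dim(X))
    expect_identical(out, repairExpression(m, X))
  }
  out1 <- repairExpression(dae, X[1, , drop = FALSE])
  expect_equal(dim(out1), c(1, 20))
})
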