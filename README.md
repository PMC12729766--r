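# screpair

Repair of degraded RNA-seq expression profiles with a one-step conditional
Transformer, plus the degradation simulator and evaluation framework needed
to train and validate it.

## The problem

RNA in archived samples (FFPE blocks, delayed-processing specimens)
fragments and degrades. Because poly-A-primed library prep needs intact 3′
ends, fragmentation preferentially erases the signal of long transcripts
(3′ bias); low-abundance transcripts drop out entirely; and processing adds
technical noise. The distorted profiles compromise cell-type
identification, differential expression, and biomarker work. True paired
(intact, degraded) measurements of the same specimen are essentially
unobtainable, so repair models are trained on *pseudo-degraded* pairs:
high-quality data corrupted by a parameterised simulator.

`screpair` is aimed at computational biologists who want to (i) simulate
realistic degradation on their own high-quality data, (ii) train a repair
model and baselines on the resulting pairs, and (iii) quantify — with both
technical and biological metrics — how much signal repair restores.

## The model

On the standard preprocessing scale (QC → counts-per-10k → log1p → top
highly variable genes), a clean profile is corrupted as

    X_deg = max(0, M ⊙ X_orig ⊙ m + ε)

where `M_g = exp(−α·L_g/median(L))` is a per-gene 3′-bias attenuation
driven by transcript length `L_g`, `m` is an independent per-entry
Bernoulli(1−p_d) dropout mask, and `ε ~ N(0, σ_n²)` is technical noise.

Repair is one-step conditional denoising: a Transformer encoder `F_θ` over
gene-chunk tokens takes the degraded profile as conditioning input and
directly outputs the repaired profile, trained with

    L = E ‖F_θ(c) − x₀‖²

(no iterative sampling; inference is a single deterministic forward pass).
MLP denoising- and variational-autoencoder baselines share the training
loop. The network stack — multi-head attention, reverse-mode gradients,
Adam, reduce-on-plateau scheduling — is implemented natively in R and
gradient-checked in the test suite.

The scorecard combines technical metrics (MSE, Pearson, PR-AUC and F1 for
the expressed-vs-unexpressed task) with biological ones on a 0–100 scale:
silhouette cell-type separation in PC space, top-k DEG preservation
(Jaccard/F1 of rank-sum DEG sets), Spearman marker-gene recovery, and
their arithmetic mean as the overall biological score — plus paired
t-tests with Cohen's d, an orthogonal RNA–protein (CITE-seq-style)
validation, and a logistic-regression cell-typing check.

## Worked example

```r
library(screpair)

truth <- generateTruth(SyntheticSpec(seed = 1))        # 2000 cells x 500 genes
prep  <- selectHVG(normalizeLog(qcFilter(truth,
           QCThresholds(minGenesPerCell = 5, minCellsPerGene = 3))), 500)
pair  <- degrade(prep, DegradationParams(alpha = 0.5, dropoutRate = 0.3,
                                         noiseSD = 0.2, seed = 2))
split <- splitDataset(ncol(pair), labels = cellTypes(pair), seed = 3)
cfg   <- RepairModelConfig(nGenes = nrow(pair), embedDim = 64, numHeads = 4,
                           numLayers = 2, ffnDim = 256, tokenSize = 25,
                           dropout = 0)
fit   <- trainRepairModel(buildRepairModel(cfg), pair, split,
                          TrainConfig(batchSize = 16, learningRate = 5e-3,
                                      maxEpochs = 30, seed = 4))

test     <- split@testIdx
repaired <- repairExpression(fit$model, t(degradedMatrix(pair))[test, ])
evaluateRepair(repaired, t(originalMatrix(pair))[test, ],
               cellTypes(pair)[test],
               intersect(markerTable(truth)$gene, rownames(pair)))
```

```
MetricsReport
  technical : MSE=1.043  Pearson=0.691  PR-AUC=0.9647  F1=0.8703
  biological: separation=50.421  DEG=40.322  marker=53.824  overall=48.189
```

Reading the report: repair reduced the reconstruction error to less than a
third of the degraded input's (MSE 1.04 vs 3.35 against the original on
the same cells) and raised the flattened Pearson correlation from 0.54 to
0.69; PR-AUC ≈ 0.96 says expressed genes are cleanly separated from
unexpressed ones; and the biological block shows the repaired data
preserving more of the top differential-expression structure (DEG 40.3 vs
35.8 for the degraded data) and marker-gene ranks (53.8 vs 50.4). The same
experiment end-to-end, with artifacts persisted, is
`runPipeline(defaultPipelineConfig(seed = 1))`.

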