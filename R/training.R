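#' Train / validation / test split
#'
#' Deterministically partitions cells into disjoint train, validation and
#' test sets at the given fractions (default 80/10/10). With labels given,
#' the split is stratified: each label contributes to each set at the
#' target fraction to within one cell.
#'
#' @param nCells integer(1), number of cells.
#' @param fractions numeric(3), positive, summing to 1.
#' @param labels optional per-cell labels for stratification.
#' @param seed integer(1).
#' @return A \linkS4class{SplitAssignment}.
#' @examples
#' s <- splitDataset(100, seed = 7)
#' lengths(list(s@trainIdx, s@valIdx, s@testIdx))
#' @export
splitDataset <- function(nCells, fractions = c(0.8, 0.1, 0.1),
                         labels = NULL, seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 positive values summing to 1")
  nCells <- as.integer(nCells)
  strata <- if (is.null(labels)) rep("all", nCells)
            else as.character(labels)
  if (length(strata) != nCells)
    stop("labels must have one entry per cell")
  if (!is.null(labels)) {
    small <- names(which(table(strata) < 3L))
    if (length(small))
      stop("stratum smaller than 3 cells: ", paste(small, collapse = ", "))
  }
  tr <- va <- te <- integer()
  .with_seed(seed, {
    for (s in sort(unique(strata))) {
      idx <- sample(which(strata == s))
      ns <- length(idx)
      n_val <- round(fractions[2L] * ns)
      n_test <- round(fractions[3L] * ns)
      n_train <- ns - n_val - n_test
      tr <- c(tr, idx[seq_len(n_train)])
      va <- c(va, idx[n_train + seq_len(n_val)])
      te <- c(te, idx[n_train + n_val + seq_len(n_test)])
    }
  })
  new("SplitAssignment", trainIdx = sort(tr), valIdx = sort(va),
      testIdx = sort(te), fractions = as.numeric(fractions),
      stratified = !is.null(labels), seed = as.integer(seed))
}

# reduce-on-plateau state machine: halve lr after `patience` epochs without
# a relative validation improvement beyond relTol
.plateau_new <- function(lr0, patience, factor, relTol) {
  list(lr = lr0, best = Inf, wait = 0L, patience = patience,
       factor = factor, relTol = relTol)
}

.plateau_update <- function(st, v) {
  if (v < st$best * (1 - st$relTol)) {
    st$best <- v
    st$wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    if (st$wait >= st$patience) {
      st$lr <- st$lr * st$factor
      st$wait <- 0L
    }
  }
  st
}

#' Replay the reduce-on-plateau schedule over a validation-loss trace
#'
#' Pure function over a sequence of validation losses: returns, for each
#' epoch, the learning rate in effect while training that epoch and the
#' rate after the scheduler saw that epoch's validation loss. Improvement
#' means a relative decrease beyond \code{relTol} over the best loss seen;
#' after \code{patience} consecutive non-improving epochs the rate is
#' multiplied by \code{factor} and the counter resets.
#'
#' @param valLosses numeric vector of per-epoch validation losses.
#' @param lr0 initial learning rate.
#' @param patience,factor,relTol schedule parameters (defaults 10, 0.5,
#'   1e-4).
#' @return data.frame with columns \code{epoch}, \code{lr_used},
#'   \code{lr_after}.
#' @examples
#' replayPlateauSchedule(rep(1, 12), lr0 = 2e-4)
#' @export
replayPlateauSchedule <- function(valLosses, lr0, patience = 10L,
                                  factor = 0.5, relTol = 1e-4) {
  st <- .plateau_new(lr0, patience, factor, relTol)
  out <- data.frame(epoch = seq_along(valLosses), lr_used = NA_real_,
                    lr_after = NA_real_)
  for (e in seq_along(valLosses)) {
    out$lr_used[e] <- st$lr
    st <- .plateau_update(st, valLosses[e])
    out$lr_after[e] <- st$lr
  }
  out
}

.batch_loss_grad <- function(model, Xb, Yb, sample_latent) {
  fw <- .model_forward(model, Xb, dropout = TRUE, cache = TRUE,
                       sample_latent = sample_latent)
  loss <- mean((fw$out - Yb)^2)
  if (model@kind == "vae")
    loss <- loss + model@config@klWeight * .vae_kl(fw$mu, fw$logvar)
  dOut <- 2 * (fw$out - Yb) / length(Yb)
  list(loss = loss, grads = .model_backward(model, fw$cache, dOut))
}

.eval_loss <- function(model, X, Y) {
  fw <- .model_forward(model, X)
  loss <- mean((fw$out - Y)^2)
  if (model@kind == "vae")
    loss <- loss + model@config@klWeight * .vae_kl(fw$mu, fw$logvar)
  loss
}

#' Train a repair model on an aligned degraded/original pair
#'
#' Minimises the mean squared error between the model's output on degraded
#' profiles and the matching original profiles over the training cells,
#' with Adam, per-epoch validation on the validation cells only, a
#' reduce-on-plateau learning-rate schedule, early stopping, and
#' best-validation checkpointing. Test cells are never touched: the indices
#' that entered gradient steps and scheduler decisions are recorded in the
#' returned history for audit.
#'
#' Given a fixed seed and single-threaded BLAS the entire run, including
#' the returned history, is bitwise reproducible.
#'
#' @param model an untrained (or warm) \linkS4class{RepairModel}.
#' @param pair a \linkS4class{DegradedPair}.
#' @param split a \linkS4class{SplitAssignment} over the pair's cells.
#' @param cfg a \linkS4class{TrainConfig}.
#' @return list with elements \code{model} (the trained
#'   \linkS4class{RepairModel}, parameters from the best-validation epoch,
#'   eval mode) and \code{history} (a \linkS4class{TrainHistory}).
#' @export
trainRepairModel <- function(model, pair, split, cfg = TrainConfig()) {
  stopifnot(is(model, "RepairModel"), is(pair, "DegradedPair"),
            is(split, "SplitAssignment"), is(cfg, "TrainConfig"))
  validObject(cfg)
  nc <- ncol(pair)
  all_idx <- c(split@trainIdx, split@valIdx, split@testIdx)
  if (length(all_idx) && max(all_idx) > nc)
    stop("split indices exceed the number of cells in the pair")
  if (length(split@trainIdx) == 0L) stop("empty training split")
  Xall <- t(degradedMatrix(pair))
  Yall <- t(originalMatrix(pair))
  Xtr <- Xall[split@trainIdx, , drop = FALSE]
  Ytr <- Yall[split@trainIdx, , drop = FALSE]
  Xva <- Xall[split@valIdx, , drop = FALSE]
  Yva <- Yall[split@valIdx, , drop = FALSE]
  sample_latent <- model@kind == "vae"
  noise_aug <- model@kind == "transformer" && model@config@noiseAugment
  st <- .plateau_new(cfg@learningRate, cfg@plateauPatience,
                     cfg@plateauFactor, cfg@plateauRelTol)
  adam <- .adam_init(model@params)
  use_ema <- cfg@emaDecay > 0
  ema <- if (use_ema) model@params else NULL
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best_val <- Inf
  best_params <- model@params
  best_epoch <- 0L
  es_wait <- 0L
  ntr <- nrow(Xtr)
  .with_seed(cfg@seed, {
    for (epoch in seq_len(cfg@maxEpochs)) {
      ord <- sample.int(ntr)
      tot_loss <- 0
      for (start in seq(1L, ntr, by = cfg@batchSize)) {
        bi <- ord[start:min(start + cfg@batchSize - 1L, ntr)]
        Xb <- Xtr[bi, , drop = FALSE]
        if (noise_aug)
          Xb <- Xb + matrix(
            stats::rnorm(length(Xb), 0, model@config@noiseAugmentSD),
            nrow(Xb), ncol(Xb))
        bl <- .batch_loss_grad(model, Xb, Ytr[bi, , drop = FALSE],
                               sample_latent)
        if (!is.finite(bl$loss))
          stop(sprintf("non-finite training loss at epoch %d; reduce the learning rate", epoch))
        up <- .adam_step(model@params, bl$grads, adam, st$lr)
        model@params <- up$params
        adam <- up$state
        if (use_ema) {
          d <- cfg@emaDecay
          for (nm in names(ema))
            ema[[nm]] <- d * ema[[nm]] + (1 - d) * model@params[[nm]]
        }
        tot_loss <- tot_loss + bl$loss * length(bi)
      }
      train_loss <- tot_loss / ntr
      # validation (and checkpointing) use the averaged weights when EMA
      # is enabled: those are the weights inference will run with
      eval_model <- model
      if (use_ema) eval_model@params <- ema
      val_loss <- if (nrow(Xva)) .eval_loss(eval_model, Xva, Yva)
                  else train_loss
      if (!is.finite(val_loss))
        stop(sprintf("non-finite validation loss at epoch %d", epoch))
      hist[nrow(hist) + 1L, ] <- list(epoch, train_loss, val_loss, st$lr)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- if (use_ema) ema else model@params
        best_epoch <- epoch
      }
      if (val_loss < st$best * (1 - cfg@plateauRelTol)) es_wait <- 0L
      else es_wait <- es_wait + 1L
      st <- .plateau_update(st, val_loss)
      if (es_wait >= cfg@earlyStopPatience) break
    }
  })
  model@params <- best_params
  model@mode <- "eval"
  history <- new("TrainHistory", history = hist,
                 bestEpoch = best_epoch,
                 usedIdx = list(gradient = sort(unique(split@trainIdx)),
                                scheduler = sort(unique(split@valIdx))))
  list(model = model, history = history)
}

#' Run a grid of model configurations
#'
#' Trains and evaluates each configuration on the same degraded/original
#' pair, split and training configuration, and reports held-out test MSE
#' and Pearson correlation per configuration. A failing run is recorded as
#' a failed row; the runner continues.
#'
#' @param pair a \linkS4class{DegradedPair}.
#' @param split a \linkS4class{SplitAssignment}.
#' @param trainCfg a \linkS4class{TrainConfig} shared by all runs.
#' @param configs nonempty list of \linkS4class{RepairModelConfig} or
#'   \linkS4class{BaselineConfig} objects.
#' @return data.frame with one row per configuration: kind, architecture
#'   fields, \code{test_mse}, \code{test_pearson}, \code{status}.
#' @export
gridRunner <- function(pair, split, trainCfg, configs) {
  if (!is.list(configs) || length(configs) == 0L)
    stop("configs must be a nonempty list")
  Xte <- t(degradedMatrix(pair))[split@testIdx, , drop = FALSE]
  Yte <- t(originalMatrix(pair))[split@testIdx, , drop = FALSE]
  rows <- lapply(configs, function(cf) {
    desc <- if (is(cf, "RepairModelConfig"))
      data.frame(kind = "transformer", embedDim = cf@embedDim,
                 numLayers = cf@numLayers, numHeads = cf@numHeads,
                 tokenSize = cf@tokenSize)
    else
      data.frame(kind = cf@kind, embedDim = cf@latentDim,
                 numLayers = length(cf@hiddenDims), numHeads = NA_integer_,
                 tokenSize = NA_integer_)
    res <- tryCatch({
      model <- if (is(cf, "RepairModelConfig")) buildRepairModel(cf)
               else buildBaseline(cf, ncol(Xte))
      fit <- trainRepairModel(model, pair, split, trainCfg)
      rep <- repairExpression(fit$model, Xte)
      data.frame(test_mse = mseLoss(rep, Yte),
                 test_pearson = stats::cor(as.vector(rep), as.vector(Yte)),
                 status = "ok")
    }, error = function(e)
      data.frame(test_mse = NA_real_, test_pearson = NA_real_,
                 status = paste("failed:", conditionMessage(e))))
    cbind(desc, res)
  })
  do.call(rbind, rows)
}
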