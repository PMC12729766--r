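#' Build the one-step Transformer repair model
#'
#' Constructs the conditional repair network F: a gene-chunk tokenizer
#' (consecutive chunks of \code{tokenSize} genes, the last chunk
#' zero-padded), a shared linear embedding of each chunk into
#' \code{embedDim} dimensions plus learned positional embeddings, a stack
#' of pre-norm Transformer encoder blocks (multi-head self-attention over
#' the chunk sequence followed by a ReLU feed-forward network, both with
#' residual connections), a final layer norm, and a linear projection back
#' to per-chunk gene values which are concatenated and truncated to
#' \code{nGenes}. Parameter initialisation is seeded and bit-reproducible.
#'
#' Inference is a single forward pass conditioned only on the degraded
#' profile: no iterative sampling and no random inputs.
#'
#' @param config a \linkS4class{RepairModelConfig}.
#' @return An untrained \linkS4class{RepairModel} in \code{"eval"} mode.
#' @seealso [repairExpression()], [trainRepairModel()], [numTokens()]
#' @export
buildRepairModel <- function(config) {
  validObject(config)
  new("RepairModel", kind = "transformer", config = config,
      nGenes = config@nGenes, params = .tf_init(config), mode = "eval")
}

#' Number of tokens the chunk tokenizer produces
#'
#' @param config a \linkS4class{RepairModelConfig}.
#' @return integer(1): \code{ceiling(nGenes / tokenSize)}.
#' @export
numTokens <- function(config) .tf_shapes(config)$Tn

#' Build an autoencoder baseline
#'
#' Constructs the MLP denoising autoencoder (\code{kind = "dae"}: encoder
#' to a latent bottleneck and mirrored decoder, trained with the same MSE
#' objective as the Transformer) or the variational autoencoder
#' (\code{kind = "vae"}: mean / log-variance latent heads, a
#' reparameterised latent draw during training and the mean latent at
#' inference, trained with MSE plus a KL term of weight
#' \code{config@klWeight}). Both consume the degraded profile and regress
#' the original.
#'
#' @param config a \linkS4class{BaselineConfig}.
#' @param nGenes integer(1), input/output dimensionality.
#' @return An untrained \linkS4class{RepairModel} in \code{"eval"} mode.
#' @export
buildBaseline <- function(config, nGenes) {
  validObject(config)
  nGenes <- as.integer(nGenes)
  params <- if (config@kind == "dae") .dae_init(config, nGenes)
            else .vae_init(config, nGenes)
  new("RepairModel", kind = config@kind, config = config, nGenes = nGenes,
      params = params, mode = "eval")
}

#' Mode of a repair model
#' @param x a \linkS4class{RepairModel}.
#' @return \code{"train"} or \code{"eval"}.
#' @export
modelMode <- function(x) x@mode

#' Mean squared error loss
#'
#' The training objective: the mean over all entries of the squared
#' difference between the model output and the original profile.
#'
#' @param prediction,original numeric matrices of identical shape.
#' @return nonnegative numeric(1).
#' @examples
#' mseLoss(matrix(c(1, 3, 2, 4), 2), matrix(c(1, 0, 0, 4), 2))  # 3.25
#' @export
mseLoss <- function(prediction, original) {
  if (!identical(dim(prediction), dim(original)))
    stop("shape mismatch between prediction and original")
  mean((prediction - original)^2)
}

#' Repair degraded expression profiles
#'
#' Applies the trained one-step repair map to degraded profiles. Inference
#' is always deterministic: dropout is disabled and the VAE uses its mean
#' latent. Cells are processed independently (the output for a cell depends
#' only on that cell's profile), in batches to bound memory.
#'
#' @param model a \linkS4class{RepairModel}.
#' @param x degraded input: a cells x genes numeric matrix, a
#'   \linkS4class{DegradedPair} (its \code{degraded} assay is used), or any
#'   SummarizedExperiment (first assay, genes x cells).
#' @return For matrix input, a cells x genes matrix of the same shape; for
#'   container input, a genes x cells matrix aligned with the container.
#' @export
setMethod("repairExpression", signature(model = "RepairModel", x = "matrix"),
  function(model, x) {
    if (ncol(x) != model@nGenes)
      stop(sprintf("gene-count mismatch: model expects %d genes, input has %d",
                   model@nGenes, ncol(x)))
    out <- matrix(0, nrow(x), ncol(x))
    batch <- 256L
    for (start in seq(1L, nrow(x), by = batch)) {
      idx <- start:min(start + batch - 1L, nrow(x))
      out[idx, ] <- .model_forward(model, x[idx, , drop = FALSE])$out
    }
    dimnames(out) <- dimnames(x)
    out
  })

#' @rdname repairExpression
#' @export
setMethod("repairExpression",
  signature(model = "RepairModel", x = "SummarizedExperiment"),
  function(model, x) {
    v <- if (is(x, "DegradedPair")) degradedMatrix(x)
         else SummarizedExperiment::assay(x, 1L)
    t(repairExpression(model, t(as.matrix(v))))
  })
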