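#' Length-dependent 3'-bias factors
#'
#' Computes the multiplicative signal-retention factor per gene under
#' fragmentation-driven 3' bias: \code{exp(-alpha * L / median(L))}.
#' Longer transcripts lose disproportionately more signal (exponential
#' fragment survival), the factor is bounded in (0, 1], non-increasing in
#' length for fixed \code{alpha > 0}, and exactly 1 for every gene when
#' \code{alpha = 0}. The median normalisation makes the parameterisation
#' independent of the length unit.
#'
#' @param geneLengths positive numeric vector of transcript lengths.
#' @param alpha nonnegative numeric(1), bias intensity.
#' @return Numeric vector of factors in (0, 1], aligned to
#'   \code{geneLengths}.
#' @examples
#' biasFactors(c(500, 1000, 2000), alpha = 0.5)
#' @export
biasFactors <- function(geneLengths, alpha) {
  if (length(geneLengths) == 0L || anyNA(geneLengths) ||
      any(geneLengths <= 0))
    stop("geneLengths must be all > 0")
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("alpha must be a nonnegative scalar")
  exp(-alpha * geneLengths / stats::median(geneLengths))
}

.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1e6) * 1009 + 7919 * k) %% .Machine$integer.max
}

#' Pseudo-degradation of a log-normalised expression profile
#'
#' Applies the three-component degradation model to a clean profile X:
#' a per-gene multiplicative 3'-bias factor M computed from transcript
#' length and intensity alpha (identical for every cell), an independent
#' per-entry Bernoulli(1 - dropoutRate) dropout mask, and additive Gaussian
#' noise of SD \code{noiseSD}, followed by clamping at zero:
#' \deqn{X_{deg} = \max(0, M \odot X \odot m + \epsilon)}
#' The clamp preserves nonnegativity of the log-normalised scale and is a
#' no-op when \code{noiseSD = 0}. The realised mask, bias factors and a
#' noise summary are returned for audit, and the whole draw is reproducible
#' given \code{params@seed} (mask and noise use independent derived
#' substreams).
#'
#' @param x a \linkS4class{RepairDataSet} on the \code{"cp10k_log1p"} scale;
#'   gene lengths are required when \code{alpha > 0}.
#' @param params a \linkS4class{DegradationParams}.
#' @return A \linkS4class{DegradedPair}.
#' @export
setMethod("degrade", signature(x = "RepairDataSet",
                               params = "DegradationParams"),
  function(x, params) {
    validObject(params)
    if (!identical(scaleTag(x), "cp10k_log1p"))
      stop("degrade expects log-normalised data: run normalizeLog first")
    lens <- geneLengths(x)
    if (params@alpha > 0 && is.null(lens))
      stop("gene lengths are required when alpha > 0")
    v <- exprValues(x)
    G <- nrow(v); C <- ncol(v)
    bias <- if (params@alpha > 0) biasFactors(lens, params@alpha)
            else rep(1, G)
    mask <- .with_seed(.derive_seed(params@seed, 1L), {
      if (params@dropoutRate > 0)
        matrix(stats::rbinom(G * C, 1L, 1 - params@dropoutRate), G, C)
      else
        matrix(1L, G, C)
    })
    deg <- bias * v * mask
    if (params@noiseSD > 0) {
      eps <- .with_seed(.derive_seed(params@seed, 2L),
                        matrix(stats::rnorm(G * C, 0, params@noiseSD), G, C))
      noise_summary <- c(mean = mean(eps), sd = stats::sd(eps))
      deg <- pmax(deg + eps, 0)
    } else {
      noise_summary <- c(mean = 0, sd = 0)
    }
    dimnames(deg) <- dimnames(v)
    dimnames(mask) <- dimnames(v)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(original = v, degraded = deg, dropoutMask = mask),
      rowData = SummarizedExperiment::rowData(x),
      colData = SummarizedExperiment::colData(x))
    metadata(sce) <- metadata(x)
    new("DegradedPair", sce, params = params, biasFactors = bias,
        noiseSummary = noise_summary)
  })

#' Degrade a dataset under a grid of parameter settings
#'
#' Maps [degrade()] over a list of \linkS4class{DegradationParams},
#' replacing each item's seed with a value derived from \code{baseSeed} and
#' the item's position so the whole grid is reproducible from one integer.
#'
#' @param x a \linkS4class{RepairDataSet} on the \code{"cp10k_log1p"} scale.
#' @param paramGrid nonempty list of \linkS4class{DegradationParams}.
#' @param baseSeed integer(1); per-item seed is \code{baseSeed + index}.
#'   Use \code{NULL} to keep each item's own seed.
#' @return List of \linkS4class{DegradedPair}, one per grid entry.
#' @export
degradeDataset <- function(x, paramGrid, baseSeed = 1L) {
  if (!is.list(paramGrid) || length(paramGrid) == 0L)
    stop("paramGrid must be a nonempty list of DegradationParams")
  lapply(seq_along(paramGrid), function(i) {
    p <- paramGrid[[i]]
    if (!is(p, "DegradationParams"))
      stop("paramGrid entries must be DegradationParams")
    if (!is.null(baseSeed))
      p@seed <- as.integer(baseSeed + i)
    degrade(x, p)
  })
}
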