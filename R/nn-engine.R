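# Native neural-network engine: dense layers, layer normalisation,
# multi-head self-attention over gene-chunk tokens, manual reverse-mode
# gradients, and the Adam optimiser. Everything runs on BLAS matrix ops
# with cells as rows (samples x features).
#
# Shape conventions: B cells per batch, G genes, s genes per token,
# Tn = ceiling(G/s) tokens, N = B*Tn token rows, D model dim, H heads,
# d = D/H per-head dim, Fd feed-forward width, L layers.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# broadcast a length-ncol vector across rows
.coladd <- function(X, v) X + rep(v, each = nrow(X))
.colmul <- function(X, v) X * rep(v, each = nrow(X))

.softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

.drop_mask <- function(n, m, p) {
  (matrix(stats::runif(n * m), n, m) >= p) / (1 - p)
}

# --- layer norm over the feature (column) dimension, per row ---------------

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = .coladd(.colmul(xhat, g), b), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxh <- .colmul(dout, g)
  dx <- cache$inv *
    (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dg, db = db)
}

# --- gene-chunk tokenisation ----------------------------------------------

.tf_shapes <- function(config) {
  G <- config@nGenes
  s <- config@tokenSize
  list(G = G, s = s, Tn = as.integer(ceiling(G / s)),
       D = config@embedDim, H = config@numHeads,
       d = config@embedDim %/% config@numHeads,
       Fd = config@ffnDim, L = config@numLayers, p = config@dropout,
       residual = isTRUE(config@predictResidual))
}

# B x G  ->  (B*Tn) x s, row (b-1)*Tn + t holds token t of cell b
.tokenize <- function(X, sh) {
  B <- nrow(X)
  pad <- sh$Tn * sh$s - sh$G
  if (pad > 0) X <- cbind(X, matrix(0, B, pad))
  t(matrix(t(X), nrow = sh$s))
}

# (B*Tn) x s  ->  B x G (padding truncated)
.untokenize <- function(Y, sh, B) {
  Xp <- t(matrix(t(Y), nrow = sh$s * sh$Tn))
  Xp[, seq_len(sh$G), drop = FALSE]
}

# --- transformer parameters ------------------------------------------------

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.tf_init <- function(config) {
  sh <- .tf_shapes(config)
  .with_seed(config@seed, {
    We <- .glorot(sh$s, sh$D)
    if (sh$D >= sh$s)
      # value-preserving init: the first tokenSize embedding dimensions
      # carry the raw chunk values, so per-gene maps are expressible
      # without first learning an unmixing
      We[, seq_len(sh$s)] <- diag(sh$s)
    p <- list(We = We, be = numeric(sh$D),
              pos = matrix(stats::rnorm(sh$Tn * sh$D, 0, 0.02), sh$Tn, sh$D))
    for (l in seq_len(sh$L)) {
      pre <- sprintf("l%d_", l)
      p[[paste0(pre, "ln1_g")]] <- rep(1, sh$D)
      p[[paste0(pre, "ln1_b")]] <- numeric(sh$D)
      p[[paste0(pre, "Wq")]] <- .glorot(sh$D, sh$D)
      p[[paste0(pre, "bq")]] <- numeric(sh$D)
      p[[paste0(pre, "Wk")]] <- .glorot(sh$D, sh$D)
      p[[paste0(pre, "bk")]] <- numeric(sh$D)
      p[[paste0(pre, "Wv")]] <- .glorot(sh$D, sh$D)
      p[[paste0(pre, "bv")]] <- numeric(sh$D)
      p[[paste0(pre, "Wo")]] <- .glorot(sh$D, sh$D)
      p[[paste0(pre, "bo")]] <- numeric(sh$D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, sh$D)
      p[[paste0(pre, "ln2_b")]] <- numeric(sh$D)
      p[[paste0(pre, "W1")]] <- .glorot(sh$D, sh$Fd)
      p[[paste0(pre, "b1")]] <- numeric(sh$Fd)
      p[[paste0(pre, "W2")]] <- .glorot(sh$Fd, sh$D)
      p[[paste0(pre, "b2")]] <- numeric(sh$D)
    }
    p$lnf_g <- rep(1, sh$D)
    p$lnf_b <- numeric(sh$D)
    if (sh$residual) {
      # gated denoising decode: per gene a correction value and a sigmoid
      # gate, applied on top of a learned per-gene diagonal skip
      p$Wout <- .glorot(sh$D, 2L * sh$s)
      p$bout <- numeric(2L * sh$s)
      p$wskip <- rep(1, sh$G)
      # highway-style input term of the gate logit: a strongly negative
      # slope initialises the gate half-open at zero signal and closed
      # where the observed signal is strong, so corrections start out
      # confined to candidate dropout entries
      p$ugate <- rep(-5, sh$G)
      # per-gene readout of the pooled cell state: lets each gene's
      # correction respond to the cell's global context (e.g. its type)
      # without routing through the chunk-shared decoder
      p$Egene <- matrix(0, sh$D, sh$G)
    } else {
      p$Wout <- .glorot(sh$D, sh$s)
      p$bout <- numeric(sh$s)
    }
    p
  })
}

# --- transformer forward ---------------------------------------------------

.tf_forward <- function(p, X, sh, dropout = FALSE, cache = FALSE) {
  B <- nrow(X)
  Z <- .tokenize(X, sh)
  N <- nrow(Z)
  drop_on <- dropout && sh$p > 0
  E <- .coladd(Z %*% p$We, p$be)
  posrep <- rep(seq_len(sh$Tn), B)
  Xc <- E + p$pos[posrep, , drop = FALSE]
  layers <- if (cache) vector("list", sh$L) else NULL
  scale <- 1 / sqrt(sh$d)
  for (l in seq_len(sh$L)) {
    pre <- sprintf("l%d_", l)
    ln1 <- .ln_fwd(Xc, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    A <- ln1$out
    Q <- .coladd(A %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- .coladd(A %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- .coladd(A %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    Ctx <- matrix(0, N, sh$D)
    Plist <- if (cache) vector("list", B) else NULL
    for (b in seq_len(B)) {
      r <- ((b - 1L) * sh$Tn + 1L):(b * sh$Tn)
      Pb <- if (cache) vector("list", sh$H) else NULL
      for (h in seq_len(sh$H)) {
        cc <- ((h - 1L) * sh$d + 1L):(h * sh$d)
        S <- tcrossprod(Q[r, cc, drop = FALSE], K[r, cc, drop = FALSE]) * scale
        P <- .softmax_rows(S)
        Ctx[r, cc] <- P %*% V[r, cc, drop = FALSE]
        if (cache) Pb[[h]] <- P
      }
      if (cache) Plist[[b]] <- Pb
    }
    O <- .coladd(Ctx %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    dm1 <- dm2 <- dm3 <- NULL
    if (drop_on) { dm1 <- .drop_mask(N, sh$D, sh$p); O <- O * dm1 }
    X1 <- Xc + O
    ln2 <- .ln_fwd(X1, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    Fin <- ln2$out
    H1r <- pmax(.coladd(Fin %*% p[[paste0(pre, "W1")]],
                        p[[paste0(pre, "b1")]]), 0)
    H1d <- H1r
    if (drop_on) { dm2 <- .drop_mask(N, sh$Fd, sh$p); H1d <- H1r * dm2 }
    Fo <- .coladd(H1d %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    if (drop_on) { dm3 <- .drop_mask(N, sh$D, sh$p); Fo <- Fo * dm3 }
    Xnew <- X1 + Fo
    if (cache)
      layers[[l]] <- list(Xin = Xc, ln1 = ln1, A = A, Q = Q, K = K, V = V,
                          Plist = Plist, Ctx = Ctx, dm1 = dm1, X1 = X1,
                          ln2 = ln2, Fin = Fin, H1r = H1r, dm2 = dm2,
                          H1d = H1d, dm3 = dm3)
    Xc <- Xnew
  }
  lnf <- .ln_fwd(Xc, p$lnf_g, p$lnf_b)
  Y <- .coladd(lnf$out %*% p$Wout, p$bout)
  if (sh$residual) {
    # denoising parameterisation: output = wskip (.) input + gate (.)
    # correction, so the encoder predicts where and how to correct the
    # conditioning profile rather than re-synthesising all of it; the
    # correction combines the chunk decode with a per-gene readout of the
    # token-pooled cell state
    Zpool <- rowsum(lnf$out, rep(seq_len(B), each = sh$Tn),
                    reorder = FALSE) / sh$Tn
    rownames(Zpool) <- NULL
    corr <- .untokenize(Y[, seq_len(sh$s), drop = FALSE], sh, B) +
      Zpool %*% p$Egene
    glogit <- .untokenize(Y[, sh$s + seq_len(sh$s), drop = FALSE], sh, B) +
      .colmul(X, p$ugate)
    gate <- 1 / (1 + exp(-glogit))
    out <- .colmul(X, p$wskip) + gate * corr
  } else {
    corr <- gate <- Zpool <- NULL
    out <- .untokenize(Y, sh, B)
  }
  list(out = out,
       cache = if (cache) list(B = B, N = N, Z = Z, posrep = posrep,
                               layers = layers, lnf = lnf, U = lnf$out,
                               X0 = if (sh$residual) X else NULL,
                               corr = corr, gate = gate, Zpool = Zpool)
               else NULL)
}

# --- transformer backward --------------------------------------------------

.tf_backward <- function(p, cache, dOut, sh) {
  B <- cache$B
  g <- list()
  # the tokenizing reshape sends padding slots a zero gradient
  if (sh$residual) {
    g$wskip <- colSums(dOut * cache$X0)
    dCorr <- dOut * cache$gate
    dGateLogit <- dOut * cache$corr * cache$gate * (1 - cache$gate)
    g$ugate <- colSums(dGateLogit * cache$X0)
    g$Egene <- crossprod(cache$Zpool, dCorr)
    dZpool <- tcrossprod(dCorr, p$Egene)
    dY <- cbind(.tokenize(dCorr, sh), .tokenize(dGateLogit, sh))
  } else {
    dZpool <- NULL
    dY <- .tokenize(dOut, sh)
  }
  g$bout <- colSums(dY)
  g$Wout <- crossprod(cache$U, dY)
  dU <- tcrossprod(dY, p$Wout)
  if (!is.null(dZpool))
    dU <- dU + dZpool[rep(seq_len(B), each = sh$Tn), , drop = FALSE] / sh$Tn
  lb <- .ln_bwd(dU, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dXc <- lb$dx
  scale <- 1 / sqrt(sh$d)
  for (l in rev(seq_len(sh$L))) {
    pre <- sprintf("l%d_", l)
    cl <- cache$layers[[l]]
    dXnew <- dXc
    dFo <- dXnew
    if (!is.null(cl$dm3)) dFo <- dFo * cl$dm3
    g[[paste0(pre, "W2")]] <- crossprod(cl$H1d, dFo)
    g[[paste0(pre, "b2")]] <- colSums(dFo)
    dH1d <- tcrossprod(dFo, p[[paste0(pre, "W2")]])
    dH1r <- if (!is.null(cl$dm2)) dH1d * cl$dm2 else dH1d
    dH1 <- dH1r * (cl$H1r > 0)
    g[[paste0(pre, "W1")]] <- crossprod(cl$Fin, dH1)
    g[[paste0(pre, "b1")]] <- colSums(dH1)
    dFin <- tcrossprod(dH1, p[[paste0(pre, "W1")]])
    lb2 <- .ln_bwd(dFin, cl$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX1 <- dXnew + lb2$dx
    dO <- dX1
    if (!is.null(cl$dm1)) dO <- dO * cl$dm1
    g[[paste0(pre, "Wo")]] <- crossprod(cl$Ctx, dO)
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dCtx <- tcrossprod(dO, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, cache$N, sh$D)
    dK <- matrix(0, cache$N, sh$D)
    dV <- matrix(0, cache$N, sh$D)
    for (b in seq_len(B)) {
      r <- ((b - 1L) * sh$Tn + 1L):(b * sh$Tn)
      for (h in seq_len(sh$H)) {
        cc <- ((h - 1L) * sh$d + 1L):(h * sh$d)
        P <- cl$Plist[[b]][[h]]
        dCtx_b <- dCtx[r, cc, drop = FALSE]
        Vb <- cl$V[r, cc, drop = FALSE]
        dP <- tcrossprod(dCtx_b, Vb)
        dV[r, cc] <- crossprod(P, dCtx_b)
        dS <- P * (dP - rowSums(dP * P)) * scale
        dQ[r, cc] <- dS %*% cl$K[r, cc, drop = FALSE]
        dK[r, cc] <- crossprod(dS, cl$Q[r, cc, drop = FALSE])
      }
    }
    A <- cl$A
    g[[paste0(pre, "Wq")]] <- crossprod(A, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(A, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(A, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dA <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
          tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
          tcrossprod(dV, p[[paste0(pre, "Wv")]])
    lb1 <- .ln_bwd(dA, cl$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dXc <- dX1 + lb1$dx
  }
  g$pos <- rowsum(dXc, cache$posrep)
  dimnames(g$pos) <- NULL
  g$We <- crossprod(cache$Z, dXc)
  g$be <- colSums(dXc)
  g[names(p)]
}

# --- MLP autoencoder (DAE) -------------------------------------------------

.dae_dims <- function(config, nGenes) {
  c(nGenes, config@hiddenDims, config@latentDim,
    rev(config@hiddenDims), nGenes)
}

.dae_init <- function(config, nGenes) {
  dims <- .dae_dims(config, nGenes)
  .with_seed(config@seed, {
    p <- list()
    for (i in seq_len(length(dims) - 1L)) {
      p[[sprintf("W%d", i)]] <- .glorot(dims[i], dims[i + 1L])
      p[[sprintf("b%d", i)]] <- numeric(dims[i + 1L])
    }
    p
  })
}

.dae_forward <- function(p, X, pdrop, dropout = FALSE, cache = FALSE) {
  nlay <- length(p) / 2L
  acts <- vector("list", nlay + 1L)
  masks <- vector("list", nlay)
  acts[[1L]] <- X
  H <- X
  drop_on <- dropout && pdrop > 0
  for (i in seq_len(nlay)) {
    H <- .coladd(H %*% p[[sprintf("W%d", i)]], p[[sprintf("b%d", i)]])
    if (i < nlay) {
      H <- pmax(H, 0)
      if (drop_on) {
        masks[[i]] <- .drop_mask(nrow(H), ncol(H), pdrop)
        H <- H * masks[[i]]
      }
    }
    acts[[i + 1L]] <- H
  }
  list(out = H, cache = if (cache) list(acts = acts, masks = masks) else NULL)
}

.dae_backward <- function(p, cache, dOut, pdrop) {
  nlay <- length(p) / 2L
  g <- list()
  dH <- dOut
  for (i in rev(seq_len(nlay))) {
    g[[sprintf("W%d", i)]] <- crossprod(cache$acts[[i]], dH)
    g[[sprintf("b%d", i)]] <- colSums(dH)
    if (i > 1L) {
      dH <- tcrossprod(dH, p[[sprintf("W%d", i)]])
      if (!is.null(cache$masks[[i - 1L]])) dH <- dH * cache$masks[[i - 1L]]
      dH <- dH * (cache$acts[[i]] > 0)
    }
  }
  g[names(p)]
}

# --- variational autoencoder ----------------------------------------------

.vae_init <- function(config, nGenes) {
  hd <- config@hiddenDims
  lat <- config@latentDim
  .with_seed(config@seed, {
    p <- list()
    dims <- c(nGenes, hd)
    for (i in seq_len(length(dims) - 1L)) {
      p[[sprintf("eW%d", i)]] <- .glorot(dims[i], dims[i + 1L])
      p[[sprintf("eb%d", i)]] <- numeric(dims[i + 1L])
    }
    hl <- dims[length(dims)]
    p$Wmu <- .glorot(hl, lat); p$bmu <- numeric(lat)
    p$Wlv <- .glorot(hl, lat); p$blv <- numeric(lat)
    ddims <- c(lat, rev(hd), nGenes)
    for (i in seq_len(length(ddims) - 1L)) {
      p[[sprintf("dW%d", i)]] <- .glorot(ddims[i], ddims[i + 1L])
      p[[sprintf("db%d", i)]] <- numeric(ddims[i + 1L])
    }
    p
  })
}

# KL(q || N(0, I)) for a diagonal Gaussian posterior, summed over latent
# dims, per sample: 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)
.vae_kl <- function(mu, logvar) {
  0.5 * sum(mu^2 + exp(logvar) - 1 - logvar) / nrow(mu)
}

.vae_forward <- function(p, X, config, dropout = FALSE, cache = FALSE,
                         sample_latent = FALSE) {
  ne <- length(config@hiddenDims)
  eacts <- vector("list", ne + 1L)
  eacts[[1L]] <- X
  H <- X
  for (i in seq_len(ne)) {
    H <- pmax(.coladd(H %*% p[[sprintf("eW%d", i)]],
                      p[[sprintf("eb%d", i)]]), 0)
    eacts[[i + 1L]] <- H
  }
  mu <- .coladd(H %*% p$Wmu, p$bmu)
  lv <- .coladd(H %*% p$Wlv, p$blv)
  lv <- pmin(pmax(lv, -10), 10)  # numerical guard on log-variance
  if (sample_latent) {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    z <- mu + exp(0.5 * lv) * eps
  } else {
    eps <- NULL
    z <- mu
  }
  nd <- ne + 1L
  dacts <- vector("list", nd + 1L)
  dacts[[1L]] <- z
  H <- z
  for (i in seq_len(nd)) {
    H <- .coladd(H %*% p[[sprintf("dW%d", i)]], p[[sprintf("db%d", i)]])
    if (i < nd) H <- pmax(H, 0)
    dacts[[i + 1L]] <- H
  }
  list(out = H, mu = mu, logvar = lv,
       cache = if (cache) list(eacts = eacts, dacts = dacts, mu = mu,
                               lv = lv, eps = eps) else NULL)
}

.vae_backward <- function(p, cache, dOut, config, klWeight) {
  ne <- length(config@hiddenDims)
  nd <- ne + 1L
  B <- nrow(dOut)
  g <- list()
  dH <- dOut
  for (i in rev(seq_len(nd))) {
    g[[sprintf("dW%d", i)]] <- crossprod(cache$dacts[[i]], dH)
    g[[sprintf("db%d", i)]] <- colSums(dH)
    dH <- tcrossprod(dH, p[[sprintf("dW%d", i)]])
    if (i > 1L) dH <- dH * (cache$dacts[[i]] > 0)
  }
  dz <- dH
  dmu <- dz
  dlv <- if (!is.null(cache$eps))
    dz * cache$eps * 0.5 * exp(0.5 * cache$lv) else dz * 0
  # KL gradients (mean over batch, summed over latent dims)
  dmu <- dmu + klWeight * cache$mu / B
  dlv <- dlv + klWeight * 0.5 * (exp(cache$lv) - 1) / B
  Henc <- cache$eacts[[ne + 1L]]
  g$Wmu <- crossprod(Henc, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(Henc, dlv); g$blv <- colSums(dlv)
  dH <- tcrossprod(dmu, p$Wmu) + tcrossprod(dlv, p$Wlv)
  for (i in rev(seq_len(ne))) {
    dH <- dH * (cache$eacts[[i + 1L]] > 0)
    g[[sprintf("eW%d", i)]] <- crossprod(cache$eacts[[i]], dH)
    g[[sprintf("eb%d", i)]] <- colSums(dH)
    dH <- tcrossprod(dH, p[[sprintf("eW%d", i)]])
  }
  g[names(p)]
}

# --- model-level dispatch --------------------------------------------------

# forward pass for any model kind; returns list(out, cache, mu, logvar)
.model_forward <- function(model, X, dropout = FALSE, cache = FALSE,
                           sample_latent = FALSE) {
  switch(model@kind,
    transformer = .tf_forward(model@params, X, .tf_shapes(model@config),
                              dropout = dropout, cache = cache),
    dae = .dae_forward(model@params, X, model@config@dropout,
                       dropout = dropout, cache = cache),
    vae = .vae_forward(model@params, X, model@config, dropout = dropout,
                       cache = cache, sample_latent = sample_latent))
}

.model_backward <- function(model, cache, dOut) {
  switch(model@kind,
    transformer = .tf_backward(model@params, cache, dOut,
                               .tf_shapes(model@config)),
    dae = .dae_backward(model@params, cache, dOut, model@config@dropout),
    vae = .vae_backward(model@params, cache, dOut, model@config,
                        model@config@klWeight))
}

# --- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
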