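## The interaction network: a two-layer MLP drug branch; a protein branch
## of residual graph convolutions (H <- ReLU(A H W) + H, L layers) followed
## by multiset-transformer attention pooling; bilinear fusion and a linear
## prediction head. Forward and backward passes are written out explicitly
## over base matrix operations; every forward caches what its backward
## needs. Gradient correctness is pinned by finite-difference tests.

## ---------------------------------------------------------------------------
## Initialisation
## ---------------------------------------------------------------------------

.kaimingU <- function(nin, nout, fanIn = nin) {
  lim <- sqrt(6 / fanIn)
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## Xavier scaling for the attention projections (keeps softmax logits at
## O(1) so attention is not saturated at initialisation).
.xavierU <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise an interaction model
#'
#' Weights use seeded Kaiming-uniform initialisation (fan-in scaling,
#' matching the ReLU activations); biases start at zero.
#'
#' @param config a [ModelConfig-class].
#' @param dDrug drug input dimension (fingerprint length under the
#'   `fingerprint_drug` ablation).
#' @param dRes per-residue feature dimension.
#' @param seed initialisation seed.
#' @return a [DTIModel-class].
#' @export
initModel <- function(config = ModelConfig(), dDrug, dRes, seed = 1) {
  validObject(config)
  h <- config@hiddenDim
  m <- config@gmtSeeds
  fd <- config@fusionDim
  L <- config@gcnLayers
  params <- .withSeed(seed, {
    p <- list(
      Wd1 = .kaimingU(dDrug, h), bd1 = numeric(h),
      Wd2 = .kaimingU(h, h),     bd2 = numeric(h),
      Win = .kaimingU(dRes, h),  bin = numeric(h),
      Wt1 = .kaimingU(h, h),     bt1 = numeric(h),
      Wt2 = .kaimingU(h, h),     bt2 = numeric(h),
      bf  = numeric(fd),
      wh  = .kaimingU(fd, 1),    bh = numeric(1))
    for (k in seq_len(L)) p[[paste0("Wg", k)]] <- .kaimingU(h, h)
    if (!"no_gmt" %in% config@ablation &&
        !"no_structure" %in% config@ablation) {
      p$S1 <- matrix(rnorm(m * h, sd = 1 / sqrt(h)), m, h)
      p$S2 <- matrix(rnorm(h, sd = 1 / sqrt(h)), 1, h)
      for (b in 1:3) {
        p[[paste0("Aq", b)]] <- .xavierU(h, h)
        p[[paste0("Ak", b)]] <- .xavierU(h, h)
        p[[paste0("Av", b)]] <- .xavierU(h, h)
        p[[paste0("Ao", b)]] <- .xavierU(h, h)
      }
    }
    ## O(1/h) scale keeps the initial logits O(1): the bilinear form sums
    ## h^2 terms over embeddings whose norms grow with sqrt(h)
    p$Bf <- array(runif(fd * h * h, -1 / h, 1 / h), c(fd, h, h))
    p
  })
  new("DTIModel", config = config, params = params,
      dims = list(dDrug = as.integer(dDrug), dRes = as.integer(dRes)),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Primitive layers (forward + backward)
## ---------------------------------------------------------------------------

## Inverted dropout; returns the scaled mask so eval passes use mask = 1.
.dropoutMask <- function(dim1, dim2, p, training) {
  if (!training || p <= 0) return(1)
  matrix((runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

.mhaForward <- function(p, b, Qin, Kin, nh) {
  h <- ncol(Qin)
  dh <- h %/% nh
  Q <- Qin %*% p[[paste0("Aq", b)]]
  K <- Kin %*% p[[paste0("Ak", b)]]
  V <- Kin %*% p[[paste0("Av", b)]]
  O <- matrix(0, nrow(Qin), h)
  attn <- vector("list", nh)
  for (j in seq_len(nh)) {
    idx <- ((j - 1) * dh + 1):(j * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    A <- .rowSoftmax(S)
    attn[[j]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p[[paste0("Ao", b)]]
  list(out = out,
       cache = list(Qin = Qin, Kin = Kin, Q = Q, K = K, V = V, O = O,
                    attn = attn, nh = nh, dh = dh, b = b))
}

.mhaBackward <- function(p, cache, dout) {
  b <- cache$b; nh <- cache$nh; dh <- cache$dh
  g <- list()
  g[[paste0("Ao", b)]] <- t(cache$O) %*% dout
  dO <- dout %*% t(p[[paste0("Ao", b)]])
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (j in seq_len(nh)) {
    idx <- ((j - 1) * dh + 1):(j * dh)
    A <- cache$attn[[j]]
    dOj <- dO[, idx, drop = FALSE]
    dA <- dOj %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dOj
    ## softmax Jacobian, row-wise
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE]
  }
  g[[paste0("Aq", b)]] <- t(cache$Qin) %*% dQ
  g[[paste0("Ak", b)]] <- t(cache$Kin) %*% dK
  g[[paste0("Av", b)]] <- t(cache$Kin) %*% dV
  dQin <- dQ %*% t(p[[paste0("Aq", b)]])
  dKin <- dK %*% t(p[[paste0("Ak", b)]]) + dV %*% t(p[[paste0("Av", b)]])
  list(grads = g, dQin = dQin, dKin = dKin)
}

## ---------------------------------------------------------------------------
## Drug branch
## ---------------------------------------------------------------------------

.forwardDrug <- function(params, X, dropoutRate, training) {
  Z1 <- sweep(X %*% params$Wd1, 2, params$bd1, `+`)
  H1 <- pmax(Z1, 0)
  mask <- .dropoutMask(nrow(H1), ncol(H1), dropoutRate, training)
  D1 <- H1 * mask
  E <- sweep(D1 %*% params$Wd2, 2, params$bd2, `+`)
  list(E = E, cache = list(X = X, Z1 = Z1, mask = mask, D1 = D1))
}

.backwardDrug <- function(params, cache, dE) {
  g <- list(Wd2 = t(cache$D1) %*% dE, bd2 = colSums(dE))
  dD1 <- dE %*% t(params$Wd2)
  dH1 <- dD1 * cache$mask
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$Wd1 <- t(cache$X) %*% dZ1
  g$bd1 <- colSums(dZ1)
  g
}

## ---------------------------------------------------------------------------
## Target branch
## ---------------------------------------------------------------------------

## `input` is either a ProteinGraph (structural paths) or a numeric vector
## (sequence-level embedding, no_structure ablation).
.forwardTarget <- function(params, cfg, input, dropoutRate, training) {
  noGmt <- "no_gmt" %in% cfg@ablation
  noStruct <- "no_structure" %in% cfg@ablation
  nh <- cfg@gmtHeads
  if (noStruct) {
    x <- matrix(as.numeric(input), nrow = 1)
    z <- sweep(x %*% params$Win, 2, params$bin, `+`)
    cache <- list(kind = "seq", x = x)
    HL <- NULL
  } else {
    H0 <- input@nodeFeatures
    A <- input@normAdjacency
    Hp <- sweep(H0 %*% params$Win, 2, params$bin, `+`)
    L <- cfg@gcnLayers
    Ms <- Zs <- vector("list", L)
    H <- Hp
    for (k in seq_len(L)) {
      Ms[[k]] <- A %*% H
      Zs[[k]] <- Ms[[k]] %*% params[[paste0("Wg", k)]]
      H <- pmax(Zs[[k]], 0) + H
    }
    HL <- H
    mask <- .dropoutMask(nrow(HL), ncol(HL), dropoutRate, training)
    HD <- HL * mask
    if (noGmt) {
      z <- matrix(colMeans(HD), nrow = 1)
      cache <- list(kind = "nogmt", H0 = H0, A = A, Ms = Ms, Zs = Zs,
                    mask = mask, nV = nrow(HD))
    } else {
      b1 <- .mhaForward(params, 1, params$S1, HD, nh)
      b2 <- .mhaForward(params, 2, b1$out, b1$out, nh)
      b3 <- .mhaForward(params, 3, params$S2, b2$out, nh)
      z <- b3$out
      cache <- list(kind = "gmt", H0 = H0, A = A, Ms = Ms, Zs = Zs,
                    mask = mask, b1 = b1$cache, b2 = b2$cache, b3 = b3$cache)
    }
  }
  T1z <- sweep(z %*% params$Wt1, 2, params$bt1, `+`)
  T1 <- pmax(T1z, 0)
  mask2 <- .dropoutMask(nrow(T1), ncol(T1), dropoutRate, training)
  T1d <- T1 * mask2
  e <- sweep(T1d %*% params$Wt2, 2, params$bt2, `+`)
  cache$z <- z; cache$T1z <- T1z; cache$mask2 <- mask2; cache$T1d <- T1d
  list(e = e, HL = HL, cache = cache)
}

## Returns parameter grads and (optionally) the gradient at the last GCN
## layer output H(L), which grad-CAM consumes.
.backwardTarget <- function(params, cfg, cache, dE, needHL = FALSE) {
  g <- list(Wt2 = t(cache$T1d) %*% dE, bt2 = colSums(dE))
  dT1d <- dE %*% t(params$Wt2)
  dT1 <- dT1d * cache$mask2
  dT1z <- dT1 * (cache$T1z > 0)
  g$Wt1 <- t(cache$z) %*% dT1z
  g$bt1 <- colSums(dT1z)
  dz <- dT1z %*% t(params$Wt1)

  if (cache$kind == "seq") {
    g$Win <- t(cache$x) %*% dz
    g$bin <- colSums(dz)
    return(list(grads = g, dHL = NULL))
  }

  if (cache$kind == "nogmt") {
    dHD <- matrix(rep(as.numeric(dz) / cache$nV, each = cache$nV),
                  nrow = cache$nV)
  } else {
    bb3 <- .mhaBackward(params, cache$b3, dz)
    g <- c(g, bb3$grads)
    g$S2 <- bb3$dQin
    bb2 <- .mhaBackward(params, cache$b2, bb3$dKin)
    g <- c(g, bb2$grads)
    dB1out <- bb2$dQin + bb2$dKin
    bb1 <- .mhaBackward(params, cache$b1, dB1out)
    g <- c(g, bb1$grads)
    g$S1 <- bb1$dQin
    dHD <- bb1$dKin
  }

  dHL <- dHD * cache$mask
  if (needHL) dHLout <- dHL

  ## residual GCN stack, layers L..1
  L <- cfg@gcnLayers
  dH <- dHL
  for (k in rev(seq_len(L))) {
    dZ <- dH * (cache$Zs[[k]] > 0)
    g[[paste0("Wg", k)]] <- t(cache$Ms[[k]]) %*% dZ
    dM <- dZ %*% t(params[[paste0("Wg", k)]])
    dH <- dH + t(cache$A) %*% dM  # residual path + conv path (A symmetric)
  }
  g$Win <- t(cache$H0) %*% dH
  g$bin <- colSums(dH)
  list(grads = g, dHL = if (needHL) dHLout else NULL)
}

## ---------------------------------------------------------------------------
## Bilinear fusion + head
## ---------------------------------------------------------------------------

.forwardFusion <- function(params, Ed, Et) {
  fd <- dim(params$Bf)[1]
  n <- nrow(Ed)
  f <- matrix(0, n, fd)
  P <- vector("list", fd)
  for (k in seq_len(fd)) {
    P[[k]] <- Ed %*% params$Bf[k, , ]
    f[, k] <- rowSums(P[[k]] * Et) + params$bf[k]
  }
  logit <- as.numeric(f %*% params$wh) + params$bh
  list(logit = logit, fused = f, cache = list(Ed = Ed, Et = Et, f = f, P = P))
}

.backwardFusion <- function(params, cache, dlogit) {
  fd <- dim(params$Bf)[1]
  Ed <- cache$Ed; Et <- cache$Et
  g <- list(wh = t(cache$f) %*% matrix(dlogit, ncol = 1),
            bh = sum(dlogit))
  df <- outer(dlogit, as.numeric(params$wh))
  g$bf <- colSums(df)
  dBf <- array(0, dim(params$Bf))
  dEd <- matrix(0, nrow(Ed), ncol(Ed))
  dEt <- matrix(0, nrow(Et), ncol(Et))
  for (k in seq_len(fd)) {
    wEt <- Et * df[, k]
    dBf[k, , ] <- t(Ed) %*% wEt
    dEd <- dEd + wEt %*% t(params$Bf[k, , ])
    dEt <- dEt + (Ed * df[, k]) %*% params$Bf[k, , ]
  }
  g$Bf <- dBf
  list(grads = g, dEd = dEd, dEt = dEt)
}

## ---------------------------------------------------------------------------
## Public forward wrappers (eval mode)
## ---------------------------------------------------------------------------

#' Residual graph-convolution forward pass
#'
#' Projects node features to the hidden width, then applies
#' `H <- ReLU(A H W) + H` for each configured layer, returning the final
#' node activations H(L).
#'
#' @param model a [DTIModel-class].
#' @param graph a [ProteinGraph-class].
#' @return numeric matrix, `nNodes(graph)` x `hiddenDim`.
#' @export
gcnForward <- function(model, graph) {
  p <- model@params
  Hp <- sweep(graph@nodeFeatures %*% p$Win, 2, p$bin, `+`)
  H <- Hp
  for (k in seq_len(model@config@gcnLayers)) {
    H <- pmax((graph@normAdjacency %*% H) %*% p[[paste0("Wg", k)]], 0) + H
  }
  H
}

#' Multiset-transformer graph pooling
#'
#' Attention pooling of node activations onto learned seed vectors, one
#' self-attention block over the seeds, then pooling onto a single seed;
#' permutation-invariant in the node order and invariant to multiset
#' duplication of nodes (the softmax re-normalises).
#'
#' @param model a [DTIModel-class].
#' @param nodeActivations numeric matrix, nodes x hiddenDim (typically
#'   H(L) from [gcnForward()]).
#' @return numeric vector of length `hiddenDim`.
#' @export
gmtPool <- function(model, nodeActivations) {
  if (is.null(dim(nodeActivations)) || nrow(nodeActivations) < 1)
    .dtiStop("empty node set")
  p <- model@params
  nh <- model@config@gmtHeads
  b1 <- .mhaForward(p, 1, p$S1, nodeActivations, nh)
  b2 <- .mhaForward(p, 2, b1$out, b1$out, nh)
  b3 <- .mhaForward(p, 3, p$S2, b2$out, nh)
  as.numeric(b3$out)
}

#' Drug branch (two-layer MLP), eval mode
#'
#' @param model a [DTIModel-class].
#' @param X drug feature matrix (rows = drugs) or a single vector.
#' @return embedding matrix (rows = drugs).
#' @export
drugBranch <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model@dims$dDrug)
    .dtiStop(sprintf("drug input width %d != expected %d", ncol(X),
                     model@dims$dDrug))
  .forwardDrug(model@params, X, 0, FALSE)$E
}

#' Target branch (GCN + pooling + MLP), eval mode
#'
#' @param model a [DTIModel-class].
#' @param input a [ProteinGraph-class], or a sequence-level embedding
#'   vector under the `no_structure` ablation.
#' @return list with `embedding` (numeric vector) and `nodeActivations`
#'   (H(L), NULL under `no_structure`).
#' @export
targetBranch <- function(model, input) {
  if ("no_structure" %in% model@config@ablation && !is.numeric(input))
    .dtiStop("no_structure model expects a sequence-level embedding vector")
  if (!"no_structure" %in% model@config@ablation && !is(input, "ProteinGraph"))
    .dtiStop("structural model expects a ProteinGraph")
  fw <- .forwardTarget(model@params, model@config, input, 0, FALSE)
  list(embedding = as.numeric(fw$e), nodeActivations = fw$HL)
}

#' Bilinear fusion and scoring, eval mode
#'
#' The drug and target embeddings are combined by a learned bilinear
#' tensor plus bias into a fused vector; a linear head maps it to one
#' logit (the sigmoid is applied downstream by losses/metrics).
#'
#' @param model a [DTIModel-class].
#' @param drugEmbedding,targetEmbedding embedding vectors or aligned
#'   matrices (rows = pairs).
#' @return list with `logit`, `probability`, `fused`.
#' @export
fuseAndScore <- function(model, drugEmbedding, targetEmbedding) {
  if (is.null(dim(drugEmbedding)))
    drugEmbedding <- matrix(drugEmbedding, nrow = 1)
  if (is.null(dim(targetEmbedding)))
    targetEmbedding <- matrix(targetEmbedding, nrow = 1)
  fw <- .forwardFusion(model@params, drugEmbedding, targetEmbedding)
  list(logit = fw$logit, probability = .sigmoid(fw$logit), fused = fw$fused)
}
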