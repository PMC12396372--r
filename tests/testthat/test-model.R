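test_that("residual GCN collapses to the projection when weights are zero", {
  g <- makeTestGraph(nV = 10, dRes = 6)
  cfg <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2)
  model <- initModel(cfg, dDrug = 4, dRes = 6, seed = 1)
  for (k in 1:3) model@params[[paste0("Wg", k)]][] <- 0
  H <- gcnForward(model, g)
  expected <- sweep(nodeFeatures(g) %*% model@params$Win, 2,
                    model@params$bin, `+`)
  expect_equal(H, expected, tolerance = 1e-12)
})

test_that("one-node graph with identity weights doubles a non-negative input", {
  cfg <- ModelConfig(gcnLayers = 1, hiddenDim = 4, gmtHeads = 1, gmtSeeds = 1)
  model <- initModel(cfg, dDrug = 2, dRes = 4, seed = 1)
  model@params$Win <- diag(4)
  model@params$bin[] <- 0
  model@params$Wg1 <- diag(4)
  h <- c(0.5, 1.2, 0, 3)
  g <- new("ProteinGraph", targetId = "one",
           nodeFeatures = matrix(h, 1, 4),
           rawAdjacency = matrix(0, 1, 1),
           normAdjacency = matrix(1, 1, 1))
  expect_equal(as.numeric(gcnForward(model, g)), 2 * h)
})

test_that("GCN forward matches a dense naive re-implementation", {
  set.seed(11)
  for (rep in 1:5) {
    g <- makeTestGraph(nV = 8 + rep, dRes = 5, seed = rep)
    cfg <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2)
    model <- initModel(cfg, dDrug = 3, dRes = 5, seed = rep)
    p <- model@params
    expected <- oracleGcn(nodeFeatures(g), normAdjacency(g), p$Win, p$bin,
                          list(p$Wg1, p$Wg2, p$Wg3))
    expect_equal(gcnForward(model, g), expected, tolerance = 1e-6)
  }
})

test_that("multiset pooling is permutation-invariant and duplication-invariant", {
  cfg <- ModelConfig(hiddenDim = 16, gmtHeads = 4, gmtSeeds = 4)
  model <- initModel(cfg, dDrug = 4, dRes = 6, seed = 2)
  set.seed(21)
  for (rep in 1:5) {
    H <- matrix(rnorm(30 * 16), 30, 16)
    z <- gmtPool(model, H)
    expect_length(z, 16)
    for (p in 1:5) {
      perm <- sample(30)
      zp <- gmtPool(model, H[perm, ])
      expect_lt(max(abs(zp - z)) / max(abs(z)), 1e-5)
    }
    ## doubling every node is a multiset no-op under softmax attention
    zd <- gmtPool(model, rbind(H, H))
    expect_lt(max(abs(zd - z)) / max(abs(z)), 1e-4)
  }
  expect_length(gmtPool(model, matrix(rnorm(16), 1, 16)), 16)
  expect_error(gmtPool(model, matrix(numeric(), 0, 16)))
})

test_that("drug branch is a row-independent two-layer MLP", {
  cfg <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2)
  model <- initModel(cfg, dDrug = 6, dRes = 4, seed = 3)
  zero <- model
  for (nm in c("Wd1", "bd1", "Wd2", "bd2")) zero@params[[nm]][] <- 0
  expect_equal(drugBranch(zero, matrix(rnorm(12), 2, 6)),
               matrix(0, 2, 8))

  X <- matrix(rnorm(5 * 6), 5, 6)
  E <- drugBranch(model, X)
  expect_equal(dim(E), c(5, 8))
  ## batch independence: each row depends only on its own input
  E2 <- drugBranch(model, X[c(3, 1), ])
  expect_equal(E2[1, ], E[3, ])
  expect_equal(E2[2, ], E[1, ])
  expect_error(drugBranch(model, matrix(0, 1, 5)), "width")

  ## hand evaluation on a 1-wide toy
  cfg1 <- ModelConfig(hiddenDim = 1, gmtHeads = 1, gmtSeeds = 1)
  m1 <- initModel(cfg1, dDrug = 1, dRes = 1, seed = 1)
  m1@params$Wd1 <- matrix(2); m1@params$bd1 <- 1
  m1@params$Wd2 <- matrix(3); m1@params$bd2 <- -1
  ## x=2: relu(2*2+1)*3 - 1 = 14; x=-4: relu(-7)=0 -> -1
  expect_equal(as.numeric(drugBranch(m1, matrix(c(2, -4), 2, 1))), c(14, -1))
})

test_that("target branch honours the pooling ablations", {
  cfg <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2,
                     ablation = "no_gmt")
  model <- initModel(cfg, dDrug = 4, dRes = 6, seed = 4)
  g <- makeTestGraph(nV = 9, dRes = 6, seed = 5)
  out <- targetBranch(model, g)
  ## pooled vector = column mean of H(L), then the 2-layer MLP
  z <- colMeans(gcnForward(model, g))
  p <- model@params
  t1 <- pmax(z %*% p$Wt1 + matrix(p$bt1, 1), 0)
  expected <- as.numeric(t1 %*% p$Wt2 + matrix(p$bt2, 1))
  expect_equal(out$embedding, expected, tolerance = 1e-10)

  cfgFull <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2)
  full <- initModel(cfgFull, dDrug = 4, dRes = 6, seed = 4)
  expect_false(isTRUE(all.equal(targetBranch(full, g)$embedding,
                                out$embedding)))
  expect_identical(targetBranch(full, g), targetBranch(full, g))

  cfgSeq <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 2,
                        ablation = "no_structure")
  seqModel <- initModel(cfgSeq, dDrug = 4, dRes = 6, seed = 4)
  sv <- rnorm(6)
  expect_length(targetBranch(seqModel, sv)$embedding, 8)
  expect_null(targetBranch(seqModel, sv)$nodeActivations)
  expect_error(targetBranch(seqModel, g), "embedding")
})

test_that("bilinear fusion matches hand-computable cases", {
  cfg <- ModelConfig(hiddenDim = 4, gmtHeads = 2, gmtSeeds = 2, fusionDim = 3)
  model <- initModel(cfg, dDrug = 4, dRes = 4, seed = 5)
  zero <- model
  zero@params$Bf[] <- 0; zero@params$bf[] <- 0; zero@params$bh[] <- 0
  out <- fuseAndScore(zero, rnorm(4), rnorm(4))
  expect_equal(out$logit, 0)
  expect_equal(out$probability, 0.5)

  ## 1-dim toy with a unit tensor: logit = e_d * e_t
  cfg1 <- ModelConfig(hiddenDim = 1, gmtHeads = 1, gmtSeeds = 1,
                      fusionDim = 1)
  m1 <- initModel(cfg1, dDrug = 1, dRes = 1, seed = 1)
  m1@params$Bf[1, 1, 1] <- 1
  m1@params$bf[] <- 0; m1@params$wh[] <- 1; m1@params$bh[] <- 0
  expect_equal(fuseAndScore(m1, 3, -2)$logit, -6)

  ## swapping two samples swaps their logits exactly
  Ed <- matrix(rnorm(8), 2, 4)
  Et <- matrix(rnorm(8), 2, 4)
  l12 <- fuseAndScore(model, Ed, Et)$logit
  l21 <- fuseAndScore(model, Ed[2:1, ], Et[2:1, ])$logit
  expect_identical(l12, l21[2:1])
})

test_that("analytic gradients agree with finite differences end to end", {
  ns <- asNamespace("graphDTI")
  cfg <- ModelConfig(hiddenDim = 8, gmtHeads = 2, gmtSeeds = 3,
                     fusionDim = 4, dropoutRate = 0)
  model <- initModel(cfg, dDrug = 5, dRes = 4, seed = 7)
  p <- model@params
  set.seed(42)
  graphs <- list(makeTestGraph(7, 4, seed = 31), makeTestGraph(6, 4, seed = 32))
  Xd <- matrix(rnorm(3 * 5), 3, 5)
  di <- c(1, 2, 3, 1, 2); ti <- c(1, 1, 2, 2, 1)
  labels <- c(1, 0, 1, 0, 1)
  dS <- matrix(c(1, .9, .3, .9, 1, .2, .3, .2, 1), 3, 3)
  tS <- matrix(c(1, .7, .7, 1), 2, 2)
  lcfg <- LossConfig()

  lossOf <- function(params) {
    Ed <- ns$.forwardDrug(params, Xd, 0, FALSE)$E
    Et <- do.call(rbind, lapply(graphs, function(g)
      ns$.forwardTarget(params, cfg, g, 0, FALSE)$e))
    ff <- ns$.forwardFusion(params, Ed[di, , drop = FALSE],
                            Et[ti, , drop = FALSE])
    totalLoss(ff$logit, labels, Ed, dS, Et, tS, lcfg)$total
  }

  grads <- local({
    fwD <- ns$.forwardDrug(p, Xd, 0, FALSE)
    fwT <- lapply(graphs, function(g) ns$.forwardTarget(p, cfg, g, 0, FALSE))
    Et <- do.call(rbind, lapply(fwT, `[[`, "e"))
    ff <- ns$.forwardFusion(p, fwD$E[di, , drop = FALSE],
                            Et[ti, , drop = FALSE])
    fl <- focalLoss(ff$logit, labels, lcfg@w, lcfg@t, gradient = TRUE)
    bF <- ns$.backwardFusion(p, ff$cache, lcfg@alpha * fl$grad)
    g <- bF$grads
    dEd <- rowsum(bF$dEd, di) +
      lcfg@beta * ntxentGeneralized(fwD$E, positiveMask(dS, lcfg@thetaDrug),
                                    lcfg@tau, gradient = TRUE)$grad
    dEt <- rowsum(bF$dEt, ti) +
      lcfg@gamma * ntxentGeneralized(Et, positiveMask(tS, lcfg@thetaProt),
                                     lcfg@tau, gradient = TRUE)$grad
    g <- ns$.addGrads(g, ns$.backwardDrug(p, fwD$cache, dEd))
    for (u in 1:2) {
      g <- ns$.addGrads(g, ns$.backwardTarget(p, cfg, fwT[[u]]$cache,
                                              dEt[u, , drop = FALSE])$grads)
    }
    g
  })

  eps <- 1e-6
  set.seed(99)
  for (nm in names(p)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
      an <- as.numeric(grads[[nm]])[i]
      ## absolute slack floors the comparison for near-zero gradients
      ## (finite differences bottom out around 1e-8 here)
      expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd)),
                label = sprintf("%s[%d]: fd=%g analytic=%g", nm, i, fd, an))
    }
  }
})

test_that("forward passes are deterministic in eval mode and checkpoints round-trip", {
  feats <- tinyFeatures()
  cfg <- ModelConfig(hiddenDim = 16, gmtSeeds = 4, gmtHeads = 2)
  model <- initModel(cfg, feats$dDrug, feats$dRes, seed = 9)
  ints <- interactions(tinySim()$bundle)[1:40, ]
  s1 <- predictPairs(model, feats, ints)
  s2 <- predictPairs(model, feats, ints)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1)))

  f <- withr::local_tempfile(fileext = ".json")
  saveModel(model, f)
  back <- loadModel(f)
  expect_equal(predictPairs(back, feats, ints), s1, tolerance = 1e-12)
})

test_that("a zero-layer GCN reduces the branch to pooled projected inputs", {
  cfg <- ModelConfig(gcnLayers = 0, hiddenDim = 8, gmtHeads = 2,
                     gmtSeeds = 2, ablation = "no_gmt")
  model <- initModel(cfg, dDrug = 4, dRes = 6, seed = 10)
  g <- makeTestGraph(nV = 7, dRes = 6, seed = 12)
  p <- model@params
  z <- colMeans(sweep(nodeFeatures(g) %*% p$Win, 2, p$bin, `+`))
  t1 <- pmax(z %*% p$Wt1 + matrix(p$bt1, 1), 0)
  expected <- as.numeric(t1 %*% p$Wt2 + matrix(p$bt2, 1))
  expect_equal(targetBranch(model, g)$embedding, expected, tolerance = 1e-10)
})
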