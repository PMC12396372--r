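test_that("grad-CAM scores match a finite-difference gradient oracle", {
  ## 5-node graph, no_gmt pooling so the post-H(L) pipeline can be
  ## re-evaluated in closed form from the parameters
  cfg <- ModelConfig(hiddenDim = 6, gmtHeads = 2, gmtSeeds = 2,
                     fusionDim = 4, dropoutRate = 0, ablation = "no_gmt")
  model <- initModel(cfg, dDrug = 4, dRes = 3, seed = 13)
  g <- makeTestGraph(nV = 5, dRes = 3, seed = 14)
  set.seed(15)
  xd <- rnorm(4)
  att <- gradcamResidues(model, xd, g, drugId = "d")

  ## independent re-evaluation: logit as a function of H(L)
  p <- model@params
  eD <- drugBranch(model, xd)
  logitFromHL <- function(HL) {
    z <- colMeans(HL)
    t1 <- pmax(z %*% p$Wt1 + matrix(p$bt1, 1), 0)
    et <- t1 %*% p$Wt2 + matrix(p$bt2, 1)
    fuseAndScore(model, eD, et)$logit
  }
  HL <- gcnForward(model, g)
  eps <- 1e-4
  fdGrad <- matrix(0, nrow(HL), ncol(HL))
  for (i in seq_len(nrow(HL))) {
    for (j in seq_len(ncol(HL))) {
      Hp <- HL; Hp[i, j] <- Hp[i, j] + eps
      Hm <- HL; Hm[i, j] <- Hm[i, j] - eps
      fdGrad[i, j] <- (logitFromHL(Hp) - logitFromHL(Hm)) / (2 * eps)
    }
  }
  alpha <- colMeans(fdGrad)
  expected <- pmax(as.numeric(HL %*% alpha), 0)
  expect_equal(att$scores, expected, tolerance = 1e-3)

  ## per-node (unpooled) variant against the same oracle
  attN <- gradcamResidues(model, xd, g, pooled = FALSE)
  expect_equal(attN$scores, pmax(rowSums(HL * fdGrad), 0), tolerance = 1e-3)
})

test_that("grad-CAM analytic linear-head case and degenerate head", {
  ## craft a model whose logit is exactly the mean of channel 1 of H(L):
  ## no_gmt pooling gives z = colMeans(H(L)); make the MLP pass z through
  ## and the fusion head read coordinate 1
  cfg <- ModelConfig(hiddenDim = 4, gmtHeads = 1, gmtSeeds = 1,
                     fusionDim = 4, dropoutRate = 0, ablation = "no_gmt")
  model <- initModel(cfg, dDrug = 2, dRes = 3, seed = 16)
  p <- model@params
  big <- 100
  p$Wt1 <- diag(4); p$bt1 <- rep(big, 4)   # shift into the ReLU-linear range
  p$Wt2 <- diag(4); p$bt2 <- rep(-big, 4)  # undo the shift
  p$Wd1[] <- 0; p$bd1 <- rep(1, 4)
  p$Wd2[] <- 0; p$bd2 <- rep(1, 4)         # constant drug embedding = 1
  p$Bf[] <- 0
  p$Bf[1, , ] <- 0
  ## fused_1 = e_d . (B_1 e_t): with B_1[i, 1] = 1/4 for all i,
  ## fused_1 = sum_i e_d_i * e_t_1 / 4 = e_t_1 (e_d = 1)
  p$Bf[1, , 1] <- 1 / 4
  p$bf[] <- 0
  p$wh[] <- 0; p$wh[1] <- 1; p$bh[] <- 0
  model@params <- p
  g <- makeTestGraph(nV = 6, dRes = 3, seed = 17)
  HL <- gcnForward(model, g)
  out <- fuseAndScore(model, drugBranch(model, c(0, 0)),
                      targetBranch(model, g)$embedding)
  expect_equal(out$logit, mean(HL[, 1]), tolerance = 1e-8)

  att <- gradcamResidues(model, c(0, 0), g)
  ## d logit / d H(L) = 1/(6) on channel 1, 0 elsewhere ->
  ## alpha = (1/6, 0, 0, 0); scores proportional to ReLU(H(L)[, 1])
  expect_equal(att$scores, pmax(HL[, 1] / 6, 0), tolerance = 1e-8)

  ## zero head: every score is zero
  zero <- model
  zero@params$wh[] <- 0; zero@params$Bf[] <- 0
  attZ <- gradcamResidues(zero, c(0, 0), g)
  expect_equal(attZ$scores, rep(0, 6))

  ## deterministic and refuses the no-structure ablation
  expect_identical(att$scores, gradcamResidues(model, c(0, 0), g)$scores)
  cfgNS <- ModelConfig(hiddenDim = 4, gmtHeads = 1, gmtSeeds = 1,
                       ablation = "no_structure")
  mNS <- initModel(cfgNS, dDrug = 2, dRes = 3, seed = 1)
  expect_error(gradcamResidues(mNS, c(0, 0), g), "no_structure")
})

test_that("pocket recall handles indicator, adversarial and random scores", {
  sites <- c(3, 7, 9)
  scores <- numeric(20); scores[sites] <- 1
  expect_equal(pocketRecall(scores, sites), 1)
  ## true sites ranked last
  anti <- seq(20, 1); anti[sites] <- 0
  expect_equal(pocketRecall(anti, sites), 0)
  expect_error(pocketRecall(scores, integer()))
  expect_error(pocketRecall(scores, 1:25))

  ## invariance under strictly monotone transforms
  set.seed(18)
  sc <- runif(30)
  st <- sample(30, 6)
  r0 <- pocketRecall(sc, st)
  expect_equal(pocketRecall(exp(4 * sc) + 2, st), r0)
  expect_equal(pocketRecall(rank(sc, ties.method = "first"), st), r0)
})

test_that("uniform-random scores recover the k/V baseline recall", {
  set.seed(19)
  n <- 100; k <- 10
  sites <- 1:k
  trials <- replicate(10000, pocketRecall(runif(n), sites))
  expect_lt(abs(mean(trials) - k / n), 0.01)
})

test_that("complex-derived annotations find residues near the ligand", {
  set.seed(20)
  co <- matrix(rnorm(30 * 3, sd = 8), 30, 3)
  lig <- co[5, , drop = FALSE]  # atom on residue 5's Calpha
  ann <- annotateFromComplex(co, lig, cutoffA = 1)
  expect_true(5 %in% ann)

  far <- matrix(c(1000, 1000, 1000), 1, 3)
  expect_error(annotateFromComplex(co, far, cutoffA = 5), "no residue")
  expect_error(annotateFromComplex(co, co[0, , drop = FALSE]), "ligand")
})

test_that("planted pockets round-trip through a pseudo-ligand annotation", {
  sim <- tinySim()
  id <- names(sim$truth$pockets)[2]
  pocket <- sim$truth$pockets[[id]]$residues
  co <- sim$bundle@coords[[id]]
  centroid <- matrix(colMeans(co[pocket, , drop = FALSE]), 1, 3)
  ann <- annotateFromComplex(co, centroid, cutoffA = 10)
  ## the recovered annotation is concentrated on the planted pocket
  expect_gt(length(intersect(ann, pocket)) / length(pocket), 0.5)
})

test_that("attribution PDB writer stores normalised scores as B-factors", {
  sim <- tinySim()
  id <- names(sim$truth$pockets)[1]
  co <- sim$bundle@coords[[id]]
  seqStr <- sim$bundle@targets$sequence[
    match(id, sim$bundle@targets$target_id)]
  scores <- runif(nchar(seqStr))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeAttributionPdb(co, seqStr, scores, f)
  lines <- grep("^ATOM", readLines(f), value = TRUE)
  expect_length(lines, nchar(seqStr))
  b <- as.numeric(substr(lines, 61, 66))
  expect_equal(b, round(scores / max(scores), 2), tolerance = 5e-3)
})
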