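test_that("stratified folds keep class proportions within one sample", {
  labels <- c(rep(1, 40), rep(0, 160))
  folds <- stratifiedKfold(labels, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_equal(sum(labels[f$test] == 1), 8)
    expect_equal(sum(labels[f$test] == 0), 32)
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  ## uneven class sizes still land within +-1 of n_class / k
  set.seed(4)
  labs <- rbinom(203, 1, 0.23)
  for (f in stratifiedKfold(labs, 5, seed = 9)) {
    expect_lte(abs(sum(labs[f$test] == 1) - sum(labs == 1) / 5), 1)
    expect_lte(abs(sum(labs[f$test] == 0) - sum(labs == 0) / 5), 1)
  }
  expect_error(stratifiedKfold(labels, k = 1), "k")
  expect_error(stratifiedKfold(rep(1, 50), k = 5), "class")
  expect_identical(stratifiedKfold(labels, 5, seed = 3), folds)
})

test_that("cold-start splits enforce entity disjointness with full accounting", {
  ints <- interactions(tinySim()$bundle)
  for (seed in 1:5) {
    for (mode in c("drug_cold", "target_cold", "pair_cold",
                   "entity_holdout")) {
      sp <- suppressMessages(coldStartSplit(ints, mode, 0.25, seed))
      expect_setequal(c(sp$train, sp$test, sp$dropped), seq_len(nrow(ints)))
      trainD <- unique(ints$drug_id[sp$train])
      testD <- unique(ints$drug_id[sp$test])
      trainT <- unique(ints$target_id[sp$train])
      testT <- unique(ints$target_id[sp$test])
      if (mode %in% c("drug_cold", "pair_cold"))
        expect_length(intersect(trainD, testD), 0)
      if (mode %in% c("target_cold", "pair_cold"))
        expect_length(intersect(trainT, testT), 0)
      if (mode == "drug_cold")
        expect_gt(length(intersect(trainT, testT)), 0)
      if (mode == "entity_holdout") {
        ## held-out entities never reach training; every test pair
        ## involves at least one held-out entity
        expect_length(intersect(sp$heldDrugs, trainD), 0)
        expect_length(intersect(sp$heldTargets, trainT), 0)
        expect_true(all(ints$drug_id[sp$test] %in% sp$heldDrugs |
                          ints$target_id[sp$test] %in% sp$heldTargets))
      }
      expect_gt(length(sp$test), 0)
    }
  }
  sp1 <- suppressMessages(coldStartSplit(ints, "pair_cold", 0.25, 42))
  sp2 <- suppressMessages(coldStartSplit(ints, "pair_cold", 0.25, 42))
  expect_identical(sp1, sp2)
  expect_error(coldStartSplit(ints, "drug_cold", 1.2), "testFraction")
})

test_that("metrics match hand arithmetic on a fixed confusion matrix", {
  ## TP=3, FP=1, TN=3, FN=1
  scores <- c(.9, .8, .7, .6, .4, .3, .2, .1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0)
  m <- evaluatePredictions(scores, labels)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 3); expect_equal(m$fn, 1)
  expect_equal(m$mcc, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$bacc, 0.75)
  expect_equal(m$averaged_acc, m$bacc)

  perfect <- evaluatePredictions(c(.9, .8, .1), c(1, 1, 0))
  for (k in c("bacc", "precision", "recall", "f1", "mcc", "auroc",
              "auprc")) {
    expect_equal(perfect[[k]], 1, info = k)
  }
  expect_error(evaluatePredictions(numeric(), numeric()))
})

test_that("metric suite matches the brute-force oracle on random data", {
  set.seed(8)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)  # rounding induces ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    m <- evaluatePredictions(scores, labels)
    o <- oracleMetrics(scores, labels)
    for (k in names(o)) {
      expect_equal(m[[k]], o[[k]], tolerance = 1e-12, info = k)
    }
    expect_equal(m$bacc, (m$pos_accuracy + m$neg_accuracy) / 2)
  }
})

test_that("AUROC agrees with an established implementation and a permutation null", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:10) {
    scores <- runif(80)
    labels <- rbinom(80, 1, 0.4)
    if (length(unique(labels)) < 2) next
    m <- evaluatePredictions(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(m$auroc, ref, tolerance = 1e-10)
  }
  ## label-independent scores give AUROC ~ 0.5
  set.seed(10)
  nulls <- replicate(20, {
    evaluatePredictions(runif(400), rbinom(400, 1, 0.3))$auroc
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.05)
})

test_that("single-class inputs flag AUROC/AUPRC as skipped", {
  m <- evaluatePredictions(c(.2, .8, .6), c(1, 1, 1))
  expect_true(is.na(m$auroc))
  expect_true(is.na(m$auprc))
  expect_setequal(attr(m, "skipped"), c("auroc", "auprc"))
})

test_that("training on planted-pocket data beats the majority baseline quickly", {
  sim <- tinySim()
  feats <- tinyFeatures()
  ints <- interactions(sim$bundle)
  folds <- stratifiedKfold(ints$label, 4, seed = 2)
  cfg <- ModelConfig(hiddenDim = 16, gmtSeeds = 4, gmtHeads = 2)
  fit <- trainModel(feats, ints, folds[[1]]$train, folds[[1]]$test,
                    cfg, LossConfig(),
                    TrainConfig(lr = 2e-3, epochs = 5, patience = 5,
                                monitor = "bacc", seed = 3),
                    sim$drugSim, sim$targetSim)
  expect_gt(max(fit$history$val_bacc), 0.5)
  expect_equal(nrow(fit$history), 5)
  expect_s4_class(fit$model, "DTIModel")
})

test_that("training is deterministic for a fixed seed", {
  sim <- tinySim()
  feats <- tinyFeatures()
  ints <- interactions(sim$bundle)
  folds <- stratifiedKfold(ints$label, 4, seed = 2)
  cfg <- ModelConfig(hiddenDim = 16, gmtSeeds = 4, gmtHeads = 2)
  run <- function() {
    fit <- trainModel(feats, ints, folds[[1]]$train, folds[[1]]$test,
                      cfg, LossConfig(),
                      TrainConfig(lr = 2e-3, epochs = 3, patience = 3,
                                  seed = 5),
                      sim$drugSim, sim$targetSim)
    evaluateModel(fit$model, feats, ints[folds[[1]]$test, ])
  }
  m1 <- run(); m2 <- run()
  expect_equal(m1$bacc, m2$bacc, tolerance = 1e-6)
  expect_equal(attr(m1, "scores"), attr(m2, "scores"), tolerance = 1e-6)
})

test_that("MC-dropout variance is zero without dropout and non-negative always", {
  feats <- tinyFeatures()
  ints <- interactions(tinySim()$bundle)[1:25, ]
  cfg0 <- ModelConfig(hiddenDim = 16, gmtSeeds = 4, gmtHeads = 2,
                      dropoutRate = 0)
  m0 <- initModel(cfg0, feats$dDrug, feats$dRes, seed = 6)
  u0 <- mcDropoutUncertainty(m0, feats, ints, passes = 10, seed = 1)
  expect_equal(u0$variance, rep(0, nrow(ints)))

  cfg1 <- ModelConfig(hiddenDim = 16, gmtSeeds = 4, gmtHeads = 2,
                      dropoutRate = 0.2)
  m1 <- initModel(cfg1, feats$dDrug, feats$dRes, seed = 6)
  u1 <- mcDropoutUncertainty(m1, feats, ints, passes = 20, seed = 1)
  expect_true(all(u1$variance >= 0))
  expect_gt(max(u1$variance), 0)
  expect_error(mcDropoutUncertainty(m1, feats, ints, passes = 1), "passes")
})
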