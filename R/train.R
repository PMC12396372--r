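## Feature assembly, batched prediction and the training loop (Adam with
## weight decay, minibatches, early stopping on a validation monitor).

#' Assemble model-ready features for a bundle
#'
#' Materialises the drug feature matrix and per-target inputs once so
#' training and prediction never rebuild graphs. Drug features are
#' provider embeddings (or stored fingerprints under the
#' `fingerprint_drug` ablation); target inputs are residue-level
#' [ProteinGraph-class] objects (or sequence-level embedding vectors
#' under `no_structure`).
#'
#' @param bundle a [DTIBundle-class].
#' @param provider an [EmbeddingProvider-class].
#' @param config a [ModelConfig-class].
#' @return list with `drugX` (matrix, rownames = drug ids),
#'   `targetInputs` (named list), `dDrug`, `dRes`.
#' @export
prepareFeatures <- function(bundle, provider, config = ModelConfig()) {
  d <- bundle@drugs
  fpDrug <- "fingerprint_drug" %in% config@ablation
  drugRows <- lapply(seq_len(nrow(d)), function(i) {
    id <- d$drug_id[i]
    if (fpDrug) {
      fp <- bundle@fingerprints[[id]]
      if (is.null(fp))
        .dtiStop(sprintf("no fingerprint stored for drug '%s'", id))
      as.numeric(fp)
    } else {
      drugEmbed(provider, id, d$smiles[i], bundle@drugEmbeddings[[id]])
    }
  })
  drugX <- do.call(rbind, drugRows)
  rownames(drugX) <- d$drug_id

  t <- bundle@targets
  noStruct <- "no_structure" %in% config@ablation
  targetInputs <- setNames(lapply(seq_len(nrow(t)), function(i) {
    id <- t$target_id[i]
    if (noStruct) {
      sequenceLevelEmbed(provider, id, t$sequence[i],
                         bundle@residueEmbeddings[[id]])
    } else {
      buildProteinGraph(id, t$sequence[i], coords = bundle@coords[[id]],
                        provider = provider,
                        features = bundle@residueEmbeddings[[id]],
                        selfLoops = config@selfLoops)
    }
  }), t$target_id)
  list(drugX = drugX, targetInputs = targetInputs,
       dDrug = ncol(drugX), dRes = provider@dRes)
}

#' Predict interaction probabilities for drug-target pairs
#'
#' @param model a [DTIModel-class].
#' @param features feature set from [prepareFeatures()].
#' @param pairs data.frame with `drug_id`, `target_id`; defaults to all
#'   combinations is not supported - pass explicit pairs.
#' @param training run with dropout active (used by MC-dropout).
#' @return numeric vector of sigmoid probabilities, one per pair.
#' @export
predictPairs <- function(model, features, pairs, training = FALSE) {
  p <- model@params
  cfg <- model@config
  rate <- if (training) cfg@dropoutRate else 0
  uD <- unique(pairs$drug_id)
  uT <- unique(pairs$target_id)
  Xd <- features$drugX[uD, , drop = FALSE]
  Ed <- .forwardDrug(p, Xd, rate, training)$E
  Et <- do.call(rbind, lapply(uT, function(id)
    .forwardTarget(p, cfg, features$targetInputs[[id]], rate, training)$e))
  di <- match(pairs$drug_id, uD)
  ti <- match(pairs$target_id, uT)
  fw <- .forwardFusion(p, Ed[di, , drop = FALSE], Et[ti, , drop = FALSE])
  .sigmoid(fw$logit)
}

## Adam with (L2-coupled) weight decay over a named list of arrays.
.adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

.adamStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Sum two gradient lists (missing entries treated as zero).
.addGrads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

#' Train an interaction model
#'
#' Minibatch training with Adam (learning rate, weight decay, batch size
#' and epoch budget from `trainCfg`), the combined focal + contrastive
#' objective from `lossCfg`, and early stopping: after every epoch the
#' monitor is evaluated on the validation pairs and the best parameters
#' are kept; training stops after `patience` epochs without improvement.
#' Contrastive terms act on the unique drugs/targets of each batch, with
#' similarity submatrices taken from `drugSim`/`targetSim`.
#'
#' @param features feature set from [prepareFeatures()].
#' @param interactions data.frame with `drug_id`, `target_id`, `label`.
#' @param trainIdx,valIdx integer row indices into `interactions`.
#' @param modelCfg,lossCfg,trainCfg configuration objects.
#' @param drugSim,targetSim [SimilarityMatrix-class] objects covering all
#'   drugs/targets (ignored when `beta`/`gamma` are 0).
#' @param verbose print a line per epoch.
#' @return list with `model` (best checkpoint), `history` (one row per
#'   trained epoch), `bestEpoch`.
#' @export
trainModel <- function(features, interactions, trainIdx, valIdx,
                       modelCfg = ModelConfig(), lossCfg = LossConfig(),
                       trainCfg = TrainConfig(), drugSim = NULL,
                       targetSim = NULL, verbose = FALSE) {
  validObject(trainCfg); validObject(lossCfg)
  useDrugC <- lossCfg@beta != 0
  useTargC <- lossCfg@gamma != 0
  if (useDrugC && is.null(drugSim))
    .dtiStop("drugSim required when beta != 0")
  if (useTargC && is.null(targetSim))
    .dtiStop("targetSim required when gamma != 0")
  dS <- if (useDrugC) similarityValues(drugSim)
  tS <- if (useTargC) similarityValues(targetSim)

  model <- initModel(modelCfg, features$dDrug, features$dRes,
                     seed = trainCfg@seed)
  params <- model@params
  state <- .adamInit(params)
  cfg <- modelCfg
  rate <- cfg@dropoutRate

  train <- interactions[trainIdx, , drop = FALSE]
  val <- interactions[valIdx, , drop = FALSE]
  nTrain <- nrow(train)
  maximize <- trainCfg@monitor != "loss"
  best <- if (maximize) -Inf else Inf
  bestParams <- params
  bestEpoch <- 0L
  wait <- 0L
  history <- list()

  valLoss <- function(params) {
    m2 <- model; m2@params <- params
    scores <- predictPairs(m2, features, val, training = FALSE)
    logits <- qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
    focalLoss(logits, val$label, lossCfg@w, lossCfg@t)
  }

  .withSeed(trainCfg@seed + 1L, {
    for (epoch in seq_len(trainCfg@epochs)) {
      ord <- sample.int(nTrain)
      nBatches <- ceiling(nTrain / trainCfg@batchSize)
      epochComponents <- c(focal = 0, contrast_drug = 0, contrast_target = 0)
      for (bi in seq_len(nBatches)) {
        rows <- ord[((bi - 1) * trainCfg@batchSize + 1):
                      min(bi * trainCfg@batchSize, nTrain)]
        batch <- train[rows, , drop = FALSE]
        uD <- unique(batch$drug_id)
        uT <- unique(batch$target_id)
        di <- match(batch$drug_id, uD)
        ti <- match(batch$target_id, uT)

        fwD <- .forwardDrug(params, features$drugX[uD, , drop = FALSE],
                            rate, TRUE)
        fwT <- lapply(uT, function(id)
          .forwardTarget(params, cfg, features$targetInputs[[id]],
                         rate, TRUE))
        Et <- do.call(rbind, lapply(fwT, `[[`, "e"))
        fwF <- .forwardFusion(params, fwD$E[di, , drop = FALSE],
                              Et[ti, , drop = FALSE])

        fl <- focalLoss(fwF$logit, batch$label, lossCfg@w, lossCfg@t,
                        gradient = TRUE)
        if (!is.finite(fl$value))
          .dtiStop(sprintf(
            "non-finite loss at epoch %d batch %d (focal=%g)",
            epoch, bi, fl$value))
        dlogit <- lossCfg@alpha * fl$grad
        bwF <- .backwardFusion(params, fwF$cache, dlogit)
        grads <- bwF$grads
        ## pair-level embedding grads -> unique-entity grads
        dEd <- rowsum(bwF$dEd, di, reorder = TRUE)
        dEt <- rowsum(bwF$dEt, ti, reorder = TRUE)

        cd <- ct <- 0
        if (useDrugC && length(uD) >= 2) {
          nx <- ntxentGeneralized(fwD$E, positiveMask(dS[uD, uD],
                                                      lossCfg@thetaDrug),
                                  lossCfg@tau, lossCfg@includeSelf,
                                  gradient = TRUE)
          cd <- nx$value
          dEd <- dEd + lossCfg@beta * nx$grad
        }
        if (useTargC && length(uT) >= 2) {
          nx <- ntxentGeneralized(Et, positiveMask(tS[uT, uT],
                                                   lossCfg@thetaProt),
                                  lossCfg@tau, lossCfg@includeSelf,
                                  gradient = TRUE)
          ct <- nx$value
          dEt <- dEt + lossCfg@gamma * nx$grad
        }
        grads <- .addGrads(grads, .backwardDrug(params, fwD$cache, dEd))
        for (u in seq_along(uT)) {
          bt <- .backwardTarget(params, cfg, fwT[[u]]$cache,
                                dEt[u, , drop = FALSE])
          grads <- .addGrads(grads, bt$grads)
        }
        upd <- .adamStep(params, grads, state, trainCfg@lr,
                         trainCfg@weightDecay)
        params <- upd$params
        state <- upd$state
        epochComponents <- epochComponents +
          c(fl$value, cd, ct) * length(rows)
      }
      epochComponents <- epochComponents / nTrain

      ## validation monitor
      m2 <- model; m2@params <- params
      valScores <- predictPairs(m2, features, val, training = FALSE)
      metrics <- evaluatePredictions(valScores, val$label)
      current <- if (maximize) metrics[[trainCfg@monitor]] else
        valLoss(params)
      improved <- if (maximize) current > best else current < best
      if (improved) {
        best <- current
        bestParams <- params
        bestEpoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, focal = epochComponents[["focal"]],
        contrast_drug = epochComponents[["contrast_drug"]],
        contrast_target = epochComponents[["contrast_target"]],
        total = lossCfg@alpha * epochComponents[["focal"]] +
          lossCfg@beta * epochComponents[["contrast_drug"]] +
          lossCfg@gamma * epochComponents[["contrast_target"]],
        val_monitor = current, val_bacc = metrics$bacc,
        val_auroc = metrics$auroc)
      if (verbose)
        message(sprintf(
          "epoch %3d  loss %.4f  val %s %.4f  val BACC %.4f", epoch,
          history[[epoch]]$total, trainCfg@monitor, current, metrics$bacc))
      if (wait >= trainCfg@patience && trainCfg@patience > 0) break
    }
  })
  model@params <- bestParams
  list(model = model, history = do.call(rbind, history),
       bestEpoch = bestEpoch)
}

#' Evaluate a model on interaction pairs
#'
#' @param model a [DTIModel-class].
#' @param features feature set from [prepareFeatures()].
#' @param pairs data.frame with `drug_id`, `target_id`, `label`.
#' @param threshold hard-label cutoff, default 0.5.
#' @return metric list from [evaluatePredictions()] with the scores
#'   attached as attribute `scores`.
#' @export
evaluateModel <- function(model, features, pairs, threshold = 0.5) {
  scores <- predictPairs(model, features, pairs)
  out <- evaluatePredictions(scores, pairs$label, threshold)
  attr(out, "scores") <- scores
  out
}
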