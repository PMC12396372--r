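#' @import methods
#' @importFrom stats rnorm runif setNames var cor qlogis
#' @importFrom utils read.delim write.table head modifyList
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' Residue-level protein graph
#'
#' Holds the contact-map graph of one protein: per-residue node features
#' \eqn{H^{(0)}}, the raw binary symmetric contact adjacency (no self
#' edges), and the normalised adjacency consumed by the graph convolution.
#'
#' @slot targetId protein identifier.
#' @slot nodeFeatures numeric matrix, one row per residue.
#' @slot rawAdjacency binary symmetric matrix with zero diagonal; entry
#'   (i, j) is 1 iff the Calpha atoms of residues i and j are closer than
#'   the contact cutoff.
#' @slot normAdjacency normalised adjacency (see [normalizeAdjacency()]).
#' @export
setClass("ProteinGraph",
  representation(targetId = "character",
                 nodeFeatures = "matrix",
                 rawAdjacency = "matrix",
                 normAdjacency = "matrix"))

setValidity("ProteinGraph", function(object) {
  A <- object@rawAdjacency
  n <- nrow(object@nodeFeatures)
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "rawAdjacency must be square")
  if (nrow(A) != n)
    msgs <- c(msgs, "rawAdjacency dimension must match nodeFeatures rows")
  if (nrow(A) > 0) {
    if (any(A != t(A))) msgs <- c(msgs, "rawAdjacency must be symmetric")
    if (any(diag(A) != 0)) msgs <- c(msgs, "rawAdjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) msgs <- c(msgs, "rawAdjacency must be binary")
  }
  if (length(msgs)) msgs else TRUE
})

#' Pairwise similarity matrix over a set of entities
#'
#' @slot ids ordered entity identifiers labelling rows and columns.
#' @slot values symmetric numeric matrix with entries in \[0, 1\].
#' @slot kind one of `"tanimoto"`, `"tm_score"`, `"nw_sequence"`,
#'   `"precomputed"`.
#' @export
setClass("SimilarityMatrix",
  representation(ids = "character", values = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) != length(object@ids))
    msgs <- c(msgs, "ids length must match matrix dimension")
  if (!object@kind %in% c("tanimoto", "tm_score", "nw_sequence", "precomputed"))
    msgs <- c(msgs, "unknown kind")
  if (nrow(v) > 0) {
    if (max(abs(v - t(v))) > 1e-8) msgs <- c(msgs, "values must be symmetric")
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
      msgs <- c(msgs, "values must lie in [0, 1]")
    if (object@kind != "precomputed" && any(abs(diag(v) - 1) > 1e-8))
      msgs <- c(msgs, "diagonal must be 1 (self-similarity)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Drug/target/interaction dataset bundle
#'
#' The full input of one experiment: a drug table (identifier + SMILES), a
#' target table (identifier + sequence), the interaction records, and
#' optional per-entity payloads (Calpha coordinates, fingerprints,
#' precomputed embeddings) held in named lists keyed by entity id.
#'
#' @slot drugs data.frame with columns `drug_id`, `smiles`.
#' @slot targets data.frame with columns `target_id`, `sequence`.
#' @slot interactions data.frame with columns `drug_id`, `target_id`,
#'   `pkd` (may be NA), `label` (0/1).
#' @slot coords named list of n x 3 Calpha coordinate matrices (Angstrom).
#' @slot fingerprints named list of 0/1 vectors.
#' @slot drugEmbeddings named list of numeric vectors.
#' @slot residueEmbeddings named list of len x d matrices.
#' @export
setClass("DTIBundle",
  representation(drugs = "data.frame",
                 targets = "data.frame",
                 interactions = "data.frame",
                 coords = "list",
                 fingerprints = "list",
                 drugEmbeddings = "list",
                 residueEmbeddings = "list"))

setValidity("DTIBundle", function(object) {
  msgs <- character()
  d <- object@drugs; t <- object@targets; i <- object@interactions
  if (!all(c("drug_id", "smiles") %in% names(d)))
    msgs <- c(msgs, "drugs needs columns drug_id, smiles")
  if (!all(c("target_id", "sequence") %in% names(t)))
    msgs <- c(msgs, "targets needs columns target_id, sequence")
  if (!all(c("drug_id", "target_id", "label") %in% names(i)))
    msgs <- c(msgs, "interactions needs columns drug_id, target_id, label")
  if (anyDuplicated(d$drug_id)) msgs <- c(msgs, "duplicate drug_id")
  if (anyDuplicated(t$target_id)) msgs <- c(msgs, "duplicate target_id")
  if (nrow(i)) {
    if (!all(i$drug_id %in% d$drug_id))
      msgs <- c(msgs, "interaction references unknown drug_id")
    if (!all(i$target_id %in% t$target_id))
      msgs <- c(msgs, "interaction references unknown target_id")
    if (anyDuplicated(paste(i$drug_id, i$target_id, sep = "\r")))
      msgs <- c(msgs, "duplicate (drug_id, target_id) pair")
    if (!all(i$label %in% c(0, 1)))
      msgs <- c(msgs, "labels must be 0/1")
  }
  for (id in names(object@coords)) {
    co <- object@coords[[id]]
    seqlen <- nchar(t$sequence[match(id, t$target_id)])
    if (!is.na(seqlen) && nrow(co) != seqlen)
      msgs <- c(msgs, sprintf("coords rows != sequence length for '%s'", id))
  }
  for (id in names(object@residueEmbeddings)) {
    seqlen <- nchar(t$sequence[match(id, t$target_id)])
    if (!is.na(seqlen) && nrow(object@residueEmbeddings[[id]]) != seqlen)
      msgs <- c(msgs,
        sprintf("residueEmbeddings rows != sequence length for '%s'", id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Embedding provider
#'
#' Pluggable source of drug embeddings and per-residue protein features.
#' The shipped providers are [fixtureProvider()] (deterministic, hash
#' seeded, optionally with injected class signal for synthetic corpora) and
#' [sidecarProvider()] (precomputed vectors read from TSV sidecar files,
#' the adapter surface for externally computed language-model embeddings).
#'
#' @slot name provider label recorded in run metadata.
#' @slot dDrug drug embedding dimension.
#' @slot dRes per-residue feature dimension.
#' @slot deterministic whether repeated calls return identical output.
#' @slot drugFun function(drug_id, smiles) -> numeric(dDrug).
#' @slot residueFun function(target_id, sequence) -> matrix(len x dRes).
#' @export
setClass("EmbeddingProvider",
  representation(name = "character", dDrug = "integer", dRes = "integer",
                 deterministic = "logical", drugFun = "function",
                 residueFun = "function"))

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Model architecture configuration
#'
#' @slot gcnLayers number of residual graph-convolution layers (default 3).
#' @slot hiddenDim shared hidden width of both branches.
#' @slot gmtHeads attention heads in the multiset-transformer pooling.
#' @slot gmtSeeds learned seed vectors in the first pooling block.
#' @slot fusionDim output dimension of the bilinear fusion layer.
#' @slot dropoutRate dropout probability (also drives MC-dropout).
#' @slot ablation character vector; any of `"no_structure"`, `"no_gmt"`,
#'   `"fingerprint_drug"`.
#' @slot selfLoops add self-loops before adjacency normalisation.
#' @export
setClass("ModelConfig",
  representation(gcnLayers = "integer", hiddenDim = "integer",
                 gmtHeads = "integer", gmtSeeds = "integer",
                 fusionDim = "integer", dropoutRate = "numeric",
                 ablation = "character", selfLoops = "logical"),
  prototype(gcnLayers = 3L, hiddenDim = 32L, gmtHeads = 4L, gmtSeeds = 8L,
            fusionDim = 32L, dropoutRate = 0.1, ablation = character(),
            selfLoops = TRUE))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@gcnLayers < 0) msgs <- c(msgs, "gcnLayers must be >= 0")
  if (object@hiddenDim < 1) msgs <- c(msgs, "hiddenDim must be positive")
  if (object@hiddenDim %% object@gmtHeads != 0)
    msgs <- c(msgs, "hiddenDim must be divisible by gmtHeads")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msgs <- c(msgs, "dropoutRate must be in [0, 1)")
  bad <- setdiff(object@ablation,
                 c("no_structure", "no_gmt", "fingerprint_drug"))
  if (length(bad)) msgs <- c(msgs, paste("unknown ablation:", bad))
  if (length(msgs)) msgs else TRUE
})

#' Loss configuration
#'
#' Defaults follow the published training recipe: focal loss class weight
#' `w = 0.5` and focusing exponent `t = 2`; contrastive temperature
#' `tau = 0.07`; similarity thresholds `thetaDrug = 0.8`,
#' `thetaProt = 0.5`; loss mixture `alpha = 1`, `beta = gamma = 0.05`.
#'
#' @slot includeSelf keep the anchor's own term in the NT-Xent softmax
#'   denominator (the literal reading of the loss as printed); set FALSE
#'   for the conventional NT-Xent denominator that excludes the anchor.
#' @export
setClass("LossConfig",
  representation(w = "numeric", t = "numeric", tau = "numeric",
                 thetaDrug = "numeric", thetaProt = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 includeSelf = "logical"),
  prototype(w = 0.5, t = 2, tau = 0.07, thetaDrug = 0.8, thetaProt = 0.5,
            alpha = 1, beta = 0.05, gamma = 0.05, includeSelf = TRUE))

setValidity("LossConfig", function(object) {
  msgs <- character()
  if (object@w <= 0 || object@w >= 1) msgs <- c(msgs, "w must be in (0, 1)")
  if (object@t < 0) msgs <- c(msgs, "t must be >= 0")
  if (object@tau <= 0) msgs <- c(msgs, "tau must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Training configuration
#'
#' Defaults follow the published recipe: Adam, initial learning rate
#' 5e-5, weight decay 1e-4, 50 epochs, batch size 64, early stopping.
#'
#' @slot monitor validation quantity watched for early stopping; either
#'   `"loss"` (validation total loss, default) or a metric name from
#'   [evaluatePredictions()] such as `"bacc"`.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric", epochs = "integer",
                 batchSize = "integer", patience = "integer",
                 monitor = "character", seed = "integer"),
  prototype(lr = 5e-5, weightDecay = 1e-4, epochs = 50L, batchSize = 64L,
            patience = 10L, monitor = "loss", seed = 1L))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@lr <= 0) msgs <- c(msgs, "lr must be > 0")
  if (object@epochs < 1) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@patience > object@epochs)
    msgs <- c(msgs, "patience must be <= epochs")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic corpus configuration
#'
#' Defaults define the package's reference synthetic study: 150 drugs, 40
#' targets, ~2000 interaction pairs at a 3.76:1 negative:positive ratio
#' (mirroring the processed training corpus the method was developed on),
#' 5% label noise, 4 latent pocket/key classes and 10 drug families.
#'
#' @export
setClass("SimConfig",
  representation(nTargets = "integer", nDrugs = "integer", nPairs = "integer",
                 lengthRange = "integer", pocketRange = "integer",
                 nClasses = "integer", negPosRatio = "numeric",
                 labelNoise = "numeric", familyCount = "integer",
                 seed = "integer"),
  prototype(nTargets = 40L, nDrugs = 150L, nPairs = 2000L,
            lengthRange = c(60L, 120L), pocketRange = c(8L, 14L),
            nClasses = 4L, negPosRatio = 3.76, labelNoise = 0.05,
            familyCount = 10L, seed = 1L))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nClasses < 2) msgs <- c(msgs, "nClasses must be >= 2")
  if (object@labelNoise < 0 || object@labelNoise >= 0.5)
    msgs <- c(msgs, "labelNoise must be in [0, 0.5)")
  if (max(object@pocketRange) >= min(object@lengthRange))
    msgs <- c(msgs, "pocket size must be smaller than protein length")
  if (object@negPosRatio <= 0) msgs <- c(msgs, "negPosRatio must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Fitted/initialised interaction model
#'
#' @slot config the [ModelConfig-class] used to build the network.
#' @slot params named list of weight matrices/vectors.
#' @slot dims list with input dimensions `dDrug`, `dRes`.
#' @slot seed integer seed used for weight initialisation.
#' @export
setClass("DTIModel",
  representation(config = "ModelConfig", params = "list", dims = "list",
                 seed = "integer"))

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

.intify <- function(x) as.integer(round(x))

#' @rdname ModelConfig-class
#' @param gcnLayers,hiddenDim,gmtHeads,gmtSeeds,fusionDim,dropoutRate,ablation,selfLoops
#'   see the corresponding slots.
#' @export
ModelConfig <- function(gcnLayers = 3, hiddenDim = 32, gmtHeads = 4,
                        gmtSeeds = 8, fusionDim = hiddenDim,
                        dropoutRate = 0.1, ablation = character(),
                        selfLoops = TRUE) {
  new("ModelConfig", gcnLayers = .intify(gcnLayers),
      hiddenDim = .intify(hiddenDim), gmtHeads = .intify(gmtHeads),
      gmtSeeds = .intify(gmtSeeds), fusionDim = .intify(fusionDim),
      dropoutRate = dropoutRate, ablation = ablation, selfLoops = selfLoops)
}

#' @rdname LossConfig-class
#' @param w,t,tau,thetaDrug,thetaProt,alpha,beta,gamma,includeSelf see slots.
#' @export
LossConfig <- function(w = 0.5, t = 2, tau = 0.07, thetaDrug = 0.8,
                       thetaProt = 0.5, alpha = 1, beta = 0.05,
                       gamma = 0.05, includeSelf = TRUE) {
  new("LossConfig", w = w, t = t, tau = tau, thetaDrug = thetaDrug,
      thetaProt = thetaProt, alpha = alpha, beta = beta, gamma = gamma,
      includeSelf = includeSelf)
}

#' @rdname TrainConfig-class
#' @param lr,weightDecay,epochs,batchSize,patience,monitor,seed see slots.
#' @export
TrainConfig <- function(lr = 5e-5, weightDecay = 1e-4, epochs = 50,
                        batchSize = 64, patience = 10, monitor = "loss",
                        seed = 1) {
  patience <- min(.intify(patience), .intify(epochs))
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      epochs = .intify(epochs), batchSize = .intify(batchSize),
      patience = patience, monitor = monitor, seed = .intify(seed))
}

#' @rdname SimConfig-class
#' @param nTargets,nDrugs,nPairs,lengthRange,pocketRange,nClasses,negPosRatio,labelNoise,familyCount,seed
#'   see slots.
#' @export
SimConfig <- function(nTargets = 40, nDrugs = 150, nPairs = 2000,
                      lengthRange = c(60, 120), pocketRange = c(8, 14),
                      nClasses = 4, negPosRatio = 3.76, labelNoise = 0.05,
                      familyCount = 10, seed = 1) {
  new("SimConfig", nTargets = .intify(nTargets), nDrugs = .intify(nDrugs),
      nPairs = .intify(nPairs), lengthRange = .intify(lengthRange),
      pocketRange = .intify(pocketRange), nClasses = .intify(nClasses),
      negPosRatio = negPosRatio, labelNoise = labelNoise,
      familyCount = .intify(familyCount), seed = .intify(seed))
}

#' Assemble a dataset bundle
#'
#' @param drugs data.frame with columns `drug_id`, `smiles`.
#' @param targets data.frame with columns `target_id`, `sequence`.
#' @param interactions data.frame with columns `drug_id`, `target_id`,
#'   optionally `pkd`, and `label`.
#' @param coords,fingerprints,drugEmbeddings,residueEmbeddings optional
#'   named lists keyed by entity id.
#' @return a [DTIBundle-class].
#' @export
DTIBundle <- function(drugs, targets, interactions,
                      coords = list(), fingerprints = list(),
                      drugEmbeddings = list(), residueEmbeddings = list()) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (is.null(interactions$pkd)) interactions$pkd <- NA_real_
  new("DTIBundle", drugs = drugs, targets = targets,
      interactions = interactions, coords = coords,
      fingerprints = fingerprints, drugEmbeddings = drugEmbeddings,
      residueEmbeddings = residueEmbeddings)
}
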