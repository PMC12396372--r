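## Embedding providers: the pluggable source of drug vectors and
## per-residue protein features. The fixture provider is a deterministic,
## hash-seeded stand-in used for synthetic corpora and tests; the sidecar
## provider is the adapter for externally computed embeddings (molecular
## graph transformers, protein language models) supplied as TSV files.

#' Deterministic fixture embedding provider
#'
#' Every vector is derived from a 31-bit hash of the entity string (the
#' SMILES for drugs; `letter:position` for residues) mixed with `seed`,
#' mapped through R's normal generator, so the provider is fully
#' deterministic and stable across sessions. When `signal` is supplied
#' (usually the truth object of [simulateBundle()]), a class-indicator
#' block is added: drug vectors of latent class `c` get `+signalStrength`
#' at position `c`, and residue rows inside a target's planted pocket get
#' `+signalStrength` at the pocket-class position. This plants recoverable
#' structure for both the classifier and the residue attribution.
#'
#' @param dDrug drug embedding dimension (default 64; the full-scale
#'   preset is 2304).
#' @param dRes per-residue feature dimension (default 32; full-scale 1280).
#' @param seed integer seed mixed into every hash.
#' @param signal optional list with elements `drugClass` (named integer
#'   vector), `pockets` (named list of lists with `residues`, `class`).
#' @param signalStrength mean shift of the signal block (default 3, i.e.
#'   three noise standard deviations).
#' @return an [EmbeddingProvider-class].
#' @export
fixtureProvider <- function(dDrug = 64, dRes = 32, seed = 1,
                            signal = NULL, signalStrength = 3) {
  dDrug <- as.integer(dDrug); dRes <- as.integer(dRes)
  if (dDrug < 1 || dRes < 1) .dtiStop("dimensions must be positive")
  seed <- as.integer(seed)

  hashVec <- function(key, d) {
    .withSeed(.stringHash(key, seed), rnorm(d))
  }

  drugFun <- function(drugId, smiles) {
    if (is.null(smiles) || !nzchar(smiles))
      .dtiStop(sprintf("fixture provider needs a non-empty SMILES (drug '%s')",
                       drugId))
    v <- hashVec(paste0("drug|", smiles), dDrug)
    if (!is.null(signal) && drugId %in% names(signal$drugClass)) {
      cls <- signal$drugClass[[drugId]]
      v[cls] <- v[cls] + signalStrength
    }
    v
  }

  residueFun <- function(targetId, sequence) {
    if (is.null(sequence) || !nzchar(sequence))
      .dtiStop(sprintf("empty sequence for target '%s'", targetId))
    letters <- strsplit(sequence, "")[[1]]
    m <- t(vapply(seq_along(letters), function(i)
      hashVec(paste0("res|", letters[i], ":", i), dRes), numeric(dRes)))
    if (!is.null(signal) && targetId %in% names(signal$pockets)) {
      p <- signal$pockets[[targetId]]
      m[p$residues, p$class] <- m[p$residues, p$class] + signalStrength
    }
    m
  }

  new("EmbeddingProvider", name = "fixture", dDrug = dDrug, dRes = dRes,
      deterministic = TRUE, drugFun = drugFun, residueFun = residueFun)
}

#' Sidecar embedding provider
#'
#' Serves precomputed embeddings from TSV sidecar files (see
#' [readVectorSidecar()] / [readMatrixSidecar()]); the adapter surface for
#' full-scale pre-trained encoders, which are run outside this package.
#'
#' @param drugVectors named list of drug vectors, or a sidecar file path.
#' @param residueMatrices named list of residue matrices, or a file path.
#' @return an [EmbeddingProvider-class].
#' @export
sidecarProvider <- function(drugVectors, residueMatrices) {
  if (is.character(drugVectors)) drugVectors <- readVectorSidecar(drugVectors)
  if (is.character(residueMatrices))
    residueMatrices <- readMatrixSidecar(residueMatrices)
  dDrug <- length(drugVectors[[1]])
  dRes <- ncol(residueMatrices[[1]])
  drugFun <- function(drugId, smiles) {
    v <- drugVectors[[drugId]]
    if (is.null(v)) .dtiStop(sprintf("no sidecar embedding for drug '%s'",
                                     drugId))
    v
  }
  residueFun <- function(targetId, sequence) {
    m <- residueMatrices[[targetId]]
    if (is.null(m)) .dtiStop(sprintf("no sidecar embedding for target '%s'",
                                     targetId))
    if (nrow(m) != nchar(sequence))
      .dtiStop(sprintf("sidecar rows != sequence length for '%s'", targetId))
    m
  }
  new("EmbeddingProvider", name = "sidecar", dDrug = as.integer(dDrug),
      dRes = as.integer(dRes), deterministic = TRUE,
      drugFun = drugFun, residueFun = residueFun)
}

#' Drug embedding
#'
#' Returns the precomputed embedding verbatim when present; otherwise
#' queries the provider.
#'
#' @param provider an [EmbeddingProvider-class].
#' @param drugId drug identifier.
#' @param smiles SMILES string (required by the fixture provider).
#' @param embedding optional precomputed vector, returned unchanged.
#' @return numeric vector of length `provider@dDrug`.
#' @export
drugEmbed <- function(provider, drugId, smiles = NULL, embedding = NULL) {
  if (!is.null(embedding)) return(as.numeric(embedding))
  v <- provider@drugFun(drugId, smiles)
  if (any(!is.finite(v))) .dtiStop("non-finite drug embedding")
  v
}

#' Per-residue protein embedding
#'
#' @param provider an [EmbeddingProvider-class].
#' @param targetId protein identifier.
#' @param sequence amino-acid sequence.
#' @param precomputed optional len x d matrix, returned unchanged.
#' @return matrix with one row per residue.
#' @export
residueEmbed <- function(provider, targetId, sequence, precomputed = NULL) {
  if (!is.null(precomputed)) {
    m <- as.matrix(precomputed)
    if (nrow(m) != nchar(sequence))
      .dtiStop("precomputed embedding rows != sequence length")
    return(m)
  }
  if (is.null(sequence) || !nzchar(sequence))
    .dtiStop("sequence must be non-empty")
  m <- provider@residueFun(targetId, sequence)
  if (any(!is.finite(m))) .dtiStop("non-finite residue embedding")
  m
}

#' Sequence-level protein embedding
#'
#' Column-wise mean of the per-residue embedding; the protein
#' representation used by the structure-free (`no_structure`) model
#' variant.
#'
#' @inheritParams residueEmbed
#' @return numeric vector of length `provider@dRes`.
#' @export
sequenceLevelEmbed <- function(provider, targetId, sequence,
                               precomputed = NULL) {
  colMeans(residueEmbed(provider, targetId, sequence, precomputed))
}
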