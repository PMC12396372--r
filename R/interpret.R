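## Residue attribution: grad-CAM adapted to the graph setting. The
## gradient of the pre-sigmoid logit is taken at the output of the last
## graph-convolution layer H(L); channel weights are the node-averaged
## gradients (the graph analogue of spatial average pooling) and the
## per-residue score is the ReLU of the weighted channel sum.

#' Grad-CAM residue attribution for one drug-target pair
#'
#' @param model a trained [DTIModel-class]; must retain node activations
#'   (any configuration except `no_structure`).
#' @param drugFeatures numeric drug input vector (same features the model
#'   was trained on).
#' @param graph the target's [ProteinGraph-class].
#' @param drugId,targetId identifiers carried into the result.
#' @param pooled use node-averaged gradients as channel weights (default);
#'   `FALSE` keeps per-node gradients (no pooling variant).
#' @return list with `targetId`, `drugId`, `scores` (non-negative, one
#'   per residue), `normalized` (max-normalised copy), `rank` (residue
#'   indices by descending score, ties broken by ascending index),
#'   `logit`.
#' @export
gradcamResidues <- function(model, drugFeatures, graph, drugId = NA_character_,
                            targetId = graph@targetId, pooled = TRUE) {
  cfg <- model@config
  if ("no_structure" %in% cfg@ablation)
    .dtiStop("grad-CAM needs node activations; not available under the no_structure ablation")
  p <- model@params
  eD <- .forwardDrug(p, matrix(drugFeatures, nrow = 1), 0, FALSE)$E
  fwT <- .forwardTarget(p, cfg, graph, 0, FALSE)
  fwF <- .forwardFusion(p, eD, fwT$e)
  ## d logit / d e_t, then back to H(L)
  bwF <- .backwardFusion(p, fwF$cache, 1)
  bwT <- .backwardTarget(p, cfg, fwT$cache, bwF$dEt, needHL = TRUE)
  dHL <- bwT$dHL
  HL <- fwT$HL
  scores <- if (pooled) {
    alpha <- colMeans(dHL)
    pmax(as.numeric(HL %*% alpha), 0)
  } else {
    pmax(rowSums(HL * dHL), 0)
  }
  mx <- max(scores)
  list(targetId = targetId, drugId = drugId, scores = scores,
       normalized = if (mx > 0) scores / mx else scores,
       rank = order(-scores, seq_along(scores)),
       logit = fwF$logit)
}

#' Recall of annotated binding residues at matched proportion
#'
#' Selects the top-k residues by attribution score where k equals the
#' number of annotated binding-site residues (so the selected proportion
#' matches the annotated proportion), and returns the fraction of true
#' binding residues recovered. Ties are broken by ascending residue
#' index; the statistic is invariant to any strictly monotone transform
#' of the scores.
#'
#' @param scores per-residue attribution scores (or the list returned by
#'   [gradcamResidues()]).
#' @param siteResidues integer indices (1-based) of annotated binding
#'   residues; non-empty.
#' @return recall in \[0, 1\].
#' @export
pocketRecall <- function(scores, siteResidues) {
  if (is.list(scores)) scores <- scores$scores
  k <- length(siteResidues)
  if (k == 0) .dtiStop("empty binding-site annotation")
  if (k > length(scores)) .dtiStop("more site residues than residues")
  if (any(siteResidues < 1 | siteResidues > length(scores)))
    .dtiStop("site residue index out of range")
  top <- order(-scores, seq_along(scores))[seq_len(k)]
  length(intersect(top, siteResidues)) / k
}

#' Derive a binding-site annotation from a complex structure
#'
#' Annotates every residue whose Calpha atom lies within `cutoffA` of any
#' ligand atom. This is a geometric helper for synthetic/complex-derived
#' annotations; curated database annotations can be supplied directly to
#' [pocketRecall()].
#'
#' @param proteinCoords n x 3 Calpha coordinates.
#' @param ligandCoords m x 3 ligand atom coordinates, m >= 1.
#' @param cutoffA distance cutoff in Angstrom (default 5).
#' @return integer vector of 1-based residue indices (non-empty; an empty
#'   result is an error).
#' @export
annotateFromComplex <- function(proteinCoords, ligandCoords, cutoffA = 5) {
  proteinCoords <- as.matrix(proteinCoords)
  ligandCoords <- as.matrix(ligandCoords)
  if (nrow(ligandCoords) == 0) .dtiStop("empty ligand")
  if (nrow(proteinCoords) == 0) .dtiStop("empty protein")
  hits <- vapply(seq_len(nrow(proteinCoords)), function(i) {
    d2 <- rowSums(sweep(ligandCoords, 2, proteinCoords[i, ])^2)
    any(d2 < cutoffA^2)
  }, logical(1))
  res <- which(hits)
  if (length(res) == 0)
    .dtiStop(sprintf("no residue within %g Angstrom of the ligand", cutoffA))
  res
}

#' Write attribution scores into the B-factor column of a PDB file
#'
#' Produces a Calpha-only PDB whose B-factor column holds the
#' max-normalised attribution scores, for colouring in a structure
#' viewer.
#'
#' @param coords n x 3 Calpha coordinates.
#' @param sequence amino-acid sequence (length n).
#' @param scores attribution scores (length n).
#' @param path output PDB path.
#' @export
writeAttributionPdb <- function(coords, sequence, scores, path) {
  mx <- max(scores)
  b <- if (mx > 0) scores / mx else scores
  .writeCalphaPdb(coords, sequence, path, bfactor = b)
}
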