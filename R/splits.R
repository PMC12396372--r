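## Data-splitting protocols: stratified k-fold cross-validation and the
## cold-start splits (unseen drugs, unseen targets, unseen pairs).

#' Stratified k-fold cross-validation indices
#'
#' Folds partition the interaction indices; within each class the
#' (seed-shuffled) samples are dealt round-robin, so per-fold class counts
#' differ from `n_class / k` by at most one.
#'
#' @param labels 0/1 vector (or a data.frame with a `label` column).
#' @param k number of folds (>= 2).
#' @param seed RNG seed; identical seeds give identical folds.
#' @return list of `k` elements, each `list(train, test)` of indices.
#' @export
stratifiedKfold <- function(labels, k = 5, seed = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  if (k < 2) .dtiStop("k must be >= 2")
  if (n < k) .dtiStop("fewer samples than folds")
  if (length(unique(labels)) < 2)
    .dtiStop("both classes must be present for stratification")
  fold <- integer(n)
  .withSeed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Cold-start train/test split
#'
#' Modes: `drug_cold` holds out a fraction of drugs (test drugs never seen
#' in training; targets may overlap); `target_cold` is the analogue for
#' targets; `pair_cold` samples disjoint drug and target sets and keeps
#' only test pairs internal to both held-out sets, dropping pairs that
#' straddle the cut; `entity_holdout` holds out a fraction of drugs and
#' targets together with every pair involving them (nothing dropped).
#'
#' @param interactions data.frame with `drug_id`, `target_id`.
#' @param mode split mode (see above).
#' @param testFraction entity fraction held out, in (0, 1).
#' @param seed RNG seed.
#' @return list with integer index vectors `train`, `test`, `dropped`
#'   (the three partition the rows), the held-out entity sets
#'   `heldDrugs`/`heldTargets`, plus `mode` and `seed`.
#' @export
coldStartSplit <- function(interactions,
                           mode = c("drug_cold", "target_cold", "pair_cold",
                                    "entity_holdout"),
                           testFraction = 0.2, seed = 1) {
  mode <- match.arg(mode)
  if (testFraction <= 0 || testFraction >= 1)
    .dtiStop("testFraction must be in (0, 1)")
  di <- interactions$drug_id
  ti <- interactions$target_id
  allDrugs <- unique(di)
  allTargets <- unique(ti)
  pick <- function(ids) {
    nTest <- max(1L, round(length(ids) * testFraction))
    if (nTest >= length(ids)) .dtiStop("not enough distinct entities")
    ids[sample.int(length(ids), nTest)]
  }
  res <- .withSeed(seed, {
    switch(mode,
      drug_cold = {
        testDrugs <- pick(allDrugs)
        list(test = which(di %in% testDrugs),
             train = which(!di %in% testDrugs),
             dropped = integer(), heldDrugs = testDrugs,
             heldTargets = character())
      },
      target_cold = {
        testTargets <- pick(allTargets)
        list(test = which(ti %in% testTargets),
             train = which(!ti %in% testTargets),
             dropped = integer(), heldDrugs = character(),
             heldTargets = testTargets)
      },
      pair_cold = {
        testDrugs <- pick(allDrugs)
        testTargets <- pick(allTargets)
        inD <- di %in% testDrugs
        inT <- ti %in% testTargets
        list(test = which(inD & inT),
             train = which(!inD & !inT),
             dropped = which(xor(inD, inT)),
             heldDrugs = testDrugs, heldTargets = testTargets)
      },
      entity_holdout = {
        testDrugs <- pick(allDrugs)
        testTargets <- pick(allTargets)
        inEither <- di %in% testDrugs | ti %in% testTargets
        list(test = which(inEither),
             train = which(!inEither),
             dropped = integer(),
             heldDrugs = testDrugs, heldTargets = testTargets)
      })
  })
  if (length(res$dropped))
    message(sprintf("%d pair(s) straddling the cold-start cut dropped",
                    length(res$dropped)))
  c(res, list(mode = mode, seed = as.integer(seed)))
}
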