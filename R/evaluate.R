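## Classification metric suite. All metrics are computed from the
## (score, label) pairs directly; AUROC uses the midrank (Wilcoxon)
## statistic so ties are handled by average rank, and AUPRC is the
## average-precision step integral with a deterministic tie order
## (descending score, then ascending index).

#' Evaluate prediction scores against binary labels
#'
#' @param scores numeric scores (probabilities or any monotone score; the
#'   threshold is applied as given).
#' @param labels 0/1 vector.
#' @param threshold hard-label cutoff on `scores` (default 0.5).
#' @return named list: `bacc`, `precision`, `recall`, `f1`, `mcc`,
#'   `auroc`, `auprc`, `pos_accuracy`, `neg_accuracy`, `averaged_acc`
#'   (identical to `bacc`: the mean of positive and negative accuracy),
#'   plus the confusion counts `tp`, `fp`, `tn`, `fn`. With a single
#'   class present, `auroc`/`auprc` are `NA` and the `skipped` attribute
#'   names them.
#' @export
evaluatePredictions <- function(scores, labels, threshold = 0.5) {
  n <- length(scores)
  if (n == 0) .dtiStop("empty input")
  if (length(labels) != n) .dtiStop("scores and labels lengths differ")
  if (!all(labels %in% c(0, 1))) .dtiStop("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  nPos <- tp + fn
  nNeg <- tn + fp
  safe <- function(num, den) if (den == 0) 0 else num / den
  posAcc <- safe(tp, nPos)
  negAcc <- safe(tn, nNeg)
  precision <- safe(tp, tp + fp)
  recall <- posAcc
  f1 <- safe(2 * precision * recall, precision + recall)
  mccDen <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mccDen == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mccDen
  skipped <- character()
  if (nPos == 0 || nNeg == 0) {
    auroc <- auprc <- NA_real_
    skipped <- c("auroc", "auprc")
  } else {
    r <- rank(scores, ties.method = "average")
    auroc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    ord <- order(-scores, seq_along(scores))
    yo <- labels[ord]
    cumTp <- cumsum(yo)
    prec <- cumTp / seq_along(yo)
    auprc <- sum(prec[yo == 1]) / nPos  # average precision
  }
  out <- list(bacc = (posAcc + negAcc) / 2, precision = precision,
              recall = recall, f1 = f1, mcc = mcc, auroc = auroc,
              auprc = auprc, pos_accuracy = posAcc, neg_accuracy = negAcc,
              averaged_acc = (posAcc + negAcc) / 2,
              tp = tp, fp = fp, tn = tn, fn = fn)
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}

#' Monte Carlo dropout predictive uncertainty
#'
#' Runs `passes` stochastic forward passes with dropout active at
#' inference and returns the per-pair variance of the raw prediction
#' score (the sigmoid probability), the standard epistemic-uncertainty
#' estimate for dropout networks.
#'
#' @param model a [DTIModel-class] (must have `dropoutRate > 0` for
#'   non-degenerate uncertainty; rate 0 gives exactly zero variance).
#' @param features feature set from [prepareFeatures()].
#' @param pairs data.frame with `drug_id`, `target_id`.
#' @param passes number of stochastic passes (>= 2), default 50.
#' @param seed RNG seed for the dropout stream.
#' @return data.frame with `drug_id`, `target_id`, `mean_score`,
#'   `variance`.
#' @export
mcDropoutUncertainty <- function(model, features, pairs, passes = 50,
                                 seed = 1) {
  if (passes < 2) .dtiStop("passes must be >= 2")
  scores <- .withSeed(seed, {
    vapply(seq_len(passes), function(i)
      predictPairs(model, features, pairs, training = TRUE),
      numeric(nrow(pairs)))
  })
  scores <- matrix(scores, nrow = nrow(pairs))
  data.frame(drug_id = pairs$drug_id, target_id = pairs$target_id,
             mean_score = rowMeans(scores),
             variance = apply(scores, 1, var))
}
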