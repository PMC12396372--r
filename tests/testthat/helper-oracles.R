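## Independent oracle implementations used to cross-check the package:
## deliberately naive, loop-based, and written only from the definitions.

## Needleman-Wunsch global alignment score, textbook DP.
oracleNW <- function(s1, s2, match = 1, mismatch = 0, gap = 0) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -gap * (0:n)
  D[1, ] <- -gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (a[i] == b[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] - gap,
                             D[i + 1, j] - gap)
    }
  }
  D[n + 1, m + 1]
}

## Per-sample focal loss straight from the definition.
oracleFocal <- function(logits, labels, w = 0.5, t = 2) {
  p <- 1 / (1 + exp(-logits))
  mean(-(w * (1 - p)^t * labels * log(p) +
           (1 - w) * p^t * (1 - labels) * log(1 - p)))
}

## Generalized NT-Xent by explicit double loop.
oracleNtxent <- function(Z, M, tau, includeSelf = TRUE) {
  n <- nrow(Z)
  Zn <- Z / sqrt(rowSums(Z^2))
  L <- (Zn %*% t(Zn)) / tau
  total <- 0
  msum <- 0
  for (i in 1:n) {
    ks <- if (includeSelf) 1:n else setdiff(1:n, i)
    denom <- sum(exp(L[i, ks]))
    for (j in 1:n) {
      if (M[i, j] == 1) {
        total <- total + log(exp(L[i, j]) / denom)
        msum <- msum + 1
      }
    }
  }
  if (msum == 0) 0 else -total / msum
}

## Confusion-matrix metrics from first principles.
oracleMetrics <- function(scores, labels, thr = 0.5) {
  pred <- ifelse(scores >= thr, 1, 0)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (pred[i] == 1 && labels[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && labels[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && labels[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && labels[i] == 1) fn <- fn + 1
  }
  posAcc <- if (tp + fn > 0) tp / (tp + fn) else 0
  negAcc <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + posAcc > 0) 2 * prec * posAcc / (prec + posAcc) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  ## AUROC by explicit pair counting with half-credit ties
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  auroc <- NA_real_
  if (length(pos) > 0 && length(neg) > 0) {
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    auroc <- wins / (length(pos) * length(neg))
  }
  list(bacc = (posAcc + negAcc) / 2, precision = prec, recall = posAcc,
       f1 = f1, mcc = mcc, auroc = auroc,
       pos_accuracy = posAcc, neg_accuracy = negAcc)
}

## Dense re-implementation of the residual GCN stack.
oracleGcn <- function(H0, A, Win, bin, Wgs) {
  H <- H0 %*% Win
  H <- sweep(H, 2, bin, `+`)
  for (W in Wgs) {
    Z <- (A %*% H) %*% W
    H <- pmax(Z, 0) + H
  }
  H
}
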