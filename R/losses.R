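## The multi-task objective: focal loss on the interaction logits plus
## similarity-masked generalized NT-Xent contrastive losses on the drug
## and target embeddings, combined as
## total = alpha * focal + beta * contrast_drug + gamma * contrast_target.

.PCLAMP <- 1e-7  # probability floor away from {0, 1}

#' Focal loss for imbalanced binary classification
#'
#' Mean over samples of
#' `-[w (1-p)^t y log p + (1-w) p^t (1-y) log(1-p)]` with
#' `p = sigmoid(logit)`. `w` balances the classes and `t` down-weights
#' easy examples; `t = 0, w = 0.5` reduces to half the mean binary
#' cross-entropy. Probabilities are clamped to `[1e-7, 1 - 1e-7]` and the
#' logs go through log-sigmoid for numerical stability.
#'
#' @param logits numeric vector of raw scores.
#' @param labels 0/1 vector, same length.
#' @param w positive-class weight in (0, 1), default 0.5.
#' @param t focusing exponent >= 0, default 2.
#' @param gradient also return d(loss)/d(logit).
#' @return loss value; with `gradient = TRUE`, a list `(value, grad)`.
#' @export
focalLoss <- function(logits, labels, w = 0.5, t = 2, gradient = FALSE) {
  n <- length(logits)
  if (n == 0) .dtiStop("empty batch")
  if (length(labels) != n) .dtiStop("logits and labels lengths differ")
  if (!all(labels %in% c(0, 1))) .dtiStop("labels must be 0/1")
  p <- pmin(pmax(.sigmoid(logits), .PCLAMP), 1 - .PCLAMP)
  logp <- pmin(.logSigmoid(logits), log(1 - .PCLAMP))
  log1mp <- pmin(.logSigmoid(-logits), log(1 - .PCLAMP))
  y <- labels
  perSample <- -(w * (1 - p)^t * y * logp +
                 (1 - w) * p^t * (1 - y) * log1mp)
  value <- mean(perSample)
  if (!gradient) return(value)
  ## d/dx for y=1:  w t p (1-p)^t log p - w (1-p)^(t+1)
  ## d/dx for y=0:  -(1-w) t p^t (1-p) log(1-p) + (1-w) p^(t+1)
  gpos <- w * t * p * (1 - p)^t * logp - w * (1 - p)^(t + 1)
  gneg <- -(1 - w) * t * p^t * (1 - p) * log1mp + (1 - w) * p^(t + 1)
  grad <- (y * gpos + (1 - y) * gneg) / n
  list(value = value, grad = grad)
}

#' Positive-pair mask from a similarity matrix
#'
#' `M[i, j] = 1` iff `S[i, j] > theta` (strictly) and `i != j`.
#'
#' @param S square similarity matrix (values in \[0, 1\]) or a
#'   [SimilarityMatrix-class].
#' @param theta similarity threshold.
#' @return binary matrix with zero diagonal.
#' @export
positiveMask <- function(S, theta) {
  if (is(S, "SimilarityMatrix")) S <- S@values
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) .dtiStop("S must be square")
  M <- (S > theta) * 1
  diag(M) <- 0
  M
}

#' Generalized NT-Xent contrastive loss with a similarity mask
#'
#' Embedding rows are L2-normalised; `L[i, j] = cos(z_i, z_j) / tau`. The
#' loss is `-(1/sum(M)) * sum_ij M[i,j] * log(exp(L[i,j]) / sum_k
#' exp(L[i,k]))`. With `includeSelf = TRUE` (default, the literal reading
#' of the printed loss) the denominator runs over all k including k = i;
#' `FALSE` gives the conventional NT-Xent denominator without the anchor.
#' Returns 0 when the mask is empty.
#'
#' @param embeddings n x d matrix, n >= 2, no zero rows.
#' @param mask n x n binary positive-pair mask (see [positiveMask()]).
#' @param tau temperature > 0, default 0.07.
#' @param includeSelf keep the anchor term in the denominator.
#' @param gradient also return d(loss)/d(embeddings).
#' @return loss value; with `gradient = TRUE`, a list `(value, grad)`.
#' @export
ntxentGeneralized <- function(embeddings, mask, tau = 0.07,
                              includeSelf = TRUE, gradient = FALSE) {
  Z0 <- as.matrix(embeddings)
  n <- nrow(Z0)
  if (n < 2) .dtiStop("need at least two embeddings")
  M <- as.matrix(mask)
  diag(M) <- 0
  msum <- sum(M)
  if (msum == 0) {
    if (gradient) return(list(value = 0, grad = matrix(0, n, ncol(Z0))))
    return(0)
  }
  norms <- sqrt(rowSums(Z0^2))
  if (any(norms == 0)) .dtiStop("zero-norm embedding")
  Z <- Z0 / norms
  L <- (Z %*% t(Z)) / tau
  if (!includeSelf) diag(L) <- -Inf
  mx <- apply(L, 1, max)
  expL <- exp(L - mx)
  denom <- rowSums(expL)
  logP <- (L - mx) - log(denom)          # log softmax per row
  value <- -sum(logP[M == 1]) / msum     # masked mean (mask excludes diag)
  if (!gradient) return(value)
  P <- expL / denom
  if (!includeSelf) P[!is.finite(P)] <- 0
  r <- rowSums(M)
  G <- -(M - r * P) / msum               # d value / d L
  if (!includeSelf) diag(G) <- 0
  GC <- G / tau                          # d value / d cosine matrix
  dZ <- (GC + t(GC)) %*% Z
  ## back through row normalisation z = e / ||e||
  dE <- (dZ - Z * rowSums(dZ * Z)) / norms
  list(value = value, grad = dE)
}

#' Combined multi-task loss
#'
#' `total = alpha * focal + beta * contrast_drug + gamma * contrast_target`.
#' The contrastive terms operate on the batch's unique drugs and unique
#' targets (duplicate entities within a batch would create trivial
#' self-similar positives); the similarity matrices must be indexed to
#' match the embedding rows.
#'
#' @param logits,labels interaction logits and 0/1 labels (one per pair).
#' @param drugEmbeddings unique-drug embedding matrix for the batch.
#' @param drugS similarity matrix over the same drugs (matrix or
#'   [SimilarityMatrix-class]).
#' @param targetEmbeddings,targetS analogous for targets.
#' @param cfg a [LossConfig-class].
#' @return list with `total` and `components`
#'   (`focal`, `contrast_drug`, `contrast_target`).
#' @export
totalLoss <- function(logits, labels, drugEmbeddings, drugS,
                      targetEmbeddings, targetS, cfg = LossConfig()) {
  lf <- focalLoss(logits, labels, cfg@w, cfg@t)
  cd <- if (cfg@beta != 0 && nrow(drugEmbeddings) >= 2) {
    ntxentGeneralized(drugEmbeddings, positiveMask(drugS, cfg@thetaDrug),
                      cfg@tau, cfg@includeSelf)
  } else 0
  ct <- if (cfg@gamma != 0 && nrow(targetEmbeddings) >= 2) {
    ntxentGeneralized(targetEmbeddings, positiveMask(targetS, cfg@thetaProt),
                      cfg@tau, cfg@includeSelf)
  } else 0
  list(total = cfg@alpha * lf + cfg@beta * cd + cfg@gamma * ct,
       components = c(focal = lf, contrast_drug = cd, contrast_target = ct))
}
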