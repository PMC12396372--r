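## Structural and sequence similarities used to define contrastive
## positive pairs: Tanimoto on fingerprints, Needleman-Wunsch sequence
## similarity, and precomputed structural (TM-score) matrices.

#' Tanimoto similarity of two non-negative vectors
#'
#' `T(a, b) = (a . b) / (||a||^2 + ||b||^2 - a . b)`. On binary
#' fingerprints this equals the Jaccard index of the on-bit sets.
#'
#' @param a,b equal-length non-negative numeric vectors, not both zero.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) .dtiStop("vectors must have equal length")
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) .dtiStop("Tanimoto undefined for two all-zero vectors")
  ab / denom
}

## Light syntactic SMILES validation: the fingerprint backend (OpenBabel)
## silently repairs some malformed strings, so reject the obvious cases
## here to give a deterministic error contract.
.validateSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    .dtiStop("SMILES must be a non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9), "(", ")", "[", "]",
               "=", "#", "+", "-", "/", "\\", "@", "%", ".", ":", "*", "$")
  if (!all(chars %in% allowed))
    .dtiStop(sprintf("unparseable SMILES '%s': illegal character", smiles))
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    .dtiStop(sprintf("unparseable SMILES '%s': unbalanced parentheses",
                     smiles))
  bdepth <- cumsum((chars == "[") - (chars == "]"))
  if (any(bdepth < 0) || bdepth[length(bdepth)] != 0)
    .dtiStop(sprintf("unparseable SMILES '%s': unbalanced brackets", smiles))
  if (grepl("[=#(\\[]$", smiles))
    .dtiStop(sprintf("unparseable SMILES '%s': dangling bond/branch", smiles))
  invisible(TRUE)
}

#' Morgan (extended-connectivity) fingerprint of a SMILES string
#'
#' Computed with OpenBabel's ECFP implementation (`ECFP{2*radius}`,
#' radius 2 = ECFP4, the standard Morgan fingerprint). OpenBabel hashes
#' into 4096 bits natively; smaller `nBits` are obtained by folding
#' (OR-combining) the vector, the conventional fingerprint reduction.
#'
#' @param smiles SMILES string.
#' @param radius Morgan radius (default 2).
#' @param nBits fingerprint length, a divisor of 4096 (default 2048).
#' @return integer 0/1 vector of length `nBits`.
#' @export
morganFingerprint <- function(smiles, radius = 2, nBits = 2048) {
  .validateSmiles(smiles)
  if (4096 %% nBits != 0) .dtiStop("nBits must divide 4096")
  fpName <- paste0("ECFP", 2 * radius)
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  bits <- tryCatch(ChemmineOB::fingerprint_OB(mol, fpName),
                   error = function(e)
                     .dtiStop(sprintf("fingerprint failed for SMILES '%s': %s",
                                      smiles, conditionMessage(e))))
  bits <- as.integer(as.vector(bits))
  if (length(bits) == nBits) return(bits)
  folded <- matrix(bits, nrow = nBits)
  as.integer(rowSums(folded) > 0)
}

#' Needleman-Wunsch global sequence similarity
#'
#' Global alignment score under unit scoring (match = 1, mismatch = 0,
#' gap penalty = 0 by default), normalised by `match * min(len1, len2)`
#' so identical sequences score 1 and the drug/protein thresholds operate
#' on a \[0, 1\] scale. The alignment itself is delegated to
#' `Biostrings::pairwiseAlignment`.
#'
#' @param seq1,seq2 non-empty amino-acid strings.
#' @param match match score (> 0).
#' @param mismatch mismatch score.
#' @param gap non-negative gap penalty (applied per gapped position).
#' @return similarity in \[0, 1\] (scores are clipped into the range).
#' @export
nwSimilarity <- function(seq1, seq2, match = 1, mismatch = 0, gap = 0) {
  if (!nzchar(seq1) || !nzchar(seq2)) .dtiStop("sequences must be non-empty")
  if (match <= 0) .dtiStop("match score must be positive")
  letters <- unique(strsplit(paste0(toupper(seq1), toupper(seq2)), "")[[1]])
  sub <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- match
  score <- Biostrings::pairwiseAlignment(
    toupper(seq1), toupper(seq2), type = "global",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = abs(gap),
    scoreOnly = TRUE)
  norm <- score / (match * min(nchar(seq1), nchar(seq2)))
  min(1, max(0, norm))
}

#' Pairwise similarity matrix
#'
#' Computes the upper triangle with the scalar operation implied by
#' `kind` and mirrors it; the diagonal is set to 1 (self-similarity).
#'
#' @param items named list; 0/1 fingerprint (or non-negative) vectors for
#'   `kind = "tanimoto"`, sequences for `kind = "nw_sequence"`.
#' @param kind `"tanimoto"` or `"nw_sequence"`.
#' @param ... forwarded to [tanimoto()] / [nwSimilarity()].
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseMatrix <- function(items, kind = c("tanimoto", "nw_sequence"), ...) {
  kind <- match.arg(kind)
  if (length(items) < 1) .dtiStop("need at least one item")
  ids <- names(items)
  if (is.null(ids) || any(!nzchar(ids))) .dtiStop("items must be named")
  empty <- vapply(items, function(x) length(x) == 0 ||
                    (is.character(x) && !nzchar(x)), logical(1))
  if (any(empty))
    .dtiStop(paste("missing payload for:", paste(ids[empty], collapse = ", ")))
  n <- length(items)
  v <- diag(1, n)
  if (n > 1) {
    fun <- if (kind == "tanimoto") tanimoto else nwSimilarity
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v[i, j] <- v[j, i] <- fun(items[[i]], items[[j]], ...)
      }
    }
  }
  new("SimilarityMatrix", ids = ids, values = v, kind = kind)
}

#' Load a precomputed similarity matrix (e.g. TM-scores)
#'
#' Reads a square TSV with an id header row and id first column, reorders
#' it to `ids`, clips values into \[0, 1\] (with a warning when any value
#' falls outside), and symmetrises small (< 1e-6) asymmetries by
#' averaging.
#'
#' @param path TSV file.
#' @param ids entity ids the matrix must cover, in the required order.
#' @return a [SimilarityMatrix-class] of kind `"precomputed"`.
#' @export
loadPrecomputedMatrix <- function(path, ids) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rowIds <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rowIds
  missing <- setdiff(ids, intersect(rowIds, colnames(m)))
  if (length(missing))
    .dtiStop(paste("similarity matrix missing ids:",
                   paste(missing, collapse = ", ")))
  m <- m[ids, ids]
  asym <- max(abs(m - t(m)))
  if (asym > 0) {
    if (asym >= 1e-6)
      .dtiStop(sprintf("matrix is asymmetric (max |S - t(S)| = %g)", asym))
    warning("small asymmetry symmetrised by averaging")
    m <- (m + t(m)) / 2
  }
  if (min(m) < 0 || max(m) > 1) {
    warning("values outside [0, 1] clipped")
    m <- pmin(pmax(m, 0), 1)
  }
  dimnames(m) <- NULL
  new("SimilarityMatrix", ids = ids, values = m, kind = "precomputed")
}

#' @rdname loadPrecomputedMatrix
#' @param sim a [SimilarityMatrix-class].
#' @export
saveSimilarityMatrix <- function(sim, path) {
  df <- data.frame(id = sim@ids, sim@values, check.names = FALSE)
  colnames(df) <- c("id", sim@ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
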