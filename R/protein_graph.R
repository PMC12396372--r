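## Contact-map graph construction: residues are nodes; an edge joins two
## residues whose Calpha atoms are closer than the cutoff (strictly).

#' Binary Calpha contact map
#'
#' @param coords n x 3 matrix of Calpha coordinates (Angstrom).
#' @param cutoffA contact distance cutoff in Angstrom; an edge is present
#'   iff the pairwise distance is strictly below it (default 8).
#' @return n x n binary symmetric matrix with zero diagonal.
#' @export
contactMap <- function(coords, cutoffA = 8.0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 1)
    .dtiStop("coords must be an n x 3 matrix with n >= 1")
  if (any(!is.finite(coords))) .dtiStop("coords contain NaN/Inf")
  d <- as.matrix(stats::dist(coords))
  A <- (d < cutoffA) * 1
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' Normalised adjacency for graph convolution
#'
#' Default form is the symmetric normalisation with self-loops,
#' \eqn{\hat A = D^{-1/2}(A + I)D^{-1/2}} where \eqn{D} is the degree
#' matrix of \eqn{A + I}; an isolated node keeps a unit self-weight. The
#' row-stochastic alternative \eqn{D^{-1}(A + I)} is available via
#' `mode = "row"`, and `selfLoops = FALSE` normalises the raw adjacency
#' (isolated nodes then get all-zero rows).
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @param mode `"sym"` (default) or `"row"`.
#' @param selfLoops add the identity before normalising (default TRUE).
#' @return numeric matrix of the same dimension.
#' @export
normalizeAdjacency <- function(A, mode = c("sym", "row"), selfLoops = TRUE) {
  mode <- match.arg(mode)
  A <- as.matrix(A)
  if (selfLoops) A <- A + diag(nrow(A))
  deg <- rowSums(A)
  deg[deg == 0] <- 1  # guards all-zero rows when selfLoops = FALSE
  if (mode == "sym") {
    dInv <- 1 / sqrt(deg)
    A * outer(dInv, dInv)
  } else {
    A / deg
  }
}

#' Build a residue-level protein graph
#'
#' Combines Calpha coordinates (or a precomputed contact map) with
#' per-residue node features from an embedding provider or a precomputed
#' feature matrix.
#'
#' @param targetId protein identifier.
#' @param sequence amino-acid sequence (1-letter codes).
#' @param coords optional n x 3 Calpha coordinates.
#' @param contacts optional precomputed binary contact matrix (used when
#'   coordinates are unavailable).
#' @param provider optional [EmbeddingProvider-class] supplying node
#'   features.
#' @param features optional precomputed n x d node feature matrix
#'   (overrides `provider`).
#' @param cutoffA contact cutoff in Angstrom.
#' @param normMode,selfLoops forwarded to [normalizeAdjacency()].
#' @return a [ProteinGraph-class].
#' @export
buildProteinGraph <- function(targetId, sequence, coords = NULL,
                              contacts = NULL, provider = NULL,
                              features = NULL, cutoffA = 8.0,
                              normMode = "sym", selfLoops = TRUE) {
  n <- nchar(sequence)
  if (is.null(coords) && is.null(contacts))
    .dtiStop(paste0("no coordinates or precomputed contact map for '",
                    targetId, "'; use the no_structure ablation for ",
                    "sequence-only models"))
  A <- if (!is.null(coords)) {
    if (nrow(coords) != n)
      .dtiStop(sprintf("coords rows (%d) != sequence length (%d) for '%s'",
                       nrow(coords), n, targetId))
    contactMap(coords, cutoffA)
  } else {
    contacts <- as.matrix(contacts)
    if (nrow(contacts) != n)
      .dtiStop("precomputed contact map dimension != sequence length")
    m <- (contacts != 0) * 1
    m <- 1 * ((m + t(m)) > 0)  # symmetrise edge-list-derived maps
    diag(m) <- 0
    m
  }
  H0 <- if (!is.null(features)) {
    as.matrix(features)
  } else if (!is.null(provider)) {
    residueEmbed(provider, targetId, sequence)
  } else {
    .dtiStop("either a provider or a precomputed feature matrix is required")
  }
  if (nrow(H0) != n) .dtiStop("node feature rows != sequence length")
  new("ProteinGraph", targetId = targetId, nodeFeatures = H0,
      rawAdjacency = A,
      normAdjacency = normalizeAdjacency(A, normMode, selfLoops))
}

#' Read/write a contact map as a 0-based edge list TSV
#'
#' @param path TSV with integer columns `i`, `j` (0-based residue indices).
#' @param n number of residues.
#' @return binary symmetric matrix.
#' @export
readContactEdges <- function(path, n) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j") %in% names(df)))
  if (nrow(df) && (min(df$i, df$j) < 0 || max(df$i, df$j) >= n))
    .dtiStop("edge index out of range")
  A <- matrix(0, n, n)
  if (nrow(df)) {
    A[cbind(df$i + 1L, df$j + 1L)] <- 1
    A <- 1 * ((A + t(A)) > 0)
  }
  diag(A) <- 0
  A
}

#' @rdname readContactEdges
#' @param A binary symmetric contact matrix.
#' @export
writeContactEdges <- function(A, path) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
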