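## Readers/writers for the external formats and the dataset preprocessing
## steps (affinity binarization, target length filter).

#' Read a drug table
#'
#' Reads a TSV/CSV table with columns `drug_id` and `smiles`. Any column
#' named `embedding` is parsed as a comma-separated numeric vector.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return data.frame with columns `drug_id`, `smiles` and an
#'   `embedding` list attribute when present.
#' @export
readDrugTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("drug_id", "smiles") %in% names(df)))
    .dtiStop("drug table must have columns 'drug_id' and 'smiles'")
  dup <- df$drug_id[duplicated(df$drug_id)]
  if (length(dup))
    .dtiStop(sprintf("duplicate drug_id in %s: %s", path,
                     paste(unique(dup), collapse = ", ")))
  missing <- which(is.na(df$smiles) | !nzchar(df$smiles))
  if (length(missing))
    .dtiStop(sprintf("missing smiles at row(s): %s",
                     paste(missing, collapse = ", ")))
  out <- df[, c("drug_id", "smiles")]
  if ("embedding" %in% names(df)) {
    emb <- lapply(strsplit(df$embedding, ","), as.numeric)
    dims <- unique(vapply(emb, length, integer(1)))
    if (length(dims) > 1)
      .dtiStop("embeddings in one table must share a dimension")
    attr(out, "embedding") <- setNames(emb, df$drug_id)
  }
  out
}

#' Read protein sequences from FASTA
#'
#' The header token before the first whitespace is taken as `target_id`;
#' sequences are uppercased. Letters outside the 20 standard amino-acid
#' codes are preserved but reported via a message.
#'
#' @param path FASTA file.
#' @return data.frame with columns `target_id`, `sequence`, in file order.
#' @export
readFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) return(data.frame(target_id = character(),
                                         sequence = character()))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    .dtiStop(sprintf("empty sequence for: %s", paste(bad, collapse = ", ")))
  }
  nonstd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(nonstd))
    message("non-standard residue letters in: ",
            paste(ids[nonstd], collapse = ", "))
  data.frame(target_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Extract ordered Calpha coordinates from a PDB file
#'
#' Keeps the first model and first altloc of each residue; residues without
#' a CA atom are skipped with a warning. Residue numbers (with insertion
#' codes) are returned in the `resno` attribute, 1-based per PDB
#' convention.
#'
#' @param path PDB file.
#' @param chain chain identifier (default first chain in the file).
#' @return n x 3 numeric matrix of Calpha coordinates in Angstrom.
#' @export
readPdbCalpha <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain %in% chain & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0)
    .dtiStop(sprintf("chain '%s' not found in %s", chain, path))
  ## first altloc only
  atoms <- atoms[atoms$alt %in% c("", "A", NA), , drop = FALSE]
  key <- paste(atoms$resno, atoms$insert %||% "", sep = "_")
  resKeys <- unique(key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert %||% "", sep = "_")), ,
           drop = FALSE]
  caKeys <- paste(ca$resno, ca$insert %||% "", sep = "_")
  gaps <- setdiff(resKeys, caKeys)
  if (length(gaps))
    warning(sprintf("%d residue(s) without CA atom skipped in %s (resno %s)",
                    length(gaps), basename(path),
                    paste(sub("_$", "", gaps), collapse = ", ")))
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- NULL
  attr(m, "resno") <- ca$resno
  attr(m, "insert") <- ca$insert
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binarize a Kd affinity
#'
#' Converts a dissociation constant measured in nanomolar to pKd
#' (`pKd = 9 - log10(Kd_nM)`, i.e. -log10 of Kd in molar) and thresholds
#' it: a pair is labelled active when `pKd >= thresholdPkd` (inclusive;
#' Kd = 100 nM exactly is active under the default threshold 7).
#'
#' @param kdNM Kd in nM, positive; vectorised.
#' @param thresholdPkd pKd threshold, default 7.
#' @param inclusive label the exact boundary as active (default TRUE).
#' @return data.frame with columns `pkd` and `label`.
#' @export
binarizeAffinity <- function(kdNM, thresholdPkd = 7, inclusive = TRUE) {
  if (any(!is.finite(kdNM)) || any(kdNM <= 0))
    .dtiStop("Kd values must be positive and finite")
  pkd <- 9 - log10(kdNM)
  label <- if (inclusive) as.integer(pkd >= thresholdPkd)
           else as.integer(pkd > thresholdPkd)
  data.frame(pkd = pkd, label = label)
}

#' Drop over-length targets and their interactions
#'
#' Removes every target whose sequence is strictly longer than `maxLen`
#' together with all interactions that reference it (the published
#' preprocessing removes targets "longer than 1000"). Drugs orphaned by
#' the removal are kept and reported in the `orphanedDrugs` attribute.
#'
#' @param bundle a [DTIBundle-class].
#' @param maxLen maximum retained sequence length (default 1000).
#' @return filtered [DTIBundle-class] with attributes `removedTargets`
#'   and `orphanedDrugs`.
#' @export
filterByLength <- function(bundle, maxLen = 1000) {
  t <- bundle@targets
  keep <- nchar(t$sequence) <= maxLen
  removed <- t$target_id[!keep]
  t2 <- t[keep, , drop = FALSE]
  i2 <- bundle@interactions[
    bundle@interactions$target_id %in% t2$target_id, , drop = FALSE]
  rownames(t2) <- rownames(i2) <- NULL
  orphans <- setdiff(bundle@drugs$drug_id, i2$drug_id)
  out <- new("DTIBundle", drugs = bundle@drugs, targets = t2,
             interactions = i2,
             coords = bundle@coords[intersect(names(bundle@coords),
                                              t2$target_id)],
             fingerprints = bundle@fingerprints,
             drugEmbeddings = bundle@drugEmbeddings,
             residueEmbeddings = bundle@residueEmbeddings[
               intersect(names(bundle@residueEmbeddings), t2$target_id)])
  attr(out, "removedTargets") <- removed
  attr(out, "orphanedDrugs") <- orphans
  out
}

#' Read an interaction table
#'
#' TSV/CSV with columns `drug_id`, `target_id` and either `label` (0/1) or
#' `kd_nM` (binarized via [binarizeAffinity()]). Duplicate (drug, target)
#' pairs keep the first occurrence with a warning.
#'
#' @param path file path.
#' @param thresholdPkd threshold forwarded to [binarizeAffinity()].
#' @return data.frame with columns `drug_id`, `target_id`, `pkd`, `label`.
#' @export
readInteractionTable <- function(path, thresholdPkd = 7) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "target_id") %in% names(df)))
    .dtiStop("interaction table needs columns drug_id, target_id")
  if (!is.null(df$kd_nM) && is.null(df$label)) {
    b <- binarizeAffinity(df$kd_nM, thresholdPkd)
    df$pkd <- b$pkd
    df$label <- b$label
  }
  if (is.null(df$label))
    .dtiStop("interaction table needs a 'label' or 'kd_nM' column")
  if (is.null(df$pkd)) df$pkd <- NA_real_
  key <- paste(df$drug_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (drug, target) pair(s) dropped, first kept",
                    sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("drug_id", "target_id", "pkd", "label")]
}

#' Write predictions to TSV
#'
#' @param pairs data.frame with columns `drug_id`, `target_id`.
#' @param scores numeric scores in \[0, 1\], aligned with `pairs`.
#' @param labels predicted 0/1 labels, aligned; computed from `scores`
#'   at 0.5 when NULL.
#' @param path output file.
#' @export
writePredictions <- function(pairs, scores, labels = NULL, path) {
  if (nrow(pairs) != length(scores))
    .dtiStop("pairs and scores lengths differ")
  if (is.null(labels)) labels <- as.integer(scores >= 0.5)
  if (length(labels) != length(scores))
    .dtiStop("labels and scores lengths differ")
  out <- data.frame(drug_id = pairs$drug_id, target_id = pairs$target_id,
                    score = sprintf("%.6f", scores), predicted = labels)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write embedding sidecar files
#'
#' Sidecar layout: TSV with first column `id` and one numeric column per
#' dimension (for per-residue matrices, one row per `id:position` key in
#' the form `id\tpos\tv1..vd`).
#'
#' @param path TSV file.
#' @return named list of numeric vectors.
#' @export
readVectorSidecar <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) .dtiStop("duplicate ids in sidecar")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  setNames(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])), ids)
}

#' @rdname readVectorSidecar
#' @param vectors named list of equal-length numeric vectors.
#' @export
writeVectorSidecar <- function(vectors, path) {
  stopifnot(length(vectors) > 0)
  m <- do.call(rbind, vectors)
  df <- data.frame(id = names(vectors), m, check.names = FALSE)
  colnames(df) <- c("id", paste0("v", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue matrix sidecar
#'
#' TSV with columns `id`, `pos` (1-based) then one column per feature
#' dimension.
#'
#' @param path TSV file.
#' @return named list of matrices ordered by position.
#' @export
readMatrixSidecar <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("id", "pos") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("id", "pos")), drop = FALSE])
  storage.mode(vals) <- "double"
  out <- lapply(split(seq_len(nrow(df)), df$id), function(idx) {
    idx <- idx[order(df$pos[idx])]
    unname(vals[idx, , drop = FALSE])
  })
  out
}

#' @rdname readMatrixSidecar
#' @param matrices named list of numeric matrices (rows = residues).
#' @export
writeMatrixSidecar <- function(matrices, path) {
  stopifnot(length(matrices) > 0)
  rows <- lapply(names(matrices), function(id) {
    m <- matrices[[id]]
    data.frame(id = id, pos = seq_len(nrow(m)), m, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  colnames(df) <- c("id", "pos", paste0("v", seq_len(ncol(df) - 2)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
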