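## Self-contained synthetic corpora with planted, spatially clustered
## binding pockets and similarity-clustered drug families. The generator
## is a statistical stand-in, not molecular realism: chains are
## excluded-volume random walks at the Calpha step length, labels follow
## a latent drug-key/pocket-class match, and fingerprints carry family
## template bits plus class key bits.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

## Random-walk Calpha chain: fixed 3.8 A steps, >= 3.5 A between
## non-adjacent residues, rejection with a retry cap, full-chain restart
## (internal reseed) when the cap is hit.
.randomWalkChain <- function(n, seed, step = 3.8, minSep = 3.5,
                             maxRetry = 200, maxRestart = 50) {
  for (attempt in 0:maxRestart) {
    coords <- .withSeed(seed + attempt * 7919L, {
      co <- matrix(0, n, 3)
      ok <- TRUE
      for (i in seq_len(n)[-1]) {
        placed <- FALSE
        for (r in seq_len(maxRetry)) {
          u <- rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- co[i - 1, ] + step * u
          if (i <= 2) { placed <- TRUE }
          else {
            d2 <- rowSums(sweep(co[1:(i - 2), , drop = FALSE], 2, cand)^2)
            placed <- all(d2 >= minSep^2)
          }
          if (placed) { co[i, ] <- cand; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) co else NULL
    })
    if (!is.null(coords)) {
      if (attempt > 0)
        message(sprintf("chain generation restarted %d time(s)", attempt))
      return(coords)
    }
  }
  .dtiStop("excluded-volume rejection cap exceeded")
}

#' Simulate one protein with a planted, spatially clustered pocket
#'
#' The Calpha chain is a 3.8 Angstrom fixed-step random walk with
#' excluded volume (non-adjacent residues >= 3.5 Angstrom apart). The
#' pocket is seeded at the residue with the densest 3D neighbourhood and
#' grown to its `pocketSize - 1` spatially nearest residues, so pocket
#' residues are guaranteed to cluster in space. Pocket sequence letters
#' are drawn with class-biased composition (a per-class preferred letter
#' triplet with probability 0.8).
#'
#' @param length number of residues.
#' @param pocketSize number of pocket residues (< length).
#' @param classId latent pocket class (determines the biased letters).
#' @param seed RNG seed; same seed gives an identical protein.
#' @return list with `sequence`, `coords` (n x 3), `pocket` (integer
#'   residue indices), `classId`.
#' @export
simulateProtein <- function(length, pocketSize, classId, seed = 1) {
  if (pocketSize >= length) .dtiStop("pocketSize must be < length")
  coords <- .randomWalkChain(length, seed)
  d <- as.matrix(stats::dist(coords))
  density <- rowSums(d < 8)
  centre <- which.max(density)
  pocket <- sort(order(d[centre, ])[seq_len(pocketSize)])
  prefStart <- ((classId - 1) * 3) %% 20 + 1
  pref <- .AA20[((prefStart - 1) + 0:2) %% 20 + 1]
  sequence <- .withSeed(seed + 1L, {
    letters <- sample(.AA20, length, replace = TRUE)
    usePref <- runif(pocketSize) < 0.8
    letters[pocket[usePref]] <- sample(pref, sum(usePref), replace = TRUE)
    paste(letters, collapse = "")
  })
  list(sequence = sequence, coords = coords, pocket = pocket,
       classId = as.integer(classId))
}

#' Simulate one drug with a family/class-structured fingerprint
#'
#' The fingerprint has a 256-bit family region (a family template kept
#' per-bit with probability 0.97 plus two random extra bits, so
#' within-family Tanimoto concentrates above 0.8 and cross-family below
#' 0.5) and an 8-bit-per-class key region encoding the latent key class.
#' A trivial valid SMILES placeholder is attached (fingerprints are the
#' primary drug payload of the generator).
#'
#' @param classId latent key class.
#' @param familyId drug family (drives the template bits).
#' @param seed RNG seed.
#' @param nClasses number of latent classes (sizes the key region).
#' @return list with `smiles`, `fingerprint` (0/1 vector), `classId`,
#'   `familyId`.
#' @export
simulateDrug <- function(classId, familyId, seed = 1, nClasses = 4) {
  famBits <- 256L
  keyBits <- 8L
  template <- .withSeed(.stringHash(paste0("family", familyId), 900001L), {
    sample.int(famBits, 64L)
  })
  fp <- .withSeed(seed, {
    v <- integer(famBits + keyBits * nClasses)
    keep <- template[runif(length(template)) < 0.97]
    v[keep] <- 1L
    extra <- sample.int(famBits, 2L)
    v[extra] <- 1L
    v
  })
  kIdx <- famBits + (classId - 1L) * keyBits + seq_len(keyBits)
  fp[kIdx] <- 1L
  nC <- max(3L, (seed %% 17L) + 3L)
  smiles <- paste0("C", strrep("C", nC), "O")
  list(smiles = smiles, fingerprint = fp, classId = as.integer(classId),
       familyId = as.integer(familyId))
}

#' Simulate a full synthetic interaction corpus
#'
#' Drugs carry a latent key class (shared within a family) and targets a
#' latent pocket class; the noiseless label of a pair is 1 iff the
#' classes match. Pairs are subsampled to the configured
#' negative:positive ratio (within 5%), every drug and target appears in
#' at least two pairs (so cold-start splits are feasible), and each label
#' is flipped independently with probability `labelNoise`. A surrogate
#' structural similarity matrix is emitted for targets (same-class pairs
#' high, cross-class low, plus noise) alongside the Tanimoto matrix of
#' the drug fingerprints.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `bundle` ([DTIBundle-class]), `truth` (list:
#'   `drugClass`, `drugFamily`, `pockets`, `noiselessLabel`), `drugSim`,
#'   `targetSim` ([SimilarityMatrix-class]).
#' @export
simulateBundle <- function(cfg = SimConfig()) {
  validObject(cfg)
  nD <- cfg@nDrugs; nT <- cfg@nTargets; nC <- cfg@nClasses
  drugIds <- sprintf("D%04d", seq_len(nD))
  targetIds <- sprintf("T%03d", seq_len(nT))

  famOf <- ((seq_len(nD) - 1L) %% cfg@familyCount) + 1L
  drugClass <- ((famOf - 1L) %% nC) + 1L
  targetClass <- ((seq_len(nT) - 1L) %% nC) + 1L

  drugsL <- lapply(seq_len(nD), function(i)
    simulateDrug(drugClass[i], famOf[i], seed = cfg@seed * 131L + i,
                 nClasses = nC))
  protL <- .withSeed(cfg@seed, {
    lens <- sample(cfg@lengthRange[1]:cfg@lengthRange[2], nT, replace = TRUE)
    pks <- sample(cfg@pocketRange[1]:cfg@pocketRange[2], nT, replace = TRUE)
    lapply(seq_len(nT), function(i)
      simulateProtein(lens[i], pks[i], targetClass[i],
                      seed = cfg@seed * 977L + i))
  })

  drugs <- data.frame(drug_id = drugIds,
                      smiles = vapply(drugsL, `[[`, character(1), "smiles"))
  targets <- data.frame(
    target_id = targetIds,
    sequence = vapply(protL, `[[`, character(1), "sequence"))
  fingerprints <- setNames(lapply(drugsL, `[[`, "fingerprint"), drugIds)
  coords <- setNames(lapply(protL, `[[`, "coords"), targetIds)

  ## pair sampling at the configured ratio with >= 2 pairs per entity
  noiseless <- outer(drugClass, targetClass, `==`) * 1L
  nPos <- max(1L, round(cfg@nPairs / (1 + cfg@negPosRatio)))
  nNeg <- cfg@nPairs - nPos
  posPool <- which(noiseless == 1L)
  negPool <- which(noiseless == 0L)
  if (nPos > length(posPool) || nNeg > length(negPool))
    .dtiStop(sprintf(
      "infeasible ratio: only %d positive / %d negative pairs available",
      length(posPool), length(negPool)))
  interactions <- .withSeed(cfg@seed + 13L, {
    chosen <- c(sample(posPool, nPos), sample(negPool, nNeg))
    dIdx <- ((chosen - 1L) %% nD) + 1L
    tIdx <- ((chosen - 1L) %/% nD) + 1L
    ## coverage fix-up: swap in pairs of under-covered entities for pairs
    ## of the same label whose entities have surplus coverage
    for (pass in 1:3) {
      cover <- c(table(factor(dIdx, levels = seq_len(nD))),
                 table(factor(tIdx, levels = seq_len(nT))))
      dShort <- which(tabulate(dIdx, nD) < 2L)
      tShort <- which(tabulate(tIdx, nT) < 2L)
      if (!length(dShort) && !length(tShort)) break
      for (d in dShort) {
        cand <- setdiff(which(((seq_along(noiseless) - 1L) %% nD) + 1L == d),
                        chosen)
        need <- 2L - sum(dIdx == d)
        if (need <= 0 || !length(cand)) next
        add <- cand[seq_len(min(need, length(cand)))]
        for (a in add) {
          lab <- noiseless[a]
          surplus <- which(noiseless[chosen] == lab &
                             tabulate(dIdx, nD)[dIdx] > 2L &
                             tabulate(tIdx, nT)[tIdx] > 2L)
          if (!length(surplus)) next
          drop <- surplus[1]
          chosen[drop] <- a
          dIdx <- ((chosen - 1L) %% nD) + 1L
          tIdx <- ((chosen - 1L) %/% nD) + 1L
        }
      }
      for (t in tShort) {
        cand <- setdiff(
          which(((seq_along(noiseless) - 1L) %/% nD) + 1L == t), chosen)
        need <- 2L - sum(tIdx == t)
        if (need <= 0 || !length(cand)) next
        add <- cand[seq_len(min(need, length(cand)))]
        for (a in add) {
          lab <- noiseless[a]
          surplus <- which(noiseless[chosen] == lab &
                             tabulate(dIdx, nD)[dIdx] > 2L &
                             tabulate(tIdx, nT)[tIdx] > 2L)
          if (!length(surplus)) next
          drop <- surplus[1]
          chosen[drop] <- a
          dIdx <- ((chosen - 1L) %% nD) + 1L
          tIdx <- ((chosen - 1L) %/% nD) + 1L
        }
      }
    }
    lab0 <- noiseless[chosen]
    flip <- runif(length(chosen)) < cfg@labelNoise
    data.frame(drug_id = drugIds[dIdx], target_id = targetIds[tIdx],
               pkd = NA_real_,
               label = ifelse(flip, 1L - lab0, lab0),
               noiseless = lab0)
  })
  interactions <- interactions[order(interactions$drug_id,
                                     interactions$target_id), ]
  rownames(interactions) <- NULL

  bundle <- DTIBundle(drugs, targets,
                      interactions[, c("drug_id", "target_id", "pkd",
                                       "label")],
                      coords = coords, fingerprints = fingerprints)

  truth <- list(
    drugClass = setNames(drugClass, drugIds),
    drugFamily = setNames(famOf, drugIds),
    pockets = setNames(lapply(protL, function(p)
      list(residues = p$pocket, class = p$classId)), targetIds),
    noiselessLabel = interactions[, c("drug_id", "target_id", "noiseless")])

  drugSim <- pairwiseMatrix(fingerprints, "tanimoto")
  tv <- .withSeed(cfg@seed + 29L, {
    base <- ifelse(outer(targetClass, targetClass, `==`), 0.75, 0.25)
    noise <- matrix(runif(nT * nT, -0.1, 0.1), nT, nT)
    noise <- (noise + t(noise)) / 2
    v <- pmin(pmax(base + noise, 0), 1)
    diag(v) <- 1
    v
  })
  targetSim <- new("SimilarityMatrix", ids = targetIds, values = tv,
                   kind = "precomputed")
  list(bundle = bundle, truth = truth, drugSim = drugSim,
       targetSim = targetSim)
}

## Calpha-only PDB writer shared with the attribution module.
.writeCalphaPdb <- function(coords, sequence, path, bfactor = NULL) {
  letters <- strsplit(sequence, "")[[1]]
  if (is.null(bfactor)) bfactor <- numeric(length(letters))
  lines <- vapply(seq_along(letters), function(i) {
    resn <- .AA3[[letters[i]]] %||% "UNK"
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
            i, resn, i, coords[i, 1], coords[i, 2], coords[i, 3],
            bfactor[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export a simulated corpus to standard on-disk formats
#'
#' Writes `drugs.tsv`, `targets.fasta`, one Calpha-only PDB per target
#' under `pdb/`, `interactions.tsv`, `fingerprints.tsv` (sidecar),
#' `drug_similarity.tsv`, `target_similarity.tsv` and `truth.json` - all
#' readable by the package's own readers.
#'
#' @param sim result of [simulateBundle()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
exportBundle <- function(sim, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    .dtiStop(sprintf("cannot write to '%s'", dir))
  b <- sim$bundle
  write.table(b@drugs, file.path(dir, "drugs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(setNames(b@targets$sequence,
                                           b@targets$target_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "targets.fasta"))
  pdbDir <- file.path(dir, "pdb")
  dir.create(pdbDir, showWarnings = FALSE)
  for (id in b@targets$target_id) {
    i <- match(id, b@targets$target_id)
    .writeCalphaPdb(b@coords[[id]], b@targets$sequence[i],
                    file.path(pdbDir, paste0(id, ".pdb")))
  }
  write.table(b@interactions, file.path(dir, "interactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeVectorSidecar(b@fingerprints, file.path(dir, "fingerprints.tsv"))
  saveSimilarityMatrix(sim$drugSim, file.path(dir, "drug_similarity.tsv"))
  saveSimilarityMatrix(sim$targetSim,
                       file.path(dir, "target_similarity.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(drugClass = as.list(truth$drugClass),
         drugFamily = as.list(truth$drugFamily),
         pockets = truth$pockets,
         noiselessLabel = truth$noiselessLabel),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a corpus directory written by [exportBundle()]
#'
#' @param dir directory path.
#' @return list with `bundle`, `truth`, `drugSim`, `targetSim` (the same
#'   shape as [simulateBundle()] output).
#' @export
readBundleDir <- function(dir) {
  drugs <- readDrugTable(file.path(dir, "drugs.tsv"))
  targets <- readFasta(file.path(dir, "targets.fasta"))
  interactions <- readInteractionTable(file.path(dir, "interactions.tsv"))
  coords <- setNames(lapply(targets$target_id, function(id) {
    m <- readPdbCalpha(file.path(dir, "pdb", paste0(id, ".pdb")))
    attr(m, "resno") <- NULL
    attr(m, "insert") <- NULL
    dimnames(m) <- NULL
    m
  }), targets$target_id)
  fps <- readVectorSidecar(file.path(dir, "fingerprints.tsv"))
  fps <- lapply(fps, as.integer)
  bundle <- DTIBundle(drugs, targets, interactions, coords = coords,
                      fingerprints = fps)
  drugSim <- loadPrecomputedMatrix(file.path(dir, "drug_similarity.tsv"),
                                   drugs$drug_id)
  targetSim <- loadPrecomputedMatrix(file.path(dir, "target_similarity.tsv"),
                                     targets$target_id)
  truthJ <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  truth <- list(
    drugClass = unlist(truthJ$drugClass),
    drugFamily = unlist(truthJ$drugFamily),
    pockets = lapply(truthJ$pockets, function(p)
      list(residues = as.integer(p$residues), class = as.integer(p$class))),
    noiselessLabel = truthJ$noiselessLabel)
  list(bundle = bundle, truth = truth, drugSim = drugSim,
       targetSim = targetSim)
}
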