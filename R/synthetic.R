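# Synthetic ALP proteome generator. Domain content is sampled from a
# polar background (so that planted anchors are the only hydrophobic
# stretches and anchor recovery is well-posed) and architectures are
# drawn from class-conditional grammars that invert the classification
# rules, guaranteeing that the generated label is what the classifier
# must recover.

# Polar background composition for linkers, decoys and (before Asn/Thr
# boosting) domain bodies. Long-chain hydrophobic residues are absent by
# design.
.POLAR_BG <- c(S = 0.14, T = 0.12, N = 0.12, G = 0.10, A = 0.08,
               D = 0.08, E = 0.08, K = 0.08, Q = 0.07, P = 0.05,
               H = 0.03, Y = 0.02, R = 0.03)

.TM_RESIDUES <- c(L = 0.40, I = 0.25, V = 0.20, F = 0.15)
.SHORT_RESIDUES <- c(L = 0.40, I = 0.30, F = 0.30)

# 0-based helical-wheel positions (100 deg/residue) whose unit vectors
# point into the hydrophobic face of an 18-mer (cos(k*100) > 0.3).
.AMPH_FACE <- c(0L, 3L, 4L, 7L, 11L, 14L, 15L)

#' Background residue frequencies of the synthetic generator
#'
#' The polar composition from which linkers and decoy sequences are
#' drawn, and which domain sequences modify (Asn/Thr boost, planted
#' glycines). Useful as the `background` argument of
#' [compositionProfile()] when measuring the planted enrichment.
#'
#' @return named frequency vector summing to 1.
#' @export
backgroundFrequencies <- function() .POLAR_BG

# Background with N and T multiplied by `boost` and the remaining
# residues scaled down proportionally.
boostedComposition <- function(boost, nFreq = NULL) {
  comp <- .POLAR_BG
  if (!is.null(nFreq)) {
    comp["N"] <- nFreq
    comp[names(comp) != "N"] <-
      comp[names(comp) != "N"] * (1 - nFreq) / sum(comp[names(comp) != "N"])
    return(comp)
  }
  ntMass <- comp["N"] + comp["T"]
  if (boost * ntMass >= 1)
    stop("asnThrBoost too large for the background composition",
         call. = FALSE)
  comp["N"] <- comp["N"] * boost
  comp["T"] <- comp["T"] * boost
  others <- setdiff(names(comp), c("N", "T"))
  comp[others] <- comp[others] * (1 - boost * ntMass) / (1 - ntMass)
  comp
}

#' Construct a synthetic proteome specification
#'
#' See [SyntheticSpec-class] for the meaning and provenance of the
#' defaults; they describe a 105-sequence candidate set containing 14
#' domain-free decoys and 91 ALPs split across the architecture groups
#' at their published frequencies.
#'
#' @param nProteins number of sequences.
#' @param groupWeights named sampling weights (IA, IB, IIA, IIB, III,
#'   OTHERS).
#' @param decoyWeight weight for domain-free decoys.
#' @param rbhRepeatRange,abdRepeatRange tandem repeat count ranges.
#' @param abdLenRange,rbhLenRange,tmLenRange residue-length ranges.
#' @param asnThrBoost Asn/Thr enrichment multiplier (>= 1).
#' @param dualMadProb probability of anchors at both termini.
#' @param madProb probability that a non-decoy protein is anchored.
#' @param anchorKindProbs named probabilities for `TM`,
#'   `SHORT_HYDROPHOBIC`, `AMPHIPATHIC` anchors.
#' @param seed integer seed.
#' @return a validated [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(nProteins = 105L,
                          groupWeights = (91 / 105) *
                            c(IA = 40, IB = 12, IIA = 13, IIB = 5,
                              III = 4, OTHERS = 13) / 87,
                          decoyWeight = 14 / 105,
                          rbhRepeatRange = c(1L, 7L),
                          abdRepeatRange = c(1L, 27L),
                          abdLenRange = c(80L, 120L),
                          rbhLenRange = c(250L, 1236L),
                          tmLenRange = c(20L, 28L),
                          asnThrBoost = 2,
                          dualMadProb = 11 / 91,
                          madProb = 86 / 91,
                          anchorKindProbs = c(TM = 0.80,
                                              SHORT_HYDROPHOBIC = 0.12,
                                              AMPHIPATHIC = 0.08),
                          seed = 1L) {
  new("SyntheticSpec",
      nProteins = as.integer(nProteins),
      groupWeights = groupWeights,
      decoyWeight = decoyWeight,
      rbhRepeatRange = as.integer(rbhRepeatRange),
      abdRepeatRange = as.integer(abdRepeatRange),
      abdLenRange = as.integer(abdLenRange),
      rbhLenRange = as.integer(rbhLenRange),
      tmLenRange = as.integer(tmLenRange),
      asnThrBoost = asnThrBoost,
      dualMadProb = dualMadProb,
      madProb = madProb,
      anchorKindProbs = anchorKindProbs,
      seed = as.integer(seed))
}

sampleRange <- function(rg) {
  if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1L)
}

# RBH lengths span nearly an order of magnitude but long rods are rare;
# log-uniform sampling keeps most domains near the short end.
sampleRbhLen <- function(rg) {
  as.integer(round(exp(stats::runif(1, log(rg[1]), log(rg[2])))))
}

makeAbd <- function(len, boost) {
  comp <- boostedComposition(boost)
  res <- sampleResidues(len, comp)
  # conserved loop glycines at fixed fractional positions
  gly <- unique(pmax(1L, pmin(len, round(len * c(0.12, 0.35, 0.60, 0.85)))))
  res[gly] <- "G"
  paste(res, collapse = "")
}

makeRbh <- function(len, boost) {
  comp <- boostedComposition(boost, nFreq = 0.30)
  res <- sampleResidues(len, comp)
  # chain of conserved asparagines in the turns of the beta-helix
  res[seq(3L, len, by = 6L)] <- "N"
  paste(res, collapse = "")
}

makeAmphipathic <- function() {
  res <- sampleResidues(18L, c(N = 0.4, K = 0.35, D = 0.25))
  res[.AMPH_FACE + 1L] <- sample(c("L", "F"), length(.AMPH_FACE),
                                 replace = TRUE, prob = c(0.7, 0.3))
  paste(res, collapse = "")
}

sampleMotifPair <- function() {
  u <- stats::runif(1)
  if (u < 0.40) "KK"
  else if (u < 0.75) "KN"
  else sample(c("KR", "RK", "KD"), 1L)
}

# Class-conditional architecture grammar (non-anchor symbols only). Each
# branch is the constructive inverse of the corresponding classification
# rule.
sampleArchitecture <- function(cls, spec) {
  k <- sampleRange(spec@rbhRepeatRange)
  m <- sampleRange(spec@abdRepeatRange)
  switch(cls,
    IA = c(rep("r", k), rep("a", m)),
    IB = {
      if (stats::runif(1) < 0.5) {
        m1 <- sample.int(m, 1L)
        c(rep("a", m1), rep("r", k), rep("a", m - m1))
      } else {
        k1 <- max(0L, k - 1L)
        c(rep("r", k1), rep("a", m), "r")
      }
    },
    IIA = rep("a", m),
    IIB = rep("r", k),
    III = c(rep("a", m), if (stats::runif(1) < 0.5) "b", "g"),
    OTHERS = switch(sample.int(4L, 1L),
                    c(rep("a", m), "o"),
                    c(rep("r", k), "o"),
                    c("o", rep("a", m)),
                    c(rep("r", k), "g")),
    stop("no grammar for class ", cls, call. = FALSE))
}

domainSequence <- function(symbol, spec) {
  switch(symbol,
         a = makeAbd(sampleRange(spec@abdLenRange), spec@asnThrBoost),
         r = makeRbh(sampleRbhLen(spec@rbhLenRange), spec@asnThrBoost),
         g = paste(sampleResidues(sampleRange(c(120L, 250L)), .POLAR_BG),
                   collapse = ""),
         b = paste(sampleResidues(sampleRange(c(60L, 150L)), .POLAR_BG),
                   collapse = ""),
         o = paste(sampleResidues(sampleRange(c(100L, 300L)), .POLAR_BG),
                   collapse = ""),
         stop("unknown architecture symbol ", symbol, call. = FALSE))
}

linker <- function(minLen = 2L, maxLen = 12L) {
  paste(sampleResidues(sampleRange(c(minLen, maxLen)), .POLAR_BG),
        collapse = "")
}

# Build one anchor block. Returns the block string plus the anchor and
# motif coordinates relative to the block start (1-based).
anchorBlock <- function(kind, spec, terminal) {
  if (kind == "TM") {
    tmLen <- sampleRange(spec@tmLenRange)
    tmSeq <- paste(sampleResidues(tmLen, .TM_RESIDUES), collapse = "")
    pair <- sampleMotifPair()
    if (terminal == "N") {
      pre <- paste(sampleResidues(sampleRange(c(1L, 4L)), .POLAR_BG),
                   collapse = "")
      mid <- paste(sampleResidues(sampleRange(c(0L, 4L)), .POLAR_BG),
                   collapse = "")
      block <- paste0(pre, pair, mid, tmSeq)
      s <- nchar(pre) + nchar(pair) + nchar(mid) + 1L
      list(block = block, anchorStart = s,
           anchorEnd = s + tmLen - 1L,
           motifPos = nchar(pre) + 1L, motifPair = pair,
           motifSide = "upstream_of_N_helix")
    } else {
      mid <- paste(sampleResidues(sampleRange(c(0L, 4L)), .POLAR_BG),
                   collapse = "")
      post <- paste(sampleResidues(sampleRange(c(1L, 4L)), .POLAR_BG),
                    collapse = "")
      block <- paste0(tmSeq, mid, pair, post)
      list(block = block, anchorStart = 1L, anchorEnd = tmLen,
           motifPos = tmLen + nchar(mid) + 1L, motifPair = pair,
           motifSide = "downstream_of_C_helix")
    }
  } else if (kind == "SHORT_HYDROPHOBIC") {
    len <- sampleRange(c(10L, 19L))
    core <- paste(sampleResidues(len, .SHORT_RESIDUES), collapse = "")
    pre <- paste(sampleResidues(sampleRange(c(0L, 3L)), .POLAR_BG),
                 collapse = "")
    block <- if (terminal == "N") paste0(pre, core) else paste0(core, pre)
    s <- if (terminal == "N") nchar(pre) + 1L else 1L
    list(block = block, anchorStart = s, anchorEnd = s + len - 1L,
         motifPos = NA_integer_, motifPair = NA_character_,
         motifSide = NA_character_)
  } else {
    core <- makeAmphipathic()
    pre <- paste(sampleResidues(sampleRange(c(0L, 2L)), .POLAR_BG),
                 collapse = "")
    block <- if (terminal == "N") paste0(pre, core) else paste0(core, pre)
    s <- if (terminal == "N") nchar(pre) + 1L else 1L
    list(block = block, anchorStart = s, anchorEnd = s + 17L,
         motifPos = NA_integer_, motifPair = NA_character_,
         motifSide = NA_character_)
  }
}

#' Generate a synthetic ALP proteome with ground truth
#'
#' For each protein a class is sampled, an architecture consistent with
#' that class is drawn from the class grammar, and per-domain sequence is
#' emitted: Asn/Thr-boosted ABDs with conserved glycines at fixed loop
#' positions, Asn-rich RBH rods, hydrophobic transmembrane anchors of
#' 20-28 residues preceded (N-terminal) or followed (C-terminal) by a
#' di-basic pair, short hydrophobic helices, and amphipathic 18-mers with
#' one hydrophobic face. Polar linkers fill the space between domains;
#' decoy sequences carry no domains at all. The output is fully
#' deterministic under the spec seed (each protein draws from its own
#' substream keyed by index).
#'
#' @param spec a [SyntheticSpec-class] object.
#' @return list with elements `proteins` (`AAStringSet`), `domains`
#'   ([DomainAnnotations-class], `source = "synthetic"`, including the
#'   MAD intervals) and `truth` (list of data frames `classes`,
#'   `anchors`, `motifs`).
#' @examples
#' out <- generateProteome(syntheticSpec(nProteins = 10, seed = 7))
#' table(out$truth$classes$class)
#' @export
generateProteome <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  clsLevels <- c(names(spec@groupWeights), "NOT_ALP")
  clsProbs <- c(spec@groupWeights, NOT_ALP = spec@decoyWeight)
  seqs <- character(spec@nProteins)
  ids <- sprintf("syn%04d", seq_len(spec@nProteins))
  domRows <- list()
  classRows <- list()
  anchorRows <- list()
  motifRows <- list()
  for (i in seq_len(spec@nProteins)) {
    set.seed(substreamSeed(spec@seed, i))
    cls <- sample(clsLevels, 1L, prob = clsProbs)
    id <- ids[i]
    classRows[[i]] <- data.frame(protein_id = id, class = cls,
                                 stringsAsFactors = FALSE)
    if (cls == "NOT_ALP") {
      seqs[i] <- paste(sampleResidues(sampleRange(c(130L, 400L)),
                                      .POLAR_BG), collapse = "")
      next
    }
    sigma <- sampleArchitecture(cls, spec)
    hasMad <- stats::runif(1) < spec@madProb
    dual <- hasMad && stats::runif(1) < spec@dualMadProb
    nKind <- if (hasMad)
      sample(names(spec@anchorKindProbs), 1L,
             prob = spec@anchorKindProbs) else NA_character_
    parts <- character(0)
    pos <- 0L
    addPart <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      start <- pos + 1L
      pos <<- pos + nchar(s)
      start
    }
    addAnchor <- function(kind, terminal) {
      blk <- anchorBlock(kind, spec, terminal)
      at <- addPart(blk$block)
      anchorRows[[length(anchorRows) + 1L]] <<- data.frame(
        protein_id = id, kind = kind,
        start = at + blk$anchorStart - 1L,
        end = at + blk$anchorEnd - 1L,
        terminal = terminal, stringsAsFactors = FALSE)
      domRows[[length(domRows) + 1L]] <<- data.frame(
        protein_id = id, domain_type = "MAD",
        start = at + blk$anchorStart - 1L,
        end = at + blk$anchorEnd - 1L,
        source = "synthetic", stringsAsFactors = FALSE)
      if (!is.na(blk$motifPos))
        motifRows[[length(motifRows) + 1L]] <<- data.frame(
          protein_id = id, position = at + blk$motifPos - 1L,
          pair = blk$motifPair, side = blk$motifSide,
          stringsAsFactors = FALSE)
    }
    if (hasMad) addAnchor(nKind, "N")
    addPart(linker())
    for (sym in sigma) {
      at <- addPart(domainSequence(sym, spec))
      domRows[[length(domRows) + 1L]] <- data.frame(
        protein_id = id,
        domain_type = names(ARCH_SYMBOLS)[match(sym, ARCH_SYMBOLS)],
        start = at, end = pos, source = "synthetic",
        stringsAsFactors = FALSE)
      addPart(linker())
    }
    if (dual) addAnchor("TM", "C")
    else addPart(paste(sampleResidues(sampleRange(c(0L, 10L)), .POLAR_BG),
                       collapse = ""))
    seqs[i] <- paste(parts, collapse = "")
  }
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  S4Vectors::mcols(proteins) <- S4Vectors::DataFrame(
    description = paste0("synthetic ",
                         vapply(classRows, `[[`, "", "class")))
  emptyMotifs <- data.frame(protein_id = character(0),
                            position = integer(0), pair = character(0),
                            side = character(0), stringsAsFactors = FALSE)
  emptyAnchors <- data.frame(protein_id = character(0), kind = character(0),
                             start = integer(0), end = integer(0),
                             terminal = character(0),
                             stringsAsFactors = FALSE)
  list(proteins = proteins,
       domains = domainAnnotations(do.call(rbind, c(domRows, list(
         data.frame(protein_id = character(0), domain_type = character(0),
                    start = integer(0), end = integer(0),
                    source = character(0), stringsAsFactors = FALSE))))),
       truth = list(
         classes = do.call(rbind, classRows),
         anchors = if (length(anchorRows)) do.call(rbind, anchorRows)
                   else emptyAnchors,
         motifs = if (length(motifRows)) do.call(rbind, motifRows)
                  else emptyMotifs))
}

#' Generate a synthetic ABD alignment with planted conservation
#'
#' Builds a gap-free core alignment emulating an archaeal-big-domain
#' repeat family: a consensus drawn from the Asn/Thr-boosted composition,
#' a configurable number of invariant glycine columns (the conserved loop
#' glycines), optional clade structure induced by clade-specific
#' consensus mutations, and i.i.d. per-column substitutions at
#' `substitutionRate`. When `substitutionRate > 0`, non-invariant columns
#' are guaranteed at least one substitution so the planted glycines are
#' the only perfectly conserved columns.
#'
#' @param nSeqs number of sequences (>= 2).
#' @param nInvariantGly number of invariant glycine columns.
#' @param cladeLabels either `NULL` (single clade), an integer number of
#'   clades (assigned cyclically), or a length-`nSeqs` label vector.
#' @param nColumns alignment width.
#' @param substitutionRate per-column probability that a sequence deviates
#'   from its clade consensus.
#' @param cladeDivergence fraction of non-invariant columns at which a
#'   clade's consensus differs from the base consensus.
#' @param asnThrBoost Asn/Thr enrichment of the consensus composition.
#' @param seed integer seed.
#' @return list with elements `alignment` (`AAStringSet`) and `truth`
#'   (list: `invariantColumns`, `cladeLabels`, `consensus`).
#' @export
generateAbdAlignment <- function(nSeqs, nInvariantGly = 5L,
                                 cladeLabels = NULL, nColumns = 90L,
                                 substitutionRate = 0.1,
                                 cladeDivergence = 0.3,
                                 asnThrBoost = 2, seed = 1L) {
  if (nSeqs < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (nInvariantGly > nColumns)
    stop("nInvariantGly exceeds the number of columns", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(cladeLabels)) {
    cladeLabels <- rep("c1", nSeqs)
  } else if (length(cladeLabels) == 1L && is.numeric(cladeLabels)) {
    cladeLabels <- paste0("c", rep_len(seq_len(cladeLabels), nSeqs))
  } else if (length(cladeLabels) != nSeqs) {
    stop("cladeLabels must be NULL, a count, or one label per sequence",
         call. = FALSE)
  } else {
    cladeLabels <- as.character(cladeLabels)
  }
  comp <- boostedComposition(asnThrBoost)
  consensus <- sampleResidues(nColumns, comp)
  inv <- if (nInvariantGly > 0L)
    unique(round(seq(1L, nColumns, length.out = nInvariantGly)))
  else integer(0)
  consensus[inv] <- "G"
  variable <- setdiff(seq_len(nColumns), inv)
  mutate <- function(res) {
    pool <- setdiff(names(comp), res)
    sample(pool, 1L, prob = comp[pool])
  }
  cladeCons <- list()
  for (cl in unique(cladeLabels)) {
    cc <- consensus
    hit <- variable[stats::runif(length(variable)) < cladeDivergence]
    for (p in hit) cc[p] <- mutate(cc[p])
    cladeCons[[cl]] <- cc
  }
  m <- matrix("", nSeqs, nColumns)
  for (s in seq_len(nSeqs)) {
    row <- cladeCons[[cladeLabels[s]]]
    hit <- variable[stats::runif(length(variable)) < substitutionRate]
    for (p in hit) row[p] <- mutate(row[p])
    m[s, ] <- row
  }
  if (substitutionRate > 0) {
    for (j in variable) {
      if (length(unique(m[, j])) == 1L) {
        s <- sample.int(nSeqs, 1L)
        m[s, j] <- mutate(m[s, j])
      }
    }
  }
  aln <- Biostrings::AAStringSet(apply(m, 1, paste, collapse = ""))
  names(aln) <- sprintf("abd%03d_%s", seq_len(nSeqs), cladeLabels)
  list(alignment = aln,
       truth = list(invariantColumns = inv,
                    cladeLabels = setNames(cladeLabels, names(aln)),
                    consensus = paste(consensus, collapse = "")))
}

#' Write a simulated proteome to disk
#'
#' Runs [generateProteome()] and writes `proteins.fasta`, `domains.tsv`
#' and `truth.tsv` (the per-protein class table) into `outDir`. Identical
#' specs produce byte-identical files.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @param outDir output directory (created if missing).
#' @return invisibly, the list returned by [generateProteome()].
#' @export
writeSimulatedProteome <- function(spec, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- generateProteome(spec)
  writeProteins(out$proteins, file.path(outDir, "proteins.fasta"))
  writeDomainTable(out$domains, file.path(outDir, "domains.tsv"))
  utils::write.table(out$truth$classes, file.path(outDir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
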