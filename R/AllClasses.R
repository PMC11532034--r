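#' Typed domain intervals on a set of proteins
#'
#' `DomainAnnotations` holds 1-based, inclusive intervals of typed domains
#' (`MAD`, `ABD`, `RBH`, `TG`, `PMB`, `OTHER`) on named proteins, together
#' with the provenance of each interval (`external`, `detected` or
#' `synthetic`). Within one protein, two annotations may overlap only when
#' exactly one of them is a membrane-anchoring domain (`MAD`): anchors sit
#' at the termini and may abut or overlap a structural domain, whereas the
#' structural domains themselves tile the sequence.
#'
#' @slot table a `data.frame` with columns `protein_id`, `domain_type`,
#'   `start`, `end`, `source`, sorted by (`protein_id`, `start`).
#'
#' @seealso [domainAnnotations()], [readDomainTable()],
#'   [encodeArchitectures()]
#' @export
setClass("DomainAnnotations", representation(table = "data.frame"))

setValidity("DomainAnnotations", function(object) {
  tab <- object@table
  required <- c("protein_id", "domain_type", "start", "end", "source")
  if (!all(required %in% names(tab)))
    return(paste("table must have columns", paste(required, collapse = ", ")))
  if (nrow(tab) == 0L) return(TRUE)
  if (!all(tab$domain_type %in% DOMAIN_TYPES))
    return(paste("unknown domain_type:",
                 paste(unique(setdiff(tab$domain_type, DOMAIN_TYPES)),
                       collapse = ", ")))
  if (!all(tab$source %in% ANNOTATION_SOURCES))
    return(paste("unknown source:",
                 paste(unique(setdiff(tab$source, ANNOTATION_SOURCES)),
                       collapse = ", ")))
  if (any(tab$start < 1L)) return("start positions must be >= 1")
  if (any(tab$start > tab$end))
    return("found annotation with start > end")
  # overlaps allowed only between MAD and non-MAD
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (k in seq_len(nrow(sub) - 1L)) {
      for (j in (k + 1L):nrow(sub)) {
        if (sub$start[j] > sub$end[k]) break
        isMad <- c(sub$domain_type[k], sub$domain_type[j]) == "MAD"
        if (sum(isMad) != 1L)
          return(sprintf("overlapping %s/%s annotations on '%s'",
                         sub$domain_type[k], sub$domain_type[j], pid))
      }
    }
  }
  TRUE
})

#' Architecture strings for a set of proteins
#'
#' An `ArchitectureSet` stores, per protein, the ordered single-letter
#' encoding of its domain annotations (alphabet `t r a b g o` for
#' MAD/RBH/ABD/PMB/TG/OTHER, in start order) and the run-length-compressed
#' form of the same string. Proteins without any annotated domain carry the
#' empty string and are later classified `NOT_ALP`.
#'
#' @slot proteinIds character vector of protein identifiers.
#' @slot raw character vector of raw architecture strings, parallel to
#'   `proteinIds`.
#' @slot compressed list of two-column data frames (`symbol`, `count`),
#'   the run-length encoding of each raw string.
#'
#' @seealso [encodeArchitectures()], [classifyProteome()], [dbscanCluster()]
#' @export
setClass("ArchitectureSet",
         representation(proteinIds = "character",
                        raw = "character",
                        compressed = "list"))

setValidity("ArchitectureSet", function(object) {
  if (length(object@proteinIds) != length(object@raw) ||
      length(object@raw) != length(object@compressed))
    return("proteinIds, raw and compressed must be parallel")
  if (anyDuplicated(object@proteinIds))
    return("duplicated protein ids")
  if (length(object@raw) &&
      any(grepl("[^trabgo]", object@raw)))
    return("raw strings must use alphabet {t, r, a, b, g, o}")
  for (k in seq_along(object@raw)) {
    cp <- object@compressed[[k]]
    expanded <- paste(rep(cp$symbol, cp$count), collapse = "")
    if (!identical(expanded, object@raw[k]))
      return(sprintf("compressed form of '%s' does not expand to raw",
                     object@proteinIds[k]))
  }
  TRUE
})

#' Repertoire-level summary of an ALP complement
#'
#' Descriptive statistics of one species' ALP repertoire: number of
#' proteins, summed length in residues, the fraction of the genome coding
#' for ALPs (at 3 bp per residue, reported as a percentage rounded half-up
#' to one decimal), and the length range.
#'
#' @slot speciesLabel display label for the repertoire.
#' @slot genomeSizeBp genome size in base pairs.
#' @slot nAlps number of ALPs.
#' @slot totalAlpAa summed ALP length, residues.
#' @slot codingFractionPct percent of the genome coding for ALPs.
#' @slot minLen,maxLen,meanLen length statistics in residues (`NA` when the
#'   repertoire is empty).
#'
#' @seealso [summarizeRepertoire()], [alpCodingFraction()]
#' @export
setClass("RepertoireSummary",
         representation(speciesLabel = "character",
                        genomeSizeBp = "numeric",
                        nAlps = "integer",
                        totalAlpAa = "numeric",
                        codingFractionPct = "numeric",
                        minLen = "numeric",
                        maxLen = "numeric",
                        meanLen = "numeric"))

setValidity("RepertoireSummary", function(object) {
  if (object@genomeSizeBp <= 0) return("genomeSizeBp must be positive")
  if (object@nAlps < 0L) return("nAlps must be >= 0")
  if (object@nAlps > 0L &&
      !(object@minLen <= object@meanLen && object@meanLen <= object@maxLen))
    return("length statistics must satisfy min <= mean <= max")
  TRUE
})

#' Positional-entropy (sequence logo) matrix
#'
#' Per retained alignment column: residue frequencies over the 20 standard
#' amino acids (gaps and `X` excluded from the counts), Shannon entropy in
#' bits and information content `log2(20) - entropy`.
#'
#' @slot frequencies 20 x n matrix of per-column residue frequencies, rows
#'   named by one-letter amino-acid code.
#' @slot entropy numeric vector of per-column entropies, bits.
#' @slot information numeric vector of per-column information contents,
#'   bits.
#' @slot retainedColumns integer indices of the columns in the original
#'   alignment (identity mapping unless gappy columns were pruned first).
#'
#' @seealso [logoMatrix()], [dropGappyColumns()]
#' @export
setClass("LogoResult",
         representation(frequencies = "matrix",
                        entropy = "numeric",
                        information = "numeric",
                        retainedColumns = "integer"))

setValidity("LogoResult", function(object) {
  n <- ncol(object@frequencies)
  if (nrow(object@frequencies) != 20L)
    return("frequencies must have 20 rows")
  if (length(object@entropy) != n || length(object@information) != n ||
      length(object@retainedColumns) != n)
    return("entropy, information and retainedColumns must match columns")
  if (any(object@entropy < -1e-9) || any(object@entropy > log2(20) + 1e-9))
    return("entropy out of [0, log2(20)]")
  TRUE
})

#' Specification of a synthetic ALP proteome
#'
#' All tunables of the synthetic proteome generator. The defaults emulate
#' the repertoire scale reported for the two human gut methanogens the
#' package targets: 105 candidate sequences of which 14 are domain-free
#' decoys, architecture-group frequencies matching the published grouping
#' (40 IA, 12 IB, 13 IIA, 5 IIB, 4 III, 13 others), 1-7 tandem RBH
#' repeats, 1-27 ABD repeats of 80-120 residues, transmembrane anchors of
#' 20-28 residues, a two-fold Asn/Thr boost over the polar background, and
#' roughly one protein in eight carrying anchors at both termini.
#'
#' @slot nProteins number of sequences to generate.
#' @slot groupWeights named sampling weights for classes IA, IB, IIA, IIB,
#'   III, OTHERS.
#' @slot decoyWeight weight of domain-free decoy sequences (`NOT_ALP`);
#'   `groupWeights` plus `decoyWeight` must sum to 1.
#' @slot rbhRepeatRange,abdRepeatRange integer ranges for tandem repeat
#'   counts.
#' @slot abdLenRange,rbhLenRange,tmLenRange integer residue-length ranges
#'   for ABD domains, RBH domains and transmembrane anchors.
#' @slot asnThrBoost multiplicative Asn/Thr enrichment of domain sequence
#'   over the polar background (>= 1).
#' @slot dualMadProb probability that an anchored protein carries anchors
#'   at both termini.
#' @slot madProb probability that a non-decoy protein carries at least one
#'   anchor.
#' @slot anchorKindProbs named probabilities for anchor kinds `TM`,
#'   `SHORT_HYDROPHOBIC`, `AMPHIPATHIC`.
#' @slot seed integer seed fixing the full output.
#'
#' @seealso [syntheticSpec()], [generateProteome()]
#' @export
setClass("SyntheticSpec",
         representation(nProteins = "integer",
                        groupWeights = "numeric",
                        decoyWeight = "numeric",
                        rbhRepeatRange = "integer",
                        abdRepeatRange = "integer",
                        abdLenRange = "integer",
                        rbhLenRange = "integer",
                        tmLenRange = "integer",
                        asnThrBoost = "numeric",
                        dualMadProb = "numeric",
                        madProb = "numeric",
                        anchorKindProbs = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nProteins < 1L) return("nProteins must be >= 1")
  gw <- object@groupWeights
  if (!setequal(names(gw), setdiff(ALP_CLASSES, "NOT_ALP")))
    return("groupWeights must be named IA, IB, IIA, IIB, III, OTHERS")
  if (any(gw < 0) || object@decoyWeight < 0)
    return("weights must be non-negative")
  if (abs(sum(gw) + object@decoyWeight - 1) > 1e-8)
    return("groupWeights plus decoyWeight must sum to 1")
  for (nm in c("rbhRepeatRange", "abdRepeatRange", "abdLenRange",
               "rbhLenRange", "tmLenRange")) {
    rg <- slot(object, nm)
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 1L)
      return(paste(nm, "must be a non-empty positive integer range"))
  }
  if (object@asnThrBoost < 1) return("asnThrBoost must be >= 1")
  probs <- c(object@dualMadProb, object@madProb)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  akp <- object@anchorKindProbs
  if (!setequal(names(akp), c("TM", "SHORT_HYDROPHOBIC", "AMPHIPATHIC")) ||
      abs(sum(akp) - 1) > 1e-8 || any(akp < 0))
    return("anchorKindProbs must be a probability vector over the 3 kinds")
  TRUE
})
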