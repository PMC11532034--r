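# Repertoire-level descriptive statistics and residue composition.

#' Fraction of a genome coding for ALPs
#'
#' Percentage of the genome occupied by ALP coding sequence at 3 bp per
#' residue (stop codons ignored; including one stop per gene would change
#' the published fractions by under 0.01 points), rounded half-up to one
#' decimal to match how such tables are conventionally printed.
#'
#' @param totalAlpAa summed ALP length, residues.
#' @param genomeSizeBp genome size, bp.
#' @return percentage, one decimal.
#' @examples
#' alpCodingFraction(67292, 1853000)   # 10.9
#' alpCodingFraction(63039, 1767000)   # 10.7
#' @export
alpCodingFraction <- function(totalAlpAa, genomeSizeBp) {
  if (genomeSizeBp <= 0) stop("genomeSizeBp must be positive",
                              call. = FALSE)
  roundHalfUp(100 * 3 * totalAlpAa / genomeSizeBp, 1)
}

#' Summarise an ALP repertoire
#'
#' @param alps an `AAStringSet` of ALP sequences (may be empty, giving a
#'   zero summary).
#' @param genomeSizeBp genome size, bp.
#' @param label species/display label.
#' @return a [RepertoireSummary-class] object.
#' @export
summarizeRepertoire <- function(alps, genomeSizeBp, label = "repertoire") {
  if (genomeSizeBp <= 0) stop("genomeSizeBp must be positive",
                              call. = FALSE)
  n <- length(alps)
  lens <- if (n) Biostrings::width(alps) else integer(0)
  total <- sum(lens)
  new("RepertoireSummary",
      speciesLabel = label,
      genomeSizeBp = as.numeric(genomeSizeBp),
      nAlps = as.integer(n),
      totalAlpAa = as.numeric(total),
      codingFractionPct = alpCodingFraction(total, genomeSizeBp),
      minLen = if (n) min(lens) else NA_real_,
      maxLen = if (n) max(lens) else NA_real_,
      meanLen = if (n) total / n else NA_real_)
}

#' Pooled residue composition of a protein set
#'
#' Residue frequencies pooled over all sequences (counted over the 20
#' standard amino acids; `X` is excluded), the combined Asn+Thr fraction
#' that characterises ALPs, and, when a background frequency map is
#' supplied, per-residue log2 enrichments over that background.
#'
#' @param proteins an `AAStringSet` (or character vector) of sequences.
#' @param background optional named frequency vector; enrichment is
#'   reported only for residues with positive background frequency.
#' @return list with elements `frequencies` (named 20-vector summing to
#'   1), `asn_thr_fraction`, `background` and `enrichment` (named log2
#'   ratios, or `NULL` without a background).
#' @examples
#' compositionProfile(Biostrings::AAStringSet(c(p = "NNTT")))$asn_thr_fraction
#' @export
compositionProfile <- function(proteins, background = NULL) {
  seqs <- as.character(proteins)
  if (!length(seqs)) stop("need at least one sequence", call. = FALSE)
  chars <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
  chars <- chars[chars %in% AA20]
  if (!length(chars))
    stop("pooled sequence contains no standard residues", call. = FALSE)
  counts <- table(factor(chars, levels = AA20))
  freqs <- as.numeric(counts) / sum(counts)
  names(freqs) <- AA20
  enrichment <- NULL
  if (!is.null(background)) {
    bg <- background[AA20]
    ok <- !is.na(bg) & bg > 0
    enrichment <- setNames(log2(freqs[ok] / as.numeric(bg[ok])),
                           AA20[ok])
  }
  list(frequencies = freqs,
       asn_thr_fraction = unname(freqs["N"] + freqs["T"]),
       background = background,
       enrichment = enrichment)
}
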