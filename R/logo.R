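# Positional-entropy (sequence-logo) matrices from alignments.

#' Remove gap-rich alignment columns
#'
#' Long gap stretches are pruned before computing a logo: columns whose
#' gap fraction exceeds `maxGapFraction` are removed, preserving the
#' order of the remaining columns.
#'
#' @param aln an `AAStringSet` of equal-width gapped rows.
#' @param maxGapFraction columns with a gap fraction strictly greater
#'   than this are dropped.
#' @return list with elements `alignment` (pruned `AAStringSet`) and
#'   `retained` (integer indices of the kept columns in the input).
#' @export
dropGappyColumns <- function(aln, maxGapFraction = 0.5) {
  m <- alnCharMatrix(aln)
  gapFrac <- colMeans(m == "-")
  keep <- which(gapFrac <= maxGapFraction)
  if (!length(keep))
    stop("all columns exceed the gap threshold", call. = FALSE)
  out <- Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1, paste,
                                       collapse = ""))
  names(out) <- rownames(m)
  list(alignment = out, retained = keep)
}

#' Positional-entropy logo matrix of an alignment
#'
#' Per column, residue frequencies over the 20 standard amino acids
#' (gaps and `X` are excluded from the counts), Shannon entropy
#' `H = -sum p log2 p` and information content `log2(20) - H` (no
#' small-sample correction). A fully conserved column reaches
#' `log2(20) ~ 4.32` bits; a uniform column reaches 0.
#'
#' @param aln an `AAStringSet` of equal-width gapped rows, normally after
#'   [dropGappyColumns()].
#' @param retained optional integer vector of original column indices
#'   (as returned by [dropGappyColumns()]); defaults to `1:ncol`.
#' @return a [LogoResult-class] object.
#' @export
logoMatrix <- function(aln, retained = NULL) {
  m <- alnCharMatrix(aln)
  nc <- ncol(m)
  if (nc == 0L) stop("empty alignment", call. = FALSE)
  if (is.null(retained)) retained <- seq_len(nc)
  if (length(retained) != nc)
    stop("retained must have one index per column", call. = FALSE)
  freqs <- matrix(0, nrow = 20L, ncol = nc,
                  dimnames = list(AA20, NULL))
  entropy <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    col <- col[col %in% AA20]
    if (!length(col))
      stop("column ", j, " has no residues (all gaps or X); ",
           "prune gappy columns first", call. = FALSE)
    p <- as.numeric(table(factor(col, levels = AA20))) / length(col)
    freqs[, j] <- p
    nz <- p[p > 0]
    entropy[j] <- -sum(nz * log2(nz))
  }
  new("LogoResult",
      frequencies = freqs,
      entropy = entropy,
      information = log2(20) - entropy,
      retainedColumns = as.integer(retained))
}

#' Export a logo matrix as a data frame
#'
#' One row per retained column: original column index, the 20 residue
#' frequencies, entropy and information content in bits.
#'
#' @param logo a [LogoResult-class] object.
#' @return a `data.frame`.
#' @export
logoAsDataFrame <- function(logo) {
  df <- as.data.frame(t(logo@frequencies))
  names(df) <- paste0("freq_", AA20)
  cbind(data.frame(column = logo@retainedColumns),
        df,
        data.frame(entropy_bits = logo@entropy,
                   information_bits = logo@information))
}
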