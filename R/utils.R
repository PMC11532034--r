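# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats setNames
NULL

# The 20 standard amino acids, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DOMAIN_TYPES <- c("MAD", "ABD", "RBH", "TG", "PMB", "OTHER")
ANNOTATION_SOURCES <- c("external", "detected", "synthetic")

# Symbol map used for architecture strings (MAD is written as its
# transmembrane-domain shorthand 't').
ARCH_SYMBOLS <- c(MAD = "t", RBH = "r", ABD = "a", PMB = "b",
                  TG = "g", OTHER = "o")

ALP_CLASSES <- c("IA", "IB", "IIA", "IIB", "III", "OTHERS", "NOT_ALP")

# round() in R rounds half to even; repertoire tables use conventional
# half-up rounding at a fixed number of decimals.
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Split a sequence (character scalar or XString) into single characters.
seqChars <- function(x) {
  x <- as.character(x)
  stopifnot(length(x) == 1L)
  strsplit(x, "", fixed = TRUE)[[1L]]
}

assertScalarString <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  invisible(x)
}

# Deterministic per-item substream seed, kept inside 32-bit integer range.
substreamSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Sample `n` residues from a named frequency vector.
sampleResidues <- function(n, freqs) {
  if (n <= 0) return(character(0))
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

fmtBranchLength <- function(x) sprintf("%.17g", x)
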