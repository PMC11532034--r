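# Kyte-Doolittle hydropathy, used for transmembrane window scanning.
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Fauchere-Pliska octanol/water transfer free energies (relative to Gly),
# the scale behind HeliQuest's hydrophobicity and hydrophobic moment.
.FAUCHERE_PLISKA <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

#' Hydrophobicity scales
#'
#' Returns one of the two per-residue hydrophobicity scales used by the
#' membrane-anchor detectors: Fauchere-Pliska (octanol/water transfer free
#' energy relative to glycine; the HeliQuest scale, used for the
#' hydrophobicity index of short helices and for the hydrophobic moment)
#' or Kyte-Doolittle (hydropathy, used for transmembrane window scans).
#' The ambiguity code `X` and the gap symbol `-` both score 0.
#'
#' @param name `"fauchere-pliska"` or `"kyte-doolittle"`.
#' @return named numeric vector over the 20 standard residues plus `X`
#'   and `-`.
#' @examples
#' hydrophobicityScale()[["G"]]           # 0: the scale is relative to Gly
#' hydrophobicityScale("kyte-doolittle")[["I"]]
#' @export
hydrophobicityScale <- function(name = c("fauchere-pliska",
                                         "kyte-doolittle")) {
  name <- match.arg(name)
  sc <- switch(name,
               "fauchere-pliska" = .FAUCHERE_PLISKA,
               "kyte-doolittle" = .KYTE_DOOLITTLE)
  c(sc, X = 0, "-" = 0)
}

scoreResidues <- function(chars, scale) {
  unknown <- setdiff(unique(chars), names(scale))
  if (length(unknown))
    stop("residue(s) not covered by the scale: ",
         paste(unknown, collapse = " "), call. = FALSE)
  unname(scale[chars])
}

#' Mean hydrophobicity of a segment
#'
#' Arithmetic mean of the per-residue scale values; with the default
#' Fauchere-Pliska scale this is the HeliQuest "hydrophobicity index"
#' (short membrane-anchoring helices typically score > 1).
#'
#' @param segment residue string (length >= 1).
#' @param scale named scale vector, see [hydrophobicityScale()].
#' @return unitless mean score.
#' @examples
#' meanHydrophobicity("LILFLILFLI")
#' @export
meanHydrophobicity <- function(segment,
                               scale = hydrophobicityScale()) {
  assertScalarString(segment, "segment")
  mean(scoreResidues(seqChars(segment), scale))
}

#' Eisenberg hydrophobic moment of a segment
#'
#' The modulus of the vector sum of per-residue hydrophobicities placed at
#' successive angles of `deltaDeg` (100 degrees for an ideal alpha helix),
#' divided by the segment length:
#' \deqn{\mu_H = \left| \sum_k H_k e^{i k \delta} \right| / N.}
#' Values of roughly 0.5 and above (Fauchere-Pliska, 18-residue window)
#' indicate a possible amphipathic helix. Any 18-residue homopolymer has
#' moment exactly 0 since 18 x 100 degrees is a multiple of 360.
#'
#' @param segment residue string (length >= 1).
#' @param scale named scale vector, see [hydrophobicityScale()].
#' @param deltaDeg angular spacing per residue, degrees.
#' @return unitless moment (>= 0).
#' @examples
#' hydrophobicMoment(strrep("L", 18))   # 0 by symmetry
#' @export
hydrophobicMoment <- function(segment,
                              scale = hydrophobicityScale(),
                              deltaDeg = 100) {
  assertScalarString(segment, "segment")
  h <- scoreResidues(seqChars(segment), scale)
  k <- seq_along(h) - 1L
  theta <- k * deltaDeg * pi / 180
  Mod(sum(h * exp(1i * theta))) / length(h)
}
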