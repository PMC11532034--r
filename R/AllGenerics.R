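#' @include AllClasses.R
NULL

#' Extract the annotation table
#'
#' @param x a [DomainAnnotations-class] object.
#' @return a `data.frame` with columns `protein_id`, `domain_type`,
#'   `start`, `end`, `source`, sorted by (`protein_id`, `start`).
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' Protein identifiers of an object
#'
#' @param x a [DomainAnnotations-class] or [ArchitectureSet-class] object.
#' @return character vector of protein ids (unique, in order of first
#'   appearance for annotation sets).
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Raw architecture strings
#'
#' @param x an [ArchitectureSet-class] object.
#' @return named character vector of raw architecture strings.
#' @export
setGeneric("rawArchitecture", function(x) standardGeneric("rawArchitecture"))

#' Run-length-compressed architectures
#'
#' @param x an [ArchitectureSet-class] object.
#' @return named list of data frames with columns `symbol` and `count`.
#' @export
setGeneric("compressedArchitecture",
           function(x) standardGeneric("compressedArchitecture"))

#' Per-column information content of a logo
#'
#' @param x a [LogoResult-class] object.
#' @return numeric vector of information contents in bits, one per
#'   retained column.
#' @export
setGeneric("informationContent",
           function(x) standardGeneric("informationContent"))

#' @rdname domainTable
#' @export
setMethod("domainTable", "DomainAnnotations", function(x) x@table)

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "DomainAnnotations",
          function(x) unique(x@table$protein_id))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "ArchitectureSet", function(x) x@proteinIds)

#' @rdname rawArchitecture
#' @export
setMethod("rawArchitecture", "ArchitectureSet",
          function(x) setNames(x@raw, x@proteinIds))

#' @rdname compressedArchitecture
#' @export
setMethod("compressedArchitecture", "ArchitectureSet",
          function(x) setNames(x@compressed, x@proteinIds))

#' @rdname informationContent
#' @export
setMethod("informationContent", "LogoResult", function(x) x@information)

setMethod("length", "DomainAnnotations", function(x) nrow(x@table))
setMethod("length", "ArchitectureSet", function(x) length(x@proteinIds))

setMethod("show", "DomainAnnotations", function(object) {
  tab <- object@table
  cat(sprintf("DomainAnnotations: %d intervals on %d proteins\n",
              nrow(tab), length(unique(tab$protein_id))))
  if (nrow(tab)) {
    counts <- table(factor(tab$domain_type, levels = DOMAIN_TYPES))
    cat("  by type:",
        paste(sprintf("%s=%d", names(counts), as.integer(counts)),
              collapse = " "), "\n")
  }
  invisible(object)
})

setMethod("show", "ArchitectureSet", function(object) {
  cat(sprintf("ArchitectureSet of %d proteins\n", length(object@proteinIds)))
  n <- min(5L, length(object@proteinIds))
  for (k in seq_len(n))
    cat(sprintf("  %s: %s\n", object@proteinIds[k],
                if (nzchar(object@raw[k])) object@raw[k] else "<empty>"))
  if (length(object@proteinIds) > n) cat("  ...\n")
  invisible(object)
})

setMethod("show", "RepertoireSummary", function(object) {
  cat(sprintf("RepertoireSummary '%s'\n", object@speciesLabel))
  cat(sprintf("  genome: %s bp; ALPs: %d; total length: %s aa\n",
              format(object@genomeSizeBp, big.mark = ","), object@nAlps,
              format(object@totalAlpAa, big.mark = ",")))
  cat(sprintf("  ALP-coding fraction: %.1f%%\n", object@codingFractionPct))
  if (object@nAlps > 0L)
    cat(sprintf("  length range: %d-%d aa (mean %.0f)\n",
                as.integer(object@minLen), as.integer(object@maxLen),
                object@meanLen))
  invisible(object)
})

setMethod("show", "LogoResult", function(object) {
  cat(sprintf("LogoResult: %d columns, information %.2f-%.2f bits\n",
              ncol(object@frequencies),
              min(object@information), max(object@information)))
  invisible(object)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d proteins (decoy weight %.2f), seed %d\n",
              object@nProteins, object@decoyWeight, object@seed))
  cat("  group weights:",
      paste(sprintf("%s=%.2f", names(object@groupWeights),
                    object@groupWeights), collapse = " "), "\n")
  invisible(object)
})

#' Coerce a RepertoireSummary to a one-row data frame
#'
#' @param x a [RepertoireSummary-class] object.
#' @param ... unused.
#' @return one-row `data.frame` mirroring the slots.
#' @export
as.data.frame.RepertoireSummary <- function(x, ...) {
  data.frame(species_label = x@speciesLabel,
             genome_size_bp = x@genomeSizeBp,
             n_alps = x@nAlps,
             total_alp_aa = x@totalAlpAa,
             coding_fraction_pct = x@codingFractionPct,
             min_len = x@minLen, max_len = x@maxLen, mean_len = x@meanLen,
             stringsAsFactors = FALSE)
}
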