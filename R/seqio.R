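#' Read a protein FASTA file
#'
#' Reads protein sequences, uppercases them, strips a single trailing stop
#' symbol (`*`) and validates that only the 20 standard one-letter codes
#' plus `X` remain. The first whitespace-delimited token of each header is
#' the protein id and must be unique; the remainder is kept as the
#' description.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet] named by protein id, with the
#'   descriptions in `mcols(x)$description`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "MKT"), tf)
#' readProteins(tf)
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  bad <- unique(unlist(lapply(seqs, function(s)
    setdiff(seqChars(s), c(AA20, "X")))))
  if (length(bad))
    stop("non-amino-acid character(s) in sequences: ",
         paste(sort(bad), collapse = " "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write proteins to FASTA
#'
#' Inverse of [readProteins()]: headers are `id` or `id description`,
#' sequences are wrapped at 60 columns. Writing, re-reading and writing
#' again is byte-identical.
#'
#' @param proteins an `AAStringSet` named by id, optionally with a
#'   `description` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteins <- function(proteins, path) {
  ids <- names(proteins)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("proteins must be named by id", call. = FALSE)
  mc <- S4Vectors::mcols(proteins)
  desc <- if (!is.null(mc) && "description" %in% names(mc))
    as.character(mc$description) else rep("", length(proteins))
  headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(proteins)) {
    writeLines(paste0(">", headers[k]), con)
    s <- as.character(proteins[[k]])
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a DomainAnnotations object
#'
#' @param table a data frame with columns `protein_id`, `domain_type`,
#'   `start`, `end`, `source` (zero rows allowed).
#' @return a validated [DomainAnnotations-class] object, sorted by
#'   (`protein_id`, `start`).
#' @export
domainAnnotations <- function(table) {
  if (nrow(table)) {
    table$protein_id <- as.character(table$protein_id)
    table$domain_type <- as.character(table$domain_type)
    table$start <- as.integer(table$start)
    table$end <- as.integer(table$end)
    table$source <- as.character(table$source)
    table <- table[order(table$protein_id, table$start, table$end), ,
                   drop = FALSE]
  } else {
    table <- data.frame(protein_id = character(0),
                        domain_type = character(0),
                        start = integer(0), end = integer(0),
                        source = character(0), stringsAsFactors = FALSE)
  }
  rownames(table) <- NULL
  new("DomainAnnotations", table = table)
}

#' Read a domain annotation table
#'
#' The interchange format is tab-separated with a mandatory header
#' `protein_id  domain_type  start  end  source`; lines starting with `#`
#' are comments. Coordinates are 1-based and inclusive. Rows are validated
#' (known domain type and source, `1 <= start <= end`, overlap only
#' between MAD and non-MAD annotations) and returned sorted by
#' (`protein_id`, `start`).
#'
#' @param path path to the TSV file.
#' @param proteins optional `AAStringSet`; when supplied, every annotation
#'   must reference a present protein and lie within its length.
#' @return a [DomainAnnotations-class] object.
#' @export
readDomainTable <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  required <- c("protein_id", "domain_type", "start", "end", "source")
  if (!all(required %in% names(tab)))
    stop("domain table must have header columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tab$domain_type), DOMAIN_TYPES)
  if (length(bad))
    stop("unknown domain_type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(tab$start > tab$end))
    stop("annotation interval with start > end for protein(s): ",
         paste(unique(tab$protein_id[tab$start > tab$end]), collapse = ", "),
         call. = FALSE)
  ann <- domainAnnotations(tab[required])
  if (!is.null(proteins)) {
    tab <- domainTable(ann)
    missing <- setdiff(tab$protein_id, names(proteins))
    if (length(missing))
      stop("annotations reference unknown protein(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    lens <- Biostrings::width(proteins)[match(tab$protein_id,
                                              names(proteins))]
    if (any(tab$end > lens))
      stop("annotation end beyond protein length for: ",
           paste(unique(tab$protein_id[tab$end > lens]), collapse = ", "),
           call. = FALSE)
  }
  ann
}

#' Write a domain annotation table
#'
#' @param annotations a [DomainAnnotations-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDomainTable <- function(annotations, path) {
  utils::write.table(domainTable(annotations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment in aligned-FASTA format
#'
#' Rows must be equal length; `-` marks gaps. Sequences are uppercased.
#'
#' @param path path to an aligned FASTA file.
#' @return an `AAStringSet` of equal-width gapped rows.
#' @export
readAlignedFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Read a Clustal .aln alignment
#'
#' Parses the interleaved Clustal format, ignoring the header line and the
#' conservation lines; only sequence rows (name, then gapped segment) are
#' used.
#'
#' @param path path to a Clustal `.aln` file.
#' @return an `AAStringSet` of equal-width gapped rows.
#' @export
readClustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1]))
    stop("not a Clustal alignment: ", path, call. = FALSE)
  lines <- lines[-1]
  pieces <- list()
  order <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.-]+)", ln))[[1]]
    if (length(m) != 3L) next
    id <- m[2]
    if (!id %in% order) order <- c(order, id)
    pieces[[id]] <- c(pieces[[id]], m[3])
  }
  if (!length(order)) stop("no sequence rows found in ", path, call. = FALSE)
  seqs <- vapply(pieces[order],
                 function(p) toupper(paste(p, collapse = "")), "")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- order
  out
}

#' Remove gaps from alignment rows
#'
#' @param aln an `AAStringSet` of gapped rows.
#' @return an `AAStringSet` with all `-` characters removed.
#' @export
ungapAlignment <- function(aln) {
  out <- Biostrings::AAStringSet(gsub("-", "", as.character(aln),
                                      fixed = TRUE))
  names(out) <- names(aln)
  out
}

#' Write a tree to Newick
#'
#' Serialises an unrooted tree (an `ape` `phylo` object, as produced by
#' [njTree()] or [bootstrapSupport()]) with branch lengths and any integer
#' bootstrap labels. Trees with fewer than two leaves are rejected.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  if (!inherits(tree, "phylo"))
    stop("tree must be a 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 leaves", call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be >= 0", call. = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}
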