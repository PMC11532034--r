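# Architecture strings: single-letter encoding of domain annotations,
# normalised edit distance, DBSCAN clustering and group classification.

#' Encode one protein's annotations as an architecture string
#'
#' Domains are sorted by start position and transcribed to single letters
#' (MAD = `t`, RBH = `r`, ABD = `a`, pseudomurein-binding = `b`,
#' transglutaminase = `g`, OTHER = `o`), so the domain sequence
#' MAD-RBH-ABD-ABD-ABD-ABD-ABD becomes `"traaaaa"`.
#'
#' @param annotations data frame of annotations for a single protein
#'   (columns `domain_type`, `start`; zero rows give the empty string).
#' @return list with elements `raw` (the architecture string) and
#'   `compressed` (data frame `symbol`, `count`, its run-length encoding).
#' @examples
#' ann <- data.frame(domain_type = c("MAD", "RBH", rep("ABD", 5)),
#'                   start = c(1, 30, 300, 400, 500, 600, 700))
#' encodeArchitecture(ann)$raw   # "traaaaa"
#' @export
encodeArchitecture <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(list(raw = "",
                compressed = data.frame(symbol = character(0),
                                        count = integer(0),
                                        stringsAsFactors = FALSE)))
  }
  bad <- setdiff(unique(annotations$domain_type), names(ARCH_SYMBOLS))
  if (length(bad))
    stop("unknown domain_type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ord <- order(annotations$start)
  syms <- unname(ARCH_SYMBOLS[annotations$domain_type[ord]])
  r <- rle(syms)
  list(raw = paste(syms, collapse = ""),
       compressed = data.frame(symbol = r$values,
                               count = as.integer(r$lengths),
                               stringsAsFactors = FALSE))
}

#' Encode all proteins of an annotation set
#'
#' @param annotations a [DomainAnnotations-class] object.
#' @param ids optional character vector fixing the proteins (and their
#'   order) in the result; proteins without annotations get the empty
#'   string. Defaults to the ids present in `annotations`.
#' @return an [ArchitectureSet-class] object.
#' @export
encodeArchitectures <- function(annotations, ids = NULL) {
  tab <- domainTable(annotations)
  if (is.null(ids)) ids <- unique(tab$protein_id)
  enc <- lapply(ids, function(id)
    encodeArchitecture(tab[tab$protein_id == id, , drop = FALSE]))
  new("ArchitectureSet",
      proteinIds = as.character(ids),
      raw = vapply(enc, `[[`, "", "raw"),
      compressed = lapply(enc, `[[`, "compressed"))
}

#' Normalised edit distance between architecture strings
#'
#' Levenshtein distance on the raw strings divided by the longer length,
#' giving a metric on `[0, 1]`; two empty strings are at distance 0.
#'
#' @param s1,s2 raw architecture strings.
#' @return unitless distance in `[0, 1]`.
#' @examples
#' stringDistance("ta", "tr")   # 0.5
#' @export
stringDistance <- function(s1, s2) {
  n <- max(nchar(s1), nchar(s2))
  if (n == 0L) return(0)
  as.numeric(utils::adist(s1, s2)) / n
}

#' Pairwise architecture distance matrix
#'
#' @param x an [ArchitectureSet-class] object or character vector of raw
#'   strings (named by protein id).
#' @return symmetric matrix of normalised Levenshtein distances.
#' @export
architectureDistances <- function(x) {
  if (is(x, "ArchitectureSet")) x <- rawArchitecture(x)
  n <- length(x)
  lens <- nchar(x)
  ed <- utils::adist(x)
  denom <- outer(lens, lens, pmax)
  d <- ifelse(denom == 0, 0, ed / denom)
  dimnames(d) <- list(names(x), names(x))
  d
}

#' Density-based clustering of architecture strings
#'
#' Standard DBSCAN over the pairwise normalised-Levenshtein distance
#' matrix. With the defaults used for ALP grouping (`eps = 0.5`,
#' `minPts = 1`) every point is a core point, so the result is exactly
#' the set of connected components of the graph joining string pairs at
#' distance `<= eps`, and there are no noise points. Cluster labels are
#' integers from 1, numbered by first occurrence in input order; with
#' `minPts > 1`, non-core points unreachable from any core point get
#' label 0 (noise).
#'
#' @param x an [ArchitectureSet-class], named character vector of raw
#'   strings, or a precomputed symmetric distance matrix.
#' @param eps neighbourhood radius.
#' @param minPts minimum neighbourhood size (including the point itself)
#'   for a core point.
#' @return data frame with columns `protein_id` and `cluster`, with
#'   attributes `eps`, `min_pts` and `metric`.
#' @export
dbscanCluster <- function(x, eps = 0.5, minPts = 1L) {
  if (is.matrix(x) && is.numeric(x)) {
    d <- x
    ids <- rownames(d)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  } else {
    if (is(x, "ArchitectureSet")) x <- rawArchitecture(x)
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    d <- architectureDistances(setNames(x, ids))
  }
  n <- nrow(d)
  if (n < 1L) stop("need at least one string", call. = FALSE)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= minPts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1]; frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  out <- data.frame(protein_id = ids, cluster = labels,
                    stringsAsFactors = FALSE)
  attr(out, "eps") <- eps
  attr(out, "min_pts") <- as.integer(minPts)
  attr(out, "metric") <- "levenshtein_raw"
  out
}

#' Classify one architecture string into an ALP group
#'
#' Deterministic rule cascade on the non-`t` symbol sequence `sigma` of
#' the raw architecture:
#' 1. no `a` and no `r` in `sigma`: `NOT_ALP` (the protein lacks both the
#'    ABD and RBH domains that define an ALP);
#' 2. `g` present: group `III` when there is no `r`, no `o`, and every
#'    `a` precedes the first `g` (`b` permitted anywhere), otherwise
#'    `OTHERS`;
#' 3. `o` or `b` present: `OTHERS`;
#' 4. both `a` and `r` present: `IA` when `sigma` matches `r+a+` (RBH
#'    block adjacent to the anchor, followed by the ABD repeats),
#'    otherwise `IB`;
#' 5. only `a`: `IIA`; only `r`: `IIB`.
#'
#' Membrane anchors (`t`) never influence the class, so proteins with no
#' MAD, or MADs at either or both termini, classify identically.
#'
#' @param raw a raw architecture string.
#' @return list with elements `class` (one of `IA`, `IB`, `IIA`, `IIB`,
#'   `III`, `OTHERS`, `NOT_ALP`) and `rationale` (which rule fired).
#' @examples
#' classifyArchitecture("traaaaa")$class  # "IA"
#' classifyArchitecture("taar")$class     # "IB"
#' @export
classifyArchitecture <- function(raw) {
  if (length(raw) != 1L || is.na(raw))
    stop("raw must be a character scalar", call. = FALSE)
  if (grepl("[^trabgo]", raw))
    stop("invalid architecture symbol in '", raw, "'", call. = FALSE)
  sigma <- gsub("t", "", raw, fixed = TRUE)
  hasA <- grepl("a", sigma, fixed = TRUE)
  hasR <- grepl("r", sigma, fixed = TRUE)
  if (!hasA && !hasR)
    return(list(class = "NOT_ALP",
                rationale = "rule 1: neither ABD nor RBH present"))
  if (grepl("g", sigma, fixed = TRUE)) {
    noO <- !grepl("o", sigma, fixed = TRUE)
    aPos <- gregexpr("a", sigma, fixed = TRUE)[[1]]
    gFirst <- regexpr("g", sigma, fixed = TRUE)
    aBeforeG <- !hasA || all(aPos < gFirst)
    if (!hasR && noO && aBeforeG)
      return(list(class = "III",
                  rationale = "rule 2: C-terminal transglutaminase after ABDs"))
    return(list(class = "OTHERS",
                rationale = "rule 2: transglutaminase in non-III context"))
  }
  if (grepl("[ob]", sigma))
    return(list(class = "OTHERS",
                rationale = "rule 3: extra domain beyond ABD/RBH/TG"))
  if (hasA && hasR) {
    if (grepl("^r+a+$", sigma))
      return(list(class = "IA",
                  rationale = "rule 4: RBH block then ABD repeats"))
    return(list(class = "IB",
                rationale = "rule 4: ABD/RBH order not fixed"))
  }
  if (hasA)
    return(list(class = "IIA", rationale = "rule 5: ABD only"))
  list(class = "IIB", rationale = "rule 5: RBH only")
}

#' Classify every protein of an architecture set
#'
#' @param arch an [ArchitectureSet-class] object.
#' @return data frame with columns `protein_id`, `raw`, `class`,
#'   `rationale`.
#' @export
classifyProteome <- function(arch) {
  raw <- rawArchitecture(arch)
  res <- lapply(raw, classifyArchitecture)
  data.frame(protein_id = proteinIds(arch),
             raw = unname(raw),
             class = vapply(res, `[[`, "", "class"),
             rationale = vapply(res, `[[`, "", "rationale"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition proteins into accepted ALPs and rejected sequences
#'
#' Sequences whose architecture contains neither an ABD nor an RBH domain
#' are not considered ALPs and are set aside.
#'
#' @param classes data frame as returned by [classifyProteome()], or a
#'   named character vector of classes.
#' @return list with character-vector elements `alps` and `rejected`.
#' @export
filterAlps <- function(classes) {
  if (is.data.frame(classes)) {
    ids <- classes$protein_id
    cls <- classes$class
  } else {
    ids <- names(classes)
    cls <- as.character(classes)
  }
  list(alps = ids[cls != "NOT_ALP"], rejected = ids[cls == "NOT_ALP"])
}
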