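# Percent-identity distances, neighbor-joining with bootstrap, and
# clade-averaged identity tables.

alnCharMatrix <- function(aln) {
  seqs <- as.character(aln)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

pidFromChars <- function(xi, xj) {
  comp <- xi != "-" & xj != "-"
  denom <- sum(comp)
  if (denom == 0L) {
    warning("no comparable columns between a sequence pair; identity 0",
            call. = FALSE)
    return(0)
  }
  100 * sum(comp & xi == xj & xi != "X") / denom
}

#' Percent identity between two gapped rows
#'
#' Pairwise-deletion convention: the denominator counts the columns where
#' both rows carry a residue (neither is a gap), and a column counts as a
#' match when the residues are equal and not the ambiguity code `X`.
#' Pairs with no comparable columns score 0 with a warning.
#'
#' @param rowI,rowJ equal-length gapped sequences (`-` gaps).
#' @return percentage in `[0, 100]`.
#' @examples
#' percentIdentity("AC-T", "AG-T")   # 66.67: columns 1,2,4 compared, 2 match
#' @export
percentIdentity <- function(rowI, rowJ) {
  rowI <- as.character(rowI); rowJ <- as.character(rowJ)
  if (nchar(rowI) != nchar(rowJ))
    stop("gapped rows must have equal length", call. = FALSE)
  pidFromChars(seqChars(rowI), seqChars(rowJ))
}

#' Pairwise percent-identity matrix of an alignment
#'
#' @param aln an `AAStringSet` of equal-width gapped rows, named.
#' @return symmetric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
identityMatrix <- function(aln) {
  m <- alnCharMatrix(aln)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        out[i, j] <- out[j, i] <- pidFromChars(m[i, ], m[j, ])
      }
    }
  }
  out
}

#' Convert percent identity to a distance
#'
#' The simple complement `d = 1 - pid/100` (no multiple-hit correction).
#'
#' @param pid percent identity (scalar, vector or matrix) in `[0, 100]`.
#' @return unitless distance(s) in `[0, 1]`; matrix diagonals stay 0.
#' @export
identityToDistance <- function(pid) {
  if (any(pid < 0 | pid > 100))
    stop("percent identity must lie in [0, 100]", call. = FALSE)
  1 - pid / 100
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimising
#' the Q-criterion is joined (ties broken by the lowest row-major index
#' pair, for reproducibility) with the standard branch-length formulas.
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling edge, so the joined pair's path length is
#' preserved. For an additive distance matrix the returned unrooted tree
#' realises the input exactly. A two-taxon matrix gives a single edge
#' split evenly between the leaves.
#'
#' @param d symmetric distance matrix (or `dist`) with labelled rows.
#' @return an unrooted `phylo` object.
#' @examples
#' d <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)$edge.length   # 0.1, 0.3, 0.5
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2L) {
    h <- fmtBranchLength(d[1, 2] / 2)
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         labs[1], h, labs[2], h)))
  }
  frag <- labs
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest row-major (i, j), i < j, among minima (within tolerance)
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      js <- which(Q[i, (i + 1L):m] <= qmin + 1e-12) + i
      if (length(js)) { best <- c(i, js[1]); break }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; lj <- D[i, j] }
    if (lj < 0) { lj <- 0; li <- D[i, j] }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmtBranchLength(li),
                       frag[j], fmtBranchLength(lj))
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
  }
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmtBranchLength(la),
                 frag[2], fmtBranchLength(lb),
                 frag[3], fmtBranchLength(lc))
  ape::read.tree(text = txt)
}

# Canonical bipartition keys for the internal edges of an unrooted tree:
# each internal node (other than the basal trifurcation) corresponds to
# one internal edge; the side of the split NOT containing the reference
# label is serialised as a sorted, '|'-joined label string.
treeBipartitions <- function(tree, refLabel = NULL) {
  tips <- tree$tip.label
  if (is.null(refLabel)) refLabel <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (refLabel %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from percent-identity distances
#' (`d = 1 - pid/100`), then resamples alignment columns with replacement
#' `nReps` times, rebuilds an NJ tree per replicate, and annotates each
#' internal bipartition of the full-data tree with its replicate
#' frequency as an integer percentage (stored in `node.label`; the basal
#' node carries an empty label). Replicate `r` draws from its own seed
#' substream (`seed + r`), so results are reproducible and independent of
#' any parallel scheduling.
#'
#' @param aln an `AAStringSet` alignment with at least 3 rows.
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @return a `phylo` object with integer percent supports in
#'   `node.label` and the support table in `attr(tree, "supports")`.
#' @export
bootstrapSupport <- function(aln, nReps = 1000L, seed = 1L) {
  if (length(aln) < 3L)
    stop("need at least 3 aligned sequences", call. = FALSE)
  if (nReps < 1L) stop("nReps must be >= 1", call. = FALSE)
  m <- alnCharMatrix(aln)
  L <- ncol(m)
  pidOf <- function(mm) {
    n <- nrow(mm)
    out <- matrix(100, n, n, dimnames = list(rownames(mm), rownames(mm)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n)
        out[i, j] <- out[j, i] <- pidFromChars(mm[i, ], mm[j, ])
    }
    out
  }
  full <- njTree(identityToDistance(pidOf(m)))
  ref <- sort(full$tip.label)[1]
  target <- treeBipartitions(full, ref)
  counts <- setNames(numeric(length(target)), target)
  for (r in seq_len(nReps)) {
    set.seed((as.numeric(seed) + r) %% 2147483647)
    cols <- sample.int(L, L, replace = TRUE)
    bip <- suppressWarnings(
      treeBipartitions(njTree(identityToDistance(pidOf(
        m[, cols, drop = FALSE]))), ref))
    hits <- intersect(bip, target)
    counts[hits] <- counts[hits] + 1
  }
  supports <- round(100 * counts / nReps)
  # map supports onto the full tree's internal nodes
  pp <- ape::prop.part(full)
  labs <- attr(pp, "labels")
  nodeLab <- character(full$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) <= 1L || length(side) >= length(full$tip.label) - 1L)
      next
    if (ref %in% side) side <- setdiff(full$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports))
      nodeLab[k] <- as.character(as.integer(supports[key]))
  }
  full$node.label <- nodeLab
  attr(full, "supports") <- supports
  full
}

#' Clade-averaged identity table
#'
#' Mean percent identities within and between groups of aligned
#' sequences: for distinct groups the mean over all cross pairs, within a
#' group the mean over unordered distinct pairs (missing for singleton
#' groups).
#'
#' @param idm symmetric percent-identity matrix with labelled rows (as
#'   from [identityMatrix()]).
#' @param groups named character vector mapping every id to a group
#'   label.
#' @return data frame with columns `group1`, `group2`, `mean_identity`,
#'   `n_pairs`; within-group rows have `group1 == group2`.
#' @export
cladeIdentityTable <- function(idm, groups) {
  ids <- rownames(idm)
  if (!all(ids %in% names(groups)))
    stop("every id must be assigned a group", call. = FALSE)
  g <- groups[ids]
  glev <- unique(unname(g))
  rows <- NULL
  for (a in seq_along(glev)) {
    for (b in a:length(glev)) {
      ia <- which(g == glev[a]); ib <- which(g == glev[b])
      if (a == b) {
        if (length(ia) < 2L) {
          rows <- rbind(rows, data.frame(
            group1 = glev[a], group2 = glev[b],
            mean_identity = NA_real_, n_pairs = 0L,
            stringsAsFactors = FALSE))
          next
        }
        pairs <- utils::combn(ia, 2L)
        vals <- idm[cbind(pairs[1, ], pairs[2, ])]
      } else {
        vals <- as.numeric(idm[ia, ib])
      }
      rows <- rbind(rows, data.frame(
        group1 = glev[a], group2 = glev[b],
        mean_identity = mean(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE))
    }
  }
  rows
}
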