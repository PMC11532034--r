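# Independent oracles used to cross-check the package implementations.
# Each is deliberately naive (dynamic programming, brute-force summation,
# union-find) and shares no code with the functions under test.

# Levenshtein distance by textbook dynamic programming.
levenshteinDP <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, numeric(m))
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,
                         cur[j] + 1L,
                         prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Hydrophobic moment by explicit trigonometric summation.
momentOracle <- function(segment, scale, deltaDeg = 100) {
  ch <- strsplit(segment, "")[[1]]
  h <- unname(scale[ch])
  k <- seq_along(h) - 1L
  sx <- sum(h * cos(k * deltaDeg * pi / 180))
  sy <- sum(h * sin(k * deltaDeg * pi / 180))
  sqrt(sx^2 + sy^2) / length(h)
}

# Connected components at threshold eps by union-find.
componentsOracle <- function(d, eps) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (d[i, j] <= eps) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

randomArchString <- function(maxLen = 8L) {
  len <- sample(0:maxLen, 1L)
  paste(sample(c("t", "r", "a", "b", "g", "o"), len, replace = TRUE),
        collapse = "")
}

# Random unrooted binary tree with positive branch lengths, returned as
# an ape phylo; its patristic matrix is additive by construction.
randomAdditiveTree <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(nTaxa))
  tr
}

# Fraction of planted intervals recovered by detected intervals at a
# minimum overlap fraction of the planted interval.
recoveryRate <- function(truth, detected, minOverlap = 0.8) {
  if (!nrow(truth)) return(NA_real_)
  hit <- mapply(function(pid, s, e) {
    d <- detected[detected$protein_id == pid, , drop = FALSE]
    if (!nrow(d)) return(FALSE)
    any(pmin(d$end, e) - pmax(d$start, s) + 1 >= minOverlap * (e - s + 1))
  }, truth$protein_id, truth$start, truth$end)
  mean(hit)
}

writeTempFasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}
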