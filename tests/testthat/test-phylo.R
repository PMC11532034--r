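test_that("percent identity uses pairwise deletion and excludes X", {
  expect_equal(percentIdentity("ACDT", "ACDT"), 100)
  expect_equal(percentIdentity("AC-T", "AG-T"), 100 * 2 / 3)
  expect_equal(percentIdentity("AAAA", "CCCC"), 0)
  # X never counts as a match but stays in the denominator
  expect_equal(percentIdentity("AXT", "AXT"), 100 * 2 / 3)
  expect_warning(pid <- percentIdentity("A---", "-CCC"), "no comparable")
  expect_equal(pid, 0)
  expect_error(percentIdentity("AC", "ACD"), "equal length")
  # identity matrix: self identity is 100 given one non-gap residue
  aln <- Biostrings::AAStringSet(c(a = "AC-T", b = "AG-T", c = "ACNT"))
  m <- identityMatrix(aln)
  expect_equal(diag(m), c(a = 100, b = 100, c = 100))
  expect_equal(m, t(m))
})

test_that("identity converts to distance by simple complement", {
  expect_equal(identityToDistance(100), 0)
  expect_equal(identityToDistance(0), 1)
  expect_equal(identityToDistance(66.7), 0.333)
  expect_error(identityToDistance(101), "\\[0, 100\\]")
})

test_that("NJ matches the three-taxon closed form and the 2-taxon split", {
  d <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens, c(A = 0.1, B = 0.3, C = 0.5))

  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  tr2 <- njTree(d2)
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))
  expect_error(njTree(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
  dbad <- d; dbad[1, 2] <- dbad[2, 1] <- NaN
  expect_error(njTree(dbad), "non-finite")
})

test_that("NJ is exact on additive distance matrices", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    tr <- randomAdditiveTree(n)
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    est <- njTree(dm)
    # identical unrooted topology
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est))[1], 0)
    # patristic distances reproduced to numerical precision
    dEst <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(dEst - dm)), 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on random input", {
  set.seed(55)
  for (k in 1:10) {
    n <- sample(5:9, 1)
    m <- matrix(stats::runif(n * n, 0.1, 1), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- njTree(m)
    ref <- ape::nj(as.dist(m))
    expect_equal(ape::dist.topo(mine, ref)[1], 0)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  sim <- generateAbdAlignment(nSeqs = 5, nInvariantGly = 4,
                              cladeLabels = c(1, 1, 2, 2, 2),
                              nColumns = 120, substitutionRate = 0.03,
                              cladeDivergence = 0.6, seed = 5)
  tr1 <- bootstrapSupport(sim$alignment, nReps = 200, seed = 17)
  tr2 <- bootstrapSupport(sim$alignment, nReps = 200, seed = 17)
  expect_identical(attr(tr1, "supports"), attr(tr2, "supports"))
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # the clearly separated clade reaches near-unanimous support
  expect_gte(max(attr(tr1, "supports")), 95)
  # one duplicated column: every resample reproduces the same alignment,
  # so every bipartition is unanimous
  col <- c(a = "A", b = "A", c = "C", d = "C", e = "G")
  wide <- Biostrings::AAStringSet(vapply(col,
                                         function(s) strrep(s, 30), ""))
  names(wide) <- names(col)
  trw <- bootstrapSupport(wide, nReps = 50, seed = 3)
  sup <- attr(trw, "supports")
  expect_gte(length(sup), 1L)
  expect_true(all(sup == 100))
  expect_error(bootstrapSupport(wide, nReps = 0, seed = 1), ">= 1")
})

test_that("clade identity tables average within and between groups", {
  aln <- Biostrings::AAStringSet(c(a1 = "AAAA", a2 = "AAAA",
                                   b1 = "CCCC", b2 = "CCCC"))
  idm <- identityMatrix(aln)
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  tab <- cladeIdentityTable(idm, groups)
  within <- tab[tab$group1 == tab$group2, ]
  expect_equal(within$mean_identity, c(100, 100))
  between <- tab[tab$group1 != tab$group2, ]
  expect_equal(between$mean_identity, 0)

  # hand-built 4-sequence, 2-group matrix vs direct averaging
  m <- matrix(c(100, 90, 30, 40,
                90, 100, 50, 60,
                30, 50, 100, 80,
                40, 60, 80, 100), 4, byrow = TRUE,
              dimnames = list(c("p", "q", "r", "s"),
                              c("p", "q", "r", "s")))
  g <- c(p = "G1", q = "G1", r = "G2", s = "G2")
  tab2 <- cladeIdentityTable(m, g)
  expect_equal(tab2$mean_identity[tab2$group1 == "G1" &
                                    tab2$group2 == "G1"], 90)
  expect_equal(tab2$mean_identity[tab2$group1 == "G2" &
                                    tab2$group2 == "G2"], 80)
  expect_equal(tab2$mean_identity[tab2$group1 == "G1" &
                                    tab2$group2 == "G2"],
               mean(c(30, 40, 50, 60)))
  # singleton groups have no within-group mean
  g2 <- c(p = "solo", q = "rest", r = "rest", s = "rest")
  tab3 <- cladeIdentityTable(m, g2)
  expect_true(is.na(tab3$mean_identity[tab3$group1 == "solo" &
                                         tab3$group2 == "solo"]))
  expect_error(cladeIdentityTable(m, c(p = "x")), "every id")
})
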