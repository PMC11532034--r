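archOf <- function(types) {
  encodeArchitecture(data.frame(domain_type = types,
                                start = seq(1, by = 200,
                                            length.out = length(types))))
}

test_that("domain annotations encode to the letter string in start order", {
  enc <- archOf(c("MAD", "RBH", rep("ABD", 5)))
  expect_equal(enc$raw, "traaaaa")
  expect_equal(enc$compressed$symbol, c("t", "r", "a"))
  expect_equal(enc$compressed$count, c(1L, 1L, 5L))

  expect_equal(encodeArchitecture(NULL)$raw, "")

  # seven RBH repeats then 18 ABDs compresses to (t,1)(r,7)(a,18)
  enc2 <- archOf(c("MAD", rep("RBH", 7), rep("ABD", 18)))
  expect_equal(enc2$compressed$symbol, c("t", "r", "a"))
  expect_equal(enc2$compressed$count, c(1L, 7L, 18L))

  # order comes from start positions, not input row order
  ann <- data.frame(domain_type = c("ABD", "MAD", "RBH"),
                    start = c(300L, 1L, 40L))
  expect_equal(encodeArchitecture(ann)$raw, "tra")
  expect_error(encodeArchitecture(
    data.frame(domain_type = "BLOB", start = 1L)), "unknown domain_type")
})

test_that("normalised Levenshtein distance matches the DP oracle", {
  expect_equal(stringDistance("traaa", "traaa"), 0)
  expect_equal(stringDistance("ta", "tr"), 0.5)
  expect_equal(stringDistance("", "ta"), 1)
  expect_equal(stringDistance("", ""), 0)
  set.seed(99)
  for (k in 1:60) {
    a <- randomArchString(); b <- randomArchString()
    n <- max(nchar(a), nchar(b))
    expected <- if (n == 0) 0 else levenshteinDP(a, b) / n
    expect_equal(stringDistance(a, b), expected)
  }
})

test_that("the architecture distance is a metric", {
  set.seed(123)
  strs <- replicate(12, randomArchString())
  d <- architectureDistances(setNames(strs, paste0("p", 1:12)))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # triangle inequality on all triples
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("DBSCAN at minPts 1 equals connected components at eps", {
  strs <- c(a = "traaa", b = "traa", c = "ooooo")
  cl <- dbscanCluster(strs, eps = 0.5, minPts = 1)
  expect_equal(cl$cluster, c(1L, 1L, 2L))

  # identical strings collapse to one cluster; no noise with minPts 1
  same <- setNames(rep("traa", 5), paste0("p", 1:5))
  expect_equal(unique(dbscanCluster(same)$cluster), 1L)

  set.seed(2024)
  for (rep in 1:5) {
    strs <- setNames(replicate(50, randomArchString()),
                     paste0("p", 1:50))
    d <- architectureDistances(strs)
    cl <- dbscanCluster(strs, eps = 0.5, minPts = 1)
    expect_true(all(cl$cluster >= 1L))
    oracle <- componentsOracle(d, 0.5)
    # same partition up to label names
    expect_equal(cl$cluster, oracle)
  }
})

test_that("DBSCAN with larger minPts can produce noise points", {
  # two far-apart singletons and one tight triple
  strs <- c(a = "aaaa", b = "aaar", c = "aaaa", d = "gggg", e = "totototo")
  cl <- dbscanCluster(strs, eps = 0.25, minPts = 3)
  expect_equal(sum(cl$cluster == 0L), 2L)
  expect_equal(length(unique(cl$cluster[cl$cluster > 0])), 1L)
})

test_that("the classification cascade reproduces the group definitions", {
  cases <- list(
    list("traaaaa", "IA"),   # RBH adjacent to anchor, then ABD repeats
    list("taar",    "IB"),   # ABDs N-terminal to the RBH
    list("tarar",   "IB"),   # interleaved ABD/RBH
    list("taaag",   "III"),  # ABDs then C-terminal transglutaminase
    list("taabg",   "III"),  # pseudomurein-binding allowed beside TG
    list("taaa",    "IIA"),
    list("trr",     "IIB"),
    list("t",       "NOT_ALP"),
    list("",        "NOT_ALP"),
    list("traao",   "OTHERS"),
    list("tab",     "OTHERS"),  # PMB outside a TG context
    list("trg",     "OTHERS"),  # TG beside RBH is not group III
    list("tgaa",    "OTHERS"),  # ABD after the TG
    list("tag",     "III"))
  for (cs in cases)
    expect_equal(classifyArchitecture(cs[[1]])$class, cs[[2]],
                 label = sprintf("classify('%s')", cs[[1]]))
  # anchors never matter: stripping or adding t leaves the class fixed
  for (cs in cases) {
    noT <- gsub("t", "", cs[[1]])
    expect_equal(classifyArchitecture(noT)$class,
                 classifyArchitecture(paste0("t", noT, "t"))$class)
  }
})

test_that("classification is invariant to annotation input order", {
  set.seed(8)
  types <- c("MAD", "RBH", "RBH", rep("ABD", 4), "TG")
  starts <- seq(1, by = 150, length.out = length(types))
  base <- encodeArchitecture(data.frame(domain_type = types,
                                        start = starts))
  for (k in 1:10) {
    perm <- sample(length(types))
    enc <- encodeArchitecture(data.frame(domain_type = types[perm],
                                         start = starts[perm]))
    expect_equal(enc$raw, base$raw)
    expect_equal(classifyArchitecture(enc$raw)$class,
                 classifyArchitecture(base$raw)$class)
  }
})

test_that("ALP filtering separates decoys from classified proteins", {
  classes <- data.frame(protein_id = c("p1", "p2", "p3"),
                        class = c("IA", "NOT_ALP", "IIB"))
  parts <- filterAlps(classes)
  expect_setequal(parts$alps, c("p1", "p3"))
  expect_equal(parts$rejected, "p2")

  allBad <- data.frame(protein_id = c("a", "b"),
                       class = c("NOT_ALP", "NOT_ALP"))
  expect_equal(filterAlps(allBad)$alps, character(0))

  # planted domain-free decoys are exactly the rejected set
  out <- generateProteome(syntheticSpec(nProteins = 70L, seed = 21L))
  arch <- encodeArchitectures(out$domains, ids = names(out$proteins))
  parts <- filterAlps(classifyProteome(arch))
  truthDecoys <- out$truth$classes$protein_id[
    out$truth$classes$class == "NOT_ALP"]
  expect_setequal(parts$rejected, truthDecoys)
})
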