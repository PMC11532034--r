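test_that("spec validation rejects impossible parameter sets", {
  expect_error(syntheticSpec(decoyWeight = 0.5), "sum to 1")
  expect_error(syntheticSpec(tmLenRange = c(28L, 20L)), "range")
  expect_error(syntheticSpec(asnThrBoost = 0.5), ">= 1")
  expect_silent(s <- syntheticSpec(nProteins = 5L))
  expect_s4_class(s, "SyntheticSpec")
})

test_that("generation is byte-deterministic under a fixed seed", {
  spec <- syntheticSpec(nProteins = 25L, seed = 42L)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  writeSimulatedProteome(spec, d1)
  writeSimulatedProteome(spec, d2)
  for (f in c("proteins.fasta", "domains.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  # a different seed changes the output
  writeSimulatedProteome(syntheticSpec(nProteins = 25L, seed = 43L), d2)
  expect_false(identical(readLines(file.path(d1, "proteins.fasta")),
                         readLines(file.path(d2, "proteins.fasta"))))
})

test_that("single-class specs generate architectures of that class only", {
  onlyIA <- syntheticSpec(nProteins = 30L,
                          groupWeights = c(IA = 1, IB = 0, IIA = 0,
                                           IIB = 0, III = 0, OTHERS = 0),
                          decoyWeight = 0, seed = 7L)
  out <- generateProteome(onlyIA)
  arch <- encodeArchitectures(out$domains, ids = names(out$proteins))
  sigma <- gsub("t", "", rawArchitecture(arch))
  expect_true(all(grepl("^r+a+$", sigma)))
  expect_true(all(classifyProteome(arch)$class == "IA"))

  # pure decoys: everything is NOT_ALP and carries no domains
  decoys <- syntheticSpec(nProteins = 10L,
                          groupWeights = c(IA = 0, IB = 0, IIA = 0,
                                           IIB = 0, III = 0, OTHERS = 0),
                          decoyWeight = 1, seed = 7L)
  outD <- generateProteome(decoys)
  expect_equal(length(outD$domains), 0L)
  archD <- encodeArchitectures(outD$domains, ids = names(outD$proteins))
  expect_true(all(classifyProteome(archD)$class == "NOT_ALP"))
})

test_that("generated truth is internally consistent", {
  out <- generateProteome(syntheticSpec(nProteins = 60L, seed = 19L))
  tab <- domainTable(out$domains)
  lens <- setNames(Biostrings::width(out$proteins), names(out$proteins))
  # intervals lie within sequence bounds
  expect_true(all(tab$start >= 1L))
  expect_true(all(tab$end <= lens[tab$protein_id]))
  # the emitted architecture classifies to the emitted label
  arch <- encodeArchitectures(out$domains, ids = names(out$proteins))
  cls <- classifyProteome(arch)
  expect_equal(cls$class, out$truth$classes$class)
  # planted anchor intervals coincide with the MAD annotations
  mads <- tab[tab$domain_type == "MAD", c("protein_id", "start", "end")]
  anchors <- out$truth$anchors[, c("protein_id", "start", "end")]
  expect_equal(mads[order(mads$protein_id, mads$start), ],
               anchors[order(anchors$protein_id, anchors$start), ],
               ignore_attr = TRUE)
  # lengths stay in the repertoire's reported scale
  expect_true(all(lens >= 100))
})

test_that("synthetic ABD alignments plant recoverable structure", {
  expect_error(generateAbdAlignment(1), "at least 2")
  expect_error(generateAbdAlignment(5, nInvariantGly = 100,
                                    nColumns = 50), "exceeds")
  # zero substitutions, single clade: all identities 100
  sim0 <- generateAbdAlignment(nSeqs = 6, nInvariantGly = 3,
                               nColumns = 60, substitutionRate = 0,
                               seed = 2)
  expect_true(all(identityMatrix(sim0$alignment) == 100))
  # invariant glycine columns carry G in every sequence
  sim <- generateAbdAlignment(nSeqs = 12, nInvariantGly = 6,
                              nColumns = 70, substitutionRate = 0.15,
                              seed = 3)
  m <- do.call(rbind, strsplit(as.character(sim$alignment), ""))
  for (j in sim$truth$invariantColumns)
    expect_true(all(m[, j] == "G"))
  # two divergent clades split with strong bootstrap support
  sim2 <- generateAbdAlignment(nSeqs = 5, nInvariantGly = 4,
                               cladeLabels = c(1, 1, 2, 2, 2),
                               nColumns = 120, substitutionRate = 0.03,
                               cladeDivergence = 0.6, seed = 5)
  tr <- bootstrapSupport(sim2$alignment, nReps = 200, seed = 1)
  cl <- sim2$truth$cladeLabels
  labs <- names(cl)
  # the canonical bipartition key is the side not holding the first label
  ref <- sort(labs)[1]
  offSide <- labs[cl != cl[match(ref, labs)]]
  key <- paste(sort(offSide), collapse = "|")
  sup <- attr(tr, "supports")
  expect_true(key %in% names(sup))
  expect_gte(sup[[key]], 95)
})

test_that("the CLI driver simulates, classifies and summarises", {
  outDir <- file.path(tempdir(), "cli_sim")
  alpscanMain(c("simulate", "--n", "20", "--seed", "42",
                "--out-dir", outDir))
  expect_true(file.exists(file.path(outDir, "proteins.fasta")))
  clsFile <- tempfile(fileext = ".tsv")
  alpscanMain(c("classify", "--domains",
                file.path(outDir, "domains.tsv"), "--out", clsFile))
  cls <- utils::read.delim(clsFile)
  expect_true(all(cls$class %in%
                    c("IA", "IB", "IIA", "IIB", "III", "OTHERS",
                      "NOT_ALP")))
  statFile <- tempfile(fileext = ".tsv")
  alpscanMain(c("stats", "--in", file.path(outDir, "proteins.fasta"),
                "--genome-size", "1853000", "--out", statFile))
  stats <- utils::read.delim(statFile)
  expect_equal(stats$n_alps, 20L)
  expect_error(alpscanMain(c("frobnicate")), "unknown subcommand")
  expect_error(alpscanMain(c("classify")), "--domains")
})
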