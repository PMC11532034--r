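polyCtx <- function(n) strrep("S", n)

test_that("TM scan finds planted anchors and nothing in polar sequence", {
  expect_equal(nrow(detectTMSegments(polyCtx(100), "p")), 0L)
  # planted 23-mer poly-Leu at 5-27 in poly-Ser
  s <- paste0(polyCtx(4), strrep("L", 23), polyCtx(73))
  tm <- detectTMSegments(s, "p")
  expect_equal(nrow(tm), 1L)
  expect_equal(tm$kind, "TM")
  ov <- min(tm$end, 27) - max(tm$start, 5) + 1
  expect_gte(ov / 23, 0.9)
  expect_equal(tm$terminal, "N")
  # sequence shorter than the window gives an empty result, not an error
  expect_equal(nrow(detectTMSegments("MKT", "p")), 0L)
})

test_that("anchors planted at both termini are found with N and C labels", {
  s <- paste0(polyCtx(5), strrep("L", 24), polyCtx(150),
              strrep("I", 24), polyCtx(5))
  tm <- detectTMSegments(s, "p")
  expect_equal(nrow(tm), 2L)
  expect_setequal(tm$terminal, c("N", "C"))
})

test_that("short hydrophobic helices are detected in terminal regions", {
  # the classic 12-mer in a polar context: short helix, not a TM
  s <- paste0("SS", "LLFILLIVLLFI", polyCtx(80))
  tm <- detectTMSegments(s, "p")
  expect_equal(nrow(tm), 0L)
  sh <- detectShortHydrophobic(s, "p", tm = tm)
  expect_equal(nrow(sh), 1L)
  expect_gt(sh$mean_hydrophobicity, 1)
  expect_gte(min(sh$end, 14) - max(sh$start, 3) + 1, 6)

  # poly-Gly scores 0 on the Fauchere-Pliska scale: nothing to find
  expect_equal(nrow(detectShortHydrophobic(strrep("G", 80), "p")), 0L)

  # a 23-mer hydrophobic stretch belongs to the TM detector instead
  s2 <- paste0(polyCtx(4), strrep("L", 23), polyCtx(73))
  tm2 <- detectTMSegments(s2, "p")
  sh2 <- detectShortHydrophobic(s2, "p", tm = tm2)
  expect_equal(nrow(tm2), 1L)
  ovl <- function(a, b) min(a$end, b$end) - max(a$start, b$start) + 1
  if (nrow(sh2) > 0)
    expect_true(all(apply(sh2, 1, function(r)
      ovl(as.list(as.numeric(r[c("start", "end")])), tm2) <= 0)))
})

test_that("amphipathic windows are scored by hydrophobic moment", {
  # an 18-mer homopolymer terminus has moment 0: no candidate
  expect_equal(nrow(detectAmphipathic(paste0(strrep("L", 18),
                                             polyCtx(60)), "p",
                                      tm = detectTMSegments(
                                        paste0(strrep("L", 18),
                                               polyCtx(60)), "p"))), 0L)
  # ideal amphipathic 18-mer: hydrophobic face every 3-4 positions
  face <- c(0, 3, 4, 7, 11, 14, 15) + 1
  res <- rep("N", 18); res[face] <- "L"
  s <- paste0(paste(res, collapse = ""), polyCtx(100))
  am <- detectAmphipathic(s, "p")
  expect_gte(nrow(am), 1L)
  expect_gte(max(am$hydrophobic_moment), 0.5)
  # an amphipathic-only anchor is reported even with zero TM segments
  expect_equal(nrow(detectTMSegments(s, "p")), 0L)
})

test_that("di-basic motifs near TM helices are classified", {
  mkTm <- function(start, end, terminal)
    data.frame(protein_id = "p", start = start, end = end, kind = "TM",
               mean_hydrophobicity = 3, hydrophobic_moment = 0,
               terminal = terminal, stringsAsFactors = FALSE)
  s <- paste0("MKK", strrep("L", 25), polyCtx(60))
  mo <- scanDibasicMotifs(s, mkTm(4, 28, "N"), "p")
  expect_equal(mo$motif_class, "DI_LYSINE")
  expect_equal(mo$position, 2L)
  expect_equal(mo$side, "upstream_of_N_helix")

  s2 <- paste0("MKN", strrep("L", 25), polyCtx(60))
  expect_equal(scanDibasicMotifs(s2, mkTm(4, 28, "N"), "p")$motif_class,
               "LYS_ASN")
  # arginine/aspartate variants
  s3 <- paste0("MRD", strrep("L", 25), polyCtx(60))
  expect_equal(scanDibasicMotifs(s3, mkTm(4, 28, "N"), "p")$motif_class,
               "OTHER_VARIANT")
  # no basic residues in the flank: nothing reported
  s4 <- paste0("MSS", strrep("L", 25), polyCtx(60))
  expect_equal(nrow(scanDibasicMotifs(s4, mkTm(4, 28, "N"), "p")), 0L)
  # C-terminal helices are scanned downstream
  s5 <- paste0(polyCtx(60), strrep("L", 25), "KKSS")
  mo5 <- scanDibasicMotifs(s5, mkTm(61, 85, "C"), "p")
  expect_equal(mo5$side, "downstream_of_C_helix")
  expect_equal(mo5$motif_class, "DI_LYSINE")
})

test_that("callMads unions candidate kinds and tolerates empty input", {
  tm <- detectTMSegments(paste0(polyCtx(4), strrep("L", 23),
                                polyCtx(73)), "p")
  sh <- detectShortHydrophobic(paste0("SS", "LLFILLIVLLFI",
                                      polyCtx(80)), "q")
  mads <- callMads(tm = tm, short = sh)
  tab <- domainTable(mads)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$domain_type == "MAD"))
  expect_true(all(tab$source == "detected"))
  # zero candidates give a valid empty annotation set
  expect_equal(length(callMads()), 0L)
})

test_that("planted anchors are recovered across a synthetic proteome", {
  out <- generateProteome(syntheticSpec(nProteins = 60L, seed = 11L))
  ann <- annotateProteome(out$proteins)
  tmTruth <- out$truth$anchors[out$truth$anchors$kind == "TM", ]
  det <- ann$candidates[ann$candidates$kind == "TM", ]
  expect_gte(recoveryRate(tmTruth, det, minOverlap = 0.8), 0.95)
  # every planted anchor of any kind surfaces in the MAD union
  madTab <- domainTable(ann$mads)
  expect_gte(recoveryRate(out$truth$anchors, madTab, minOverlap = 0.5),
             0.95)
  # planted di-basic pairs are found beside their helices
  mo <- ann$motifs
  found <- mapply(function(pid, pos) {
    any(mo$protein_id == pid & abs(mo$position - pos) <= 8)
  }, out$truth$motifs$protein_id, out$truth$motifs$position)
  expect_gte(mean(found), 0.9)
})
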