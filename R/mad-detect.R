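# Membrane-anchor detection: transmembrane helices by Kyte-Doolittle
# window scanning, short hydrophobic helices and amphipathic helices in
# the terminal regions, plus the di-basic motifs that flank TM helices on
# the cytoplasmic side.

emptyCandidates <- function() {
  data.frame(protein_id = character(0), start = integer(0),
             end = integer(0), kind = character(0),
             mean_hydrophobicity = numeric(0),
             hydrophobic_moment = numeric(0),
             terminal = character(0), stringsAsFactors = FALSE)
}

candidateRow <- function(proteinId, start, end, kind, seq, L,
                         terminalSpan = 60L) {
  fp <- hydrophobicityScale("fauchere-pliska")
  segment <- substr(seq, start, end)
  terminal <- if (start <= 40L && (L - end) <= 39L) {
    if ((start - 1L) <= (L - end)) "N" else "C"
  } else if (start <= 40L) "N"
  else if (end >= L - 39L) "C"
  else "internal"
  data.frame(protein_id = proteinId, start = as.integer(start),
             end = as.integer(end), kind = kind,
             mean_hydrophobicity = meanHydrophobicity(segment, fp),
             hydrophobic_moment = hydrophobicMoment(segment, fp),
             terminal = terminal, stringsAsFactors = FALSE)
}

overlapLen <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# fraction of [s1,e1] covered by [s2,e2]
overlapFrac <- function(s1, e1, s2, e2) {
  overlapLen(s1, e1, s2, e2) / (e1 - s1 + 1L)
}

#' Detect transmembrane helix candidates
#'
#' Slides a centred Kyte-Doolittle window along the sequence and finds
#' maximal runs of window means above the threshold; each run is expanded
#' to the union of its qualifying windows (clipped to the sequence) and
#' overlapping runs are merged. With the classic hydropathy-plot settings
#' (window 19, threshold 1.6) a planted 20-28-residue hydrophobic stretch
#' in a polar context is recovered as a single candidate. A candidate is
#' terminal `N` when it starts within the first 40 residues and `C` when
#' it ends within the last 40.
#'
#' A window mean can cross the threshold on the strength of a hydrophobic
#' stretch far too short to span the membrane, so each merged run is
#' trimmed to its longest contiguous core of residues scoring
#' `coreCutoff` or better and reported only when that core reaches
#' `minCoreLen` residues; shorter hydrophobic stretches are left for
#' [detectShortHydrophobic()] to pick up. Trimming to the core also keeps
#' the reported boundaries close to the underlying helix, which matters
#' when [scanDibasicMotifs()] scans the flanking residues.
#'
#' @param sequence protein sequence (character scalar or `AAString`).
#' @param proteinId id recorded in the output.
#' @param window odd window length, residues.
#' @param threshold Kyte-Doolittle window-mean cutoff.
#' @param minCoreLen minimum length of the contiguous hydrophobic core.
#' @param coreCutoff per-residue Kyte-Doolittle score counted as core.
#' @return data frame of candidates (`kind = "TM"`); zero rows when the
#'   sequence is shorter than the window or nothing crosses the threshold.
#' @examples
#' s <- paste0(strrep("S", 4), strrep("L", 23), strrep("S", 73))
#' detectTMSegments(s, "toy")
#' @export
detectTMSegments <- function(sequence, proteinId = "protein",
                             window = 19L, threshold = 1.6,
                             minCoreLen = 17L, coreCutoff = 1.0) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  if (L < window) return(emptyCandidates())
  kd <- hydrophobicityScale("kyte-doolittle")
  scores <- scoreResidues(seqChars(seq), kd)
  hw <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(scores, rep(1 / window, window),
                                    sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (!length(centers)) return(emptyCandidates())
  # maximal runs of qualifying centers
  breaks <- which(diff(centers) > 1L)
  runStart <- centers[c(1L, breaks + 1L)]
  runEnd <- centers[c(breaks, length(centers))]
  starts <- pmax(1L, runStart - hw)
  ends <- pmin(L, runEnd + hw)
  # merge expanded intervals that overlap
  keepS <- starts[1]; keepE <- ends[1]
  if (length(starts) > 1L) {
    for (k in 2L:length(starts)) {
      last <- length(keepS)
      if (starts[k] <= keepE[last] + 1L) {
        keepE[last] <- max(keepE[last], ends[k])
      } else {
        keepS <- c(keepS, starts[k]); keepE <- c(keepE, ends[k])
      }
    }
  }
  # trim each run to its longest hydrophobic core; discard short cores
  cores <- lapply(seq_along(keepS), function(k) {
    idx <- keepS[k]:keepE[k]
    r <- rle(scores[idx] >= coreCutoff)
    if (!any(r$values & r$lengths >= minCoreLen)) return(NULL)
    ends <- cumsum(r$lengths)
    best <- which(r$values & r$lengths == max(r$lengths[r$values]))[1]
    c(idx[ends[best] - r$lengths[best] + 1L], idx[ends[best]])
  })
  cores <- cores[!vapply(cores, is.null, TRUE)]
  if (!length(cores)) return(emptyCandidates())
  do.call(rbind, lapply(cores, function(core)
    candidateRow(proteinId, core[1], core[2], "TM", seq, L)))
}

#' Detect short hydrophobic helix candidates at the termini
#'
#' Short (10-19 residue) stretches of hydrophobic residues that do not
#' span the membrane but can still anchor a protein. Within the first and
#' last `terminalSpan` residues, all segments with length in
#' `[minLen, maxLen]` and Fauchere-Pliska mean hydrophobicity above
#' `indexMin` are enumerated; only maximal segments (not contained in a
#' longer qualifying segment) are kept, segments overlapping a TM
#' candidate by 50% or more are dropped (TM takes precedence), and
#' remaining overlapping segments are resolved greedily by descending mean
#' hydrophobicity.
#'
#' @param sequence protein sequence.
#' @param proteinId id recorded in the output.
#' @param terminalSpan width of the terminal regions scanned, residues.
#' @param minLen,maxLen segment length bounds.
#' @param indexMin Fauchere-Pliska mean cutoff (short anchoring helices
#'   typically score > 1).
#' @param tm optional data frame of TM candidates for the same protein.
#' @return data frame of candidates (`kind = "SHORT_HYDROPHOBIC"`).
#' @export
detectShortHydrophobic <- function(sequence, proteinId = "protein",
                                   terminalSpan = 60L, minLen = 10L,
                                   maxLen = 19L, indexMin = 1.0,
                                   tm = NULL) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  if (L < minLen) return(emptyCandidates())
  fp <- hydrophobicityScale("fauchere-pliska")
  scores <- scoreResidues(seqChars(seq), fp)
  cum <- c(0, cumsum(scores))
  regions <- unique(rbind(
    c(1L, min(L, terminalSpan)),
    c(max(1L, L - terminalSpan + 1L), L)))
  cand <- NULL
  for (r in seq_len(nrow(regions))) {
    lo <- regions[r, 1]; hi <- regions[r, 2]
    for (len in seq(min(maxLen, hi - lo + 1L), minLen)) {
      if (len < minLen) break
      for (s in lo:(hi - len + 1L)) {
        e <- s + len - 1L
        m <- (cum[e + 1L] - cum[s]) / len
        if (m > indexMin)
          cand <- rbind(cand, data.frame(start = s, end = e, mean = m))
      }
    }
  }
  if (is.null(cand)) return(emptyCandidates())
  cand <- unique(cand)
  # maximality: drop segments strictly contained in another qualifying one
  contained <- vapply(seq_len(nrow(cand)), function(k) {
    any(cand$start <= cand$start[k] & cand$end >= cand$end[k] &
          (cand$start < cand$start[k] | cand$end > cand$end[k]))
  }, logical(1))
  cand <- cand[!contained, , drop = FALSE]
  # TM precedence
  if (!is.null(tm) && nrow(tm)) {
    hit <- vapply(seq_len(nrow(cand)), function(k)
      any(mapply(function(ts, te)
        overlapFrac(cand$start[k], cand$end[k], ts, te) >= 0.5,
        tm$start, tm$end)), logical(1))
    cand <- cand[!hit, , drop = FALSE]
  }
  if (!nrow(cand)) return(emptyCandidates())
  # greedy overlap resolution by descending mean
  cand <- cand[order(-cand$mean, cand$start), , drop = FALSE]
  kept <- cand[1, , drop = FALSE]
  for (k in seq_len(nrow(cand))[-1]) {
    if (!any(mapply(function(s, e)
      overlapLen(cand$start[k], cand$end[k], s, e) > 0,
      kept$start, kept$end)))
      kept <- rbind(kept, cand[k, , drop = FALSE])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(kept)), function(k)
    candidateRow(proteinId, kept$start[k], kept$end[k],
                 "SHORT_HYDROPHOBIC", seq, L)))
}

#' Detect amphipathic helix candidates at the termini
#'
#' HeliQuest-style scan: every `window`-residue (default 18) window lying
#' inside the terminal regions is scored by its Eisenberg hydrophobic
#' moment on the Fauchere-Pliska scale; windows with moment at or above
#' `muMin` are candidates. Windows overlapping a TM or short-hydrophobic
#' candidate by 50% or more are dropped (those kinds take precedence), and
#' overlapping amphipathic windows are merged keeping the maximal-moment
#' one.
#'
#' @param sequence protein sequence.
#' @param proteinId id recorded in the output.
#' @param window window length, residues.
#' @param muMin hydrophobic-moment cutoff.
#' @param terminalSpan width of the terminal regions scanned, residues.
#' @param tm,short optional candidate data frames given precedence.
#' @return data frame of candidates (`kind = "AMPHIPATHIC"`).
#' @export
detectAmphipathic <- function(sequence, proteinId = "protein",
                              window = 18L, muMin = 0.5,
                              terminalSpan = 60L, tm = NULL,
                              short = NULL) {
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  if (L < window) return(emptyCandidates())
  fp <- hydrophobicityScale("fauchere-pliska")
  regions <- unique(rbind(
    c(1L, min(L, terminalSpan)),
    c(max(1L, L - terminalSpan + 1L), L)))
  cand <- NULL
  for (r in seq_len(nrow(regions))) {
    lo <- regions[r, 1]; hi <- regions[r, 2]
    if (hi - lo + 1L < window) next
    for (s in lo:(hi - window + 1L)) {
      e <- s + window - 1L
      mu <- hydrophobicMoment(substr(seq, s, e), fp)
      if (mu >= muMin)
        cand <- rbind(cand, data.frame(start = s, end = e, mu = mu))
    }
  }
  if (is.null(cand)) return(emptyCandidates())
  cand <- unique(cand)
  blockers <- rbind(if (!is.null(tm)) tm[, c("start", "end")],
                    if (!is.null(short)) short[, c("start", "end")])
  if (!is.null(blockers) && nrow(blockers)) {
    hit <- vapply(seq_len(nrow(cand)), function(k)
      any(mapply(function(s, e)
        overlapFrac(cand$start[k], cand$end[k], s, e) >= 0.5,
        blockers$start, blockers$end)), logical(1))
    cand <- cand[!hit, , drop = FALSE]
  }
  if (!nrow(cand)) return(emptyCandidates())
  cand <- cand[order(-cand$mu, cand$start), , drop = FALSE]
  kept <- cand[1, , drop = FALSE]
  for (k in seq_len(nrow(cand))[-1]) {
    if (!any(mapply(function(s, e)
      overlapLen(cand$start[k], cand$end[k], s, e) > 0,
      kept$start, kept$end)))
      kept <- rbind(kept, cand[k, , drop = FALSE])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(kept)), function(k)
    candidateRow(proteinId, kept$start[k], kept$end[k],
                 "AMPHIPATHIC", seq, L)))
}

DIBASIC_PAIRS <- {
  other <- as.vector(outer(c("K", "R"), c("K", "R", "N", "D"), paste0))
  setdiff(other, c("KK", "KN"))
}

#' Scan for di-basic motifs flanking TM helices
#'
#' Di-lysine (`KK`) and variant pairs on the presumed cytoplasmic side of
#' a transmembrane helix act as orientation/sorting signals. For each
#' N-terminal-side TM candidate the `flank` residues immediately upstream
#' of the helix start are scanned left to right, and for each
#' C-terminal-side TM the `flank` residues downstream of the helix end;
#' the first matching pair is reported as `DI_LYSINE` (`KK`), `LYS_ASN`
#' (`KN`/`NK`) or `OTHER_VARIANT` (remaining pairs from \{K,R\} x
#' \{K,R,N,D\}).
#'
#' @param sequence protein sequence.
#' @param tm data frame of TM candidates for the protein (as from
#'   [detectTMSegments()]).
#' @param proteinId id recorded in the output.
#' @param flank scan-window width, residues.
#' @return data frame with columns `protein_id`, `position`, `pair`,
#'   `motif_class`, `side`, `tm_start`, `tm_end`.
#' @examples
#' tm <- detectTMSegments(paste0("MKK", strrep("L", 25), strrep("S", 60)),
#'                        "toy")
#' scanDibasicMotifs(paste0("MKK", strrep("L", 25), strrep("S", 60)), tm,
#'                   "toy")
#' @export
scanDibasicMotifs <- function(sequence, tm, proteinId = "protein",
                              flank = 10L) {
  out <- data.frame(protein_id = character(0), position = integer(0),
                    pair = character(0), motif_class = character(0),
                    side = character(0), tm_start = integer(0),
                    tm_end = integer(0), stringsAsFactors = FALSE)
  if (is.null(tm) || !nrow(tm)) return(out)
  seq <- toupper(as.character(sequence))
  L <- nchar(seq)
  classify <- function(pair) {
    if (pair == "KK") "DI_LYSINE"
    else if (pair %in% c("KN", "NK")) "LYS_ASN"
    else if (pair %in% DIBASIC_PAIRS) "OTHER_VARIANT"
    else NA_character_
  }
  for (k in seq_len(nrow(tm))) {
    if (tm$terminal[k] == "N") {
      lo <- max(1L, tm$start[k] - flank); hi <- tm$start[k] - 1L
      side <- "upstream_of_N_helix"
    } else if (tm$terminal[k] == "C") {
      lo <- tm$end[k] + 1L; hi <- min(L, tm$end[k] + flank)
      side <- "downstream_of_C_helix"
    } else next
    if (hi - lo < 1L) next
    for (p in lo:(hi - 1L)) {
      cls <- classify(substr(seq, p, p + 1L))
      if (!is.na(cls)) {
        out <- rbind(out, data.frame(
          protein_id = proteinId, position = p,
          pair = substr(seq, p, p + 1L), motif_class = cls, side = side,
          tm_start = tm$start[k], tm_end = tm$end[k],
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  out
}

#' Combine anchor candidates into MAD annotations
#'
#' The union of the transmembrane, short-hydrophobic and amphipathic
#' candidates of one protein, emitted as `MAD` annotations with
#' `source = "detected"`. A protein may legitimately yield zero anchors
#' and still be processed downstream.
#'
#' @param tm,short,amphipathic candidate data frames for one protein (any
#'   may be `NULL` or empty).
#' @return a [DomainAnnotations-class] object (possibly zero rows).
#' @export
callMads <- function(tm = NULL, short = NULL, amphipathic = NULL) {
  cand <- rbind(if (!is.null(tm)) tm,
                if (!is.null(short)) short,
                if (!is.null(amphipathic)) amphipathic)
  if (is.null(cand) || !nrow(cand)) return(domainAnnotations(
    data.frame(protein_id = character(0), domain_type = character(0),
               start = integer(0), end = integer(0),
               source = character(0), stringsAsFactors = FALSE)))
  domainAnnotations(data.frame(
    protein_id = cand$protein_id, domain_type = "MAD",
    start = cand$start, end = cand$end, source = "detected",
    stringsAsFactors = FALSE))
}

#' Run all anchor detectors over a proteome
#'
#' Convenience wrapper applying [detectTMSegments()],
#' [detectShortHydrophobic()], [detectAmphipathic()] and
#' [scanDibasicMotifs()] to every protein, with the documented precedence
#' (TM > short hydrophobic > amphipathic on 50% overlap).
#'
#' @param proteins an `AAStringSet` named by protein id.
#' @param ... parameters forwarded to the individual detectors
#'   (`window`, `threshold`, `terminalSpan`, `indexMin`, `muMin`,
#'   `flank`).
#' @return list with elements `candidates` (all helix candidates),
#'   `motifs` (di-basic motifs) and `mads` (a
#'   [DomainAnnotations-class] of detected MADs).
#' @export
annotateProteome <- function(proteins, ...) {
  dots <- list(...)
  arg <- function(name, default) {
    if (name %in% names(dots)) dots[[name]] else default
  }
  allCand <- emptyCandidates()
  allMotifs <- NULL
  for (k in seq_along(proteins)) {
    id <- names(proteins)[k]
    s <- as.character(proteins[[k]])
    tm <- detectTMSegments(s, id, window = arg("window", 19L),
                           threshold = arg("threshold", 1.6))
    sh <- detectShortHydrophobic(
      s, id, terminalSpan = arg("terminalSpan", 60L),
      indexMin = arg("indexMin", 1.0), tm = tm)
    am <- detectAmphipathic(
      s, id, muMin = arg("muMin", 0.5),
      terminalSpan = arg("terminalSpan", 60L), tm = tm, short = sh)
    mo <- scanDibasicMotifs(s, tm, id, flank = arg("flank", 10L))
    allCand <- rbind(allCand, tm, sh, am)
    allMotifs <- rbind(allMotifs, mo)
  }
  mads <- callMads(allCand)
  if (is.null(allMotifs))
    allMotifs <- scanDibasicMotifs("M", emptyCandidates())
  list(candidates = allCand, motifs = allMotifs, mads = mads)
}

#' Read TMHMM short-format output as external MAD annotations
#'
#' Accepts the one-line-per-protein "short" format whose last field is a
#' topology string such as `Topology=i7-29o100-122i`; every helix interval
#' becomes an external `MAD` annotation. Externally supplied annotations
#' take precedence over detected ones when both are available.
#'
#' @param path path to a TMHMM short-format file.
#' @return a [DomainAnnotations-class] object with `source = "external"`.
#' @export
readTmhmm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- NULL
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    id <- fields[1]
    topo <- sub("^Topology=", "", fields[grepl("^Topology=", fields)])
    if (!length(topo)) next
    m <- gregexpr("(\\d+)-(\\d+)", topo)[[1]]
    if (m[1] == -1L) next
    for (piece in regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1]]) {
      se <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
      rows <- rbind(rows, data.frame(
        protein_id = id, domain_type = "MAD", start = se[1], end = se[2],
        source = "external", stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows))
    rows <- data.frame(protein_id = character(0),
                       domain_type = character(0), start = integer(0),
                       end = integer(0), source = character(0),
                       stringsAsFactors = FALSE)
  domainAnnotations(rows)
}
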