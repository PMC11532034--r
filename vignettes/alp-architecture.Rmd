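---
title: "Analysing adhesin-like protein repertoires from sequence"
author: "alpscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing adhesin-like protein repertoires from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpscan)
```

## The problem

Gut and rumen methanogens such as *Methanobrevibacter smithii* and
*Methanosphaera stadtmanae* devote an unusually large share of their
genomes — on the order of 10% — to adhesin-like proteins (ALPs): very
large (roughly 130 to 4,700 residues), Asn/Thr-enriched surface proteins
built from tandem repeats of a small number of domain types. The
recurring parts list is: a membrane-anchoring domain (MAD, which can be a
transmembrane helix, a sub-20-residue hydrophobic helix, or a terminal
amphipathic helix), the archaeal big domain (ABD, an 80–120-residue
β-sandwich repeat with conserved loop glycines), the right-handed
β-helical domain (RBH, an Asn-rich parallel β-helix rod of 250 to over
1,200 residues), and rarer transglutaminase-like (TG),
pseudomurein-binding (PMB) and miscellaneous (OTHER) domains.

`alpscan` implements the sequence-level half of an ALP repertoire
analysis as a tested pipeline: anchor detection from raw sequence,
architecture-string encoding/clustering/classification, repertoire
statistics, identity-based neighbor-joining phylogenetics with
bootstrap, and positional-entropy logo matrices. Structure- and
homology-based domain assignment (AlphaFold, Pfam, BLAST, TMHMM) is out
of scope: those annotations are imported through a simple TSV (or a
TMHMM short-format reader), or planted by the synthetic generator.

## Membrane-anchor detection

Three detectors operate on raw sequence, all on published
hydrophobicity scales (`hydrophobicityScale()`):

* **Transmembrane helices** (`detectTMSegments()`): a centred
  Kyte–Doolittle window scan with the classic hydropathy-plot settings,
  window 19 and mean threshold 1.6. Above-threshold regions are merged
  and then *trimmed to their hydrophobic core* — the longest contiguous
  run of residues scoring at least 1.0 — and reported only when that
  core reaches 17 residues. The trim matters twice: a 12-residue
  hydrophobic stretch can push a 19-residue window mean over 1.6 without
  being able to span a membrane, and untrimmed boundaries overshoot by
  half a window, which would defeat the flank scan for sorting motifs
  below. Candidates starting within the first 40 residues are labelled
  `N`-terminal, ending within the last 40 `C`-terminal.
* **Short hydrophobic helices** (`detectShortHydrophobic()`): within the
  first and last 60 residues (the paper-scale notion of "terminal" left
  unquantified in the source material; 60 is this package's convention),
  maximal segments of 10–19 residues whose Fauchère–Pliška mean exceeds
  1.0 — the HeliQuest hydrophobicity-index regime typical of short
  anchoring helices. TM candidates take precedence at ≥ 50% overlap.
* **Amphipathic helices** (`detectAmphipathic()`): HeliQuest-style
  18-residue windows scored by the Eisenberg hydrophobic moment
  \(\mu_H = |\sum_k H_k e^{ik\delta}|/N\) at δ = 100°; windows with
  \(\mu_H \ge 0.5\) are candidates, with TM and short-hydrophobic
  candidates taking precedence and overlapping windows resolved to the
  maximal moment.

Because the kind definitions overlap (a fully hydrophobic 17–19-mer is
both a legal short helix and a minimal TM), the biologically meaningful
output is the union that `callMads()` emits as `MAD` annotations;
`scanDibasicMotifs()` then looks 10 residues upstream of N-terminal TM
starts (and downstream of C-terminal TM ends) for the first `KK`,
`KN`/`NK` or \{K,R\}×\{K,R,N,D\} pair — the cytoplasmic sorting signal
that hints at helix orientation. The 10-residue flank is a package
convention; the source material gives no distance.

```{r anchors}
s <- paste0("MKK", strrep("L", 24), strrep("S", 120))
tm <- detectTMSegments(s, "demo")
tm
scanDibasicMotifs(s, tm, "demo")
```

## Architecture strings, clustering, classification

Domain annotations sorted by start are transcribed to single letters
(MAD = `t`, RBH = `r`, ABD = `a`, PMB = `b`, TG = `g`, OTHER = `o`), so
MAD-RBH-ABD×5 is `"traaaaa"`. Architectures are compared with a
normalised Levenshtein distance on the raw (uncompressed) strings —
repeat-count differences then matter in proportion to their size — and
clustered with DBSCAN at eps 0.5, minPts 1. The metric itself is a
package choice (the method's description names only the clustering
algorithm and its parameters), which is why downstream results that
depend on it, like cluster counts, should not be over-interpreted. With
minPts 1 every point is core, so the clustering is exactly
single-linkage connected components at the eps threshold — a property
the tests verify against an independent union-find oracle.

Classification is a deterministic cascade on the non-`t` symbols:
proteins with neither `a` nor `r` are not ALPs at all (`NOT_ALP`);
`g`-containing architectures are group `III` exactly when they have no
`r`, no `o`, and all ABDs precede the transglutaminase (with `b`
permitted, since PMB repeats co-occur with TG domains); any other `o` or
`b` routes to `OTHERS`; proteins with both ABD and RBH are `IA` when the
symbols match `r+a+` (RBH block adjacent to the anchor, then the ABD
repeats) and `IB` otherwise; single-type proteins are `IIA` (ABD only)
or `IIB` (RBH only). Anchors never influence the class, so MAD-less
proteins and dual-anchored proteins classify like their anchored
single-MAD counterparts. Two edge rules were genuinely open and are
fixed here: interleaved architectures such as `tarar` are `IB` (the
defining property of IB is exactly that the relative order is not
fixed), and trailing `o` symbols disqualify an architecture from `III`
(routes to `OTHERS`).

```{r classify}
classifyArchitecture("traaaaa")$class
classifyArchitecture("taar")$class
dbscanCluster(c(a = "traaa", b = "traa", c = "ooooo"))
```

## Repertoire statistics

`summarizeRepertoire()` reports counts, summed residue lengths, the
length range, and the fraction of the genome coding for ALPs at 3 bp
per residue, rounded half-up to one decimal as such tables are printed.
Ignoring stop codons changes the fraction by under 0.01 points, so the
simpler convention is used. Note that a mean defined as total/count need
not match a separately printed per-protein average when the underlying
per-protein table is not available; this package always reports
total/count. `compositionProfile()` pools residue frequencies (over the
20 standard residues; `X` is excluded), reports the Asn+Thr fraction
that gave ALPs their original "Asn/Thr-rich" annotation, and log2
enrichments against any background frequency map.

```{r repertoire}
alpCodingFraction(67292, 1853000)
alpCodingFraction(63039, 1767000)
```

## Identity distances, neighbor joining, bootstrap

`percentIdentity()` uses pairwise deletion — the denominator counts
columns where both rows carry a residue — and `X` never counts as a
match; `identityToDistance()` is the plain complement `1 − pid/100`
with no multiple-hit correction (the upstream tool's exact correction is
unspecified, so the transparent choice is made and stated).
`njTree()` is a canonical Saitou–Nei implementation with three
deliberately fixed numerical behaviours: Q-ties break to the lowest
row-major index pair, negative branch-length estimates are clamped to
zero with the deficit moved to the sibling edge (preserving the joined
pair's path length), and two-taxon input splits the single edge evenly.
On additive matrices the output realises the input exactly (tested to
1e-9 against patristic-distance oracles on random trees, and
cross-checked against an independent NJ implementation).
`bootstrapSupport()` resamples alignment columns with replacement,
rebuilds an NJ tree per replicate, and annotates each internal
bipartition of the full-data tree with its replicate frequency as an
integer percentage; replicate *r* uses seed substream `seed + r`, so
supports are reproducible and independent of scheduling.
`cladeIdentityTable()` averages identities within and between groups,
leaving singleton within-group means as missing.

## Logo matrices

`dropGappyColumns()` removes columns whose gap fraction exceeds 0.5 (a
configurable convention — the source material deletes "long gaps"
without a threshold), and `logoMatrix()` computes per-column residue
frequencies, Shannon entropy and information `log2(20) − H` in bits,
without the small-sample correction (logos here rank planted
conservation rather than estimate absolute information from few
sequences; the correction would subtract a constant at fixed depth and
change no ranking).

## The synthetic proteome generator

Ground truth comes from `generateProteome()` under a `syntheticSpec()`.
The defaults are the study conditions the package is validated under:
105 candidate sequences of which 14 are domain-free decoys and 91 are
ALPs split across groups at relative frequencies 40:12:13:5:4:13 (the
published group sizes; they sum to 87 because four partially annotated
proteins carry no printed group count, so the six frequencies are scaled
proportionally to the 91 ALPs); 1–7 RBH repeats and 1–27 ABD repeats;
ABDs of 80–120 residues with invariant glycines at fixed fractional
positions; RBH lengths log-uniform on [250, 1236] (the range spans
nearly an order of magnitude but long rods are rare, and log-uniform
sampling keeps totals in the repertoire's reported 128–4,691-residue
scale); TM anchors of 20–28 residues (the literature's 24.0 ± 5.6)
flanked by a di-basic pair; anchors at both termini for roughly one
anchored protein in eight (11 of 91); a two-fold Asn/Thr boost of domain
sequence over the polar background; and about one non-decoy protein in
18 without any anchor (5 of 91 published ALPs lack a MAD).

Two generator design choices keep recovery well-posed, and define what
passing tests do and do not show. First, linkers, decoys and domain
bodies are drawn from a polar background with no long-chain hydrophobic
residues, so planted anchors are the only hydrophobic stretches; real
proteomes contain hydrophobic patches inside folded domains, so the
near-perfect synthetic TM sensitivity is an upper bound, not a field
estimate. Second, class-conditional architecture grammars are the
constructive inverse of the classification rules, so label recovery
tests the encode→classify path, not the realism of the grammar.
Similarly, `generateAbdAlignment()` plants invariant glycine columns and
(when the substitution rate is positive) forces at least one deviation
in every other column, making the planted columns identifiable by
construction; clade structure is induced by clade-specific consensus
mutations with i.i.d. per-column substitution noise — no indels, no
rate heterogeneity, no phylogenetic autocorrelation beyond the two-level
clade/sequence hierarchy.

All randomness flows through per-protein substreams keyed by the spec
seed, so output is byte-deterministic:

```{r generator}
out <- generateProteome(syntheticSpec(nProteins = 30, seed = 42))
table(out$truth$classes$class)
arch <- encodeArchitectures(out$domains, ids = names(out$proteins))
mean(classifyProteome(arch)$class == out$truth$classes$class)
```

## Problem sizes and numerical conventions

The shipped tests validate on proteomes of 60–500 synthetic proteins,
alignments of 5–30 sequences and 60–120 columns, NJ recovery on 100
random 4–8-taxon additive trees, 200-replicate bootstraps, and 1,000
random 18-mers against the brute-force moment oracle — sizes chosen so
the full suite runs in well under a minute while every property is
exercised at non-trivial scale. Degenerate inputs are defined rather
than left to chance: empty architecture strings are at distance 0 from
each other and classify as `NOT_ALP`; sequence pairs with no comparable
alignment columns score identity 0 with a warning; an empty repertoire
summarises to zeros; all-gap logo columns are an error (prune first).

## Limitations

Domain intervals for real proteomes must come from external
structure/profile searches — the package deliberately does not infer
ABD/RBH/TG boundaries from sequence. The TM detector is a hydropathy
scan, not an HMM; imported topology predictions (`readTmhmm()`) take
precedence when available. The architecture distance metric and the
gap-pruning threshold are package conventions exposed as parameters;
conclusions that depend on them (e.g. the exact number of DBSCAN
clusters) should be checked for robustness. Percent-identity NJ on raw
complement distances ignores multiple substitutions and is meant for
the within-family divergences ALP repeats show, not deep phylogeny.
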