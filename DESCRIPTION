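Package: alpscan
Title: Domain-Architecture Analysis of Methanogen Adhesin-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the adhesin-like protein (ALP) repertoires
    of methanogenic archaea from sequence alone. Detects candidate
    membrane-anchoring domains (transmembrane helices by Kyte-Doolittle
    hydropathy scanning, short hydrophobic helices, and amphipathic helices
    by Eisenberg hydrophobic moment) together with flanking di-basic
    sorting motifs; encodes per-protein domain annotations as single-letter
    architecture strings; clusters architectures with DBSCAN over a
    normalised edit distance and classifies proteins into architecture
    groups; computes repertoire-level statistics (genome coding fraction,
    Asn/Thr compositional enrichment); builds neighbor-joining trees with
    bootstrap supports from percent-identity distances and positional
    entropy (sequence-logo) matrices from alignments; and generates
    synthetic ALP proteomes with planted ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alpscan-package.R'
    'architecture.R'
    'cli.R'
    'hydrophobicity.R'
    'logo.R'
    'mad-detect.R'
    'phylo.R'
    'repertoire.R'
    'seqio.R'
    'synthetic.R'
    'utils.R'
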