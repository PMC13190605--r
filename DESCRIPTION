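Package: pilyprofiler
Title: Repertoire Profiling of PilY1 Adhesins: Motifs, Synteny, Clades and Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Profiling pipeline for bacterial PilY1/PilC tip-adhesin repertoires.
    Scans degenerate calcium-binding, MIDAS and RGD sequence motifs and takes a
    cysteine census per protein; computes EMBOSS-needle-style global pairwise
    percent identity and similarity; classifies the genomic context of pilY1
    genes (minor-pilin clusters, major-cluster embedding, solitary copies,
    translational coupling); builds neighbor-joining trees from identity
    distances and assigns clade labels from reference exemplars with
    feature-consistency checks; superposes coordinate models (Kabsch RMSD) and
    detects disulfide bridges geometrically. A seeded synthetic-data generator
    emits clade-structured proteomes, annotated genomes and coordinate models
    with a ground-truth manifest so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'pilyprofiler-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'align.R'
    'io.R'
    'motifs.R'
    'phylo.R'
    'pipeline.R'
    'structure.R'
    'synteny.R'
    'synthetic.R'
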