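---
title: "Profiling PilY1 adhesin repertoires: methods and design notes"
author: "pilyprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling PilY1 adhesin repertoires: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilyprofiler)
```

## The biological problem

PilY1 (PilC in *Neisseria*) is the large adhesin at the tip of type IVa
pili (T4aP), the retractile filaments that drive twitching and social
motility in many Gram-negative bacteria. All PilY1 proteins share a
C-terminal beta-propeller domain, while the N-terminal region is highly
variable: some carry a mechanosensory vWFA domain (often with a MIDAS
metal-coordination site), others a DUF4114 domain implicated in
polysaccharide binding, and many carry short degenerate calcium-binding
motifs and sometimes an integrin-binding RGD tripeptide. Genomes
frequently encode several PilY1 paralogs, each inside its own minor-pilin
gene cluster (*fimU-pilV-pilW-pilX-pilY1*), embedded in the major pilin
cluster, or as solitary, unlinked copies.

`pilyprofiler` turns this repertoire analysis into a reusable, fully
seeded pipeline: per-protein motif and cysteine profiles, pairwise
identity/similarity, genomic-context classification, distance-based clade
assignment, rigid-body structure comparison, and a synthetic-data
generator whose ground-truth manifest makes every stage testable without
any downloads.

## Motif model

Motifs are degenerate patterns over the amino-acid alphabet:

* motif 1: `Dx(D/N)xDGxxD` (9 positions)
* motif 2: `DxDxNxxxD` (9 positions)
* motif 3: `DxD/NxDxxxxxxD/E` (12 positions)
* MIDAS: contiguous core `DxSxS`, plus a discontinuous tail (a T roughly
  6-40 residues and a D roughly 7-80 residues downstream of the core
  start, the spacing seen in canonical vWFA MIDAS sites)
* RGD: `RGD`

`compilePattern()` parses this notation into token lists; `scanMotif()`
reports every (possibly overlapping) core match, ascending by start,
1-based inclusive. Two semantics are worth making explicit:

* an `X` in a sequence (including letters folded from U/B/Z/J on input)
  never satisfies a fixed residue position, but does satisfy a wildcard;
* the MIDAS flag is driven by the contiguous `DxSxS` core alone. The
  exact spacing of the full discontinuous site is not standardized, so
  requiring the tail risks silently missing true sites; instead the T and
  D tail residues are *annotated* when found in the windows above
  (`tail_pos` column). Users who want a strict full-site definition can
  mark tail elements as required in the motif catalog
  (`inst/extdata/motifs.tsv`, `T:+6..+40!` syntax).

Scanning runs over the full annotated sequence, signal peptide included;
no region restriction is imposed. The scanner is verified against a
brute-force per-offset oracle on thousands of random sequences.

```{r motif-example}
scanMotif("AARGDKK", compilePattern("RGD"))
cysteineCensus("CACC")
```

## Pairwise identity and similarity

`globalAlign()` implements Gotoh affine-gap global alignment with
EMBOSS-needle conventions: BLOSUM62 (shipped as a plain-text matrix),
gap open 10, gap extension 0.5 per position (a gap of length L costs
`10 + 0.5 L`), terminal gaps free but *counted* in the alignment length.
Percent identity is `100 * identical columns / alignment length`;
similarity counts columns whose residue pair scores positive. The
traceback tie-break (residue pair, then gap in the first sequence, then
gap in the second) is fixed so the reported alignment is reproducible;
co-optimal tracebacks can differ slightly in identity, so the tie-break
is part of the contract. The implementation is in C++ for speed
(a 100-protein identity matrix takes on the order of a minute) and is
tested against exhaustive enumeration on short pairs and against an
independent ends-free aligner.

`identityMatrix()` gives the symmetric percent-identity matrix; the
companion distance `d = 100 - identity` feeds the tree.

## Genomic context

Gene roles (pilY1, the minor pilins pilX/pilW/pilV/fimU, tfcP, and the
core genes pilQ/P/O/N/M/B/T/C/A) are read from `role=` or `gene=` GFF3
attributes; the pipeline never re-detects roles from sequence, since
homolog detection is an upstream concern.

* `detectClusters()` chains role-bearing genes greedily: two join one
  cluster when at most `maxGapGenes = 2` non-role genes intervene *and*
  the intergenic span is at most `maxGapBp = 3000` bp. A cluster is a
  `major_cluster` with >= 5 distinct core roles, a `minor_cluster` with a
  pilY1 plus >= 2 minor pilins, `major_embedded_pilY1` when both hold,
  `solitary_pilY1` for a pilY1 that joins nothing, and `other` otherwise
  (e.g. a pilY1 with only a pilX neighbor).
* `classifyLinkage()` calls a pilY1 `linked` iff any minor-pilin gene
  lies within `windowGenes = 5` genes on the same contig, strand
  ignored. Linked/unlinked partitions the pilY1 set by construction.
* `detectTranslationalCoupling()` reports consecutive same-strand CDS
  whose intergenic distance `g = next_start - prev_end - 1` is at most
  4 bp, covering the canonical 1-bp (`TGA`/`ATG` sharing) and 4-bp
  (`ATGA`) stop-start overlaps.
* `edgeFlag()` marks pilY1 genes within 2000 bp of a contig boundary as
  possible assembly artifacts, using `##sequence-region` pragma lengths.

None of these thresholds has a field-standard value; all are
config-exposed (`pilyConfig()`), and the defaults were chosen to capture
typical minor-pilin operon layouts (at most one intervening gene) with
slack. Strand is ignored for linkage (a positional notion) but required
equal for coupling (co-translation needs co-orientation).

## Trees, clades, PCA

Maximum-likelihood phylogenetics over a trimmed multiple alignment is
deliberately out of scope: at desk scale the pipeline uses
neighbor joining (Saitou-Nei Q criterion) over `100 - identity`, which is
deterministic, fast, and sufficient for clade demarcation on
well-separated families. Determinism details: Q-minimum ties break on the
lowest index pair; negative branch lengths are clamped to zero with the
deficit moved to the sibling so the pair's path length is preserved; the
unrooted tree is serialized with a trifurcating root. NJ provably
recovers additive distances exactly, and the tests check every 4- and
5-taxon shape against its additive matrix, plus an independent NJ
implementation.

`assignClades()` labels queries from reference exemplars: a query takes
the clade of the smallest exemplar-spanning subtree containing it. Two
operational details: a clade whose exemplars straddle the trifurcating
root spans every tip, which carries no information, so such a clade falls
back to nearest-exemplar distance; and a query contained in no subtree
(or in conflicting ones) also falls back to the nearest exemplar, with
`unassigned` reserved for conflicted queries farther than
`cladeCeiling = 75` distance units from every exemplar. Assignments are
then checked against the expected N-terminal architecture (DUF4114 for
clades 1.1/1.2, vWFA for 1.3/1.4b/1.5/1.6/1.7, neither for 1.4a/1.4c);
inconsistent assignments keep their label but carry a flag.

PCA uses the rows of the identity matrix as feature vectors
(column-centered, unscaled). The exact featurization behind published
identity-based PCAs is rarely stated; this choice is recorded as an
assumption. Component signs follow a fixed convention (largest-magnitude
loading positive) so coordinates are reproducible.

## Structure comparison

`kabschSuperpose()` is the standard Kabsch least-squares fit: centroid
alignment, covariance SVD, reflection fixed by the determinant sign. The
default compares *all* paired CA atoms with no outlier rejection,
because that is exactly reproducible; an optional iterative rejection
mode (5 cycles, 2-sigma cutoff) approximates the behavior of interactive
tools that trim outlier pairs, and the mode is recorded in the output.
Collinear point sets are rejected (the rotation is underdetermined).
`detectDisulfides()` pairs cysteine SG atoms within 2.5 Angstrom
(canonical S-S bond about 2.05 plus model tolerance) by greedy ascending
distance, so each cysteine joins at most one bridge; the threshold is
config-exposed because no standard criterion exists for predicted
bridges in coordinate models.

## The synthetic-data generator

`generateProteome()` emulates a clade-structured PilY1 family. Study
conditions are fixed in `cladeTemplates()`:

* per-clade cysteine medians 23, 22, 35, 21, 25, 17, 30, 36, 41 for
  clades 1.1-1.7 — the repertoire structure the pipeline is designed to
  recover;
* length medians 1250, 1200, 1450, 900, 1100, 1000, 1500, 1700, 1650
  residues, following the qualitative ordering of the clades (1.4a
  shortest; 1.6/1.7 longest) at realistic PilY1 sizes (the
  *P. aeruginosa* protein is 1163 aa);
* the N-terminal domain emitted per clade (DUF4114, vWFA or none; a
  beta-propeller always), and motif-repertoire probabilities (motif 1
  predominant in 1.1/1.2; 1.4a/1.4c/1.7 mostly lacking all three
  calcium-binding motifs; MIDAS spread across lineages; RGD in roughly a
  fifth of proteins).

Construction guarantees exactness where the tests demand it. The
background alphabet excludes cysteine, so planted cysteine counts are
exact per protein; per-clade count and length deltas form balanced
multisets with median zero, so clade medians equal the templates exactly.
Each clade has a conserved random core (90 percent of the median length),
mutated per protein at rate 0.04 — tuned so within-clade identity stays
at or above 70 percent while between-clade identity stays far below 40
percent, the separation regime in which clade assignment should be
perfect. Planted motif instances are recorded in the manifest, and any
protein whose random background produces a *chance* motif hit is
regenerated (logged, at most 100 attempts), so the manifest equals the
scanner output exactly rather than merely containing it.

What the generator does **not** emulate: insertion/deletion evolution
(within a clade only substitutions and terminal-length variation occur),
realistic amino-acid composition (backgrounds are uniform over 19
letters), true beta-propeller folds (structure pairs are self-avoiding
random CA traces), and draft-assembly fragmentation. Green tests
therefore demonstrate algorithmic correctness under controlled
conditions, not performance on real, indel-rich, compositionally biased
proteomes — on real data the identity separation between clades is the
binding assumption to check first.

`generateGenome()` plants six genomic layouts (three *M. xanthus*-style
minor-pilin clusters, one with a tfcP-pilY1 coupling overlap and one
with a trailing coupled accessory gene; a major-cluster-embedded
arrangement; a solitary unlinked pilY1; a partial pilX-adjacent case)
with known cluster types, linkage labels and coupling pairs.
`generateStructurePair()` plants cysteine bridges at exactly 2.05
Angstrom and applies a known rigid transform plus optional Gaussian
coordinate noise.

```{r generator, message = FALSE}
gp <- generateProteome(nPerClade = 3, seed = 1)
gp$proteins
head(gp$manifest[, c("protein_id", "clade", "length", "n_cys")], 4)
```

## Numerical choices and degenerate inputs

* Alignment scores are doubles; the oracle comparisons use 1e-9
  tolerances. Identity matrices are symmetric by construction (each pair
  aligned once).
* NJ rejects asymmetric (beyond 1e-8), non-finite or negative inputs;
  distance ties are resolved by index order, documented above.
* PCA of identical rows returns all-zero coordinates (zero variance).
* PDB text stores three decimals, so coordinates round-trip with about
  5e-4 Angstrom quantization per axis; a noise-free rigid pair written to
  disk and re-read superposes near 1e-3 Angstrom, not machine zero.
* Proteome scale in the bundled checks: 9 clades x 12 proteins (108
  sequences, 5778 alignments), the size at which the full identity
  matrix, tree, and assignment stage complete in about a minute.

## Limitations

* Homolog detection, domain-calling engines, multiple alignment and ML
  tree inference are inputs or non-goals, not package features.
* Clade labels require user-supplied exemplars; with a single exemplar
  per clade the subtree rule degenerates to nearest-exemplar
  classification.
* Reported percent identities follow needle conventions; tools that
  exclude terminal gap columns from the denominator will report higher
  values on length-mismatched pairs.
* The RMSD of two real structure models depends on the atom pairing and
  outlier policy; the default here (all shared CA atoms, no rejection)
  is the reproducible choice, not necessarily the one interactive tools
  use by default.
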