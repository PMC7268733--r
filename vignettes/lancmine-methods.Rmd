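---
title: "Mining lanthipeptide gene clusters: models, heuristics, and design choices"
author: "lancmine developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining lanthipeptide gene clusters: models, heuristics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model behind each stage, the tunable parameters and their defaults, what
the synthetic fixtures do and do not establish, and the places where the
design was genuinely open and a choice had to be made.

## The mining model

Lanthipeptide biosynthesis leaves a consistent genomic signature. Every
class of modification machinery carries a LanC-like cyclase domain, so a
profile-HMM search with a LanC-like model enumerates candidate anchors
with high sensitivity. Around each anchor, the accessory-domain content of
the gene neighborhood identifies the class:

| class | machinery | neighborhood evidence |
|---|---|---|
| I | LanB dehydratase + LanC cyclase | both dehydratase roles (N- and C-terminal domains), possibly on two polypeptides (split LanB) |
| II | LanM bifunctional synthetase | LanM dehydratase domain (DUF4135 role) |
| III | LanKC kinase–cyclase | anchor protein also hits a protein-kinase role; class-III subfamily model scores lower (better) |
| IV | LanL kinase–cyclase | as III, but the class-IV subfamily model scores lower |

The rules fire *independently*, not as an if/else cascade: a neighborhood
can satisfy several (bifunctional-enzyme clusters plus a stray LanB do
occur). We label by precedence I > II > III/IV and set
`multi_class_flag`, preserving the information instead of discarding the
cluster. Where the class III vs IV subfamily E-values tie exactly — or a
kinase-positive anchor hits neither subfamily model — we assign class III;
the rule must be deterministic, ties are measure-zero with real models,
and the choice is recorded here rather than hidden.

The precursor search is the delicate stage. LanA genes are short (30–120
aa), often unannotated, and lie within a few genes of the machinery. We
therefore translate the whole neighborhood span in six frames, keep every
ATG/GTG/TTG-initiated ORF with an in-frame stop, and filter: length
bounds inclusive (counting the initiator Met), at least one Cys (no Cys,
no thioether), not strictly nested inside an annotated gene, longest ORF
per stop codon. The nesting rule has one deliberate carve-out: an ORF
whose interval *exactly equals* an annotated gene is kept and marked
`annotated = TRUE`. A substantial fraction of real precursors are
annotated genes; reading "entirely within an annotated gene" literally
would discard all of them, which is plainly not the intent of the
procedure.

## The leader/core boundary heuristic

The boundary search region starts after the best leader-motif match
(whole peptide when no motif is found; the motif library — FxLD,
LxLxKx₅L, LxLQ, (E/D)(L/M), terminal GG — ships as data because de novo
motif discovery is out of scope). Within that region:

* a `GG` or `GA` occurrence puts the core start immediately after the
  second residue (double-Gly protease logic);
* an `S/T(x)₂₋₇C` occurrence puts the core start one residue *before* the
  S/T (the first ring of the core starts at a dehydratable residue);
* occurrences starting within 10 residues of the C-terminus are ignored
  (a core must have room for at least one ring);
* among qualifying occurrences, the one yielding the longest core wins;
* with no qualifying occurrence, the C-terminal half is the core; for odd
  lengths the core takes the extra residue (`boundary = floor(len/2)`),
  a parity rule the verbal description leaves open;
* a core without Cys rejects the candidate (typed rejection, not an
  error).

"Best-scoring" motif match is realized as library-order priority (most
specific pattern first) with leftmost occurrence, restricted to the
N-terminal two thirds. Regular-expression motifs carry no natural score;
priority order is the deterministic substitute, and the library is
user-replaceable JSON.

## Features, ANOVA, SVM, rubric

Each surviving candidate is described by a versioned catalog of 1343
features: lengths; per-region (full/leader/core) amino-acid counts and
frequencies, Ser+Thr+Cys count and fraction, net charge (K+R−D−E), mean
Kyte–Doolittle hydropathy, aromaticity; per-region dipeptide frequencies
(400 × 3); and one indicator per library motif. The original feature list
is not public in its entirety (2458 features, supplementary material), so
the catalog is declared, versioned (`lancmine-1.0`), and pluggable rather
than claimed as a reconstruction. Models pin the catalog version they
were trained against and refuse to score against another.

Feature selection is a per-feature one-way ANOVA F-test between labels
with strict `p < alpha` (default 0.05); zero-variance features are
dropped before testing so F is always defined. The test is computed in
closed form and verified against `anova(lm(...))` to 1e-9 in the test
suite.

The classifier is a C-SVC with RBF kernel. No SVM package exists in the
supported environment, so the dual problem is solved in-package by SMO
with maximal-violating-pair working-set selection (the standard LIBSVM
scheme); the solver is exercised against statistical oracles (separable
data trains to accuracy 1; 3-pooled-sd Gaussians cross-validate ≥ 0.95;
permuted labels fall in the 0.5 ± 0.12 null band). Standardization is
fitted on training folds only; cost (default grid {1, 10}) and gamma
(default 1/p) are chosen by seeded k-fold cross-validation; everything is
deterministic given the seed.

The final verdict combines the SVM with a heuristic rubric: motif present
+3, GG/GA boundary +2, core S+T+C fraction ≥ 0.2 +2, encoded within 1 kb
of and co-directional with a class-evidence gene +2, SVM positive +10,
threshold 10. The published point tables are supplementary material not
reproduced here; these defaults keep the structure (SVM-dominant, with
heuristics able to confirm but not outvote it — heuristics alone reach at
most 9 < 10) and are editable JSON, so holders of the original tables can
transcribe them.

## The synthetic world

`make_genome` is a stated world, not a tuning dial. Its defaults: three
BGCs (classes I, II, III), one precursor per BGC carrying an FxLD leader
motif and a GG cleavage site with a Ser/Thr/Cys fraction of 0.5 in the
core, four decoy ORFs per BGC each violating exactly one filter rule
(too short, too long, no Cys, nested in a gene), intergenic GC 0.5,
linear records with ≥ 3.5 kb flanks (or a 500 nt flank in the
contig-edge case). Planted proteins are emitted from the same synthetic
domain families the fixture HMMs are built from — anchors from a shared
LanC-like consensus, class III/IV anchors as kinase-domain fusions drawn
from two subfamilies at 35% between-family divergence — which guarantees
detectability without any real Pfam model. Planted ORFs are
reverse-translated without internal in-frame start codons and behind
in-frame stop walls, so each planted stop codon owns exactly one ORF and
ground-truth coordinates survive stop-codon deduplication.

Two things the fixtures deliberately do *not* do. First, intergenic
spacers are rejection-sampled to contain no internal ORF ≥ 30 aa, but
ORFs straddling gene boundaries (reverse-strand reads of coding genes,
mostly) are left in place: real neighborhoods are full of such
candidates, and rejecting them is the scorer's job. The end-to-end test
accordingly demands exact recovery — planted precursors called, every
decoy and background candidate rejected. Second, training negatives are
not uniform random amino-acid strings: they follow the codon
multiplicities of genetic code 11, i.e. the residue composition of
translated random DNA, because that is what the negative class actually
is (peptides arising from translation of noncoding regions) and what the
mining run will encounter. An early uniform-composition version produced
an occasional borderline SVM false positive on background ORFs; matching
the negative class's stated composition removed it without touching any
threshold.

`make_training_peptides(separation = s)` maps `s` ∈ [0, 1] to structure
strength: each positive is a fully structured precursor-like peptide with
probability `s` and a background draw otherwise, so `s = 0` is an exact
label-permutation null and `s ≥ 1` the fully separated case — the two
endpoints the acceptance properties test.

A green fixture suite establishes that the machinery is correct on a
world with known truth. It does not establish recall on real genomes:
real leader motifs are weaker, real intergenic composition is not i.i.d.,
and real Pfam models have different score distributions than the fixture
families. Users mining real data should supply the real Pfam and custom
subfamily HMM files and train on curated peptides.

## Numerical and I/O choices

* Internal coordinates are 0-based half-open everywhere; GenBank and GFF3
  emit their native 1-based inclusive forms. One internal convention, no
  per-module off-by-ones.
* Circular replicons: neighborhoods never wrap the origin and circular
  records are never contig-edge-flagged — the edge rule exists for
  fragmented drafts, which are linear.
* Codons containing N translate to X and never act as start or stop;
  ambiguity is handled identically on every path.
* HMMER is the profile-HMM backend (`hmmbuild`/`hmmsearch`). E-values are
  engine-defined; the pipeline consumes only ranks and cutoffs, and the
  `DATE` header of built models is normalized so identical alignments
  yield byte-identical model files.
* Overlapping neighborhoods from nearby anchors are reported separately,
  one call per anchor, rather than merged; shared genes simply appear in
  both neighborhoods.
* Report TSV/GFF3/FASTA bytes are stable across reruns for identical
  inputs (fixed number formatting, deterministic sort orders); run
  metadata with timestamps lives in a separate JSON.

## Known limitations

* Class assignment uses full-sequence E-values only; domain coordinates
  are parsed but unused, so a multi-domain protein's hit location is not
  interrogated.
* The per-class SVM interface is in place, but nothing prevents training
  all classes on one peptide set (as the examples do); class-specific
  training data is the user's responsibility.
* The heuristic rubric's point values are substitutes, not the published
  tables.
* No ribosome-binding-site evidence, no modification-site prediction, no
  ring-topology inference — the pipeline stops at "this ORF is a
  precursor".
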