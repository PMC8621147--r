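---
title: "Characterizing a gamma-gliadin gene family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a gamma-gliadin gene family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliadinr)
```

## The problem

Gamma-gliadins are monomeric gluten storage proteins of wheat, encoded by
intronless multigene families at the *Gli-1* loci.  Characterizing such a
family from an assembled genome involves a fixed sequence of steps: find the
intronless open reading frames, separate full-length genes from pseudogenes
(in prolamins these arise almost exclusively from C→T transitions turning a
glutamine codon CAA/CAG into a TAA/TAG stop, or from truncation), translate
the genes, segment the proteins into the canonical six-domain architecture,
profile the cysteine skeleton and the poly-glutamine tract, compute
physicochemical characteristics, scan for celiac-disease (CD) T-cell epitope
cores, and compare the family members by pairwise identity and a
neighbor-joining tree.

gliadinr implements this pipeline as composable, tibble-returning functions
plus a synthetic-data generator that emits gamma-gliadin-like genes with
*fully known ground truth*, so every stage has an exact recovery test that
needs no external data.

## The gene and protein model

A gamma-gliadin preprotein is modelled as six consecutive regions:

| region | content |
|---|---|
| S | signal peptide (fixed length, default 19 aa) |
| I | unique N-terminal region |
| II | repetitive region tiled by PQQPFPQ-family heptapeptide units, where CD epitopes concentrate |
| III | first non-repetitive region, carrying six conserved cysteines |
| IV | poly-glutamine tract encoded by CAA codons with occasional single-base mutant codons (CAG, GAA, CTA) |
| V | C-terminal region with the remaining two conserved cysteines |

The conserved cysteine skeleton is eight residues (6 in III, 2 in V); an
extra cysteine (as seen in some B-genome members) is represented as a
single-residue substitution inside a domain-II unit, mirroring the
TCC/TAC→TGC point-mutation mechanism.

## Synthetic data: what it emulates, and what it does not

`gene_spec()` + `build_gamma_gene()` assemble a protein from the six regions
and reverse-translate it with a deliberately restricted codon table; the
stated truth (domain intervals, epitope start positions, cysteine positions,
poly-Q tract and interruption offsets) is recomputed from the emitted
sequence by exhaustive search, so truth and sequence cannot disagree.
Key design choices:

* **Recoverability is engineered at the codon level.**  Outside the planted
  tract, glutamine is encoded CAG-only and glutamate/leucine avoid GAA/CTA,
  so no CAA-mutant run can form outside domain IV.  No generator codon ends
  in `A` or `AT`, none is `CAT`, and filler alphabets exclude Met/Ile, so
  the only ATG a scanner can see in a gene — on either strand, in any frame,
  beyond short bounded stretches near domain II — is the initiator.  This is
  what makes "the scanner recovers exactly the planted genes" a theorem
  about the generator rather than a statistical hope.
* **Filler composition.**  Domains I, III and V draw from a
  glutamine/proline-rich alphabet (Q 22%, P 16%) chosen so whole-protein
  glutamine lands in the 29–34% band typical of the family; fillers are
  re-sampled if they accidentally spell a heptapeptide-family unit, a
  planted epitope, or a poly-Q run.
* **Epitope junctions.**  Embedded epitopes sit one per slot between
  heptapeptide units.  Some junctions inherently spell extra epitope copies
  (a `...QQ` tail followed by PQQPFPQ reads QQPQQPFPQ); when that would
  exceed the requested copy number the generator inserts a one-proline
  spacer after each epitope.  Domain II therefore always begins and ends
  with a unit, and its truth interval is exactly the unit-to-unit span.
* **Defaults are the study conditions.**  The default spec (signal 19,
  domain I 25, five units plus three embedded QQPQQPFPQ copies, domain III
  100 aa with 6 Cys, 25 CAA codons, domain V 60 aa with 2 Cys) yields a
  291-aa preprotein, inside the 285–328 aa range reported for the family;
  loci place genes between 200–400 bp spacers at GC 0.45.
* **What is not emulated:** introns (the family is intronless), transposon
  or repeat content of real intergenic DNA, homology decay between family
  members (synthetic genes are unrelated draws, so identity matrices on
  them sit near the random-sequence baseline), and signal-peptide biology
  (the S boundary is a configured length, not a prediction).  Passing
  recovery tests therefore demonstrates correctness of the *operations*,
  not performance on real assemblies.

The spacer model is our own: i.i.d. bases at a target GC, with every ATG and
CAT rewritten by GC-preserving substitutions and a `CTAGCTAGCTAG` cassette
(its own reverse complement, carrying stops in all frames on both strands)
capping each spacer, so no open stretch crosses a spacer.

## Annotation

`find_orfs()` reports every maximal ATG-to-first-in-frame-stop stretch of at
least `min_len` bp (default 450, below the shortest family member) on both
strands, with 1-based inclusive forward-axis coordinates; nested ORFs
sharing a stop are reported from the 5'-most ATG.  Printed gene sizes in
family tables include the stop codon, so a full-length gene satisfies
`protein length = bp/3 − 1`; `validate_length_consistency()` surfaces rows
violating this instead of silently correcting them.

A pseudogene's leading ORF (ATG to its premature stop) is usually far below
`min_len`, so `annotate_genes()` adds a rescue pass: a short leading stretch
is extended through successive in-frame stops and accepted as a pseudogene
region when the extension lands inside `expected_len_range` (default
858–996 bp).  Internal stops become premature-stop records at
`3·(codon − 1) + 1` bp from the ATG — the convention under which every
position is ≡ 1 (mod 3) — with the ancestral codon inferred from the C→T
glutamine mechanism (TAA←CAA, TAG←CAG, TGA←unknown).  The rescue is tuned
for family-sized genes; a premature stop lying beyond `min_len` from the
ATG is only classified correctly when the gene sequence is supplied
directly to `classify_orf()`.

Family labels are feature-driven, not homology-driven: at least two
heptapeptide-family units ⇒ gamma-gliadin; prolamin-sized and Q-rich
without the repeat ⇒ delta-gliadin-like; shorter ⇒ avenin-like.

## Protein features

* **Domain II** is the span of the densest chain of heptapeptide-family
  units (Hamming distance ≤ 1 per unit, ≥ 2 units, inter-unit gaps ≤ 10
  residues to accommodate an embedded 9-mer plus its junction spacer).  An
  exact-only mode is `max_mismatch = 0`.
* **Domain IV** is the protein projection of `find_polyq()`: the longest
  codon run of CAA and its accepted single-base mutants with ≥ 60% CAA, no
  two consecutive non-CAA codons and length ≥ 5; ties go leftmost.  When
  only a protein is available, a residue-level analogue (Q-runs with single
  non-Q interruptions) is used.
* **Unresolvable boundaries merge.**  Without a repetitive domain II the
  I/III boundary does not exist in the sequence, and the merged span is
  reported as I; without a poly-Q tract the III/V boundary likewise merges
  into III.  With neither, segmentation returns S+I and warns about a
  non-gliadin-like architecture.
* **Cysteine profile:** positions, per-domain counts, a canonical flag
  (exactly 6 in III, 2 in V, 8 total) and the positions outside that
  layout.  The adjacency of a configurable pair of domain-III cysteines
  (default ranks 4 and 6) is reported separately and deliberately excluded
  from the canonical flag: the published description of "consecutive"
  cysteines is internally ambiguous, so it is surfaced as information, not
  enforced as a rule.
* **Physicochemistry:** average molecular weight (ExPASy average residue
  masses + one water) and theoretical pI by bisection (tolerance 0.001 pH)
  on the Henderson–Hasselbalch net charge under the Bjellqvist pK set — the
  set behind the ProtParam values that family tables print.  MW/pI are
  computed on the full preprotein (the `bp/3 − 1` arithmetic of the
  published tables implies the signal peptide was not cleaved) and refused
  (NA) for sequences containing `*` or `X`.  The essential-amino-acid set
  defaults to {H, I, K, L, M, F, T, W, V} — histidine included — and is
  configurable, since composition summaries rarely state the set used.

## Epitope scanning

Matching is exact and case-normalized, on the native glutamine-form
sequences; the deamidation annotations in the database are metadata only.
The bundled database holds the ten 9-mer gamma-gliadin T-cell epitope
cores, including the same 9-mer listed under both its DQ2.5 and DQ8
restrictions — sequence-duplicate entries are allowed and always report
identical hit sets, while duplicate names are rejected.  Overlapping
counting (all start positions) is the default because published copy
numbers rarely state a convention and overlapping is the conservative
superset; a greedy non-overlapping mode is available and labelled.
`epitope_summary()` adds the clustering fraction (hits starting inside
domain II over all hits; 0 with a `no_hits` flag when there are none) and
the B-cell 7-mer QPQQPFP count under the same convention.

## Comparison and phylogeny

`global_align()` is affine-gap global (Needleman–Wunsch) alignment via
Biostrings, with nucleotide defaults match +1 / mismatch −1, gap open 5 /
extend 1 and amino-acid defaults BLOSUM62, gap open 10 / extend 1.  The
original alignment tool's parameters for such family tables are typically
unpublished, so identity reproduction is tolerance-based (±0.5 points) and
every scoring parameter is exposed.  `percent_identity()` reports both
denominators — all alignment columns (default) and ungapped columns —
because the published convention is unknown; the columns value is never
larger.  Score ties in the underlying dynamic program depend on argument
order, so `identity_matrix()` aligns each pair in a canonical
(lexicographic-label) order, making the matrix invariant under input
permutation.  The matrix uses the dual-triangle layout: nucleotide identity
above the diagonal, amino-acid identity below, 100 on the diagonal.

Trees use `d = 100 − AA identity` (p-distance-like, no multiple-hit
correction, since no substitution model was stated) and Saitou–Nei neighbor
joining via ape; negative branch lengths are clamped to zero with a
warning, and Newick output rounds lengths to 4 decimals.  On additive
matrices NJ provably recovers the generating tree, which the tests verify
via Robinson–Foulds distance and path-length (cophenetic) reconstruction —
an oracle independent of the NJ route itself.

## Pipeline conventions

`run_pipeline()` validates its configuration before writing anything, then
emits TSV/GFF3/Newick/JSON reports with fixed column orders, a version
header comment, and printed precision matching family-table practice
(identity 1 dp, pI 2 dp, MW integer Da).  Pseudogenes are excluded from the
protein-level reports by default — published family characterizations
describe the functional members — and included as flagged readthrough
products (internal stops removed) with `readthrough = TRUE`.  Reruns with
identical inputs and settings are byte-identical; the seed exists for the
synthetic generator and is recorded in the manifest.

## Problem sizes and test design

The test suite and the acceptance script regenerate everything from code:
100 randomized generator genes for feature-recovery rates, 1000 random
protein/epitope pairs against a naive sliding-window oracle, 100 random
additive 5–8-taxon trees for NJ, 1000 random peptides for MW additivity and
pI monotonicity, and a nine-member synthetic family (seven functional genes
plus two pseudogenes, the composition reported for the durum wheat family)
through the full pipeline.  These sizes give every rate a denominator large
enough to be meaningful while keeping the whole suite to a couple of
minutes.  Two checks depend on records the package does not redistribute —
the deposited reference ORF (GenBank MZ399711) and two
coding sequences extracted from the Svevo assembly — and fail with
instructions when those files are absent rather than being skipped.

## Known limitations

* The segmentation is tuned to gamma-gliadin architecture; proteins without
  the heptapeptide repeat or the poly-Q tract get merged, partially
  informative segmentations by design.
* The pseudogene rescue assumes family-sized ancestral ORFs and spacers
  without spurious ATGs; on real assemblies it should be reviewed together
  with homology evidence.
* Identity values depend on alignment scoring; only tolerance-based
  comparison with published matrices is meaningful.
* The generator's synthetic genes are mutually unrelated, so downstream
  statistics that depend on real evolutionary structure (identity ranges,
  tree shape) are exercised for correctness, not realism.
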