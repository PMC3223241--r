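---
title: "Methods: annotating and comparing small circular viral genomes"
author: "baculoannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and comparing small circular viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculoannot)
```

Granuloviruses and other baculoviruses carry circular, covalently closed
dsDNA genomes of roughly 80–180 kb that are annotated almost entirely by a
small set of explicit conventions: ORFs of at least 50 codons with minimal
overlap, coordinates anchored at the granulin (or polyhedrin) start codon,
canonical early/late promoter motifs sought upstream of each ORF, and
comparative analyses — homolog tables, dot plots, gene-order diagrams,
concatenated-gene phylogenies — built on top of that annotation. This
vignette records how each of those steps is defined in `baculoannot`, which
knobs exist, and which design choices were genuinely open.

## Coordinates and genome records

All coordinates are 1-based and inclusive, exactly as in GenBank and GFF3.
A feature on a circular genome may cross the origin; it is stored with
`end < start` and `wraps = TRUE`, and written to GFF3 as two parts sharing an
`ID` (and to GenBank as an origin-spanning `join`). `start` and `end` are the
two ends of the genomic interval — the biological start codon begins at
`start` on the plus strand and at `end` (reading downward) on the minus
strand. This keeps files bit-for-bit compatible with the standard formats
while still carrying strand information explicitly.

`anchor_to_gene()` implements the anchoring convention: the genome is rotated
(and reverse-complemented if the anchor gene lies on the minus strand) so the
first nucleotide of the anchor's start codon is nucleotide 1 and numbering
runs in its direction of transcription. Anchoring is idempotent, preserves
lengths, base composition and every feature's translation, and is invertible
by anchoring back on the original first gene.

`N` is allowed in sequences; any codon containing `N` translates to `X` and
can never act as a start or stop codon, so behaviour on ambiguous bases is
deterministic.

## ORF calling

`enumerate_orfs()` reports every *maximal* ORF in all six frames: the first
ATG after the previous in-frame stop, read through the next in-frame stop.
Lengths include the stop codon, so the conventional "50 or more amino acids"
threshold is `min_codons = 50`, i.e. at least 150 nt — the two common
phrasings of the rule coincide under this reading. On circular genomes the
scan runs over a doubled copy of the sequence so ORFs may wrap the origin
(never more than one full turn); with a genome length not divisible by three
the frames simply merge into longer cyclic chains, which the per-stop
maximality rule handles without special cases. The enumerator is checked
against a brute-force scanner that walks codon-by-codon from every position
of the sequence.

`select_orfs()` applies the minimal-overlap convention as a greedy filter:
candidates are admitted in order of decreasing length provided they overlap
every previously admitted ORF by at most `max_overlap_bp`. The default of
47 bp is "less than 16 codons", the conventional dividing line between
tolerated minimal overlaps and noteworthy large ones. Candidates flagged as
*homology-rescued* (significant similarity to known genes, from the homology
module) are admitted regardless of overlap. Because the published analyses do
not state how ties were resolved, ties are broken deterministically: smaller
start first, then plus strand first. Selected ORFs are named serially in
genome order, mirroring the Spli1…SpliN style of anchored annotations.

`overlap_table()` reports the coordinate intersection of each pair of
adjacent ORFs (adjacent = consecutive by start coordinate), closing the
circle between the last and first ORF on circular genomes — the genome has no
privileged end, so the origin-spanning pair is a real adjacency. With exactly
two ORFs the two circular adjacencies coincide and one row is reported.
`genome_stats()` reports the A+T percentage over the full sequence and the
coding percentage under **both** natural definitions — the sum of ORF lengths
over genome length (overlapping bases counted twice) and the union of covered
positions over genome length — because published coding fractions rarely say
which was used. Percentages are rounded half-up to one decimal, matching
printed precision; base R's banker's rounding is deliberately not used.

## Promoter association

Baculovirus late transcription initiates within a (A/T/G)TAAG motif; early
promoters are host-RNA-polymerase TATA promoters with a CAGT initiator. Since
the exact motif set behind any given published count is usually in
supplementary material (and unavailable here), `scan_promoters()` uses the
standard conventions and makes everything configurable via
`promoter_motifs()`:

* late: IUPAC `DTAAG` anywhere in the upstream window;
* early: `TATAA` with a `CAGT` whose start lies 20–40 nt downstream of the
  TATA match's end;
* window: 120 nt immediately 5' of the start codon on the coding strand
  (wrapping the origin on circular genomes).

Upstream windows are scanned as-is even where they overlap the neighbouring
ORF — masking would make calls depend on the annotation order. Calls are
classified `early`, `late`, `both` or `none`; every reported hit carries its
offset (nt between motif start and the ATG) and matched sequence. Calls are
invariant under genome rotation, and widening the window can only add hits.
Published per-genome counts of promoter-associated ORFs should be read as
calibration points for this class of scan, not as exact targets: they depend
on the unpublished window and motif choices.

## Protein homology and gene classes

`align_local()` is exact local (Smith–Waterman) alignment with affine gaps,
delegated to Biostrings, with BLASTP-style defaults: BLOSUM62, gap open 11,
gap extend 1 (a gap of length *k* costs 11 + *k*). Percent identity is
computed over aligned columns with no gap in either sequence — the convention
behind statements like "43% identity over 140 aa" — while `aligned_len`
counts all alignment columns. The scores are verified against a naive
dynamic-programming oracle in the test suite.

`reciprocal_best_hits()` pairs proteins that are each other's *unique*
highest-scoring hit with score ≥ 50 over ≥ 30 aligned columns (configurable).
Uniqueness is strict: a tie for best hit disqualifies the protein, so an
equally-good decoy paralog drops a pair rather than silently picking one.
There is no E-value machinery — score thresholds keep the engine
self-contained and deterministic; this is the one deliberate departure from
BLAST semantics.

`classify_genes()` turns an ortholog table plus per-genome group labels
(e.g. NPV-I, NPV-II, GV) into the usual four classes: `core` (present in
every panel genome), `group-specific` (all genomes of exactly one group, no
others), `unique` (focal genome only), and `shared-subset` otherwise. Class
counts are properties of the panel supplied, not constants of a genome:
changing the panel changes the counts, which is why the package asserts the
procedure, never any published split.

## Dot plots and gene order

`dotplot()` reports every exact shared word (default `word_size = 8`) between
two sequences on both strands; `dotplot_runs()` collapses matches into
maximal exact diagonal (and anti-diagonal) runs, so a planted inversion shows
up as a reverse-strand run at its exact coordinates. Exact word matching
deliberately replaces alignment-based dot plots: it is parameter-light,
verifiable by direct substring comparison, and sufficient to display
co-linearity and inversions at genome scale.

Gene order is compared on signed vectors (`gene_order_vector()`): each genome
lists its orthologs of the focal gene set in genomic order, signed by strand.
Two neighbouring genes form a signed adjacency; `(a, b)` and `(−b, −a)` are
the same adjacency, which makes every comparison invariant to reversing a
whole genome. `conserved_runs()` restricts all vectors to their shared genes
(homolog content differs between genome groups), then reports the maximal
blocks of the focal order whose adjacencies appear in every genome — each
block may sit forward or reversed in any particular genome. A gene conserved
with neither neighbour is a singleton run. `breakpoint_distance()` counts
focal adjacencies missing from the other vector after restriction to the
shared genes; it is symmetric, non-negative, and zero exactly for identity or
global reversal. Vectors are treated as linear (anchored at the granulin
end), so a circular rotation of gene order is one breakpoint — consistent
with comparing genomes that have all been anchored the same way. The gene
panel itself (e.g. a 24-gene core set) is a user input: no published figure
enumerates it completely, so it cannot be hard-coded.

## Alignment, concatenation and maximum parsimony

`progressive_msa()` is a deterministic progressive aligner: pairwise 3-mer
distances, UPGMA guide tree, and profile–profile global dynamic programming
with sum-of-pairs BLOSUM62 scores and a linear gap penalty of −8 per
residue-against-gap column. Ties in the DP prefer substitution, then a gap in
the second profile, then the first. With two sequences this reduces exactly
to Needleman–Wunsch under the same scoring, which is how it is tested. The
aligner is intentionally simple — it is the plumbing under the phylogeny, not
a contribution — and its planted-indel recovery is measured in the tests.

`concatenate()` builds the supermatrix in canonical (alphabetical) gene
order, padding a taxon's missing genes with gaps (recorded in `padded`) and
dropping, with a warning, any taxon present in no gene. Since gaps are
treated as missing data downstream, trimming gappy columns is optional:
`trim_gap_frac = 0.5` drops columns more than half gap, the conventional rule
for "partial" sequence sets; the default keeps every column.

`parsimony_score()` is the Fitch length with gaps and ambiguity codes
(`X`, `B`, `Z`, …) treated as compatible with every state — the PAUP default.
Site patterns are compressed with weights before scoring. `search_mp()` is
seeded random-order stepwise addition followed by nearest-neighbour
interchange to a local optimum, over `n_restarts` independent restarts
(default 10). Every tie — insertion point, NNI neighbour, restart winner — is
broken by canonical newick order, so a fixed seed gives a byte-identical
tree. The search is verified exact against exhaustive enumeration on five and
six taxa; beyond that it is a heuristic, as any parsimony search must be.
`bootstrap_mp()` resamples columns with replacement, reruns the search per
replicate (2 restarts by default), and reports the percentage of replicate
trees containing each internal bipartition of the focal tree; supports are
attached as node labels for newick export, and `tidy()`/`glance()` expose the
splits and fit summary. A zero-variation matrix is flagged as degenerate
rather than silently reported. Branch lengths and likelihood models are out
of scope.

## What the simulator emulates — and what it does not

`simulate_genome()` produces a circular genome with *exactly recoverable*
planted truth under these defaults, chosen once to match the headline
structure of a granulovirus genome: 120 kb, 130 ORFs on both strands (42%
reverse), 61% A+T, ORF lengths 150–1,290 nt, intergenic spacers of at least
160 bp. Construction guarantees, in order:

1. planted ORFs are valid coding sequences (ATG, non-stop interior codons
   drawn with base frequencies matching the A+T target, one stop);
2. an in-frame stop *guard* sits immediately 5' of every planted ATG, so the
   maximal-ORF rule starts each called ORF exactly at the planted start;
3. promoter motifs are written at fixed upstream offsets (late motif start
   30 nt, TATA 70 nt, initiator 40 nt before the ATG) for a configurable
   fraction of ORFs, on the correct strand;
4. the remaining background is a *shuffled multiset* of bases hitting the
   A+T target exactly, not an i.i.d. draw, so composition checks are sharp;
5. a cleanup pass re-enumerates ORFs and converts one fully-background codon
   of every chance ORF into a stop, iterating to a fixed point. Chance ORFs
   confined to a planted ORF's footprint cannot be touched without damaging
   the planted gene — they are left in place, because being shorter than
   their host they are always rejected by the minimal-overlap selection.

The spacer minimum of 160 bp leaves room for the guard and both flanking
ORFs' motifs even in the worst strand arrangement; with 130 ORFs this caps
mean ORF length near 760 nt, which is why the default coding fraction comes
out somewhat below real granulovirus genomes (~86%) — a deliberate trade for
exact truth recovery. The generator does **not** emulate codon usage bias,
repeated gene families (*bro*-like repeats), overlapping genes, promoter
sequence context beyond the planted motifs, or sequencing artefacts. Passing
the planted-truth tests therefore demonstrates the correctness of the
algorithms under the stated conventions, not robustness to every property of
real genomes; the checks against deposited RefSeq records (when their flat
files are supplied locally, see `?refseq_path`) cover the latter.

`simulate_panel()` evolves a gene set down a user tree: per-site amino-acid
substitutions at `subst_rate` per unit branch length, plus seeded inversions
(segment reversed, signs flipped) and transpositions of the gene order at
per-branch Poisson rates, every operation recorded. Zero divergence and zero
rearrangement give byte-identical gene tables across taxa, which pins the
identity behaviour of RBH, gene-order and phylogeny stages.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`local_seed` restores
the caller's RNG state, so library calls never perturb user code). The test
suite exercises 15–30 kb genomes, panels of up to eight taxa, 100-replicate
bootstraps, and exhaustive tree enumeration up to six taxa; the acceptance
script runs the full default study conditions (120 kb genome, 8-taxon panel,
100 bootstrap replicates). These sizes were chosen as the smallest at which
every property under test is non-trivial. Bootstrap convention in the wider
literature is 1,000 replicates; all replicate counts here are arguments, and
100 is used as the routine default for verification runs.

## Known limitations

* GenBank parsing covers single-record nucleotide flat files with simple,
  complement and origin-wrapping two-part join locations — the subset the
  pipeline emits and consumes. Multi-exon joins, multi-record files and
  protein records are rejected explicitly.
* Homology significance is score-based; no extreme-value statistics.
* The parsimony search is exact only where exhaustively verified (≤ 6 taxa);
  larger trees rely on restarts to escape local optima.
* The progressive aligner has no iterative refinement; deep divergence
  (> ~60% amino-acid distance) will degrade column homology and with it
  downstream ortholog and tree quality.
* Conserved-run analysis assumes each focal gene occurs at most once per
  genome; duplicated homologs must be resolved (e.g. best hit only) upstream,
  as `reciprocal_best_hits()` does by construction.
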