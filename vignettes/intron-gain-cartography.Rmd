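---
title: "Cartography and dating of spliceosomal intron gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cartography and dating of spliceosomal intron gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgain)
```

## The problem

Most vertebrate genes lost and gained their spliceosomal introns long
ago; documented *recent* gains are rare enough that each case is worth
careful bookkeeping. Melanocortin receptors (MC1R-MC5R) are a textbook
example of intronless GPCR genes, yet the MC5R and MC2R orthologs of a
small clade of ray-finned fishes with compacted genomes (the pufferfishes
*Takifugu rubripes* and *Tetraodon nigroviridis*, medaka *Oryzias
latipes*, and stickleback *Gasterosteus aculeatus*) carry novel introns at
positions that line up exactly across genes and species, while zebrafish
and tetrapods remain intronless. introgain packages the analysis that
establishes such a pattern: extract the introns, describe them, name their
insertion points in a common reference frame, ask which positions are
conserved, and date the gains on a species tree.

## Position labels

An intron's location is its **CDS offset**: the number of coding
nucleotides 5' of the insertion point. `assign_phase()` converts the
offset to a codon index plus a phase letter -- `a`, `b`, `c` for
insertions after the first, second, or third base of the codon, so phase
`c` sits between codons (standard phase 0; `as_standard_phase()` converts).
Offsets 121, 231 and 420 give the labels `41a`, `77c` and `140c` used
throughout the reference tables. Some of the literature equates phase `c`
with "phase 2"; that usage is inconsistent with the letter definition
above and this package follows the letter definition only.

To compare positions across genes and species, `project_to_reference()`
walks the alignment column of the query codon and renumbers it in a
designated reference protein (human MC5R for the melanocortin work).
When the reference has a gap in that column the label falls back to
query-local numbering with a taxon suffix (`225c-TRU` style) rather than
snapping to the nearest reference residue, because snapping would silently
merge non-homologous positions. Alignments are *inputs*: the package
never aligns, so results are reproducible given the alignment.

## Per-intron descriptors

`extract_introns()` reports, per inter-exon gap and in transcript
orientation: coordinates (1-based inclusive), length, CDS offset, donor
and acceptor dinucleotides, a 4+4 flanking context (`XXXX^YYYY`), GC
percent and an ultrasmall flag.

* **GC** is `100 * (G+C)/length`, with N in the denominator only, rounded
  half-up to one decimal -- the convention used when such tables print
  values like 55.9 or 93.9.
* **Proto-splice compliance** (`classify_proto_splice()`) scores the
  three exonic bases 5' of the insertion point against the MAG consensus
  (M = A/C) and, when available, the first downstream exonic base against
  R = A/G; deviations are reported per slot. The bundled survey table
  records deviations by this rule. One published context (`ATCG`) is
  marked in the original table at the A slot only, although its M-slot T
  also violates M = A/C; the package reports both deviations.
* **Ultrasmall** introns default to `length < 60` bp. The survey calls
  its 18 and 33 bp introns ultrasmall without defining a cutoff; 60 bp is
  the conventional vertebrate minimal-intron scale, flags both cases and
  passes the smallest ordinary intron (87 bp). The threshold is an
  argument.
* **Simple repeats** (`find_simple_repeats()`) are perfect tandem runs of
  1-6 nt primitive units, at least 3 copies and 12 bp by default. A
  maximal periodic run is trimmed at its 5' end to a whole number of
  copies, so the reported interval starts on a unit boundary -- this is
  what makes a `GTG(CGG)10` sequence report `(CGG)n` from position 4
  rather than a `GCG`-phased run from position 3. Overlaps resolve
  longest-run-wins. Complex elements (SINEs, LINEs, DNA transposons) are
  never detected natively; they are imported from an external annotation
  TSV (`read_repeat_annotation()`), which warns on -- but keeps -- rows
  whose interval exceeds the stated intron length, since one published
  row has exactly that defect.

## Conservation and dating

`build_presence_matrix()` turns projected introns into a taxon-gene by
position matrix with cells present/absent/unknown. Unknown means the gene
was not available for that taxon; unknowns are never evidence of loss.
Label equality is exact (residue + phase + reference): the operative
criterion for calling positions identical is identical numbering and
identical phase, with no fuzzy window.

`dollo_gain()` maps a position's presence vector onto a dated species
tree under Dollo parsimony (one gain, any number of losses). The gain
lands on the edge above the MRCA of the present taxa -- for a single
present taxon, its terminal edge -- and is dated to the interval between
the MRCA's age and its parent's age. Losses are charged to the topmost
edges below the MRCA whose subtrees contain absences but no presences.
The test suite checks this against brute-force enumeration of all
single-gain assignments on random trees of up to 8 leaves.

The bundled seven-taxon tree carries node ages as `name#age` labels; ages
can alternatively be derived from branch lengths plus a root age, but the
two dialects never mix within a file. Its two anchor ages are the
zebrafish/Acanthopterygii split at 320 MY and the crown of the four
fishes at 190 MY; the remaining ages (tetraodontid crown 96 MY,
medaka-stickleback 110 MY, root 450 MY) are round interpolations that do
not affect the gain interval of the acanthopterygian pattern, and they
stay editable in the newick fixture. With presence in the four fishes and
absence in zebrafish and tetrapods, the gain maps to the Acanthopterygii
stem at 190-320 MY with zero losses:

```{r}
tree <- acanthopterygii_tree()
dollo_gain(tree, c(Takifugu = 1, Tetraodon = 1, medaka = 1,
                   stickleback = 1, zebrafish = 0, tetrapods = 0))
```

## DRY-motif codon usage

The rhodopsin-family DRY tripeptide at the end of TM3 hosts a recurrent
phase-c intron in many GPCRs. `scan_dry_motifs()` matches the variant
pattern `[DEHLIS][R][YFSN]` (configurable) over a protein/CDS pair and
records each hit's codons. `proto_splice_competent()` captures why the
motif is an insertion hotspot: the third base of the first codon plus the
first two bases of the arginine codon form the exonic MAG context, which
requires an AGR-family arginine codon (AGA/AGG, never CGN) preceded by a
codon ending in A or C. The test suite verifies this by exhaustive
enumeration of all first-position x arginine codon pairs.
`codon_usage_matrix()` tallies per-position nucleotide counts over the
9-nt motif coding strings (the counts behind a sequence logo, insertion
marker after position 5), and `compare_genome_sets()` differences two
such matrices as column frequencies.

## The synthetic-data generator

`simulate_intron_gain()` makes every stage testable without downloads.
It emulates the study scenario: an intronless ancestral single-exon
GPCR-like CDS (default 350 codons; ATG followed by codons uniform over
the 61 sense codons), evolved along the dated tree by per-branch
Jukes-Cantor-style substitutions (`substitution_rate` expected
substitutions per site per MY; codons mutated into stops are re-drawn),
with introns materialised on every tip descending from each
`insertion_spec()` branch.

Choices that matter for what the tests can claim:

* **No indels in coding sequence.** The true alignment is the gap-free
  stack of tip translations, so projected labels are exactly recoverable
  at any substitution rate; intron placement is substitution-independent.
  Robustness to gapped alignments is exercised separately with hand-built
  alignments in the projection tests.
* **GC targeting by rejection sampling** on the intron interior (GT/AG
  termini fixed), tolerance plus or minus 1 percentage point; an
  unachievable target (e.g. GC 0 with GT...AG ends, or a GC-rich repeat
  in a short AT-rich intron) aborts with the offending spec named.
* **Proto-splice enforcement at generation time.** When a spec requests
  a proto-splice context, the ancestral codons around the site are
  recoded (synonymously when the random amino acids allow, otherwise
  re-drawn from compatible sense codons) and the three window bases are
  held invariant during evolution -- the same constraint that keeps real
  proto-splice sites recognisable. Fixing a site in an externally
  supplied sequence remains strictly synonymous and is rejected with a
  report when impossible.
* **Intron length range 18-10000 bp** mirrors the observed novel-intron
  scale (87-4500 bp for ordinary introns plus the 18/33 bp ultrasmall
  pair).
* A repeat spec is constrained to fit inside the interior. The published
  33 bp intron with a `(CGG)n` annotation spanning 4-33 cannot coexist
  with a GT...AG acceptor; the matching simulator scenario therefore
  embeds nine CGG copies (27 bp), which the detector recovers.

Identical seed and configuration give byte-identical output. What the
simulator does *not* emulate: rate heterogeneity, selection, indels,
transposon sequence models, or intron sequence divergence after gain (all
descendants of a gain branch share the inserted sequence). Passing the
end-to-end tests therefore demonstrates correctness of the coordinate
arithmetic, descriptor computation, projection and gain mapping -- not
robustness to alignment error or gene-prediction error in real data.

## Problem sizes

The shipped tests run the simulator at 40-300 ancestral codons on the
seven-taxon tree, enumerate Dollo assignments on random trees of 4-8
leaves, and use the 18-intron survey fixture; these sizes make the whole
suite run in well under a minute while still covering every code path,
including a 4500 bp simulated intron at the survey's extreme GC values.

## Limitations

Gene structures are inputs (GFF3 or exon tables): the package does no
gene prediction, ortholog retrieval, tree inference, alignment or
transmembrane annotation. Probabilistic gain/loss models are out of
scope; Dollo parsimony is the inference criterion, which by construction
cannot detect parallel independent gains at one position.
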