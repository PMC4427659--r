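---
title: "Profile-based screening for endospore-formation marker genes"
author: "sporescan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based screening for endospore-formation marker genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporescan)
```

# Motivation

Endospore-forming *Firmicutes* carry a small set of sporulation genes —
most prominently *spo0A*, the master regulator committing a cell to
sporulation, and *gpr*, the germination protease — that are essentially
restricted to this group and therefore work as presence/absence markers
for endospore formers in sequence collections. Because endospores resist
standard DNA extraction, these organisms are easily under-detected in
metagenomes; a sensitive, profile-based search for the marker genes is a
way to quantify that under-detection. `sporescan` implements the full
marker-detection workflow: ortholog delineation across reference
proteomes, construction of a Gribskov-style scoring profile from a marker
alignment, calibration of a score cutoff against shuffled-sequence nulls,
validation on positive and negative genomes, six-frame screening of
metagenome contigs, and quality control plus profile confirmation of
marker amplicon reads. A seeded synthetic-data generator reproduces each
stage's input shape so the entire workflow is testable without any
external download.

# The profile model

A profile is built from a multiple alignment of `N` marker proteins
(`MarkerAlignment`). For alignment column `p` and alphabet residue `a`
the position score is the Gribskov average

$$ M_{p,a} = \frac{1}{N} \sum_{s\,:\,x_{s,p} \neq \texttt{-}} S(x_{s,p}, a), $$

where `S` is a symmetric substitution matrix (BLOSUM62 by default) and
gap cells contribute zero to the sum. This construction is invariant
under duplication of alignment rows. Per-position gap penalties are the
global penalties scaled by the column's non-gap fraction, so positions
that are mostly gaps in the alignment are cheap to skip:

$$ g^{open}_p = G_{open} \cdot f_p, \qquad g^{ext}_p = G_{ext} \cdot f_p. $$

Defaults are `G_open = 10`, `G_extend = 0.5` in matrix units. To reduce
taxonomic sampling bias, `onePerGenus()` retains a single randomly chosen
sequence per genus (seeded, deterministic) before profile construction.

## Scoring a sequence

`scoreSequence()` computes the optimal *local* alignment of a protein
sequence against the profile by affine-gap dynamic programming (Gotoh
states, implemented in C++). Local alignment is the right mode here:
targets are contigs and fragments that contain the marker as a
sub-region. Conventions, fixed for determinism and shared by the
exhaustive-enumeration oracle in the test suite:

* an alignment starts and ends with a residue matched to a column;
* skipping profile column `p` costs `gapOpen[p]` when the gap opens and
  `gapExtend[p]` per further skipped column — a gap of length `k` costs
  `open + (k-1)·extend`;
* a sequence residue consumed between columns `p` and `p+1` costs the
  mean of the two flanking columns' penalties (the single flanking
  column's value at the profile ends);
* between two consecutive matched columns a gap is purely in the profile
  or purely in the sequence;
* the score is floored at 0 (the empty alignment), and among
  equal-scoring hits the leftmost, then longest, is reported;
* residues outside the profile alphabet (e.g. `X` from ambiguous codons)
  score 0 against every column.

Nucleotide records are searched through `sixFrameFragments()`: all six
frame translations (standard genetic code; ambiguity codons render `X`,
trailing partial codons are dropped) are split at stop codons, and every
stop-free fragment of at least `minAaLen` residues (default 50) is
scored. Overlapping passing hits within a record are reduced greedily by
descending score to a non-overlapping set in nucleotide coordinates.

# Cutoff calibration

Raw profile scores have no portable absolute scale — they depend on the
substitution matrix, the alignment, and the gap parameters — so a cutoff
is always re-derived rather than reused. `calibrateCutoff()` scores the
profile's own sequence set as positives and, for each positive,
`nShuffles` (default 100) whole-sequence residue permutations as a
composition-preserving null. Shuffling is at the amino-acid level, since
profiles live in protein space. The cutoff is placed at the midpoint of
the gap between the two distributions,

$$ c = \tfrac{1}{2}\left(\max(\text{null}) + \min(\text{positive})\right), $$

and calibration *fails* (an error of class
`sporescanCalibrationError`, carrying both distributions) when the
distributions overlap. The midpoint rule is deterministic, symmetric and
auditable; quantile-based rules would be a reasonable alternative but
offer no advantage on the wide margins a conserved family produces.
Shuffle seeds are derived from the single user seed and the (positive,
shuffle) indices by a multiplicative mixing function, so the full null is
reproducible and independent of evaluation order.

# Screening pipelines

**Genome validation.** `validateProfile()` scans labelled genomes and
reports per-genome hit counts. The expected pattern for a well-separated
marker is exactly one passing hit per marker-bearing genome and none in
negative controls; counts are reported faithfully either way.

**Metagenome contigs.** `screenDataset()` keeps contigs *strictly longer
than* 800 bp (the boundary is read literally: an 800 bp contig is
excluded), six-frame translates the survivors and scores the fragments.
Contigs meet the protein profile through translation; that is the only
coherent reading for a protein-space profile, and it is made explicit
here rather than left implicit.

**Amplicon QC.** `ampliconPipeline()` chains four stages: a Phred
quality filter (`minQ = 30`; "minimum of 30" is interpreted as *mean*
read quality by default, the common convention for read-level quality
summaries of long amplicon reads, with a strict per-base mode
available), a length filter that *removes reads shorter than* 600 bp
(600 itself is kept), a full-length ORF requirement (the first of the
six frames, in the order +1, +2, +3, −1, −2, −3, whose translation of
the whole read is stop-free), and profile confirmation
(`score >= cutoff`). Stage counts are non-increasing by construction and
are carried in the result object.

# Orthology

Ortholog groups across reference proteomes are delineated from best
reciprocal hits: every protein is aligned against all proteins of every
*other* species (same-species comparisons are skipped, avoiding
paralogs), the best-scoring target per species is retained (ties broken
by lexicographic sequence id), and pairs that are each other's best
match become BRH edges. Groups are the connected components of the BRH
graph with at least two members. The pairwise engine is the same optimal
local aligner used for profiles, run with BLASTp-like defaults (BLOSUM62,
gap open 11, extend 1) — at curated marker-set scale optimal alignment
subsumes a heuristic search, and no e-value model is needed because BRH
only requires the "best match" ordering. Full OrthoDB-style clustering
(e-value triangulation, in-paralog expansion) is deliberately simplified
to connected components, which are its deterministic core.

# The synthetic generator

`makeFamily()` draws a consensus from background amino-acid frequencies
and evolves descendants by i.i.d. per-site substitution (uniform over
the 19 alternative residues) and single-residue indels. Indels are
restricted to single residues so that the returned alignment tracks
positions exactly — fixtures need exact positional ground truth more
than biological realism. Defaults (14 sequences, 150-residue consensus,
substitution rate 0.15, indel rate 0.01) emulate a curated marker set of
about a dozen moderately diverged family members. Under this model two
descendants agree at a site with probability \((1-r)^2 + r^2/19\); the
test suite checks the empirical identity against this closed form.

`makeContigSet()` embeds a start/stop-framed, randomly reverse-translated
copy of a marker protein at a random offset and strand inside decoy
sequence drawn i.i.d. from a configurable nucleotide composition, and
returns exact ground-truth coordinates. `makeAmplicons()` emits
codon-aligned windows of the reverse-translated marker (so frame +1 is
always stop-free) with normally distributed, clipped integer Phred
qualities — emulating clean marker amplicons around the filter
thresholds. What the generators do *not* model: sequencing error
profiles (homopolymer errors, chimeras), codon usage bias, repeat
structure, or realistic taxon abundances. Passing tests therefore show
the algorithmic chain is correct on data matching its assumptions, not
that real metagenomes will separate as cleanly.

# Numerical and design choices

* **Translation**: standard genetic code (table 1) throughout — all the
  relevant taxa are bacteria; no initiator-codon special-casing, so the
  first codon of a window translates by the same table as any other.
* **Alphabet handling**: `U` is accepted on input and stored as `T`;
  codons containing IUPAC ambiguity codes translate to `X`; `X` scores
  through the substitution matrix (0 against columns when absent).
* **Determinism**: every random choice (genus sampling, shuffles,
  generators) flows from one user seed through an integer mixing
  function; reruns are byte-identical, and results are independent of
  record order (screen hits are sorted and tested for permutation
  invariance).
* **Degenerate inputs**: empty FASTA files read as empty sets; empty
  sequences are scoring errors; an all-negative score row yields a
  score-0 degenerate hit flagged as not passed; profiles must have at
  least one position and no all-gap alignment columns.
* **Serialization**: profiles round-trip bit-exactly through a versioned
  TSV (numbers written with 17 significant digits); calibrations
  round-trip through JSON.

# Problem sizes in the shipped checks

The test suite and the acceptance script run the whole workflow at desk
scale, chosen to exercise every code path with comfortable statistical
margins: 14-sequence families over 150-residue consensi, 10 positive and
10 negative synthetic genomes, screens of ~100 contigs with 3 embedded
markers, 100-replicate calibration sweeps at substitution rate 0.3, and
exhaustive dynamic-programming verification against a brute-force
enumerator for all profile lengths up to 4 against sequences up to 5
residues over a reduced alphabet.

# Known limitations

* Profile scores are not comparable across substitution matrices or gap
  settings; cutoffs must be recalibrated whenever any of these change.
* The BRH clustering has no in-paralog handling: recent duplicates
  within a species are left out of groups by construction.
* The amplicon ORF rule requires the *entire* read to be stop-free in
  some frame; sequencing errors that introduce stops reject otherwise
  genuine marker reads (a real effect on noisy platforms).
* No extreme-value model of the null is fitted; the midpoint cutoff is
  only meaningful when the positive and null distributions separate.

# Session info

```{r}
sessionInfo()
```
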