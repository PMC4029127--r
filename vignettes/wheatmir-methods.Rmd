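---
title: "Models and design of the wheatmir miRNA discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the wheatmir miRNA discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wheatmir` re-implements, as a tested and reusable R pipeline, the analysis
path from raw multi-tissue small RNA sequencing reads to miRNA annotation in
wheat: read cleaning and unique-tag collapsing, exact genome matching,
removal of reads resembling structural non-coding RNAs, exact-match
assignment of known miRNAs with conservation classing, hairpin-based
discovery of novel and candidate miRNAs with miRNA* evidence, RPM expression
profiling with tissue-preference classes, complementarity-based target
prediction with a site-accessibility filter, and comparative-CT qPCR
analysis with platform concordance. A synthetic-data module generates toy
genomes, planted MIRNA hairpins and five tissue libraries with full per-read
ground truth, so that every downstream stage is testable without access to
sequencing archives.

# Read cleaning and collapsing

Raw tags are 50-nt Illumina-style reads: the sequenced insert followed by
the 3' adapter. Cleaning proceeds per read: reads failing a mean Phred
threshold (default 20 — the convention adopted here, since "low quality" has
no universal definition) are dropped; reads beginning with the 5' adapter
are discarded as adapter contaminants (the insert boundary of such reads is
ambiguous, so discarding rather than trimming is the default); the 3'
adapter is located by an exact 8-nt seed whose extension must match the
adapter exactly, and reads without a locatable adapter are discarded for the
same boundary-ambiguity reason (both behaviours are configurable). Surviving
inserts must be 18–30 nt, and must not be dominated by low-complexity
repeats: a read is removed when its longest homopolymer run or longest
dinucleotide-repeat run covers more than half of its length. Every discard
is tallied by reason, and the tallies partition the input exactly — a
property enforced by the test suite.

Clean reads are pooled per library into a table of distinct sequences with
per-library redundant counts. All later stages work on this table; "unique"
counts refer to distinct sequences, "redundant" counts to reads.

# Annotation

**Genome matching.** Reads are matched to contigs by exact, full-length
search on both strands (T/U treated as equivalent), using width-grouped
`PDict`/`matchPDict` from Biostrings; the test suite proves equivalence with
a naive substring scan. The copy number of each read (loci per genome) is
recorded and used later by the discovery copy-number cap.

**ncRNA removal.** A read is removed when it aligns to an rRNA/tRNA/
snRNA/snoRNA reference with identity above 0.90. Identity is defined as
matching bases divided by *read length*, the stricter of the possible
readings, and the alignment is ungapped and full-length (mismatch budget
`floor(len * 0.1)`, strict inequality); gapped local alignment adds little
for short degradation fragments and would cost determinism. Both strands
are checked.

**Known miRNAs.** A read is assigned to a known miRNA only when sequence
*and* length match a catalogue entry exactly. Catalogue entries carry
`name|family|species` headers; matches whose entry has no wheat tag are
flagged as requiring wheat precursor validation. Family conservation over
the six reference species (three dicots: Arabidopsis, soybean, Populus;
three monocots: rice, maize, Brachypodium) is classed as highly conserved
(all six), moderately conserved (at least one but not all), or
non-conserved (none).

# Hairpin discovery

For each unassigned read of mature length (20–23 nt), candidate precursor
windows are cut around each genomic locus, placing the read on either arm
with a grid of spacer extents up to the maximal arm span (300 nt) plus
20-nt flanks. All windows are folded in one batched call to ViennaRNA's
`RNAfold` (the pipeline's folding engine throughout), and the
miRNA/miRNA* duplex is read off the dot-bracket: the star arm spans the
positions pairing with the mature, shifted for the canonical Dicer 2-nt 3'
overhangs; walking consecutive paired mature bases yields paired-base,
mismatch and bulge counts, where a mismatch is the symmetric part of an
internal loop and an asymmetric bulge is the surplus on one side (the
reported asymmetry is the largest surplus). A brute-force pairing-table
walk reproduces these metrics on every structure in the test suite.

A window passes when: mature length 20–23 nt; precursor MFE ≤ −18 kcal/mol;
≥ 16 mature bases paired; every bulge ≤ 2 nt, at most 2 asymmetric bulges,
asymmetry ≤ 2; arm span ≤ 300 nt; ≤ 4 mismatched mature bases, relaxed to 5
when the star is detected; and ≤ 20 genomic copies. "Maximal/minimal"
thresholds are read as inclusive; the locus-read fractions below are strict
inequalities, following the literal wording of each clause. Among passing
windows the lowest-MFE one is kept (ties: shortest precursor).

Two read-level rules then apply, on redundant counts: reads on the
mature/star arms must account for more than 95% of all precursor-mapped
reads, and reads exactly matching the mature sequence for more than 75% of
the arm reads ("reliable reads" is read literally as exact matches; the arm
reads are used as the denominator of the 75% rule, the more conservative of
the two possible readings of that clause — both choices are configurable).
The star is "detected" when any read's 5' end lies within ±2 nt of the
predicted star 5' end in any library, the conventional isomiR tolerance
(configurable).

A locus passing everything is **novel** if its mature abundance reaches 5
RPM in at least one tissue *and* a star read was observed; with the
abundance but no star read it is a **candidate**; otherwise it is rejected
with every violated criterion listed. Loci are deduplicated dominant-arm
first: reads are processed in decreasing redundant count, and a read whose
genomic position falls inside an already-accepted precursor (an isomiR or
the star of that locus) is absorbed by it.

# Expression profiling

Counts are normalised to reads per million of total miRNA-mapped reads per
library (RPM) — the literal reading of the normalisation used for the
published tables; the denominator is configurable to total clean reads.
Log2 fold changes are taken against the seedlings library and are missing
when either side is zero; reported values are rounded to one decimal, half
away from zero, while internal values stay unrounded (which is also why
family totals are summed before rounding). Tissue preference classes:
*seed-specific* (nothing in seedlings or flag leaves, expression in at
least one seed stage), *leaf-specific* (mirrored), *seed-preferential*
(best seed fold change positive and above the flag-leaf one),
*leaf-preferential* (mirrored), else none; missing fold changes compare as
−∞. Presence for the "specific" classes means RPM > 0 by default
(configurable floor). Composition statistics (5'-nucleotide and length
fractions) and per-tissue miRNA* accumulation with star-only flags complete
the profiling stage.

# Target prediction

Targets are scored by a complementarity expectation penalty: mismatch 1.0,
G:U wobble 0.5, gap 2.0, each doubled at miRNA positions 2–13 (1-based from
the miRNA 5' end), with at most 20 miRNA positions scored. These weights
follow the established plant target-scoring scheme; only the thresholds are
fixed by the reference parameterization (expectation ≤ 3, UPE ≤ 25, 17/13
flanks, central positions 9–11), so all weights are configurable and
labelled as defaults. Alignments allow up to one gap by default — under the
default weights two gaps already cost more than the expectation cut-off —
and ties prefer gap-free, then leftmost alignments. Scanning uses a
complementarity prefilter that is conservative for any site within the
cut-off, and the suite proves equivalence with exhaustive
position-by-position scoring. Site accessibility (UPE) is the energy
difference between the site window (17 nt upstream, 13 nt downstream,
clipped at transcript ends) folded freely and folded with the site forced
unpaired (RNAfold hard constraints); folding failure retains the hit with a
missing UPE and a warning rather than silently dropping it. A mismatch or
gap at miRNA positions 9–11 calls translational inhibition; otherwise
cleavage (wobbles do not count as mismatches for this rule).

# qPCR analysis

Technical replicates are averaged as arithmetic mean CT before ΔCT — the
conventional choice, as the reference protocol runs triplicates without
stating an aggregation. Per miRNA the calibrator is the sample with the
lowest mean ΔCT, whose relative expression is set to 1.0; other samples get
2^−ΔΔCT, so every value lies in (0, 1] and the per-miRNA maximum is exactly
1.0. For platform concordance each miRNA's sequencing profile is scaled so
its highest RPM across the five samples is 1.0, matching the calibrator
convention, and pairs are pooled across miRNAs for a single Pearson
correlation (pooling, rather than averaging per-miRNA fits, is the default
because the published comparison pools one panel).

# The synthetic study

The simulator is the package's ground-truth instrument, and its defaults
are the study conditions for all recovery tests: four 12-kb contigs; 6
known, 12 novel and 4 star-less (candidate) MIRNA loci, of which 3 novel
loci are seed-specific and 2 leaf-specific; an ncRNA fraction of 15%
sampled verbatim from planted rRNA/tRNA-like references; 20,000 raw 50-nt
tags per library with the 3' adapter appended and 2% 5'-adapter
contaminants; locus reads composed of mature isoforms (90% exact, 6%/4%
±1 nt at the 3' end — exercising the 75% reliable-read rule), star reads at
7% of mature and loop-degradation reads at 1.2%; per-locus expression
weights log-uniform between 100 and 4000 RPM with ±70% tissue variation.
Mature sequences lean GC in the stem (keeping the planned duplex the MFE
fold) and start with U 55% of the time, as mature plant miRNAs
predominantly do. Sequencing errors are off by default (the exact-match
genome step implies error-free tags dominate) but available as a uniform
substitution rate. Library depth is configurable, not calibrated: no
per-tissue depth targets exist to calibrate against, and 20,000 reads keep
the default test runs fast while leaving every planted locus two orders of
magnitude above the 5 RPM threshold.

Hairpin construction is *certified*, not merely intended: a candidate
precursor (flank–mature–loop–star–flank, or mirrored) is built with planned
mismatch substitutions and star-side bulges positioned for 2-nt 3'
overhangs, folded, and accepted only when the observed duplex metrics equal
the plan and pass the discovery thresholds; otherwise new random sequences
are drawn. Mismatch positions place the same base on both strands, which
can neither pair nor wobble, so planned counts survive folding. Planted
loci are separated by at least 700 nt so no precursor window of one locus
reaches another.

What the simulation does *not* emulate: hexaploid homeolog structure,
realistic wheat base composition, multi-locus miRNA families, RNA
degradation biases, or sequencing error profiles. Passing recovery tests
therefore demonstrates the correctness of the pipeline's logic under
Dicer-consistent loci, not its robustness to every artefact of real
libraries.

# Numerical and degenerate-input choices

Folding is delegated to RNAfold and is deterministic per sequence; MFE
comparisons use the printed kcal/mol values. Window selection and target
deduplication have total, deterministic tie-breaks (MFE then length;
expectation then gaps then position). Empty inputs return empty outputs
(empty FASTQ warns; empty size distributions avoid division by zero; zero
precursor-mapped reads fail the locus rule with a reason rather than
dividing by zero). Zero RPM denominators are an error naming the library.
Rounding for reported values is half-away-from-zero, applied only at the
reporting boundary. All simulation and pipeline randomness flows from one
integer seed; identical configurations give byte-identical outputs.

The default test runs use the simulator defaults above (20,000 reads per
library, 22 loci) for the recovery checks and a reduced configuration
(1,500 reads, 6 loci) for determinism and toggle checks; these sizes were
chosen so the full suite exercises every stage end to end in a few minutes.

# Known limitations

Known miRNAs whose catalogue entry lacks a wheat tag are flagged for
precursor validation but the pipeline does not currently merge their
validated loci back into the known table; they are simply excluded from
novel discovery. Target prediction allows at most one gap by default, which
is complete for the default expectation cut-off but not for substantially
relaxed ones. The ncRNA filter is ungapped by design. GFF3/BED exports are
limited to the tabular locus output.
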