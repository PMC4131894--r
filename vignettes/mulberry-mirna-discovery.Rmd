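---
title: "Methods: miRNA discovery, conservation profiling and expression analysis in mulmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, conservation profiling and expression analysis in mulmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulmir)
```

mulmir re-implements a complete plant small-RNA analysis for mulberry
tissue libraries: read cleaning, annotation, conserved-miRNA cataloguing
with cross-species profiling, hairpin-based novel-miRNA prediction, RPM
tissue-bias calling, target prediction and 2^−ΔΔCt quantification. This
vignette documents the models, the parameters and their defaults, the
numerical choices inside the folding engine, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the method description leaves room.

## Read cleaning and annotation

`clean_reads()` discards reads of mean Phred quality below 20 (the
published filtering names only "low-quality reads", so a concrete,
configurable threshold was fixed), locates the 3' adapter by the longest
adapter-prefix match with at least 6 nt overlap and at most one mismatch,
drops reads containing N, and retains trimmed inserts of 18–30 nt — the
gel-excision window of the library protocol. Reads without a detectable
adapter are kept untrimmed if already inside the window, because collapsed
public datasets often arrive pre-trimmed. Cleaning is idempotent, and
collapsing conserves read mass.

`classify()` assigns each unique read one category by a fixed cascade:
rRNA → tRNA → snRNA → snoRNA → miRNA → repeat → exon (sense/antisense) →
intron (sense/antisense) → unannotated. Non-coding hits are exact
substrings of a reference sequence in either orientation; the miRNA step
requires an exact full-length match to a mature reference. miRNA is
deliberately tested *after* the structural RNA classes but *before*
repeat/exon/intron, mirroring an Rfam-before-miRBase workflow while not
losing miRNAs that overlap annotated genes. Because the cascade order is
fixed by category, annotation is invariant to the order in which reference
sets are supplied.

## The folding engine

Novel-miRNA prediction needs secondary structure, minimum free energy
(MFE) and duplex statistics. mulmir ships its own engine so that all
results are deterministic and self-contained: a Nussinov-style dynamic
program scored with a nearest-neighbor stacked-pair energy table
(Turner-like values in kcal/mol, symmetrised so a helix has the same
energy read from either strand, clamped to ≤ 0; see
`stack_energy_table()`). Hairpin loops are at least 3 nt. Closing a
hairpin loop or a non-stacked interior (bulge, internal or multibranch
loop) costs a flat +3 kcal/mol. That penalty matters: with zero-cost
loops, scattered 2–3-pair helices between a candidate mature and random
flanking sequence are "free" and can outcompete a genuinely weak stem;
the penalty makes isolated pairs unprofitable and recovers the expected
hairpin geometry. Traceback prefers stacked continuations, making
structures reproducible. An oracle mode (`engine = "maxpair"`, −1 per
pair, no penalties) exists purely so the engine can be checked against an
exhaustive maximum-pairing recursion on short sequences.

The engine is simplified by design: no partition function, no
temperature dependence, no sequence-dependent loop energies, no
pseudoknots. MFE thresholds quoted below are therefore engine-relative;
they sit in the same range as thermodynamic folders for stem-loops of
this size, but should not be compared digit-for-digit with other
software.

`mfei()` computes AMFE = |MFE|/L × 100 and MFEI = AMFE / GC%. MFEI is
undefined at GC = 0 and errors there. It is scale-invariant: doubling a
sequence and its MFE leaves it unchanged.

`duplex()` performs ungapped antiparallel alignment (position *i* of the
miRNA against position L−i+1 of the site), classes each position WC, G:U
or mismatch, counts G:U as half a mismatch, and sums stack energies over
consecutive paired positions. Bulged duplex alignment exists only on the
miRNA:miRNA* path inside hairpin evaluation, where bulges are explicit
criteria; the target rules mention only mismatches, so target scanning
stays ungapped.

## Novel miRNA discovery

`discovery_params()` carries the criteria with their published defaults:
mature length 18–25 nt, seed-read ("reference") length 20–23 nt, at most
20 genomic copies, precursor MFE strictly below −18 kcal/mol, at most
300 nt between miRNA and miRNA*, at least 16 duplex base pairs, duplex
bulge ≤ 4 nt, duplex asymmetry ≤ 4 nt, 20-nt flanks; manual criteria
MFEI ≥ 0.85 (inclusive), fewer than 3 asymmetric bulges, fewer than 4
mismatches. Strictness follows the wording: "less than −18" is strict,
"at least 0.85" inclusive, "maximum 4" inclusive.

For each genome-mapped unannotated read, `candidate_precursors()` excises
two windows (mature assumed on the 5' or the 3' arm). The excision radius
is `max_star_space + max mature length + flank` rather than the bare
300-nt bound, so that a star sitting slightly beyond the legal gap is
still inside the window and fails the star-space criterion specifically,
instead of degenerating into a pair-count failure. Windows are clipped at
contig ends; the precursor used for MFE/MFEI is re-trimmed to the folded
hairpin extent plus 20-nt flanks.

`evaluate_candidate()` folds the window, requires the read to lie on one
arm (loop-spanning reads are rejected with that reason), and predicts the
miRNA* from the pairing partners of the mature with the 2-nt 3'-overhang
convention of Dicer processing; star matching in the libraries tolerates
±2-nt end shifts, since exact star reads are rare. Duplex statistics walk
the paired anchors: symmetric gaps count as mismatches, one-sided gaps as
bulge events of their length, asymmetry is the absolute difference
between total mature-side and star-side unpaired nucleotides inside the
duplex, and unpaired mature termini count as mismatches (the terminal
overhangs belong to the star by construction). "Asymmetric bulges < 3"
is read as at most 2 bulge events; "mismatches < 4" as at most 3
unpaired-position mismatches.

`manual_filter()` implements the acceptance logic: all structural
(Mireap-parameter) criteria must pass; a candidate failing one of the
three manual criteria is rescued if its miRNA* was observed. The rescue
branch deliberately does **not** apply to structural failures — the
stricter of the two possible readings. The copy-number criterion applies
at catalog level: `build_novel_catalog()` groups accepted candidates by
mature sequence, drops entries at more than 20 loci entirely, and names
the rest miRn1, miRn2, … in descending total count. An entry whose mature
sequence matches the predicted miRNA* of a more abundant entry (within
the 2-nt end tolerance) is folded into that entry rather than reported
separately — the two reads are the two strands of one duplex.

## Conserved catalog and conservation profiles

"Perfectly matched" is read strictly: a unique read must be identical,
full length, to a reference mature (no shifted or trimmed isomiR
variants; isomiR handling is out of scope). Presence in a tissue means
count > 0. Within a family, suffix letters are assigned in descending
total-count order; a single-member family gets a bare name without a
letter, matching the published naming of singleton families. No
downstream statistic depends on letter assignment, which is not
recoverable from the publication.

Cross-species symbols use minimum edit distance (unit costs, indels
count 1) to any mature of the species, so matures of unequal length
remain comparable: distance 0 → `++`, 1–3 → `+`, otherwise (or an empty
species set) → `-`. A family counts as present in a species if any
member is `+` or `++` there; the "less-conserved" set is families seen
in at most two of the seven comparison species.

## Expression, tissue bias and qRT-PCR

RPM uses the per-library clean-read totals as denominators — the
published analysis says only "normalized reads", and the clean-read
choice reproduces the published leaf- and bark-biased family sets. Bias
calls operate at family level on counts summed before scaling: a unit is
biased to a tissue when its RPM there is ≥ 2× its RPM in each other
tissue and strictly positive (boundary inclusive; all-zero rows and ties
are unbiased); it is additionally *specific* when its raw count is zero
elsewhere. Under this denominator one published male-flower family sits
about 1 % short of the 2× bound, and the rule also admits a
vanishing-count family — the exact published denominator is
undeterminable, so male-flower counts are not treated as a reproducible
statistic. Bias calls are invariant to uniform rescaling of all library
totals.

`ddct()` averages replicate Cts per assay and sample, combines the two
reference assays (5.8S rRNA, RPL15) by the arithmetic mean of their mean
Cts (equivalently the geometric mean of linear quantities; the
publication does not state the combination), and computes
ΔCt, ΔΔCt against the calibrator sample and RQ = 2^−ΔΔCt. The calibrator
always has RQ = 1 exactly.

## Target prediction

`score_site()` checks the six rules in order, so `first_violated` is
well-defined: (1) weighted total ≤ 4 with G:U = 0.5; (2) no run of more
than 2 consecutive mismatch positions; (3) no two adjacent mismatch
positions both inside 2–12; (4) positions 10 and 11 Watson–Crick;
(5) ≤ 2.5 weighted mismatches in positions 1–12; (6) duplex energy at
least 75 % of the perfect-complement energy. A G:U wobble contributes
half weight to the totals but counts as a mismatch *position* for rules
2–4 — the strict reading of "no mismatches in the position 10 and 11";
`gu_positional = "pair"` switches to the lenient reading. Scanning is
ungapped and sense-strand only; accepted sites sort by weighted total,
then energy ratio. `annotate_targets()` keeps each transcript's best site
per miRNA and fills missing descriptions with "NA".

## The synthetic-data generator

`simulate_dataset()` emulates the study design: three tissue libraries at
50,000 reads by default, 24-nt-dominated background length profiles for
leaf and bark and a 21-nt-dominated profile for male flower, ~10 % rRNA
and smaller tRNA/snRNA/snoRNA/repeat fractions drawn as fragments of
generated reference sets, sense/antisense exonic and intronic degradation
fragments, planted conserved miRNAs in six families (one family biased
per tissue at a planted 3× enrichment — comfortably above the 2× decision
boundary at this depth, where multinomial noise on a few hundred counts
is a few percent), planted novel hairpins, miRNA* reads for the rescue
and star-dominance cases, transcripts with planted target sites, and a
triplicate Ct table with designed fold changes 1 : 0.25 : 8.

Every planted hairpin is verified *at generation time* by running the
package's own candidate evaluator in the exact committed genome context
(items are spaced by ≥ 500 nt, more than the excision radius, so later
items cannot disturb earlier windows); construction is resampled up to
100 times before the generator gives up with the criterion name. Each
knockout decoy violates exactly one criterion. Two structural facts are
worth recording. First, a mature-length-only violation cannot exist:
the mature-length window (18–25 nt) strictly contains the seed-read
window (20–23 nt), so any length outside the former is outside the
latter; the over-long decoy is therefore verified to fail exactly the
two length criteria together. Second, the copy-number decoy necessarily
occupies 21 identical loci, each individually compliant — its violation
exists only at catalog level. Planted stems always carry at least one
imperfection: a perfect stem would make the mature read the exact
reverse complement of its own star and create a mirror-image locus on
the opposite strand.

What the generator does **not** emulate: sequencing errors and quality
decay, isomiR end-heterogeneity, genomic repeat structure, correlated
family sequences (family members are independent random sequences,
unlike real paralogs), and realistic transcriptome composition. Passing
recovery tests therefore demonstrates that the pipeline's logic is
correct and its filters are each live — not that real-data performance
matches any published figure. The published headline counts (85/31
conserved, 262 novel at 371 loci, Table-1 category percentages) depend
on the deposited sequencing data and the real genome and are outside
what desk-scale synthetic data can or should reproduce; the shipped
published-catalog fixture covers the statistics that *are* exactly
recomputable.

## Problem sizes and determinism

Default test and acceptance runs use three libraries of 50,000 reads
(module tests reuse a 20,000-read fixture), a ~25 kb two-contig genome
with 23 planted items, 63 species-reference entries, 36 transcripts and
one Ct table — sizes chosen so a full recovery run completes in about a
minute on one core while every planted signal remains statistically
unambiguous. All stochastic draws derive from one user seed; identical
seeds give byte-identical outputs.

## Known limitations

The folding engine's energies are approximate (flat loop penalties, no
dangling ends), so MFE/MFEI thresholds are engine-relative. Target
scanning does not model bulged target sites or translational inhibition.
Conservation profiling compares matures only, not precursors. The
annotation cascade uses exact substring matching, not alignment, so
near-matches to non-coding references fall through to later categories.
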