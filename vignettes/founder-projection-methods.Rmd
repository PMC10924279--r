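---
title: "Founder-sequence alignment projection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-sequence alignment projection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panproject)
```

# The problem

Short-read genotyping against a single linear reference is biased toward the
alleles that happen to sit in the reference: at a heterozygous site, reads
carrying the alternative allele accrue mismatch or gap penalties that
reference-allele reads do not, so they are mapped less often, mapped
elsewhere, or filtered on mapping quality. `panproject` implements the
founder-sequence strategy against this bias: known variation is compressed
into a handful of founder sequences, reads are aligned to the founders (by
any external aligner), and the alignments are projected back onto the
reference so downstream callers operate in ordinary reference coordinates.

This vignette records the models behind each stage, the tunable parameters
and their defaults, the numerical conventions, and the places where the
design was genuinely open.

# Founder generation

## Model

A phased panel over one contig is an allele-index matrix: one row per
haplotype, one column per variant site (0 = reference allele). Founder
generation has two steps.

**Segmentation.** Sites are partitioned into consecutive segments such that
within each segment the haplotypes collapse to at most `F − 1` distinct
allele strings, where `F` is the founder count *including* the reference
sequence (the reference is always indexed alongside the founders). The scan
is greedy left-to-right: extend the current segment site by site, close it
at the earliest position where it already spans at least `L` sites and
taking the next site would exceed the capacity. A trailing segment shorter
than `L` is merged into its predecessor, so all segments span at least `L`
sites unless the whole panel is shorter than `L`.

We chose greedy scanning over a provably minimal segmentation: it preserves
every stated invariant, runs in linear time over the matrix, and on
exhaustive search over all valid segmentations of small panels (up to 8
sites, 6 haplotypes in the test suite) it uses at most one extra segment.
The package does not claim minimality.

**Capacity collapse.** A segment can be forced past capacity when diversity
exceeds `F − 1` before the segment is `L` sites long (or after the trailing
merge). The segment then keeps its `F − 1` most frequent strings (ties
toward the earlier string) and reassigns each remaining haplotype to the
retained string with minimum Hamming distance over the segment's allele
indices (ties toward the lower retained index). Collapse is the one lossy
step: collapsed haplotypes are no longer exact founder mosaics. The
`collapsed` flag on each segment records whether it happened, and the
property tests assert exact reconstructibility precisely in the
configurations where collapse cannot occur (biallelic sites at `L = 1`, or
any collapse-free segmentation).

**Founder reconstruction.** Within a segment, distinct strings are ordered
by descending haplotype support (ties toward first occurrence). Across each
boundary, the two segments' strings are matched greedily by descending
joint support — the number of haplotypes carrying both — with ties toward
the lower index pair. A matched pair with zero joint support is a possible
discontinuation position and increments the recombination count; minimizing
these keeps founders locally faithful to real haplotypes. Founder *k* is
the concatenation of the *k*-th chained string per segment; segments with
fewer strings than founders are padded with the all-reference string.

## Parameters

* `n_founders` (`F`): founder count including the reference; at least 2.
  More founders cover more diversity per segment at the cost of a larger
  alignment index. The CLI default is 4.
* `min_sites` (`L`): minimum segment length, measured in *variant sites*.
  Published founder tools describe this parameter as a distance between
  subgraphs without fixing the unit; we chose sites because segmentation
  operates on the site matrix, and made it configurable. Larger `L` yields
  longer uninterrupted founder stretches (fewer switch points for a read to
  straddle) but forces more collapses.

## The reference-guided MSA

Each site contributes a column block as wide as the longest allele used
there by the reference or any founder; alleles are left-aligned and
right-padded with `-`; reference stretches between sites are copied
gap-free. Ungapping the reference row reproduces the reference exactly, and
ungapping founder row *k* gives founder *k*'s sequence — both asserted in
the tests. This construction is consistent with each founder's pairwise
alignment to the reference, which is all the projection step requires; no
optimal MSA is attempted.

# Alignment projection

## Coordinate index

One left-to-right column walk over (reference row, founder row) produces,
for each ungapped founder position, the projected 0-based reference
position and an insertion flag (the column has no reference base; the
stored position is then the count of reference bases strictly before the
column). Lookup is constant-time. All internal coordinates are 0-based
half-open; SAM emission converts to 1-based `POS`.

## Edit-script rewriting

A read-vs-founder CIGAR is composed with the founder-vs-reference gap
structure in a single pass, linear in the operation count plus the columns
spanned:

* aligned founder bases (`M`/`=`/`X`) in insertion columns become `I`;
* reference bases skipped where the founder row has gaps become `D`,
  attached to the next reference-consuming base — skipped reference bases
  before the first or after the last aligned base are outside the
  alignment, never leading/trailing `D`;
* a read `I` stays `I`; a read `D` over inserted founder bases is elided
  (it consumes neither read nor reference);
* clips pass through.

The rewriter is validated against an independent brute-force oracle that
recomposes the alignment column by column over the MSA; the suite runs 10⁴
random (MSA, alignment) instances with MSAs up to 60 columns and asserts
bit-identical output and query-length conservation in every case.

## Normalization

The projected script is normalized deterministically: adjacent `I`/`D` runs
are paired base-for-base into `M` up to the shorter length (repeated until
stable), runs merge, and boundary insertions become soft clips because SAM
cannot anchor an alignment on an insertion. The `I`/`D` pairing is a
deliberate, deterministic stand-in for local realignment of the affected
read portion: it produces the minimal edit script consistent with the
composition without any heuristic indel left-shifting, and it is idempotent.
Alignments that cover no reference base at all (wholly inside a founder
insertion) are returned flagged unmapped rather than dropped, so read
accounting downstream stays exact.

By default the output uses `M` (aligner convention); `extended = TRUE`
re-splits against the reference into `=`/`X`. `NM` and `MD` are recomputed
when the reference sequence is available and dropped otherwise — never
copied stale. `AS` is preserved.

# Mapping-quality recalculation

## Why

Founder sequences share long identical stretches, so a read can align
equally well to several founders at positions that project to the *same*
reference locus. An aligner unaware of the projection sees multiple
co-optimal placements and reports MAPQ near 0; after projection the
placement is unique. Alignments of a read are therefore partitioned by
(target, projected leftmost, strand), and mapping quality is recomputed
from the best and second-best *partition representatives* (each partition's
maximum-scoring member).

Strand is part of the partition key: the same leftmost coordinate on
opposite strands is a different placement. Members of non-best partitions
receive MAPQ 0 and the secondary flag — consistent with one-best semantics,
while MR-style output still carries them. Both choices are configurable at
the data level (the partition key is built from record fields; secondary
MAPQ is set in one place).

## Scoring scheme

`alignment_score()` reimplements the end-to-end scheme of the short-read
aligner this workflow targets: match bonus 0; mismatch penalty
`MN + floor((MX − MN) · min(q, 40) / 40)` with `MN = 2`, `MX = 6` and `q`
the base quality; ambiguous-base penalty 1; affine gaps at
`5 + 3·length`; soft clips free. The minimum acceptable score is
`−0.6 − 0.6·read_length` and the perfect score 0. All constants are fields
of `scoring_scheme()`.

## MAPQ model

`mapq_model_bt2()` carries the aligner's published end-to-end piecewise
table (maximum 42) as data, so alternative models can be swapped in. With
`diff = max(perfect − min, 1)` and `bestOver = best − min`, unique
alignments map through one threshold table (42/40/24/23/8/3/0); with a
second-best score, the gap `best − second` picks a row and `bestOver` a
column. Two properties worth knowing:

* a tie (`best == second`) yields MAPQ ≤ 1 when the placements differ, but
  42 when they fall into one partition — the operational point of the
  partitioning step;
* the genuine table is *not* globally monotone in the score gap (there are
  corners where a wider gap maps to a slightly lower value, e.g. 25 → 22
  across one row boundary). We kept it faithful rather than smoothing it;
  the tests assert the guarantees it does provide (range, unique ≥ tied,
  tie capped low, unique table monotone in score).

`filter_max_mapq()` implements MM post-processing: keep each read's
maximum-MAPQ record, ties broken by higher alignment score, then lowest
(target, position); the kept record's secondary flag is cleared.

# Evaluation

`pileup_balance()` counts, per heterozygous site, reads supporting the
reference allele (`R`) and the correct alternative (`A`), and reports
`x_i = R/(R+A)`. A read is counted only if its alignment fully encloses the
site — at least one aligned (`M`/`=`/`X`) reference base strictly before
the site start and at least one at or after the site end — and the site is
kept only if such enclosing reads number at least `min_coverage` (default
20). Allele support is called on the expanded alignment string over the
site's reference span (insertions anchored inside the span or at its right
edge included): the bases must reproduce the reference or the alternative
allele exactly. Reads reproducing neither (e.g. carrying a sequencing error
at the site) count toward coverage but toward neither `R` nor `A`; whether
such reads should enter the coverage threshold is not externally specified,
so the conservative reading (they do) is the default and the threshold is a
parameter.

`mean_absolute_error()` is `(1/n)·Σ|x_i − 0.5|`; with reads drawn equally
from both haplotypes, balances should sit at 0.5 and the MAE reflects
sampling noise. `balance_by_length_diff()` buckets by
`len(alt) − len(ref)` with per-bucket n, median, quartiles and MAE.

`alignment_precision_recall()` calls a placement a true positive when it is
within `tolerance` bases (default 5) of the truth on the right contig. A
read aligned elsewhere counts as a false positive *and* a false negative;
an unaligned or missing read as a false negative only. This accounting is
the one choice that keeps both identities: `TP + FN = #reads` (asserted on
every run) and `precision = TP/(TP + FP)` over aligned reads. The false
positive definition is inferred — wrong placements are described as false
negatives where this metric originates, yet a precision is reported — and
both the tolerance and the accounting are parameters of the function, not
constants.

# The synthetic fixture

`simulate_fixture()` is first-class, tested code, not a test-only shim. It
emulates the study design the evaluation metrics assume:

* an i.i.d. uniform A/C/G/T reference (default 100 kb);
* SNP sites at rate 10⁻³ per base and indel sites at 10⁻⁴
  (insertions/deletions equiprobable, lengths uniform on 1..10), spans
  non-overlapping, alleles Bernoulli(0.5) per haplotype across 16
  haplotypes;
* a held-out diploid donor (take-one-out): the last sample's two haplotypes
  are removed from the emitted panel and kept as truth, with their
  heterozygous sites and haplotype-to-reference coordinate maps;
* reads of 100 bp at 40× total coverage, split exactly evenly between the
  two donor haplotypes, uniform starts, substitution errors at 0.2% with
  base quality 40 everywhere except injected errors (quality 10), so
  quality-aware mismatch penalties are exercised deterministically;
* an oracle aligner that places each read at its true reference position
  with the variant-induced CIGAR and MAPQ 42.

One global seed streams into per-stage derived seeds, so each stage is
individually reproducible. The donor's coordinate maps are built by laying
donor haplotypes into the same block MSA used for founders and indexing it
with the projection machinery; the projection machinery itself is validated
against an independent column-walk oracle, so this reuse is not circular.

What the generator does *not* emulate: realistic error and quality profiles,
indel sequencing errors, paired-end inserts, strand sampling (reads are
forward-strand; the evaluation is strand-agnostic), structural variants
beyond 10 bp, and linkage structure in the panel (alleles are independent
per haplotype). Tests passing on this fixture therefore demonstrate the
correctness of the machinery — coordinate arithmetic, filters, accounting —
not performance on real data.

The test suite scales the fixture to its purpose: module tests run 3–20 kb
references at 2–30×; the balance property runs the full 100 kb / 40×
configuration; the projection and scoring oracles run 10⁴ random instances
each; the founder property runs 100 random panels of up to 20 haplotypes
and 200 sites.

# Degenerate inputs and edge conventions

* Overlapping VCF records: first record wins; later overlaps are skipped
  with a warning. Missing genotype calls are reference alleles. Unphased
  genotypes and reference-allele mismatches are hard errors naming the
  record.
* Alignments overrunning the founder end are errors; positions are
  validated against index lengths.
* An empty partition list, an empty balance vector, and unsorted site
  tables are errors, not silent empties.
* Ties are broken deterministically everywhere (documented per function),
  so every pipeline stage is a pure function of its input.

# Known limitations

* Segmentation is greedy, not provably minimal; the measured gap on small
  exhaustive searches is at most one segment.
* The `I`/`D` pairing normalization is a stand-in for full local
  realignment; it never left-shifts indels.
* Mapping qualities follow one aligner's end-to-end model; local-mode
  scoring and paired-end concordance bonuses are out of scope, and
  bit-exactness across aligner versions is not claimed.
* Long reads are unsupported by design: a long read can straddle many
  founder switch points, and the projection of spliced (`N`-heavy)
  alignments is untested beyond basic pass-through.
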