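---
title: "Methods: detecting and typing TERC-flanked interstitial telomeric sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and typing TERC-flanked interstitial telomeric sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tercits)
```

## The model

A TERC-ITS locus is the joint product of two molecular events at a DNA
double-strand break: reverse transcription of a fragment of the
telomerase RNA (TERC) and addition of telomeric `TTAGGG` repeats from
the repeat template that TERC carries. The observable anatomy on the
repaired chromosome is therefore a short interstitial telomeric array
(s-ITS) immediately adjacent to a TERC-like fragment, with the
relative position and orientation of the two parts falling into three
organizations:

* **A** — fragment 5′ of the array and complementary to TERC (the
  array read off the template, the fragment off the 3′ domain that
  folded back);
* **B** — fragment 3′ of the array and in TERC orientation (repeats
  first, then read-through into the adjacent TERC sequence);
* **C** — fragment 5′ of two head-to-head repeat stretches
  (`CCCTAA … TTAGGG`), in TERC orientation.

Because the repair goes through non-homologous end joining, the
junction against the ancestral (empty) allele typically shows a
deletion, a random-sequence addition, both, or neither, and often a
short microhomology between the insert 3′ end and the retained flank.
The pipeline recovers all of these observables from sequence alone.

## Search parameters

The homology search reproduces the blastn parameterisation used for
short nucleotide queries: exact word seeds of length 11, match +2,
mismatch −3, affine gaps costing 5 to open plus 2 per base, and no
low-complexity filtering. Two deliberate departures from a stock BLAST
run:

* **No E-values.** The analysis never used an E-value cutoff as a
  filter, and E-values depend on database size, which would make the
  synthetic tests irreproducible. Hits are gated on raw score
  (`min_score = 30`, i.e. 15 matched bases), configurable.
* **x-drop extension, default 30.** The gapped extension abandons a
  path when its running score falls 30 below the best seen. This
  crosses one affine gap plus several mismatches without truncating
  short TERC-like fragments (published fragments are mostly 25–98 nt).
  With `xdrop >= 2 * gap_open + 20` the extension is exact on
  test-sized sequences, which is what the oracle-equivalence suite
  checks against an independent dynamic program.

Because low-complexity filtering is off, the repeat template inside
TERC will hit genomic telomeric arrays. Such hits — query interval
fully inside the annotated template, or an array fully contained in
the hit (a pseudogene's own template) — are excluded from candidate
pairing; full-length TERC matches without adjacent hexamers are
reported separately as pseudogenes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `word_size` | 11 | exact seed length (nt) |
| `min_score` | 30 | minimum raw hit score |
| `xdrop` | 30 | extension termination threshold |
| `max_bridge` | 6 | non-motif bases bridged inside an array (nt) |
| `adjacency_window` | 30 | maximum hit-to-array gap (nt) |
| `flank` | 500 | window flank for ortholog comparison (bp) |
| `min_flank_identity` | 0.6 | per-flank identity to accept a placement |
| `max_span` | 20000 | maximum ortholog span between placed flanks (bp) |

Hexamer arrays are exact `TTAGGG`/`CCCTAA` runs; "almost exact" arrays
are represented by bridging interruptions of up to `max_bridge` bases
rather than by degenerate-motif matching, which keeps the unit
definition crisp while reproducing array lengths that are not
multiples of six. `adjacency_window = 30` operationalises "adjacent":
worked junction alignments show zero to a few bases between fragment
and array. Flank placement is deliberately permissive
(identity ≥ 0.6 over ≥ 200 aligned bases per flank) because empty
orthologs may be sought in species separated by tens of millions of
years.

## Canonical orientation and classification

A locus is classified after reorienting it so the principal (longest)
array reads `TTAGGG` left to right; for head-to-head pairs the
orientation placing the TERC-like fragment 5′ of the arrays is used.
Fragment side and strand then determine A, B or C. Two conventions
matter:

* head-to-head arrays alone do not force class C — C additionally
  requires the fragment upstream in the same orientation; an
  opposite-orientation fragment next to a head-to-head pair stays
  class A with `head_to_head = TRUE`;
* any configuration outside the three canonical ones is assigned the
  nearest class and flagged `nonstandard` rather than dropped.

The in-frame 3′ extension is measured at the fragment/array boundary
on the canonical strand: the largest k ≤ 3 such that the k boundary
bases continue the hexamer ring in a single phase. For organization B
the boundary that abuts the repeats is the fragment start, so the same
ring test is applied there; the exported `inframe_extension()`
operation keeps the fragment-3′-plus-ITS-start signature throughout.

## Junction typing

The focal window (locus ± 500 bp) is compared with the placed ortholog
span by two independent anchored extensions: the left flank from the
shared left edge, the right flank from the right edge. The unaligned
ortholog segment between the two placements is the deletion; focal
junction bases outside the detected insert and outside both flank
alignments are the random insertion. Score ties are broken by pushing
the left boundary maximally toward the junction and the right boundary
minimally — the same deterministic left-alignment convention VCF
normalisation uses when repeats make several equal-cost placements
possible. Junction bases that continue the telomeric register
contiguously from the insert edge are attributed to the ITS, not to
the random insertion: this is the conservative reading under which
in-frame bases are telomere-derived. Deletion lengths are reported
relative to the given empty ortholog; polarity (deletion in the focal
lineage versus insertion in the ortholog lineage) needs an outgroup
and is left to the user.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes: one ancestral/derived contig pair per locus (4 kb, background
GC 0.42 — a genome-average base composition), the insertion at the
contig midpoint, a shared synthetic TERC (451 nt human-like or 397 nt
mouse-like layout, with the canonical repeat template at the annotated
interval), fragments of 25–98 nt sampled outside the template, and
i.i.d. substitution divergence (default 0.02 per contig, ~4% pairwise
— a within-order vertebrate scale) applied outside the insert.
Divergence is substitution-only by design: indel divergence would be
indistinguishable from the junction modifications being measured, a
confound the comparative method itself cannot resolve.

Ground-truth identifiability is engineered, not assumed:

* background contigs and the TERC outside its template are scrubbed of
  telomeric hexamers, so the planted array is the only one near the
  locus and array lengths recover exactly;
* the bases flanking the planted fragment are constrained so that
  alignment extension stops exactly at the fragment boundary (a single
  chance match would otherwise shift the recovered interval);
* in-frame extensions are planted by constraining the TERC bases at
  the fragment boundary — the fragment then genuinely ends in
  register, as at real loci — rather than by mutating the genomic
  copy, which would break fragment-interval recovery;
* random insertions are generated so they neither continue the repeat
  register nor extend a flank alignment, and the realised
  microhomology is verified (and deterministically repaired) to equal
  the configured one.

Each locus draws from an RNG substream derived by hashing its id, so
adding a locus never perturbs the others, and identical seeds give
byte-identical cohorts.

What passing the recovery suites shows — and what it does not: the
generator produces clean biallelic presence/absence with
substitution-only divergence and single-copy flanks. Real assemblies
add assembly gaps, repeat-rich flanks, segmental duplication, indel
divergence and polymorphic loci, none of which the synthetic cohort
models; recovery there is bounded by those factors, not by the ones
tested here.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (BED convention);
  reports print 1-based inclusive positions to match locus naming like
  `HSA6:33092493`.
* `N` never matches anything — not even another `N` — so masked
  assembly stretches cannot seed, extend, or form hexamer runs.
* Overlapping same-strand hits collapse to the highest-scoring
  representative (ties: leftmost, then `+` strand); loci whose spans
  overlap collapse to the best-scoring fragment, so quasi-palindromic
  TERC self-matches cannot duplicate a locus.
* A zero-length or header-only result is a valid, empty report, not an
  error; `not_found` is a status, not a failure.
* The fixture of published loci stores printed values verbatim,
  including a fragment shorter than the search word (8 nt, flagged
  `below_word_size` — such a hit cannot be reproduced by an 11-mer
  seed) and an ITS length (213 bp) outside the prose range (6–205 bp);
  both are surfaced rather than resolved.

## Problem sizes

The shipped tests run the full pipeline on cohorts of up to 41 loci
(4-kb contigs), 200 aligner-oracle pairs of ≤ 200 nt, and 500
scanner-oracle sequences of 1 kb — sizes at which the exhaustive
oracles are exact and the whole suite completes in about a minute on
one core. The acceptance script classifies one 41-locus cohort in a
few seconds.

## Known limitations

* Variant telomeric motifs (`TTAGGC`, `TTGGGG`) and heterochromatic
  FISH-scale ITS blocks are out of scope.
* No E-value statistics, translated search, database indexing, or
  exact replication of NCBI HSP chaining.
* TERC domain labels are only as good as the supplied annotation; the
  packaged human-like and mouse-like layouts are approximate, editable
  stand-ins, and real species coordinates must come from a curated
  source.
* Dating is reported only as per-genome occupied/empty/not-found
  status; no time calibration is attempted.
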