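---
title: "Detecting cascading higher-order repeats in satellite DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cascading higher-order repeats in satellite DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeHOR)
```

## The problem

Human centromeres are built from ~171 bp alpha satellite monomers arranged
in tandem. In many arrays the monomers organize into *higher-order repeats*
(HORs): a unit of *n* monomers (an *n*mer) repeated in tandem, with
inter-copy divergence typically below 5% while any two monomers *within*
one copy diverge by roughly 20–40%. Monomers closer than 5% to each other
belong to the same *monomer type* (family). In the classical Willard
organization every monomer of the canonical copy has its own type
(τ = *n*). Complete telomere-to-telomere assemblies have revealed arrays in
which types *repeat within* the canonical copy (τ < *n*); we call these
*cascading* HORs, because the natural display of such a copy is a multi-row
scheme in which rows are aligned vertically by type.

`cascadeHOR` detects monomers in raw sequence, clusters them into types,
computes the two diagnostic diagrams of repeat periodicity, and reconstructs
per-copy cascading schemes:

1. **Monomer scan** (`scan_monomers()`): semi-global edit-distance search of
   a consensus query against both strands.
2. **Families** (`assign_families()`, `family_consensus()`): single-linkage
   clustering of the all-vs-all divergence matrix at the 5% threshold.
3. **Periodicity** (`compute_md_points()`, `grm_histogram()`,
   `detect_segments()`, `classify_segments()`): for each monomer, the
   *period* is the distance, in monomer units, to the next monomer of the
   same type. The GRM histogram tabulates periods; the MD diagram plots
   (enumeration, period) points, whose dense horizontal segments mark HOR
   arrays. Within overlapping segments, the best-supported period is the
   HOR; co-located shorter periods are *subfragments* (e.g. the intra-copy
   t1→t1 distance 15 and the inter-copy distance 2 inside a cascading
   17mer).
4. **Cascade schemes** (`segment_arrays()`, `infer_canonical_unit()`,
   `partition_copies()`, `cascade_layout()`): arrays are delimited by
   genomic gaps, the canonical unit is the most frequent length-*n* label
   substring up to rotation, copies are classified canonical/variant, and
   each copy is rendered as type-aligned rows with a row signature such as
   `15 + 2` (canonical 17mer), `15 + 15 + 2` (first-row duplication) or
   `(6 + 4)+2` (a row with a deleted interior block).

`grm_hor()` runs all stages and returns one object with `print()`,
`summary()` and `plot()` methods.

```{r example}
spec <- hor_array_spec(unit = c(1:15, 1, 16), n_copies = 10,
                       per_base_mutation = 0.01, seed = 7,
                       variant_events = list(list(copy = 7,
                                                  event = "duplicate_row",
                                                  row = 1, times = 2)))
sim <- build_array(spec)
fit <- grm_hor(sim)
fit
head(format_cascade_scheme(fit$schemes[[1]]$copies, fit$schemes[[1]]$unit,
                           fit$schemes[[1]]$start_bp), 8)
```

## The divergence measure

All comparisons use one divergence: unit-cost edit (Levenshtein) distance
divided by the length of the longer sequence. It is symmetric, bounded in
[0, 1], zero exactly on identity, and insertion-tolerant; `N` never matches
anything, so assembly gaps cannot anchor alignments. The 5% family
threshold and the scanner's acceptance cutoff are both expressed on this
scale.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_div` | 0.30 | scanner acceptance: divergence of a hit to the consensus query. Monomer types diverge ~20–40% from each other, so query-to-monomer distances cluster near half that; 0.30 tolerates them with margin while rejecting non-satellite sequence (random DNA sits near 0.5). |
| `min_len`, `max_len` | 0.5×, 1.5× query length | rejects fragments and fused dimers. |
| `threshold` | 0.05 | family definition: monomers differing by less than 5% share a type. |
| `max_period` | 50 | largest period reported in MD/GRM diagrams, in monomer units; satellite HOR periods in practice stay well below this. |
| `min_support` | 10 | minimum MD points per segment. |
| `max_gap` | `max(5·period, 50)` | largest enumeration gap inside one MD-line segment. The proportional part adapts to sparse long periods. The floor matters for short subfragment periods: the period-2 line of a cascading 17mer receives one point per 17mer copy, so its inter-point gap is 17 — a purely proportional rule (gap 10 at period 2) could never segment it and period 2 could never be classified as a subfragment. The floor of 50 admits one point per copy for units up to 50mers, matching `max_period`. |
| `max_gap_bp` | 2000 | genomic gap that splits tandem arrays (about eleven monomer lengths). |

## Scanner design

The scanner computes, for every subject position, the minimal edit distance
of the full query against a substring ending there (one dynamic-programming
pass per strand). Local minima below the threshold become candidate ends; a
per-end reverse pass recovers the best start for every admissible length.
Candidates from both strands are ranked by raw edit distance — with ties
broken toward the query length, then the leftmost start, then the `+`
strand — and accepted greedily if they do not overlap an accepted hit.

Two deterministic repair passes follow. Edit-distance plateaus can jitter a
boundary by a few bases, and a jittered neighbour can crowd out a true
monomer entirely; uncovered intervals long enough to hold a monomer are
therefore rescanned in isolation, and sub-monomer holes flanked by a poor
hit trigger a rescan of the merged window. Finally, cut positions between
adjacent hits that deviate from the query length are re-optimized to
minimize the total edit distance (ties again toward query-length pieces).
On simulated tandem arrays in the recovery regime this tiles the truth
monomer set exactly; the residual imprecision is ±1–2 bp at alignment-score
ties, which is irrelevant at the 5% family threshold.

Ranking candidates by raw edit distance rather than by normalized
divergence is deliberate: normalization by the longer length makes a window
extended a few bases into its neighbour score *better* at equal edit
distance, which systematically erodes tandem boundaries.

## Family assignment modes

The exact mode builds the all-vs-all divergence matrix and takes connected
components of the `< threshold` relation (single linkage — the
order-independent reading of "all monomers that differ from each other by
less than 5%"). Because the matrix is quadratic in the monomer count, the
default `"auto"` mode switches above 600 monomers to a streaming
representative-first pass: each monomer is compared to one representative
per family (the first member, refreshed to a star consensus of the earliest
members as the family doubles), families hit below the threshold are
merged, and a final repair step re-examines families of at most three
members against all monomers, absorbing them wherever a sub-threshold link
exists — restoring the transitive closure the representative shortcut can
miss. Both modes are required by the test suite to agree on all fixtures.

Family consensi are medoid-anchored star alignments: the member minimizing
summed divergence anchors the columns, every member is globally aligned to
it with a deterministic traceback, and each column takes its majority base
(ties resolved A < C < G < T; columns where gaps outvote every base are
dropped; insertions relative to the medoid are ignored).

## Copy partitioning and signatures

A new copy opens at an occurrence of the unit's first type that is
immediately followed by the unit's second type, provided the running copy
has already passed the unit's final type (one full cycle completed). Both
conditions are needed: without the cycle condition, a duplicated first row
(`t1..t15 t1..t15 t1 t16`) would split although it is one 32-monomer
variant; without the lookahead, trailing `(t1,t16)` doublet rows would
start spurious copies although they belong to `15 + 2 + 2`-type variants.
Monomers before the first qualifying start form a leading partial copy
marked `variant`, so ragged array edges degrade gracefully instead of
erroring.

Rows are laid out left to right, starting a new row whenever the next
monomer's type column (first occurrence order in the unit) does not lie
strictly to the right of the previous one. This is what makes the deeply
cascading 36mer render as rows of 6, 17, 8 and 5: its fourth row starts at
a type whose column lies left of the previous row's last column even though
the type itself is not repeated within the row.

Signature terms count *consecutive canonical-unit positions*, not columns:
the canonical 17mer's second row `(t1, t16)` occupies unit positions 16–17
and prints `2`, while visually t1 still sits in column 1 under the first
row's t1. Each monomer takes the unit position of its type that maximizes
the current run (ties toward the smallest position). A row whose positions
break into several runs is parenthesized, e.g. `(6 + 4)`; rows are joined
with `" + "`, except immediately after a parenthesized row, where the join
is a bare `+` — reproducing the signature dialect of published cascading
schemes verbatim.

**Known limitation.** Units whose *interior* rows begin with the unit's own
two-type prefix and whose final type already appears mid-unit (the
canonical 36mer is such a case: every row starts `t1 t16 t17` and the final
type t15 ends row two) are over-segmented by the partitioner. The layout
and signature machinery handle such units correctly when the unit is given;
only the automatic copy delimitation is affected.

## What the simulator emulates — and what it does not

`build_array()` generates: a library of type seeds descended from one
AT-rich ancestor with verified pairwise divergence (default 0.25, the
middle of the 20–40% intra-copy range, verified to stay above 0.8× the
target); tandem copies of an arbitrary unit grammar (repeated types
allowed); independent per-monomer substitution noise (default 1%, so
inter-copy divergence ≈ 2% — comfortably below the 5% family threshold, as
in real HOR arrays); optional single-base indels (10% of mutation events)
to exercise the scanner's length tolerance; structured variant events (row
duplication/multiplication, type deletions, row insertions); random
non-repetitive flanks; and whole-array reverse complementation. Output is a
pure function of the seed.

Monomers realizing more than ~2.4× the expected mutation load are resampled
(cap 0.024 at 1% mutation). This is the constructive form of the
recovery-regime guarantee: by the triangle inequality, intra-type pairs
then stay below 2 × 0.024 < 5%, so threshold clustering can recover the
truth on *every* seed. Without the cap, a far-tail monomer can exceed 5%
from every sibling, in which case *no* threshold clustering could recover
the generated types — a property of threshold clustering near its boundary,
not of this implementation; the cap truncates only a ~3% tail and leaves
realized divergence concentrated at 2m(1−m), which the test suite asserts.

The simulator does **not** emulate centromere evolution: no layered
expansions, gene conversion, higher-order mutation correlation,
transposable-element insertions, or assembly errors. Passing tests on these
fixtures demonstrate algorithmic correctness under the stated repeat
grammar and noise model, not performance on real centromeres — on real
data, detection completeness depends on the quality of the consensus query
and arrays blend into diverged pericentromeric monomers without sharp
boundaries.

The packaged default query (`default_consensus()`) is a **synthetic** seeded
171-mer with alphoid-like AT content, shipped only so the command-line
interface runs out of the box; it is *not* a published alphoid consensus.
Real analyses should supply a real consensus; simulated analyses use the
generator's own ancestor (`sim$query`).

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED output; FASTA
  headers, scheme text and array tables print 1-based inclusive positions.
* All greedy steps (candidate acceptance, rotation choice, medoid, ties in
  consensus bases and unit-position assignment) carry explicit
  deterministic tie-breaks, so every pipeline output is byte-reproducible.
* An empty subject yields an empty monomer set, not an error; fewer than
  two monomers yield empty diagrams with a warning; an array shorter than
  two units raises a classed insufficient-data error from unit inference
  and is simply skipped (no scheme) by `grm_hor()`.
* `scan_monomers()` validates the query alphabet and `max_div < 0.5`;
  family and segment thresholds are validated the same way, with classed
  parameter errors that the command-line front end maps to exit status 2.

## Problem sizes used in the shipped checks

The test-suite fixtures run 2–12 copies per array (a few hundred monomers);
the study-scale fixtures in `scripts/acceptance.R` and the acceptance tests
run 100-copy arrays (1700 and 1000 monomers), where the closed form for a
tandem of C cascading 17mer copies — 15(C−1) MD points at period 17, C at
15, C−1 at 2, total points = monomers − families — is checked exactly.
These sizes were chosen so the whole suite completes in about a minute on
one core while still exercising the streaming clustering path (which
engages above 600 monomers).
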