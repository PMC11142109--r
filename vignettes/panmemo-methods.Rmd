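---
title: "panmemo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panmemo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmemo)
```

## The model

`panmemo` answers two questions about a pangenome of `N` genomes, anchored
to one of them (the *pivot*): for a k-mer drawn from a pivot region,

* **membership** — which genomes contain it (a length-`N` true/false vector;
  the pivot's entry is always true), and
* **conservation** — how many genomes contain it (an integer in `[1, N]`
  when the pivot is counted).

A k-mer "occurs" in a genome if it matches either strand of any sequence of
that genome, without crossing a sequence boundary. Both queries are limited
to k-mers taken from the pivot; this is what lets a single interval index
answer them for every k simultaneously.

### Matching statistics and MEMs

For pivot sequence `P[1..m]` and a target text `T` built from another genome
(each sequence followed by a separator, then its reverse complement and
another separator), the matching-statistics vector assigns to every position
`j` the length of the longest suffix of `P[1..j]` occurring in `T`
(`compute_ms()`). Two structural facts drive everything else:

1. *Sawtooth*: `MS[j] − MS[j−1] ≤ 1`, since extending the prefix by one
   character can extend its best-matching suffix by at most one.
2. *Peaks are MEMs*: `j` with `MS[j] ≥ MS[j+1]` (or `j = m`) ends a match
   that cannot be extended right (the next MS value did not grow past it)
   nor left (MS is already the longest suffix). The peak `(j, ℓ)` maps to
   the 0-based half-open interval `[j+1−ℓ, j+1)` (`mems_from_ms()`).

A pivot k-mer is present in the other genome iff its interval is contained
in a MEM. `panmemo` stores, by default, not the MEMs but the *overlaps*
between consecutive MEMs (`overlaps_from_mems()`): for consecutive MEMs
`A`, `B` the record is `(start(B), end(A))`. A k-mer is absent iff it
straddles such a record with overhang on both sides (`x < start` and
`x + k > end`); since MEMs never contain one another, a k-mer not contained
in either of two consecutive MEMs is contained in none.

### Order-MEMs and conservation

Stacking the `t − 1` MS vectors (one per non-pivot genome) and sorting each
column in descending order gives the order-MS matrix (`order_ms()`). Sorted
rows still satisfy the sawtooth — at most `i` entries of column `j − 1`
exceed the `i`-th entry, and each grows by at most one — so the peak rule
applies row-wise and yields *order-MEMs*: containment in the rank-`r` track
certifies presence in at least `r` non-pivot genomes, monotonically in `r`.
A conservation query therefore scans ranks for the smallest failing track;
the count of other genomes is that rank minus one, or `t − 1` if no rank
fails (`conservation()`). Row identity (which genome contributed a value)
is deliberately destroyed by the sort; membership queries need the
genome-annotated index.

### Quantile sampling

When coarse answers suffice, only order ranks at quantile thresholds are
kept (`quantile_rows()`): rank `ceil(q · t')` is the smallest count
certifying presence in at least a fraction `q` of the `t'` non-pivot
samples. For 89 samples at decile resolution the retained ranks are
9, 18, 27, …, 81, 89. A decile query returns the largest retained rank the
k-mer is certified for, which equals the exact other-genome count floored
onto the retained ranks (`quantile_conservation()`).

## Engine and numerical choices

* **MS engine.** A suffix automaton of the target text (C++, linear
  construction) with the standard streaming scan giving the longest matched
  suffix per pattern position. Any engine honouring the MS contract would
  do; the automaton was chosen because it is exact, simple, and fast at the
  scale this package targets (targets held in memory, up to tens of Mb).
  An independent `ms_oracle()` — the quadratic longest-common-suffix dynamic
  program — ships with the package and is held equal to the automaton on
  randomized corpora in the tests.
* **Separators and non-ACGT residues.** Separators and every non-`ACGT`
  residue are encoded as unique symbols that match nothing, including
  themselves. N therefore never matches N, preventing runs of masked or
  ambiguous sequence from inflating conservation; matches can never cross a
  sequence boundary. Non-ACGT residues in the pivot likewise terminate
  matches and make the containing k-mers absent everywhere.
* **Zero MS values are never peaks.** A zero-length "match" is not an exact
  substring match and would create degenerate empty intervals.
* **Sentinels and gaps.** Each track gets a leading record
  `(first_start, 0)` and a trailing record `(pivot_len, last_end)`, so
  k-mers overhanging the first or last MEM correctly test absent; an empty
  track is the single record `(pivot_len, 0)` under which every k-mer tests
  absent. When consecutive MEMs neither overlap nor adjoin (possible after
  an unmatchable residue), the record has `start > end`; the straddle test
  `end − (k − 1) < start` then fires for every k across the uncovered span,
  which is exactly right.
* **k-range filtering.** A record `(s, e)` can only be straddled when
  `k ≥ (e − s) + 2`, so an index restricted to queries with `k ≤ k_max`
  may drop records with `e − s > k_max − 2` losslessly
  (`filter_overlaps_for_max_k()`); this is the tight bound implied by the
  straddle geometry. Dually, MEMs shorter than `k_min` cannot contain a
  permitted k-mer (`filter_mems_for_min_k()`). Both filters are
  property-tested for query invariance at the boundary k.
* **Query window.** Results are reported for valid k-mer starts only,
  `x ∈ [i, j − k]`; marking intervals from records are clipped to that
  range. When no order fails, the other-genome count is defined as `t'`
  (an unguarded per-column argmax would report nonsense on an all-zero
  column).
* **Ceiling rule.** `quantile_rows()` computes the smallest integer
  `x ≥ q · t'` with a `1e-9` guard against floating-point noise in
  `q · t'`.
* **Canonical k-mers** (oracle only) are the lexicographic minimum of a
  k-mer and its reverse complement — the strand-symmetric normal form used
  by k-mer counters. The tests verify this convention agrees with the
  forward-plus-reverse-complement target construction.
* **Storage.** Records sort by `(chrom, start, end, annotation)` — starts
  cluster, which compresses well column-wise — and are written to Parquet
  with the ZSTD codec, chromosome names dictionary-encoded, integers
  unsigned 32-bit. The row-block target is 16 MB by default (configurable),
  appropriate for the genome sizes this package targets. Metadata (flavor,
  roster, retained ranks, permitted k-range, pivot sequence lengths) lives
  in the Parquet footer, so the index is one self-describing file.
  `read_region()` fetches the records relevant to a window — for overlap
  stores those with `start > i` and `end < j` plus sentinels, for MEM
  stores those intersecting the window — and is property-tested equivalent
  to a full scan.

## Design choices where the design was open

* **Rows of the order matrix.** The order matrix is built from the `t − 1`
  non-pivot comparisons only; a pivot-vs-self row would be the constant
  maximum and carry no information. Reported conservation adds 1 for the
  pivot (configurable via `include_pivot`), giving values in `[1, N]`.
* **Genomes are indexed jointly, per genome.** All sequences of a genome
  (and their reverse complements) form one target text, so a pivot k-mer
  "occurs in genome G" regardless of which sequence of G it lands in. MS
  vectors and index records are nonetheless computed and stored per pivot
  sequence, which is what anchors BED-style outputs to chromosomes.
* **Soft-masked input** is uppercased and used; only non-ACGT symbols are
  excluded from matching.
* **Multiple index flavors.** The overlap encoding is the default store
  (smaller and the natural input of the straddle test); the MEM encoding is
  kept as a first-class alternative because containment queries are easier
  to reason about, and the two are held equal in the tests.

## The synthetic pangenome generator

`simulate_pangenome()` draws a uniform-random pivot and derives each other
genome independently (a star phylogeny) with per-base substitutions and
indels of 1–10 bp; output is deterministic given the seed, and a JSON
manifest of applied mutations accompanies the FASTA files. Defaults
(`sim_config()`: 5 kb pivot, 4 genomes, SNP rate 0.01, indel rate 0.001)
reflect intra-species divergence at desk scale. The validation corpus used
by the test suite spans `t` from 2 to 8, pivots of 2–10 kb over 1–3
sequences, SNP rates 0.005–0.02 and indel rates 5e-4–2e-3, with k from 1
to 51.

What the generator does *not* emulate: structural variation, repeat
families, realistic base composition, coalescent genealogies, or sequencing
error. Passing tests therefore demonstrate algorithmic correctness of the
index and queries — equality with a brute-force canonical k-mer oracle on
every tested instance — not calibrated performance on real assemblies.
Repeat-rich real genomes mainly change MEM length distributions and index
size, not the correctness argument, which is purely interval-combinatorial.

## Known limitations

* Queries are restricted to k-mers of the pivot; k-mers private to other
  genomes are invisible. Several pivots require several indexes.
* The in-memory suffix automaton bounds practical genome sizes to tens of
  megabases per genome; chromosome-scale mammalian pangenomes need an
  external matching-statistics engine in front of the same index and query
  machinery.
* Order tracks cannot attribute conservation to specific genomes; use the
  membership flavor for that.
* A quantile index answers only quantile queries; the discarded ranks are
  gone.
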