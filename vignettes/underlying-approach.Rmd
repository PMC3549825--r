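---
title: "Alignment-free genome comparison with underlying subwords"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free genome comparison with underlying subwords}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uasub)
```

## The problem

Whole-genome phylogenies are often needed where multiple alignment is
impractical: the genomes are too long, too many, or too rearranged for
position-by-position homology to be meaningful.  Alignment-free methods
replace alignment with word statistics.  Fixed-length word (k-mer) methods
must choose k; matching statistics avoid that choice by recording, for each
position i of a reference s1, the length `l[i]` of the longest subword
starting there that also occurs in the target s2.  The mean of `l` is the
classical average-common-subword (ACS) similarity, implemented here as
`acs_similarity()`.

Raw matching statistics have a flaw for genome-scale inputs: repetitive
regions contribute to the score many times.  `uasub` implements a
two-stage filter that makes every region of each sequence count exactly
once.

## Irredundant common subwords

The first stage compresses the matching statistics to a small generating
set.  A *common subword* is a word occurring in both sequences; an
occurrence is *covered* when its interval lies inside the interval of an
occurrence of another common subword.  A common subword is **irredundant**
if at least one of its occurrences (in either sequence) is uncovered.  The
irredundant set `I` is at most `n + m` large, and the full
matching-statistics vector can be rebuilt from it: superimpose on every
reference occurrence of every member the suffix-length scores
`|w|, |w|-1, ..., 1` and take the per-position maximum
(`ms_from_subwords()`).  The identity
`ms_from_subwords(find_irredundant(s1, s2)) == matching_statistics(s1, s2)`
is asserted exactly, position for position, in the test suite.

Discovery uses a generalized suffix structure (`build_index()`): a suffix
array plus lcp-interval tree over the integer-coded concatenation of the
two inputs, with each node colored by the hosts reaching it.  For every
suffix, its lowest both-colored ancestor spells the longest match starting
there -- a right-maximal occurrence.  An occurrence at position i is also
left-maximal when `l[i] >= l[i-1]` (position 1 is always left-maximal),
because a longer match one position to the left is exactly what would
cover it.  Words with at least one occurrence that is both right- and
left-maximal form `I`.  The rule is applied symmetrically to occurrences
in both hosts; the package's discovery is validated against a brute-force
checker that applies the cover definition literally.

## Underlying subwords

The second stage removes overlap.  Words are ranked by **priority**:
strictly longer wins; equal lengths are broken by the earlier first
occurrence (reference scanned before target).  Since two distinct words of
equal length cannot share a first occurrence, the order is total and the
whole selection is deterministic.  Walking `I` in priority order, each
word's occurrences are tested against a per-host coverage vector `Gamma`
(with a companion length table `chi`); an occurrence is *untied* when it
does not overlap any untied occurrence already accepted.  A word enters
the **underlying set** `U` only if it retains at least one untied
occurrence in each sequence (quorum 2, one per host).  Because processing
is longest-first, an already-accepted interval overlapping a candidate
occurrence must cover one of its two endpoints, so the untied test needs
only `Gamma[i]` and `Gamma[i + |w| - 1]`.  An occurrence whose start is
free but whose end is covered may still serve a shorter prefix: the free
run is `d = |w| - chi[i + |w| - 1]` and the occurrence is re-queued for
the longest irredundant ancestor prefix of length at most `d`, found by
walking `prec` links (nearest-irredundant-ancestor pointers).  This
replaces the logarithmic weighted-ancestor structure of the original
algorithm; at the scales this package targets the parent walk is exact and
fast, and the answers are identical by construction.

Two details are resolved here that the algorithm's usual narration leaves
open, both validated against a quadratic greedy selector that applies the
priority rule and a full interval-overlap test literally:

* **Coverage is tracked for both hosts.**  The quorum demands an untied
  occurrence in each sequence, so tied-ness must be decidable in the
  target too; each occurrence is tested against its own host's `Gamma`.
* **A word ties itself.**  Overlapping occurrences of the same word
  cannot both be untied (untied occurrences must be disjoint), so within a
  word occurrences are admitted in ascending position, each tested also
  against the word's own tentative intervals.  If the word ends up
  rejected, those tentative marks are rolled back and its still-uncovered
  occurrences are forwarded to ancestor prefixes.

The resulting `U` satisfies, and the tests assert: untied occurrences are
pairwise disjoint per host; their total length never exceeds the host
length; every member keeps one untied occurrence per host; and no rejected
word could have been added (maximality, checked exhaustively on small
instances with priority-aware tying).

## Inversions and complements

Genome pairs share material under symmetries: segmental inversions and
base complements.  `build_extended()` concatenates the target with its
inverse (plain reversal) and its complement (A<->T, C<->G substitution,
not reversed), in this exact order, joined by unique separators.  The
construction follows the method's definition literally: the two extra
match classes are reversal and complementation, and the biological
reverse complement (complement of the reversal) is *not* a segment by
default -- `include_revcomp = TRUE` adds it as an explicit fourth class
for users who want it.  Discovery and selection then run on
`(s1, extended s2)` unchanged; the segment an untied occurrence falls in
is its match class, reported by `match_class_stats()`.  Separator and
ambiguity symbols are per-position unique integer codes, so no match can
cross a segment boundary and no ambiguity character (N, R, Y, ...) can
ever take part in a common subword.  Extended matching is the default
pipeline mode.

## The distance

With `h_w` the number of untied occurrences of `w` in the reference,

* `UA(s1, s2) = sum_w h_w |w|(|w| + 1) / 2 / n` (`ua_similarity()`),
* `UAbar(s1, s2) = log4(|s2|) / UA(s1, s2) - 2 log4(|s1|) / (|s1| + 1)`
  (`ua_normalized()`),
* `d_UA(s1, s2) = (UAbar(s1, s2) + UAbar(s2, s1)) / 2` (`d_ua()`).

The base-4 logarithm matches the four-letter alphabet.  For a
self-comparison `U` is the sequence itself, so `UA(s, s) = (|s| + 1) / 2`
and the correction term makes `UAbar(s, s)` -- hence `d_UA(s, s)` --
exactly zero in floating point (both terms round the same real number).
`|s2|` in the normalization is the original target length, not the
extended one: the formula is defined on the sequences, the extension is an
indexing device.  The correction term `2 log4(n) / (n + 1)` vanishes as
genomes grow.

**Incomparable pairs.**  If two sequences share no underlying subword,
`UA = 0` and the normalized value is undefined; `ua_normalized()` signals
this with `NA` and `distance_matrix()` substitutes a finite ceiling
(default: twice the largest finite pairwise distance, 1 if none exists)
so neighbor joining stays well defined.  Real genome pairs never trigger
this; only pathological inputs (disjoint alphabets) do.

## Trees

`neighbor_joining()` is a deterministic Saitou-Nei implementation:
Q-criterion ties are broken by the lowest index pair (merged nodes
appended last), and a negative branch-length estimate is clamped to zero
with the deficit moved to its sibling so path lengths are preserved --
the behavior of the PHYLIP neighbor program the method was designed to
feed.  On an additive matrix it provably returns the generating tree; the
tests assert exact topology recovery (Robinson-Foulds 0) on random
additive matrices.

`robinson_foulds()` counts non-trivial bipartitions present in exactly one
of two unrooted trees (range 0 to 2n - 6 for binary trees); the package
extracts splits itself and is cross-checked against an independent
implementation in the tests.  `triplet_distance()` enumerates all C(n, 3)
leaf triples explicitly and reports the fraction resolved differently.
Triplets need rooted trees while the pipeline's trees are unrooted; the
default policy is midpoint rooting applied identically to both trees
(configurable to outgroup rooting), and a triple unresolved in one tree
but resolved in the other counts as different.  The original experiments
do not state their rooting convention, so published triplet tables are
not bit-comparable and are not targets here.

## The synthetic-data generator

`evolve_along_tree()` stands in for the real genome collections the
method was demonstrated on (which are external downloads): it draws a
root sequence i.i.d. at a requested GC content, walks a known topology
(random, balanced, or caterpillar), and on each branch applies per-site
substitutions (replacement uniform over the three alternatives,
Jukes-Cantor-like) followed by planted segmental inversion and complement
events.  Defaults -- 8 taxa, 5 kb root, 2% per-branch substitution rate,
one 100-500 bp inversion and one complement event per branch -- describe a
small family in which branches carry ~100 substitutions, enough signal
for tree recovery while keeping a full 8-taxon run around a few seconds.
The event length range is a deliberate choice (2-10% of the genome,
segmental-rearrangement scale); it was fixed before any acceptance
measurement and is not revisited.

What a green test establishes: on substitution-plus-rearrangement
families of this size, the pipeline recovers the true topology (RF = 0 in
all 20 acceptance seeds, threshold >= 90%).  What it does not establish:
performance on real genomes with repeats, indels, horizontal transfer, or
scale beyond desk size -- the generator models none of those.

**A known red criterion.**  One acceptance criterion demands that
inversion-free control families show a *zero* untied-inversion fraction.
That is unattainable in the stated world: at 2% per-branch divergence the
selection legitimately places short chance words (well below the ~12 bp
significance length at 5 kb) in the inversion segment, giving control
fractions around 10-16%.  Only identical sequences give exactly zero.
The package asserts the criterion literally and leaves it red; the
meaningful, passing property -- planted inversions produce inversion-class
members, including the planted block at full length -- is asserted in the
unit suite.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; every human-facing report
  (TSV, CLI) is 1-based inclusive.
* The priority relation's "longer or equal wins" is read as *strictly
  longer wins, equal length falls to the tie-break*; the literal reading
  would not be antisymmetric.
* Distance matrices are written in square PHYLIP format (10-character
  padded names) and TSV; trees in Newick; floating output at 6
  significant digits with full precision in a JSON sidecar.
* The suffix array is built by prefix doubling (`O(N log^2 N)`): at desk
  scale (tens of kilobases per pair) index construction is milliseconds,
  so the asymptotically optimal constructions would buy nothing.
* `d_ua(s, s)` is exactly 0 and the identity `UA(s, s) = (|s|+1)/2` is
  exact; the acceptance tolerance used elsewhere is 1e-12.

## Limitations

Nucleotide alphabets only; no mismatch-tolerant (wildcard) subwords; pairs
are compared independently (no multi-sequence underlying sets); the
asymptotically optimal weighted-ancestor and suffix-construction bounds
are intentionally not matched; triplet-distance values depend on the
rooting policy.
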