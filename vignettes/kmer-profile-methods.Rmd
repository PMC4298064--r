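---
title: "k-mer profile methods: model, transforms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{k-mer profile methods: model, transforms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerprof)
```

This vignette is the package's account of its own method: what the
profile, the transforms and the distance assume; which parameters matter
and why their defaults are what they are; what the simulation module does
and does not emulate; and the numerical and design decisions taken where
more than one reasonable convention exists.

## The profile model

A dataset is reduced to the vector of counts of all 4^k DNA words,
obtained by sliding a window of size k over every read. Two modelling
assumptions are built in:

* **Windows never span records.** Each read is an independent fragment;
  a word straddling two reads is an artefact of file order, not of the
  library.
* **Ambiguity codes void a window.** A window containing any character
  outside ACGT contributes nothing; equivalently each record is split
  into maximal ACGT-only fragments, a fragment of length L contributing
  max(0, L − k + 1) windows. Inventing counts for ambiguous positions
  would bias exactly the rare-word tail the distance is most sensitive
  to, so absent evidence is treated as absent.

An ACGT-only record of length L therefore contributes L − k + 1 windows:
a 12-nt read is seen once in a 12-mer profile but seven times in a 6-mer
profile. This window arithmetic is also why `profile_shrink()` (summing
the four counts per (k−1)-prefix) is *not* identical to re-counting at
k−1: direct counting sees one extra terminal window per read. The
difference is one count per record — negligible for long reads, but a
reason to count at the k you intend to analyse when read counts are
large relative to read length.

### The codec

Words are indexed by a 2-bit code: A=00, C=01, G=10, T=11, first base
most significant. The base assignment is a package convention (any key
with complement = bitwise NOT would do); it is recorded in the profile
container so files are self-describing. Its two useful properties:

* complementation is XOR with all-ones, so the reverse complement of a
  code needs only field reversal and inversion — no string round trip;
* code order equals ACGT-lexicographic order, so the four words sharing
  a (k−1)-prefix occupy four consecutive positions, making shrink and
  smoothing contiguous-block operations on the dense vector.

k is capped at 15 so codes stay exact in doubles and the dense vector
(4^k entries) stays addressable; practical analyses use k ≤ 12.

## The multiset distance

With x and y the count vectors and S = {i : x_i > 0 or y_i > 0},

D(X, Y) = Σ_{i∈S} f(x_i, y_i) / (|S| + 1), with
f(x, y) = |x − y| / ((x + 1)(y + 1)) by default.

Numerical conventions, fixed here because more than one normalisation of
a "multiset distance" exists in the literature:

* the sum runs only over words present in at least one profile — words
  absent from both carry no evidence;
* the denominator is |S| + 1, not |S|: it guards the empty-set case
  (D = 0 when both profiles are empty) and keeps D strictly below 1 for
  the default f. These choices affect absolute values, not orderings.
* accumulation is in fixed (code) order, so results are bit-reproducible
  on a platform.

f is a *pluggable* parameter (`multiset_distance(a, b, f = ...)`); only
the default is studied here.

### Strand balance

`strand_balance()` applies the same machinery to the two
reverse-complementary halves of one profile: words w with
code(w) < code(revcomp(w)) form the forward vector, their mirrors the
reverse vector. Palindromic words (possible only at even k) are excluded
— a self-pair always contributes f(c, c) = 0 while inflating |S|, so
keeping them would dilute the statistic without adding information.

A caveat discovered by simulation and worth stating: the "balance falls
as depth grows" behaviour expected of a strand-symmetric library holds
when the source occupies the k-mer space with multiplicity above one
(mean occupancy λ > 1). At sparse occupancy (λ ≪ 1) most word/mirror
pairs are one-sided singletons, f saturates towards 1 as counts grow,
and single-strand balance *rises* with depth instead. Choose k so that
genome_size / 4^k comfortably exceeds 1 before reading strand balance as
a depth gauge; the package's own strand-balance simulations use a 20-kb
source at k = 6 (λ ≈ 4.9) for exactly this reason.

## Making libraries comparable

`prepare_pair()` applies up to three steps in a fixed order — balance
(per profile), smoothing (pairwise), scaling (pairwise). The order is
normative: smoothing must see raw integer count structure (its default
trigger is exact zeros, which scaling would turn into exact zeros times
a factor — harmless — but a nonzero threshold would be distorted), and
scaling last equalises areas on the final block structure. The CLI
deliberately cannot reorder the steps, only switch them on and off, so
matrices computed in different runs remain comparable.

### Dynamic smoothing: the normative algorithm

Smoothing is a *joint, local, bottom-up* collapse over the quartary
prefix tree:

1. Start at level k with every code a singleton block.
2. At each level, consider every group of four sibling blocks whose
   members are each already collapsed to a single carrier position. If
   `summary` of the four block totals is ≤ `threshold` in **either**
   profile, merge the group in **both**: the group total moves to the
   lexicographically first code of the merged prefix range, other
   positions become zero.
3. Only freshly merged groups are candidates one level up; stop when no
   group qualifies or when blocks reach word length 1.

Decisions embedded there, each of which had a defensible alternative:

* **Bottom-up, not top-down.** A top-down rule ("collapse any subtree
  whose summary is below threshold") degenerates under the default
  min/0 policy: one nullomer anywhere in a profile would collapse the
  entire tree at the root. Bottom-up merging localises the correction.
* **OR across the pair.** A block weak in either library is merged in
  both, because the two vectors must keep identical block structure for
  positionwise comparison. The result is symmetric in (a, b).
* **Carrier = first code of the block.** Any fixed convention works;
  this one is stable, testable, and keeps the carrier set nested as
  blocks merge.
* **Stop at word length 1.** The profile is never collapsed to a single
  bin, so a pair of profiles always retains at least the four
  composition bins.
* **Defaults min/0.** Merge exactly where a group contains an absent
  word in either library — the paper-motivated setting that rare and
  absent words are what make profiles depth-sensitive. `summary` also
  accepts max, mean, median or any user function; `threshold` is in
  count units (after balancing, if balancing is on).

Smoothing conserves each profile's total, is idempotent at a fixed
policy, and a higher threshold never yields a finer partition; all three
are enforced by the test suite, and `smooth_pair()` returns the final
block partition (`blocks`) so callers can inspect the effective
resolution.

### Scaling

`scale_pair()` multiplies the smaller-total profile by the exact ratio
larger/smaller in floating point; nothing is rounded back to integers.
Scaling up rather than down preserves the deeper library's resolution.
Equality of totals after scaling is exact to floating tolerance (the
tests use 1e−9 relative). Scaling exactly removes uniform read
duplication: duplicating every read n-fold multiplies the vector by n,
which the ratio cancels.

## What the simulator emulates — and what it does not

The `simulate` module generates the study conditions used throughout the
tests and the acceptance script:

* **Genomes** are i.i.d. base sequences at a chosen GC content; 50 kb
  stands in for the ~2-Mb bacterial genomes of the mixture experiments
  (the geometry assertions depend on relatedness and copy numbers, not
  on absolute genome size). Relatedness is emulated by point-mutating a
  copy at rate 0.1, echoing the 85–95% homology of the two related
  bifidobacterial genomes the mixture design models.
* **Mixtures** replicate whole genome sequences at integer copy numbers
  (6:0:0, 3:3:0, 2:2:2, ...), so the mixture profile is exactly the
  integer combination of genome profiles — the linearity the tests use
  as an oracle.
* **Reads** are drawn uniformly with fair-coin strands by default (so
  strand-balance expectations are well defined), with i.i.d.
  substitution errors only.
* **Permutation controls** shuffle bases within each record, preserving
  composition (hence the 1-mer profile) while destroying all word
  structure — the null model of `scan_k()`.

Real data differ in ways none of this captures: genomes have repeats,
GC-skew and context-dependent composition; errors are indel-containing
and quality-correlated; abundances in real microbiomes are far from
integer copy ratios; coverage is non-uniform. Passing the simulation
suite therefore shows the *mechanics* — counting, transforms, distance —
behave as designed under controlled conditions, not that any particular
real cohort will separate cleanly.

Problem sizes in the tests and acceptance script (50-kb genomes at
k = 10 for mixtures, 20-kb genomes at k = 8 for depth robustness and
k = 6 for strand balance, a 9.6-kb repeat-containing sequence for the
k-scan) were chosen as the smallest scales at which the studied effects
are comfortably away from their noise floors, and they keep a full run
in seconds.

## Tunable parameters at a glance

| parameter | where | default | units | why |
|---|---|---|---|---|
| `k` | counting, CLI | 12 | bases | balances nullomers vs unique vs recurrent words for mammalian-scale data; use ~10 for bacterial metagenome comparisons, or run `scan_k()` |
| `summary` | smoothing | `"min"` | — | trigger on the weakest member: merges any group containing an absent word |
| `threshold` | smoothing | 0 | counts | merge only where a word is entirely absent; raise to also merge low-evidence groups |
| `gc_fraction` | simulation | 0.5 | fraction | neutral composition unless a skew is under study |
| `error_rate` | simulation | 0 | per base | substitutions only; raise to study artificial-word enrichment |
| `rate` | `mutate_sequence` | 0.1 | fraction | ~90% identity, emulating closely related genomes |

## Degenerate inputs and edge behaviour

* Records shorter than k, and empty FASTA files, are silent no-ops;
  a profile of all zeros is valid everywhere except `scale_pair()`,
  which refuses zero-total input.
* `kmer_spectrum()` refuses non-integral (scaled) counts rather than
  silently binning them.
* `profile_balance()` doubles palindromic words: the alternative
  (leaving self-pairs untouched) breaks linearity
  (balance(balance(p)) = 2·balance(p)) and the symmetry fixed-point
  property, so doubling is used and documented.
* `profile_shuffle()` permutes the *full* vector including zeros, so the
  nullomer mass participates in the permutation and the whole count
  distribution is preserved.
* Distance-matrix computation transforms fresh copies per pair; an
  input profile is never mutated, and results are independent of pair
  evaluation order.

## Known limitations

* Dense vectors only: memory is 8·4^k bytes per profile (~134 MB at
  k = 12); k > 15 is rejected. No minimizer/Bloom-filter counting.
* FASTQ support is a conversion path (qualities are discarded), not
  quality-aware counting.
* The distance is a dissimilarity, not a metric with a triangle
  inequality guarantee; downstream embedding (PCA, clustering) is left
  to standard tools.
* Strand balance assumes a strand-symmetric library; it is not
  meaningful for strand-specific protocols.
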