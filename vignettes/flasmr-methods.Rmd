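---
title: "Fixed-length approximate string matching: models, parameters and design"
author: "flasmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-length approximate string matching: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flasmr)
```

## The problem

Classic approximate string matching (ASM) asks for all factors of a text
`t` (length `n`) within distance `k` of a pattern `x` (length `m`).
Fixed-length approximate string matching (FLASM) generalises this: given a
factor length `ell <= m`, report all factors of `t` within distance `k < ell`
of *any* length-`ell` factor of `x`. A match is the tuple `<j, i, e>`:
the 0-based ending position `j` of the matched factor in the text, the
ending position `i` of the pattern window, and the distance `e`.

Two distance models are supported. The **Hamming** model counts
substitutions between equal-length windows. The **edit** model counts
unit-cost substitutions, insertions and deletions; for a text ending
position `j` the reported distance is the minimum over start positions of
the edit distance between a text factor ending at `j` and the pattern
window (standard semi-global semantics). This minimum-over-starts
convention is a deliberate design decision: enumerating every
`(start, end)` factor pair would blow up the output quadratically while
adding nothing the `<j, i, e>` tuple can carry; consumers that need a
start position (the structured motif chain join) recover the minimising
start, smallest on ties.

```{r}
flasm("ATGGCAAGT", "AAGATG", factor_length = 3, max_distance = 1)
```

## The bit-parallel cores

Both cores follow the bit-vector dynamic programming approach whose run
time is `O(m * ceil(ell/w) * n)` and space `O(m * ceil(ell/w))`, with `w`
the machine word size (`flasm_word_size()`, 64 here). Crucially the cost
is independent of `k` and of the alphabet, and `ell` may exceed `w`.

**Hamming core.** The DP state is, per cell, an `ell`-bit vector whose
set bits mark the mismatching columns of the current window alignment:
`M[i][j] = (M[i-1][j-1] << 1) | (x[i-1] != t[j-1])`, truncated to `ell`
bits, with `popcount(M[i][j])` equal to the window Hamming distance once
`i, j >= ell`. The implementation streams the text in blocks of 256
columns and sweeps the state one 64-bit word plane at a time: plane 0
shifts in mismatch bits taken from per-letter text masks, each later
plane shifts in the carries its predecessor recorded in a per-block bit
matrix, and every plane accumulates its words' popcounts into a per-block
count matrix from which matches are read. The persistent state between
blocks is a single column of `m + 1` bit vectors, so the stated space
bound holds and the per-cell work is exactly the `ceil(ell/w)` word loop.
This layout is what makes the complexity's word-count factor visible in
measured run times (flat for `ell` in 32–64, then proportional to
`ceil(ell/64)`), which the test suite checks at `n = m = 1000` — a
deliberate scale-down of the classic performance experiment at
`n = m = 10000` with `k = ell/2`.

**Edit core.** Myers' bit-vector ASM algorithm is run once per
length-`ell` factor of the pattern (text start free, so the running score
at the factor's last row is the semi-global minimum). The vertical delta
vectors `Pv`/`Mv` are multi-word; the only step needing cross-word
communication is the `Xh` addition chain, which uses carry-propagating
multi-word addition. The per-letter `Peq` table is rebuilt per factor —
an `O(sigma)` constant per factor that keeps the code simple without
changing the complexity class.

The `bitrow` type exposes exactly the word-level kernels the cores use
(truncating left shift, carry-propagating addition modulo `2^ell`,
boolean operations, popcount), with bit 0 the most recent alignment
column so that shifting in the newest mismatch bit is a left shift. Tests
exercise widths 1–200 against plain-R digit-vector arithmetic.

**Parameter domain.** `1 <= ell <= min(n, m)` and `0 <= k < ell`. Two
boundary decisions: `k = 0` is accepted (exact fixed-length matching; the
degenerate case is well defined and used by the circular and index
applications), and the pattern may be longer than the text — the circular
applications search a text of length about `m` with a doubled pattern of
length `2m - 1`, so rejecting `m > n` would contradict them. Sequences
are uppercased on ingest; any symbol (`N`, gaps, protein letters) is an
ordinary letter matching only itself. This is the simplest defensible
semantics; users wanting IUPAC wildcard behaviour must preprocess.

## Circular matching and rotation refinement

A circular pattern is handled by doubling: the length-`m` factors of
`x[0..m-1]x[0..m-2]` are exactly the `m` rotations, so one FLASM run with
`ell = m` solves approximate circular string matching, at a cost
independent of `k`. The rotation index is recovered as
`(i - m + 1) mod m`; for periodic patterns distinct windows can spell the
same rotation and all are retained by default (`dedupe_rotations`
collapses them).

Rotation refinement for multiple circular sequence alignment builds an
`N x N` matrix of best pairwise window matches (`mode = "best"`, one
tuple minimising `(e, j, i)` lexicographically — the library's best-match
flag is defined here as one global tuple with that deterministic
tie-break) and derives the rotation `(i - j) mod m_i` aligning the best
window of `s_i` with its match in `s_j`. Sequences are then grouped by
single-linkage agglomerative clustering (via `stats::hclust`) on the
symmetrised distance `min(e_ij, e_ji)`; single linkage is the natural
choice because the matrix stores exactly one best pair per sequence pair.
At each merge the joining cluster is rotated as a block by
`(r_qp + rho_p - rho_q) mod length`, where `(p, q)` is the
minimal-distance cross-pair; the cluster containing the first input
sequence keeps its frame, so the first sequence anchors at rotation 0.
Pairs with no admissible window (or shorter than `ell`) carry an infinite
sentinel and merge last. Note that for `ell` smaller than the sequence
length the two directions of a pair compare different window sets (the
doubled pattern is circular, the text linear), so `e_ij` and `e_ji` can
differ; the symmetrised minimum is what clustering consumes.

The recovery property the tests assert: for rotated copies of one
aperiodic 500-bp ancestor, refinement restores identical sequences
(`ell = 500`, `k = 0`, 20 seeded datasets of 6 sequences); with 5%
random substitutions per copy (`ell = 100`, `k = 25`) at least 90% of
rotations match ground truth. Window length matters here exactly as in
full-scale practice: short windows can match spuriously, long windows
pin the rotation.

## Motif extraction

A single motif of length `ell` is **valid** when it k-occurs (has a
factor within `k`) in at least `quorum` of the `N` input sequences, and
**strictly valid** when it additionally occurs somewhere with zero
errors. Extraction therefore only ever reports factors of the input:
for every ordered sequence pair the core computes, per pattern window,
the minimal distance and occurrence count in the other sequence, and
windows reaching the quorum are reported (deduplicated by motif string,
keeping the lexicographically least source). A factor trivially 0-occurs
in its own sequence, so the source sequence counts towards the quorum —
quorum counts sequences, not occurrences.

Structured motifs are `beta` boxes separated by spacers whose lengths
must fall in given intervals — the shape of composite transcription
factor binding sites. The **gap convention** here: the interval
constrains the number of letters strictly between consecutive boxes,
`g = start_{next} - end_prev - 1`. The phrase "distance between the
ending position and the starting position" is ambiguous by one either
way; spacer-letter count matches the biological reading (a non-conserved
spacer separating two contact points) and is stated so users can shift
their intervals if they follow the other convention. Strict validity is
extended to the structured case: candidates are box tuples read off
exact occurrence chains with compliant spacers in a single source
sequence. Extraction then (1) finds per-slot valid boxes — a necessary
condition, since a chain in a sequence implies each box occurs there —
(2) reads candidate tuples off exact chains, and (3) verifies each
candidate per sequence with an interval join over the boxes' occurrence
lists, sorted by start, extending partial chains whose admissible next
window `[end + dmin + 1, end + dmax + 1]` contains an occurrence start.
Under the edit model an occurrence's start is the minimal-distance start
(smallest on ties), which makes the join well defined.

Motif significance statistics are out of scope; the package reports
validity, not surprise.

## Synthetic data

The generators are pure functions of their parameters and a seed:
uniform random sequences over a given alphabet, uniform random rotations
with ground truth, and motif implantation. An implantation writes one
instance per target sequence at a uniform position (spacer lengths drawn
uniformly within their intervals, spacer letters left as background).
Because a strictly valid motif must occur somewhere exactly, one
designated copy is implanted uncorrupted; every other copy receives
exactly `floor(k_i/2)` substitutions per box by default — within the
occurrence threshold, so full recall of the canonical motif is the
designed outcome, while still exercising the approximate-matching path.
How heavily implanted copies should be corrupted is not pinned down by
the experimental design this emulates; `floor(k/2)` places copies midway
between exact duplication and the validity boundary, and the setting is
a generator argument, not a constant.

The reference synthetic experiment the acceptance script reruns: 50
random 1,000-bp DNA sequences, one instance of a canonical
`(80,15)[5,15](60,10)[5,20](230,20)` structured motif implanted into each
of 25 of them, extraction with those parameters and quorum 25 under the
Hamming model, expecting all 25 implanted instances recovered. The test
suite asserts the same property at a reduced scale (20 sequences of
600 bp, 10 implants, boxes and thresholds halved) — chosen over the
literal half-size instance so that "implanted in half of the sequences"
still holds. What these fixtures do *not* emulate: indel evolution,
compositional bias, repeats, or correlated mutation — passing them shows
the machinery is correct on the designed signal, not that real regulatory
motifs at these parameter settings are recoverable from real genomes.

## The Chang–Marr q-gram index

The index `D` stores, for every q-gram over the alphabet, the minimal
distance to any factor of a pattern `x` — the preprocessing behind
average-case optimal ASM. One FLASM run computes it: the lexicographically
least de Bruijn sequence `B(q, sigma)` (Lyndon-word/FKM construction,
linear in the output, deterministic) is linearised by appending its first
`q - 1` letters so every circular q-gram is a linear factor, and used as
the FLASM pattern with `x` as the text, `ell = q`, `k = q - 1` — the
largest threshold the core admits. Q-grams never reported get `D = q`:
under Hamming a length-q window is always reachable with q substitutions,
so an unreported minimum is exactly q; under edit the entry is capped at
q, which loses nothing for consumers thresholding below q. The naive
baseline (`build_cm_index_naive`) minimises directly over every
(q-gram, factor) pair and doubles as the test oracle; the suite checks
agreement for patterns of length 32 and 64, `q` in 2–6, both models.

## Numerical and degenerate-input choices

* Ties in `mode = "best"`: lexicographic `(e, j, i)` — deterministic and
  sufficient for rotation refinement.
* Result tables are sorted by `(text_end, pattern_end)`; at most one
  tuple per `(j, i)` pair, carrying the minimal distance.
* A single-letter alphabet degenerates the de Bruijn sequence to one
  letter repeated `q` times; a single box degenerates structured to
  single motif extraction.
* All coordinates are 0-based inclusive ending positions everywhere in
  the library; the CLI's `--one-based` flag converts on output only.
* Infinite distances appear only in the rotation matrix sentinel and are
  replaced by (max finite + 1) before clustering.

## Problem sizes used by the test suite

Oracle-equivalence suites run 500 random instances per core (strings up
to 50 letters, factor lengths 2–12, every threshold class, plus
instances with `ell` 65–70 on strings of 72–84 letters to cross the word
boundary — the small-string bound and the above-word factor lengths
cannot be satisfied simultaneously, so the word-boundary cases use the
longer strings). Circular matching is checked against a per-rotation
matcher at `n = 200`, `m = 16`, `k` up to 8; the rotation-recovery and
implant-recovery experiments run at the scales quoted above. These sizes
keep the default suite in a few minutes while covering every code path
the full-scale experiments exercise.

## Known limitations

* The edit core reports ending positions and distances only — no
  alignment traceback, and no affine or weighted costs.
* Motif extraction is exhaustive over input factors; it does not build
  profile models and does not assess statistical significance.
* Rotation refinement applies one rotation per merge step; with very
  divergent sequences (distances near `k` everywhere) the anchoring is
  still deterministic but the recovered frame may be arbitrary.
* The structured-motif gap convention (spacer-letter count) must match
  the user's interval definition; off-by-one interval shifts are the
  most likely source of surprise.
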