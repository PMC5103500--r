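# flasmr

Fixed-length approximate string matching (FLASM) for biological
sequences, with the applications that make it useful: circular sequence
matching and rotation refinement, motif extraction, and the Chang–Marr
q-gram index.

## The problem

Given a text *t* of length *n*, a pattern *x* of length *m*, a factor
length *ℓ* ≤ *m* and a threshold *k* < *ℓ*, FLASM reports every factor of
*t* within distance *k* of **any** length-*ℓ* factor of *x*, under the
Hamming distance (substitutions) or the edit distance (substitutions,
insertions, deletions, unit costs). Each match is a tuple **⟨j, i, e⟩**:
0-based ending position *j* in the text, ending position *i* of the
pattern window, and distance *e*. Under the edit model, *e* at a text
position is the minimum over start positions (semi-global semantics).

The cores are bit-parallel dynamic programs — a MaxShiftM-style
mismatch-vector DP for Hamming, Myers' bit-vector matcher per pattern
factor for edit — running in time *O(m ⌈ℓ/w⌉ n)* and space
*O(m ⌈ℓ/w⌉)* with *w* the machine word size (64). The cost is
independent of *k* and of the alphabet, and multi-word state vectors
make any factor length work, not just *ℓ* ≤ 64: long conserved regions,
full-length circular patterns, 200-mer motifs.

This matters to anyone who needs *all* approximate occurrences of many
windows at once: comparing circular genomes (plasmids, mitochondrial
DNA, viral genomes) whose linearisation start is arbitrary, hunting
transcription-factor binding sites shared across promoter sequences, or
precomputing q-gram distance tables for filtration-based search.

## A worked example

The length-3 factors of the pattern `AAGATG` are `AAG`, `AGA`, `GAT`,
`ATG`. In the text `ATGGCAAGT`, two of them occur exactly, and with one
mismatch allowed `AGA` also pairs with `AGT`:

```r
library(flasmr)
flasm("ATGGCAAGT", "AAGATG", factor_length = 3, max_distance = 1)
#>   text_end pattern_end distance
#> 1        2           2        1
#> 2        2           5        0
#> 3        7           2        0
#> 4        7           5        1
#> 5        8           3        1
```

Row 2 is `ATG` ending at text position 2 matching the pattern window
ending at position 5 exactly; row 5 is the one-mismatch pair `AGT`/`AGA`.

Circular matching doubles the pattern so each rotation is one window
(`rotation` = which rotation matched):

```r
acsm("CCGATGAACC", "AAGATG", max_distance = 0)
#>   text_end pattern_end distance rotation
#> 1        7           7        0        2
```

Rotation 2 of `AAGATG` is `GATGAA`, found at text positions 2–7.

Motif extraction reports factors k-occurring in at least `quorum`
sequences (here the shared core `ACGT`, found in all three):

```r
single_motif_extract(c("AACGTT", "CACGTG", "TACGTA"), 4, 0, quorum = 3)
#>   motif source_seq source_end quorum_count seq_hits
#> 1  ACGT          1          4            3  1, 1, 1
```

And the Chang–Marr index gives every q-gram's minimal distance to a
factor of the pattern:

```r
build_cm_index("AAC", 2, alphabet = c("A", "C"))$D
#> [1] 0 0 1 1    # AA, AC exact; CA, CC at distance 1
```

Other entry points: `structured_motif_extract()` (gapped motif boxes
with spacer-length intervals), `refine_rotations()` (rotate a set of
circular sequences into a common frame before multiple alignment),
`random_dna()` / `implant_structured()` / `random_rotate()` (seeded
synthetic data), and a CLI (`exec/flasm`, subcommands `flasm`, `acsm`,
`index`, `motif-single`, `motif-structured`, `rotate`, `synth`).

The methods vignette (`vignettes/flasmr-methods.Rmd`) documents the
models, the semantic decisions (edit-model start positions, gap
convention, tie-breaks) and the limits of the synthetic designs.

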