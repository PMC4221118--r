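---
title: "Bit-parallel pairwise alignment under general integer scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-parallel pairwise alignment under general integer scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitalign)
```

## The problem and the model

Global pairwise alignment under integer scoring assigns a score
`M >= 0` to every matched column, `I < 0` to every mismatch and `G < 0`
to every gap, and seeks the highest-scoring alignment of two sequences
`x` (length `n`) and `y` (length `m`).  The classical solution fills an
`(m+1) x (n+1)` matrix `S` cell by cell:

    S[i, j] = max( S[i-1, j-1] + (M or I),   # diagonal
                   S[i-1, j]   + G,          # gap from above
                   S[i,   j-1] + G )         # gap from the left

The additional constraint `I >= 2G` (a mismatch never costs more than a
deletion plus an insertion) keeps substitutions usable; outside that
regime the problem degenerates to simpler special cases.

`bitalign` never materializes `S`.  It tracks only the *differences*
between adjacent cells — vertical `dV[i,j] = S[i,j] - S[i-1,j]` and
horizontal `dH[i,j] = S[i,j] - S[i,j-1]` — which are confined to the
integer interval `[G, M - G]`.  With `vmin = G`, `vmid = I - G` and
`vmax = M - G`, the output `dV` of a cell is a *function table* of just
three inputs: the `dV` entering from the left, the `dH` from above, and
the match flag.  Enumerating the three score candidates on a 2x2 patch
shows

    dV_out = max(M or I, dH + G, dV + G) - dH,

and the table splits into zones according to which candidate wins: a
high output carried from the left (zone A), a low output from a gap on
the left (zone B), a mismatch whose output `I - dH` ignores the left
input entirely (zone C), or a gap from above, output `vmin` (zone D).
Two structural facts drive everything else:

* **the `dH = vmin` column is an identity for inputs `>= vmid`** — a
  value entering a *run* of `vmin` columns propagates unchanged through
  the whole run, and values below `vmid` come out as `vmid`;
* **a match behaves exactly like a left input of `vmax`**, so match
  columns can be folded into the input partition instead of being a
  special case.

```{r table}
w <- alignment_weights(2, -3, -5)
weight_bounds(w)
delta_v_table(w)
```

## The standard engine

Bit *i* of a machine word corresponds to column *i* of the matrix.  The
standard representation keeps one word per distinct difference value
(13 words for the illustration weights above): bit *i* of vector
`dH_v` says "column *i* carries horizontal difference `v`".  Rows are
processed top to bottom; for each row the inputs are the previous row's
`dH` vectors, the leftmost `dV` of the current row (the column
initialization) and the row's match vector.

The only sequential hazard is that a cell's `dV` input is its left
neighbour's output.  The engine breaks it the same way bit-parallel
longest-common-subsequence and edit-distance algorithms do, with binary
addition: within a run of `dH = vmin` the identity property means a
value entering the run claims every following column, and a single
`ADD` of the run mask ripples a carry across exactly those columns.
Outputs are computed value by value, from `vmax` down:

1. `vmax` outputs are matches sitting on `dH = vmin`, extended through
   the rest of each run (AND, ADD, two XORs);
2. each remaining high value `v` collects AND-pairs of already-known
   higher inputs with their diagonal `dH` partner (`dH = b + G - v`),
   is shifted one column right, and is carried through the `vmin` runs
   that have not already been claimed by a higher value;
3. low outputs combine zone-B diagonal pairs with the zone-C term — the
   appropriate `dH` vector restricted to columns with no high input;
4. `vmin` takes every column still unassigned;
5. the new `dH` row follows from the transposed table: match columns of
   the old `dH` are promoted to `vmax`, the whole low range collapses to
   `vmid` (all of `[vmin, vmid]` behaves identically there), and
   AND/OR diagonal pairs produce each new value.

Internally every row vector carries one *padding column* past the
sequence (bit `n`), so the output of the last real column survives the
right-shift without any special case; scores never touch the padding.

The score is decoded with popcounts: the last row satisfies
`S[m, n] = m*G + sum_v v * popcount(dH_v)` (with `0` replacing `m*G`
when the first column is free).

```{r score}
align_score("GATTACA", "GATCACA", w)
nw_score("GATTACA", "GATCACA", w)$score
```

## The packed engine

The per-value representation spends most of its operations on the
AND/OR diagonals of zones B and C.  The packed variant instead stores,
per column, the *binary digits* of the value offsets across
`k = ceiling(log2(2*(vmax - vmin) + 1))` bit planes: vertical values map
to non-negative offsets `dV - vmin`, horizontal values to non-positive
`vmin - dH` kept in two's complement.  One digit-serial ripple of
AND/OR/XOR over the planes then adds *all columns at once*:

    (dV_left - vmin) + (vmin - dH_above) = dV_left - dH_above,

which is precisely the zone-A/B output offset; sums with the sign bit
set are zone D and are clamped to offset zero.  Zone C costs nothing
extra: before the addition every column without a high vertical input
is encoded as `vmid`, and `vmid + G - dH = I - dH` is exactly the
mismatch output.  The new `dH` row needs a second addition after two
fix-ups: the low horizontal range is re-encoded to `vmid` (tested by
adding the constant `vmid - vmin` and reading the sign) and match
columns are forced to `vmax`.  Positive sums — impossible for a real
`dH` — are clamped to zero.

Zone A itself still runs in the standard representation: the engine
unpacks only the horizontal vectors steps 1–2 actually consume, namely
`vmin` (the runs) and the diagonal partners
`b + G - v` for `b in (v, vmax]`, `v in (vmid, vmax)` — a low-value
interval `[vmin + 1, vmax + G - vmid - 1]`.  Packing and unpacking use
shared-subexpression trees (aligned-block OR trees for packing, common
digit-prefix AND chains for unpacking), so no primitive OR or AND is
computed twice.

The packed decode reads `k` popcounts instead of `value_count`:
since the planes hold `vmin - dH` in two's complement, the high plane
enters the digit-weighted sum negatively, and
`S[m, n] = m*G + n*vmin - sum_digits`.

## Generated programs and operation counting

Every weight set has its own straight-line program over the six
primitives AND, OR, XOR, NOT, ADD, SHIFT.  `generate_program()` emits
it, `run_program()` interprets it (bit-identical to the engines, which
is tested row by row), and `count_ops()` reports `p`, the number of
logic and addition operations per word, and the efficiency `e = w/p` —
cells advanced per operation at word width `w`.  Stores and moves are
not represented at all, a convention calibrated so that the classical
4-operation LCS word recipe scores `e = 64/4 = 16`.

```{r ops}
for (wt in list(c(0, -1, -1), c(2, -3, -5), c(4, -7, -11))) {
  wi <- alignment_weights(wt[1], wt[2], wt[3])
  cat(sprintf("(%2d,%3d,%4d): standard p = %4d, packed p = %4d\n",
              wt[1], wt[2], wt[3],
              count_ops(generate_program(wi, "standard"))$p,
              count_ops(generate_program(wi, "packed"))$p))
}
```

The standard count grows linearly with the function-table workload
`((M - 2G + 1)^2 - (I - 2G)^2) / 2` — that closed form is kept as an
a-priori scaling estimate only; all reported counts are measured on the
emitted instructions.  The packed count is dominated by zone A, the
pack/unpack trees and two `k`-digit additions, so it grows much more
slowly, and the two variants cross over: for unit-cost edit distance
the packed machinery does not pay for itself, while for wide tables
such as `(4, -7, -11)` it needs a small fraction of the standard
operations.

## Initialization modes, chunks, and words

* **Modes.**  The first row and first column can each be `"gap"`
  (`j*G` / `i*G`) or `"free"` (zero), and the score can be read at the
  last cell, the best of the last row, or the best of the last column —
  the usual global and semi-global conventions.  "Semi-global" is not a
  single fixed convention in the literature, so the two initializations
  are independent switches and all four combinations are exercised in
  the tests.  Free-column modes inject a leftmost vertical value of `0`
  instead of `G`; the injection rides the first shift fill of whichever
  value vector `0` belongs to.  Best-of-last-row is decoded by prefix
  accumulation over the final `dH` row; best-of-last-column by decoding
  each row's `dH` sum incrementally.
* **Chunks.**  Sequences longer than one word tile into chunks of
  `word_width` columns.  The two places where information crosses a
  chunk boundary are addition carries and shifted-out bits; both are
  chained explicitly, and a single arbitrary-width word (the default
  whenever `word_width >= n + 1`) serves as the oracle: chunked runs
  must be bit-identical to wide runs, which the suite asserts at width
  8 against width 512.
* **Words in R.**  Bit vectors are emulated as vectors of 8-bit limbs
  (R has no native 64-bit integer words), which makes any multiple of 8
  a valid word width; widths 8 and 64 are the tested configurations.
  The engines batch their per-value AND/OR work into whole-matrix calls
  — and exploit the fact that vectors drawn from a column partition are
  disjoint, so OR-accumulation can be done by integer addition at C
  speed — but the generated programs retain the per-pair operation
  structure, which is what the operation counts describe.

## Numerical and degenerate-input choices

* `I = 2G` is accepted (the boundary makes `vmid = vmin` and zone C
  vanish); `M = 0` is accepted (matches score nothing but still act as
  `vmax` inputs).  Both have dedicated tests.
* Empty sequences are legal; the score is forced by initialization.
* Characters outside the alphabet (e.g. `N`) never match by default —
  the conservative alignment semantics — and `strict` switches turn
  them into errors.
* Function-table ties on zone borders are resolved by candidate
  enumeration, so the numeric output is well defined even where the
  zone label is ambiguous; border cells are labelled `"border"`.
* Packed sums cannot overflow: `k` is chosen so `2^k >= 2*span + 1`,
  which guarantees both operand ranges and the sum fit a `k`-bit two's
  complement word.

## What the synthetic data does and does not show

The fixture generator draws uniform random sequences over `{A,C,G,T}`
and weights from `M in [0, 6]`, `G in [-12, -1]`, `I in [2G, -1]`, with
forced corner cases (empty sequences, all-match, all-mismatch, word-
boundary lengths).  The acceptance batch runs 1000 instances spanning
five benchmark weight sets spanning small to large function tables,
plus the `I = 2G` boundary and two more
valid schemes, all four initialization modes, and word widths 64
(lengths 0–200) and 8 (lengths 0–48, so that the many-chunk stratum
costs about as much per instance as the wide stratum); row-level
bit-identity is checked on 200 further instances and the edit-distance
law on 200 pairs.  Since the engines are proven *exactly* equal to the
classical recurrence on these inputs, and the recurrence itself is
input-distribution-free, uniform sequences are not a limitation for
correctness claims.  What random tests cannot show is performance on
real genomic data — repeat structure changes run lengths and therefore
constant factors, though never results — and nothing here validates
scoring-scheme choices for a particular biological question.

## Limitations

Scores only: traceback and alignment strings are out of scope by
design, as are affine gaps, per-pair substitution matrices
(BLOSUM/PAM), local alignment, and SIMD/GPU execution.  Operation
counts measure the emitted straight-line programs of *this* generator;
they are comparable across weight sets and variants but are not
hardware timings, and no wall-clock claims are made.  The limb-based
emulation makes the R engines useful as a verified reference and for
moderate batch sizes, not as a replacement for a compiled implementation
when millions of alignments are needed.
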