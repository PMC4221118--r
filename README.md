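# bitalign

Bit-parallel computation of optimal global and semi-global pairwise
alignment scores under general integer scoring, in R.

## The problem

Bulk sequence comparison — read mapping, variant screening, repeat
analysis — needs millions of pairwise alignment scores, and the
classical dynamic programming recurrence

    S[i,j] = max( S[i-1,j-1] + (M or I),  S[i-1,j] + G,  S[i,j-1] + G )

computes them one cell at a time.  Bit-parallel algorithms instead pack
one matrix **column per bit** of a machine word and advance a whole
word of cells per logic/addition operation.  This was long restricted
to special scorings (LCS, unit-cost edit distance); `bitalign`
implements the general integer case — any match score `M >= 0`,
mismatch `I < 0` and gap `G < 0` with `I >= 2G` — by tracking only the
differences between adjacent cells, `dV = S[i,j] - S[i-1,j]` and
`dH = S[i,j] - S[i,j-1]`, which live in the finite interval
`[G, M - G]`.  A finite *function table* maps a cell's two input
differences (plus the match flag) to its outputs, and runs of
`dH = G` are crossed in constant time with one binary addition.

Two engines are provided, exact to the last bit and verified against
classical DP oracles:

* **standard** — one bit vector per distinct difference value
  (`M - 2G + 1` of them);
* **packed** — binary digits of the value offsets spread across
  `ceiling(log2(2(M - 2G) + 1))` bit planes, so all columns are added
  simultaneously; cheaper whenever the function table is large.

A per-weight-set **program generator** emits the specialized
straight-line word program (AND/OR/XOR/NOT/ADD/SHIFT), interprets it,
and counts operations: `e = w/p` cells per operation at word width `w`.

## Worked example

```r
library(bitalign)

w <- alignment_weights(2, -3, -5)     # match +2, mismatch -3, gap -5
weight_bounds(w)
#> difference-value bounds: vmin = -5, vmid = 2, vmax = 7
#>   13 distinct values, span 12, 5 packed bit planes

align_score("GATTACA", "GATCACA", w)  # six matches, one mismatch
#> [1] 9
align_score("GATTACA", "GATCACA", w, variant = "packed")
#> [1] 9
nw_score("GATTACA", "GATCACA", w)$score   # classical DP agrees
#> [1] 9

count_ops(generate_program(w, "standard"))$p
#> [1] 284
count_ops(generate_program(w, "packed"))$p
#> [1] 204
```

The bounds line is the whole data layout: differences range over the 13
values `-5..7`, split at `vmid = I - G = 2`, and the packed engine
needs 5 bit planes.  The operation counts are per word and per row;
for this weight set the packed variant already beats the standard one,
while for unit-cost edit distance (`0, -1, -1`) the standard program
needs only 24 operations and packing does not pay.

Batch scoring and the command-line driver:

```r
score_batch(c(q = "ACGTT"), read_fasta("targets.fa"),
            alignment_weights(0, -1, -1))        # data.frame, TSV-ready
```

```sh
bitalign score --query q.fa --target t.fa --weights 2,-3,-5 --out scores.tsv
bitalign gen --weights 2,-3,-5 --variant packed   # program listing + counts
```

Semi-global alignment (free first row/column, best-of-last-row/column
score sites) is selected with `align_mode()`; word width is
configurable (`word_width = 8` forces multi-chunk processing, chained
bit-exactly across words).

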