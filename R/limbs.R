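## Internal fixed-point of the whole package: bit vectors are emulated as
## integer vectors of 8-bit limbs.  Limb l (1-based) holds columns
## 8*(l-1) .. 8*l-1 of the alignment matrix; bit b of a limb is column
## 8*(l-1)+b.  "Up" shifts move bits toward higher column index (the
## direction written ">>" in left-to-right pictures of the matrix).
## All vectors are kept canonical: bits at or above the width are zero.

.LIMB_BITS <- 8L
.LIMB_MASK <- 255L

.POP8 <- local({
  p <- integer(256L)
  for (i in 1:255) p[i + 1L] <- p[bitwShiftR(i, 1L) + 1L] + bitwAnd(i, 1L)
  p
})

.nlimbs <- function(width) as.integer(ceiling(width / .LIMB_BITS))

.lv_zero <- function(nl) integer(nl)

## all-ones over the first `width` columns, in `nl` limbs
.lv_mask <- function(width, nl = .nlimbs(width)) {
  m <- integer(nl)
  if (width <= 0L) return(m)
  full <- width %/% .LIMB_BITS
  if (full > 0L) m[seq_len(full)] <- .LIMB_MASK
  rem <- width %% .LIMB_BITS
  if (rem > 0L) m[full + 1L] <- bitwShiftL(1L, rem) - 1L
  m
}

.lv_from_bits <- function(bits, width, nl = .nlimbs(width)) {
  v <- integer(nl)
  if (length(bits)) {
    stopifnot(all(bits >= 0L), all(bits < width))
    for (b in as.integer(bits)) {
      l <- b %/% .LIMB_BITS + 1L
      v[l] <- bitwOr(v[l], bitwShiftL(1L, b %% .LIMB_BITS))
    }
  }
  v
}

.lv_bits <- function(v) {
  out <- integer(0)
  for (l in seq_along(v)) {
    x <- v[l]
    if (x != 0L) {
      b <- which(bitwAnd(bitwShiftR(x, 0:7), 1L) == 1L) - 1L
      out <- c(out, b + .LIMB_BITS * (l - 1L))
    }
  }
  out
}

.lv_not <- function(v, mask) bitwAnd(bitwXor(v, .LIMB_MASK), mask)

.lv_popcount <- function(v) sum(.POP8[v + 1L])

## ripple-carry addition; carry_in/carry_out are 0/1 integers
.lv_add <- function(a, b, carry_in = 0L) {
  nl <- length(a)
  s <- integer(nl)
  c <- carry_in
  for (l in seq_len(nl)) {
    t <- a[l] + b[l] + c
    c <- if (t > .LIMB_MASK) 1L else 0L
    s[l] <- t - 256L * c
  }
  list(sum = s, carry = c)
}

## shift one position toward higher column index; fill enters column 0,
## the bit leaving the top of the highest limb is returned.
## NOTE: operates on whole limbs; the caller masks to width if the top
## limb is partial.
.lv_shift_up <- function(v, fill = 0L) {
  nl <- length(v)
  if (nl == 0L) return(list(result = v, evicted = fill))
  hi <- bitwShiftR(v, 7L)
  res <- bitwOr(bitwAnd(bitwShiftL(v, 1L), .LIMB_MASK),
                c(fill, hi[-nl]))
  list(result = res, evicted = hi[nl])
}

## shift one position toward lower column index; column 0 is dropped,
## fill_top enters the highest column of the highest limb
.lv_shift_down <- function(v, fill_top = 0L) {
  nl <- length(v)
  if (nl == 0L) return(v)
  lo <- bitwAnd(v, 1L)
  bitwOr(bitwShiftR(v, 1L),
         bitwShiftL(c(lo[-1L], fill_top), 7L))
}

## OR-fold the P stacked vectors of a flat L*P integer vector down to one
## vector of length L (tree reduction; order immaterial for OR)
.lv_or_fold <- function(flat, L) {
  n <- length(flat) %/% L
  if (n == 0L) return(integer(L))
  while (n > 1L) {
    half <- n %/% 2L
    a <- flat[seq_len(L * half)]
    b <- flat[L * half + seq_len(L * half)]
    rest <- if (n %% 2L == 1L) flat[L * 2L * half + seq_len(L)] else integer(0)
    flat <- c(bitwOr(a, b), rest)
    n <- half + n %% 2L
  }
  flat
}

## Fold of P stacked vectors KNOWN to be pairwise disjoint: OR equals
## integer addition, so the C-level row sum applies.  Callers must only
## pass vector families drawn from column partitions.
.lv_sum_fold <- function(flat, L) {
  n <- length(flat) %/% L
  if (n <= 1L) return(if (n == 1L) flat else integer(L))
  as.integer(.rowSums(flat, L, n))
}

## Match vectors over the limb representation: one column per alphabet
## character, bit i set where x[i] == character.  Characters of x outside
## the alphabet belong to no vector (they never match).
.match_limb_matrix <- function(xchars, alphabet, nl) {
  m <- matrix(0L, nl, length(alphabet), dimnames = list(NULL, alphabet))
  if (length(xchars)) {
    idx <- match(xchars, alphabet)
    pos <- which(!is.na(idx)) - 1L
    for (k in seq_along(pos)) {
      p <- pos[k]
      l <- p %/% .LIMB_BITS + 1L
      m[l, idx[pos[k] + 1L]] <- bitwOr(m[l, idx[pos[k] + 1L]],
                                       bitwShiftL(1L, p %% .LIMB_BITS))
    }
  }
  m
}
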