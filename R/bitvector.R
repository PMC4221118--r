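#' Fixed-width bit vectors over alignment-matrix columns
#'
#' A `bitvec` is a canonical fixed-width word in which bit `i` corresponds
#' to column `i` of the alignment scoring matrix (bit 0 = leftmost column
#' of the current chunk).  Only the primitive operations the bit-parallel
#' engines use are provided: AND, OR, XOR, complement, shifts, addition
#' with an explicit carry, and popcount.  Addition carries and shift
#' eviction bits are exposed so words can be chained into multi-word
#' "chunks" for sequences longer than one word.
#'
#' @param width Number of bit positions (columns), `>= 0`.
#' @param bits Integer vector of 0-based positions to set.
#' @return An object of class `"bitvec"`.
#' @examples
#' a <- bitvec(5, c(0, 2))
#' b <- bitvec(5, c(1, 2))
#' bv_bits(bv_and(a, b))     # 2
#' bv_popcount(bv_not(a))    # 3
#' @export
bitvec <- function(width, bits = integer()) {
  width <- .as_int1(width, "width")
  stopifnot(width >= 0L)
  structure(list(width = width,
                 limbs = .lv_from_bits(bits, width)),
            class = "bitvec")
}

.bv <- function(width, limbs) {
  structure(list(width = width, limbs = limbs), class = "bitvec")
}

.bv_check2 <- function(a, b) {
  stopifnot(inherits(a, "bitvec"), inherits(b, "bitvec"))
  if (a$width != b$width)
    stop("bit-vector width mismatch: ", a$width, " vs ", b$width)
}

#' @rdname bitvec
#' @param a,b `bitvec` operands of equal width.
#' @export
bv_and <- function(a, b) {
  .bv_check2(a, b)
  .bv(a$width, bitwAnd(a$limbs, b$limbs))
}

#' @rdname bitvec
#' @export
bv_or <- function(a, b) {
  .bv_check2(a, b)
  .bv(a$width, bitwOr(a$limbs, b$limbs))
}

#' @rdname bitvec
#' @export
bv_xor <- function(a, b) {
  .bv_check2(a, b)
  .bv(a$width, bitwXor(a$limbs, b$limbs))
}

#' @rdname bitvec
#' @export
bv_not <- function(a) {
  stopifnot(inherits(a, "bitvec"))
  .bv(a$width, .lv_not(a$limbs, .lv_mask(a$width)))
}

#' Binary addition of two bit vectors with explicit carry
#'
#' Addition modulo `2^width`; the carry in/out bits support chaining words
#' of a multi-chunk layout so that chunked addition is bit-identical to
#' addition on one wide word.
#'
#' @param a,b `bitvec` operands of equal width.
#' @param carry_in 0 or 1.
#' @return A list with components `sum` (a `bitvec`) and `carry` (0 or 1).
#' @export
bv_add <- function(a, b, carry_in = 0L) {
  .bv_check2(a, b)
  r <- .lv_add(a$limbs, b$limbs, as.integer(carry_in))
  s <- bitwAnd(r$sum, .lv_mask(a$width))
  ## a carry out of the width, not out of the top limb
  carry <- if (a$width %% .LIMB_BITS == 0L) r$carry else {
    bitwAnd(bitwShiftR(r$sum[length(r$sum)], a$width %% .LIMB_BITS), 1L)
  }
  list(sum = .bv(a$width, s), carry = carry)
}

#' Shift a bit vector one column to the right (toward higher index)
#'
#' Every bit moves one column index higher; `fill` enters column 0 and the
#' bit leaving the top column is returned for chunk chaining.
#'
#' @param a A `bitvec`.
#' @param fill Bit (0/1) entering position 0.
#' @return List with `result` (a `bitvec`) and `evicted` (0/1).
#' @export
bv_shift_in <- function(a, fill = 0L) {
  stopifnot(inherits(a, "bitvec"))
  if (a$width == 0L) return(list(result = a, evicted = as.integer(fill)))
  r <- .lv_shift_up(a$limbs, as.integer(fill))
  mask <- .lv_mask(a$width)
  res <- bitwAnd(r$result, mask)
  rem <- a$width %% .LIMB_BITS
  evicted <- if (rem == 0L) r$evicted else {
    bitwAnd(bitwShiftR(r$result[length(r$result)], rem), 1L)
  }
  list(result = .bv(a$width, res), evicted = evicted)
}

#' @rdname bitvec
#' @export
bv_popcount <- function(a) {
  stopifnot(inherits(a, "bitvec"))
  .lv_popcount(a$limbs)
}

#' @rdname bitvec
#' @export
bv_bits <- function(a) {
  stopifnot(inherits(a, "bitvec"))
  .lv_bits(a$limbs)
}

#' @export
format.bitvec <- function(x, ...) {
  if (x$width == 0L) return("<empty bitvec>")
  bits <- integer(x$width)
  bits[.lv_bits(x$limbs) + 1L] <- 1L
  paste(bits, collapse = "")  # low-order bit (column 0) printed first
}

#' @export
print.bitvec <- function(x, ...) {
  cat(sprintf("bitvec width %d (bit 0 first): %s\n", x$width, format(x)))
  invisible(x)
}

#' @export
`==.bitvec` <- function(e1, e2) {
  e1$width == e2$width && all(e1$limbs == e2$limbs)
}

#' Chunk layout for sequences longer than one machine word
#'
#' Columns `0..n-1` are tiled left to right into chunks of `word_width`
#' bits; the last chunk may be partially filled.
#'
#' @param n Number of columns (sequence length).
#' @param word_width Word size in bits (positive).
#' @return List with `word_width`, `n_chunks` and `last_chunk_fill`.
#' @export
chunk_layout <- function(n, word_width = 64L) {
  n <- .as_int1(n, "n")
  word_width <- .as_int1(word_width, "word_width")
  stopifnot(n >= 0L, word_width > 0L)
  n_chunks <- max(1L, as.integer(ceiling(n / word_width)))
  fill <- n - (n_chunks - 1L) * word_width
  list(word_width = word_width, n_chunks = n_chunks,
       last_chunk_fill = as.integer(fill))
}

#' Per-character match vectors of a sequence
#'
#' For each character of the alphabet, records the positions of the
#' horizontal sequence holding that character, as a `bitvec` of width
#' `nchar(x)`.  Built in a single pass.  Characters of `x` outside the
#' alphabet belong to no vector — they never match anything — unless
#' `strict = TRUE`, in which case they are an error.
#'
#' @param x A character string (the horizontal sequence).
#' @param alphabet Character vector of single characters.
#' @param strict Reject characters outside the alphabet?
#' @return Named list of `bitvec` (class `"match_vectors"`), one per
#'   alphabet character, with attributes `width` and `alphabet`.
#' @examples
#' mv <- match_vectors("ACGTA")
#' bv_bits(mv$A)  # 0 4
#' @export
match_vectors <- function(x, alphabet = c("A", "C", "G", "T"),
                          strict = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (strict && length(bad <- setdiff(unique(chars), alphabet)))
    stop("characters outside alphabet: ", paste(bad, collapse = ", "))
  n <- length(chars)
  m <- .match_limb_matrix(chars, alphabet, .nlimbs(max(n, 1L)))
  out <- lapply(seq_along(alphabet), function(k) .bv(n, if (n) m[, k] else integer(0)))
  names(out) <- alphabet
  structure(out, width = n, alphabet = alphabet, class = "match_vectors")
}
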