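#' Classical dynamic-programming alignment score (reference oracle)
#'
#' Deliberately naive O(nm) integer dynamic programming over the full
#' scoring matrix, used as ground truth for the bit-parallel engines.
#' `S[i, j]` is the best score of aligning the first `i` characters of `y`
#' with the first `j` characters of `x`; each cell takes the maximum of a
#' (mis)match from the diagonal and a gap from above or from the left.
#'
#' @param x Horizontal sequence (columns).
#' @param y Vertical sequence (rows).
#' @param weights An [alignment_weights()] object or numeric triple.
#' @param mode An [align_mode()].
#' @return List with `score` (integer, read at the mode's score site) and
#'   `S` (the full `(m+1) x (n+1)` integer matrix).
#' @examples
#' nw_score("AG", "G", alignment_weights(2, -3, -5))$score  # -3
#' @export
nw_score <- function(x, y, weights, mode = align_mode()) {
  w <- .as_weights(weights)
  stopifnot(inherits(mode, "align_mode"))
  xc <- .chars(x); yc <- .chars(y)
  n <- length(xc); m <- length(yc)
  G <- w$G
  S <- matrix(0L, m + 1L, n + 1L)
  S[1L, ] <- if (mode$first_row == "gap") G * (0L:n) else 0L
  S[, 1L] <- if (mode$first_column == "gap") G * (0L:m) else 0L
  if (m > 0L && n > 0L) {
    for (i in 1L:m) {
      yi <- yc[i]
      for (j in 1L:n) {
        s <- S[i, j] + (if (xc[j] == yi) w$M else w$I)
        t <- S[i, j + 1L] + G
        if (t > s) s <- t
        t <- S[i + 1L, j] + G
        if (t > s) s <- t
        S[i + 1L, j + 1L] <- s
      }
    }
  }
  score <- switch(mode$score_site,
                  last_cell = S[m + 1L, n + 1L],
                  last_row = max(S[m + 1L, ]),
                  last_col = max(S[, n + 1L]))
  list(score = as.integer(score), S = S)
}

#' Difference matrices of a scoring matrix
#'
#' Vertical differences `dv[i, j] = S[i, j] - S[i-1, j]` (one row per
#' sequence-`y` position, columns `0..n` of the matrix) and horizontal
#' differences `dh[i, j] = S[i, j] - S[i, j-1]` (rows `0..m`, one column
#' per sequence-`x` position).  Both are confined to `[G, M - G]`.
#'
#' @param S The score matrix from [nw_score()].
#' @return List with integer matrices `dv` (`m x (n+1)`) and `dh`
#'   (`(m+1) x n`).
#' @export
delta_matrices <- function(S) {
  m <- nrow(S) - 1L
  n <- ncol(S) - 1L
  dv <- if (m > 0L) S[-1L, , drop = FALSE] - S[-(m + 1L), , drop = FALSE] else
    matrix(0L, 0L, n + 1L)
  dh <- if (n > 0L) S[, -1L, drop = FALSE] - S[, -(n + 1L), drop = FALSE] else
    matrix(0L, m + 1L, 0L)
  list(dv = dv, dh = dh)
}

#' Score from the difference recurrence alone (second oracle)
#'
#' Computes the alignment score cell by cell using only the recursive
#' case analysis of the difference values — match, mismatch, indel from
#' above, indel from the left — without ever materializing the scoring
#' matrix.  Kept deliberately independent of both the candidate-maximum
#' function table and the bit-parallel engines so that it can serve as a
#' second ground truth.
#'
#' @inheritParams nw_score
#' @return Integer score at the mode's score site.
#' @export
delta_recurrence_score <- function(x, y, weights, mode = align_mode()) {
  w <- .as_weights(weights)
  stopifnot(inherits(mode, "align_mode"))
  xc <- .chars(x); yc <- .chars(y)
  n <- length(xc); m <- length(yc)
  G <- w$G; I <- w$I; M <- w$M
  mid <- I - G
  dh <- if (mode$first_row == "gap") rep(G, n) else rep(0L, n)
  col0 <- function(i) if (mode$first_column == "gap") i * G else 0L
  best_last_col <- col0(0L) + sum(dh)            # S[0, n]
  if (m > 0L) {
    for (i in 1L:m) {
      dvl <- if (mode$first_column == "gap") G else 0L
      if (n > 0L) {
        yi <- yc[i]
        for (j in 1L:n) {
          h <- dh[j]
          dv <- if (xc[j] == yi) {
            M - h
          } else if (mid >= h && mid >= dvl) {
            I - h
          } else if (h >= mid && h >= dvl) {
            G
          } else {
            dvl + G - h
          }
          ## S[i,j]-S[i,j-1] = dv + dh_above - dv_left (telescoping square)
          dh[j] <- dv + h - dvl
          dvl <- dv
        }
      }
      if (mode$score_site == "last_col") {
        s <- col0(i) + sum(dh)
        if (s > best_last_col) best_last_col <- s
      }
    }
  }
  base <- col0(m)
  switch(mode$score_site,
         last_cell = as.integer(base + sum(dh)),
         last_row = as.integer(base +
           if (n > 0L) max(0L, max(cumsum(dh))) else 0L),
         last_col = as.integer(best_last_col))
}

#' Seeded synthetic alignment fixtures
#'
#' Reproducible stream of `(x, y, weights)` triples for property testing.
#' Weights are sampled from the rule `M` in `0..6`, `G` in `-12..-1`,
#' `I` in `2G..-1`, so every triple is a valid scoring scheme.  The first
#' ten fixtures are forced corner cases: empty sequences, all-match and
#' all-mismatch pairs, single characters, and lengths exactly at the word
#' size and one off it.
#'
#' @param count Number of fixtures (at least 10).
#' @param seed Integer seed for the stream.
#' @param len_range Integer range (lo, hi) for random sequence lengths.
#' @param alphabet Characters to draw sequences from.
#' @param word_width Word size used for the boundary-length corner cases.
#' @return A list of `count` lists with components `x`, `y`, `weights`.
#' @export
make_fixtures <- function(count, seed = 1L, len_range = c(0L, 200L),
                          alphabet = c("A", "C", "G", "T"),
                          word_width = 64L) {
  stopifnot(count >= 10L)
  set.seed(seed)
  rs <- function(len) paste(sample(alphabet, len, replace = TRUE), collapse = "")
  rl <- function() sample(len_range[1L]:len_range[2L], 1L)
  rw <- function() {
    G <- sample(-12L:-1L, 1L)
    alignment_weights(sample(0L:6L, 1L), sample((2L * G):(-1L), 1L), G)
  }
  s <- rs(max(4L, min(12L, len_range[2L])))
  wde <- word_width
  corners <- list(
    list(x = "", y = rs(max(1L, min(5L, len_range[2L])))),
    list(x = rs(max(1L, min(5L, len_range[2L]))), y = ""),
    list(x = "", y = ""),
    list(x = s, y = s),                                    # all match
    list(x = strrep(alphabet[1L], 6L), y = strrep(alphabet[2L], 6L)),
    list(x = alphabet[1L], y = alphabet[1L]),
    list(x = rs(wde), y = rs(wde)),
    list(x = rs(wde + 1L), y = rs(wde)),
    list(x = rs(wde - 1L), y = rs(wde + 1L)),
    list(x = rs(wde), y = rs(max(1L, wde %/% 2L)))
  )
  out <- vector("list", count)
  for (k in seq_len(count)) {
    p <- if (k <= 10L) corners[[k]] else list(x = rs(rl()), y = rs(rl()))
    p$weights <- rw()
    out[[k]] <- p
  }
  out
}
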