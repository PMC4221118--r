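## Standard bit-parallel engine: one bit vector per distinct difference
## value.  Row state lives in L x value_count integer limb matrices.
##
## Coordinate conventions (crucial, used throughout):
##  * "output space": bit j = column j of the current row, j in [0, n).
##  * "input space": bit j = the vertical-difference value ENTERING column
##    j from the left, i.e. the output of column j-1 shifted one right,
##    with bit 0 holding the leftmost (initialization) value and bit n --
##    one position past the sequence -- holding the output of the last
##    column.  Input-space vectors therefore have width n+1.
## A value's input-space vector SRAW[v] satisfies
##    SRAW[v] = (outputs of v) << 1  |  (bit0 if leftmost value == v),
## so outputs are recovered by one shift down.  Effective inputs EIN[v]
## additionally treat every match column as holding input vmax.

## Diagonal (input value, horizontal value) pairs feeding each output
## value, precomputed once per weight set.  Indices are 1-based columns
## into the value-indexed matrices (value v -> v - vmin + 1).
.pairs_standard <- function(w, b) {
  vmin <- b$vmin; vmid <- b$vmid; vmax <- b$vmax
  vi <- function(v) v - vmin + 1L
  high_desc <- if (vmax - 1L >= vmid + 1L) seq(vmax - 1L, vmid + 1L) else integer(0)
  step2 <- lapply(high_desc, function(v) {
    bs <- (v + 1L):vmax                       # larger input carried diagonally
    list(v = v, bi = vi(bs), ai = vi(bs + w$G - v))
  })
  lows <- if (vmid >= vmin + 1L) seq(vmid, vmin + 1L) else integer(0)
  step3 <- lapply(lows, function(v) {
    bs <- if (vmax >= vmid + 1L) (vmid + 1L):vmax else integer(0)
    list(v = v, bi = vi(bs), ai = vi(bs + w$G - v),   # Zone B diagonals
         ci = vi(w$I - v))                            # Zone C: dh alone
  })
  ## new horizontal values: (modified dh, true dv input) pairs
  as <- vmid:vmax
  s5 <- vector("list", b$value_count)
  for (a in as) for (bb in vmin:vmax) {
    u <- max(w$I, a + w$G, bb + w$G) - bb
    if (u > vmin) {
      k <- vi(u)
      s5[[k]] <- rbind(s5[[k]], c(a - vmid + 1L, vi(bb)))
    }
  }
  step5 <- lapply(seq_along(s5), function(k) {
    if (is.null(s5[[k]])) NULL else list(ai = s5[[k]][, 1L], bi = s5[[k]][, 2L])
  })
  ## batched index/grouping forms: the AND products of all pairs are
  ## computed in one call and group-summed per output value (legitimate
  ## because products over distinct pairs are disjoint)
  s3bi <- unlist(lapply(step3, `[[`, "bi"))
  s3ai <- unlist(lapply(step3, `[[`, "ai"))
  G3 <- if (length(step3)) {
    g <- matrix(0, length(s3bi), length(step3))
    ofs <- 0L
    for (k in seq_along(step3)) {
      nk <- length(step3[[k]]$bi)
      if (nk) g[ofs + seq_len(nk), k] <- 1
      ofs <- ofs + nk
    }
    g
  } else NULL
  s5ai <- integer(0); s5bi <- integer(0); s5u <- integer(0)
  for (u in seq_along(step5)) if (!is.null(step5[[u]])) {
    s5ai <- c(s5ai, step5[[u]]$ai)
    s5bi <- c(s5bi, step5[[u]]$bi)
    s5u <- c(s5u, rep(u, length(step5[[u]]$ai)))
  }
  G5 <- matrix(0, length(s5u), b$value_count)
  if (length(s5u)) G5[cbind(seq_along(s5u), s5u)] <- 1
  list(high_desc = high_desc, step2 = step2, step3 = step3, step5 = step5,
       n_dhd = vmax - vmid + 1L,
       s3bi = s3bi, s3ai = s3ai, G3 = G3,
       s3ci = vapply(step3, `[[`, 0L, "ci"),
       s5ai = s5ai, s5bi = s5bi, G5 = G5)
}

## Context shared by all rows of one alignment
.std_ctx <- function(n, w, b, mode, word_width) {
  if (word_width %% .LIMB_BITS != 0L || word_width <= 0L)
    stop("word_width must be a positive multiple of ", .LIMB_BITS)
  pw <- n + 1L                      # padded width (virtual column n)
  L <- .nlimbs(pw)
  wl <- word_width %/% .LIMB_BITS
  n_chunks <- as.integer(ceiling(L / wl))
  chunks <- lapply(seq_len(n_chunks), function(c)
    ((c - 1L) * wl + 1L):min(c * wl, L))
  leftmost <- if (mode$first_column == "gap") w$G else 0L
  list(n = n, pw = pw, L = L, V = b$value_count, chunks = chunks,
       nmask = .lv_mask(n, L), pmask = .lv_mask(pw, L),
       vmin = b$vmin, vmid = b$vmid, vmax = b$vmax,
       leftmost = leftmost, li = leftmost - b$vmin + 1L,
       w = w, b = b, pairs = .pairs_standard(w, b))
}

## One row of the standard engine.  dh_mat: L x V limb matrix of the
## previous row's horizontal differences; match_lv: limbs of this row's
## match vector.  Processes the row chunk by chunk, chaining addition
## carries and shift eviction bits between chunks.  Returns the
## input-space vertical vectors (sraw) and the new horizontal vectors.
## Steps 1 and 2 (Zone A) for one chunk.  dh_c must hold valid columns for
## vmin and every diagonal partner the high-value pairs consume; `ch` is an
## environment with chain state (s1carry, s2fill, s2carry) that persists
## across chunks of the same row.  Both engines share this code: the
## packed engine runs Zone A in the standard representation.
.zoneA_chunk <- function(dh_c, mt_c, pmask_c, Lc, ctx, ch) {
  pr <- ctx$pairs
  V <- ctx$V
  notm <- bitwXor(mt_c, .LIMB_MASK)
  dhmin_c <- dh_c[, 1L]

  ## Step 1: vmax outputs -- matches on dh = vmin, carried through runs
  t1 <- bitwAnd(mt_c, dhmin_c)
  r <- .lv_add(dhmin_c, t1, ch$s1carry); ch$s1carry <- r$carry
  s_max <- bitwAnd(bitwXor(bitwXor(r$sum, dhmin_c), t1), pmask_c)
  ein_max <- bitwOr(s_max, mt_c)
  sr_c <- matrix(0L, Lc, V)
  ein_c <- matrix(0L, Lc, V)            # only high columns are ever used
  sr_c[, V] <- s_max
  ein_c[, V] <- ein_max
  highun <- ein_max                     # union of effective inputs > v
  allun <- s_max                        # union of all assigned inputs

  ## Step 2: remaining high outputs, in decreasing value order
  for (k in seq_along(pr$step2)) {
    p <- pr$step2[[k]]
    u <- .lv_sum_fold(bitwAnd(ein_c[, p$bi], dh_c[, p$ai]), Lc)
    sh <- .lv_shift_up(u, ch$s2fill[k]); ch$s2fill[k] <- sh$evicted
    e <- bitwAnd(sh$result, pmask_c)
    rmask <- bitwAnd(dhmin_c, bitwXor(highun, .LIMB_MASK))
    r <- .lv_add(rmask, e, ch$s2carry[k]); ch$s2carry[k] <- r$carry
    s_v <- bitwAnd(bitwOr(bitwXor(bitwXor(r$sum, rmask), e), e), pmask_c)
    ki <- p$v - ctx$vmin + 1L
    sr_c[, ki] <- s_v
    ein_c[, ki] <- bitwAnd(s_v, notm)
    highun <- bitwOr(highun, ein_c[, ki])
    allun <- bitwOr(allun, s_v)
  }
  list(sr = sr_c, ein = ein_c, highun = highun, allun = allun)
}

## Fresh chain-state environment for one row; the leftmost-value
## injection enters as the very first shift fill of its step.
.row_chain <- function(ctx) {
  pr <- ctx$pairs
  ch <- new.env(parent = emptyenv())
  ch$s1carry <- 0L
  ch$s2fill <- integer(length(pr$step2))
  ch$s2carry <- integer(length(pr$step2))
  ch$s3fill <- integer(length(pr$step3))
  for (k in seq_along(pr$step2))
    if (pr$step2[[k]]$v == ctx$leftmost) ch$s2fill[k] <- 1L
  for (k in seq_along(pr$step3))
    if (pr$step3[[k]]$v == ctx$leftmost) ch$s3fill[k] <- 1L
  ch
}

.std_row <- function(dh_mat, match_lv, ctx) {
  L <- ctx$L; V <- ctx$V
  pr <- ctx$pairs
  sraw <- matrix(0L, L, V)
  dhnew <- matrix(0L, L, V)
  ch <- .row_chain(ctx)
  for (idx in ctx$chunks) {
    Lc <- length(idx)
    dh_c <- dh_mat[idx, , drop = FALSE]
    mt_c <- match_lv[idx]
    notm <- bitwXor(mt_c, .LIMB_MASK)
    pmask_c <- ctx$pmask[idx]
    nmask_c <- ctx$nmask[idx]

    za <- .zoneA_chunk(dh_c, mt_c, pmask_c, Lc, ctx, ch)
    sr_c <- za$sr; ein_c <- za$ein
    allun <- za$allun
    nohigh <- bitwAnd(bitwXor(za$highun, .LIMB_MASK), pmask_c)

    ## Step 3: low outputs from Zone B diagonals and Zone C (dh alone),
    ## all values batched: one AND over every diagonal pair, group-summed
    ## per output value (pair products are disjoint)
    nlow <- length(pr$step3)
    if (nlow) {
      zb <- matrix(bitwAnd(ein_c[, pr$s3bi], dh_c[, pr$s3ai]), Lc) %*% pr$G3
      cterms <- matrix(bitwAnd(dh_c[, pr$s3ci, drop = FALSE], nohigh), Lc)
      for (k in seq_len(nlow)) {
        u <- as.integer(zb[, k]) + cterms[, k]   # disjoint: sum == OR
        sh <- .lv_shift_up(u, ch$s3fill[k]); ch$s3fill[k] <- sh$evicted
        s_v <- bitwAnd(sh$result, pmask_c)
        sr_c[, pr$step3[[k]]$v - ctx$vmin + 1L] <- s_v
        allun <- bitwOr(allun, s_v)
      }
    }

    ## Step 4: vmin takes every remaining position
    sr_c[, 1L] <- bitwAnd(bitwXor(allun, .LIMB_MASK), pmask_c)

    ## Step 5: new horizontal differences.  Previous-row dh is modified:
    ## match columns act as vmax, all low values collapse to vmid.
    dhd <- matrix(0L, Lc, pr$n_dhd)
    midi <- ctx$vmid - ctx$vmin + 1L
    dhd[, 1L] <- bitwAnd(.lv_sum_fold(dh_c[, seq_len(midi)], Lc), notm)
    if (pr$n_dhd > 2L)
      for (a in 2L:(pr$n_dhd - 1L))
        dhd[, a] <- bitwAnd(dh_c[, midi + a - 1L], notm)
    if (pr$n_dhd >= 2L)
      dhd[, pr$n_dhd] <- bitwOr(dh_c[, V], mt_c)
    else
      dhd[, 1L] <- bitwOr(dhd[, 1L], mt_c)   # degenerate vmid == vmax
    ## all (modified dh, vertical input) pairs in one AND, group-summed
    ## per new horizontal value (products are disjoint)
    pm <- matrix(bitwAnd(dhd[, pr$s5ai], sr_c[, pr$s5bi]), Lc) %*% pr$G5
    dn_c <- matrix(as.integer(pm), Lc, V)
    dun <- as.integer(.rowSums(pm, Lc, V))
    dn_c[, 1L] <- bitwAnd(bitwXor(dun, .LIMB_MASK), nmask_c)
    sraw[idx, ] <- sr_c
    dhnew[idx, ] <- dn_c
  }
  list(sraw = sraw, dhnew = dhnew)
}

## Decode S[i, n] - S[i, 0] from a horizontal difference matrix
.decode_dh_sum <- function(dh_mat, vmin) {
  V <- ncol(dh_mat)
  vals <- vmin + 0:(V - 1L)
  s <- 0L
  for (k in seq_len(V)) s <- s + vals[k] * .lv_popcount(dh_mat[, k])
  s
}

## Per-column values of a value-indexed limb matrix (n columns)
.decode_columns <- function(mat, vmin, n) {
  out <- integer(n)
  for (k in seq_len(ncol(mat))) {
    bits <- .lv_bits(mat[, k])
    bits <- bits[bits < n]
    if (length(bits)) out[bits + 1L] <- vmin + k - 1L
  }
  out
}

.init_dh <- function(ctx, mode) {
  dh <- matrix(0L, ctx$L, ctx$V)
  h0 <- if (mode$first_row == "gap") ctx$w$G else 0L
  dh[, h0 - ctx$vmin + 1L] <- ctx$nmask
  dh
}

.col0_score <- function(i, w, mode) {
  if (mode$first_column == "gap") i * w$G else 0L
}

## Full standard-engine driver.  keep_rows retains, per row, the decoded
## input-space vectors, output vectors and new dh vectors for inspection.
.std_align <- function(x, y, w, b, mode, word_width = 64L, keep_rows = FALSE) {
  xc <- .chars(x); yc <- .chars(y)
  n <- length(xc); m <- length(yc)
  ctx <- .std_ctx(n, w, b, mode, word_width)
  mm <- .match_limb_matrix(xc, unique(xc), ctx$L)
  zero_match <- integer(ctx$L)
  dh <- .init_dh(ctx, mode)
  rows <- if (keep_rows) vector("list", m) else NULL
  best_col <- .col0_score(0L, w, mode) + .decode_dh_sum(dh, ctx$vmin)
  for (i in seq_len(m)) {
    ml <- if (yc[i] %in% colnames(mm)) mm[, yc[i]] else zero_match
    st <- .std_row(dh, ml, ctx)
    dh <- st$dhnew
    if (keep_rows) {
      out <- apply(st$sraw, 2L, .lv_shift_down)
      if (is.null(dim(out))) out <- matrix(out, nrow = ctx$L)
      rows[[i]] <- list(sraw = st$sraw, out = out, dh = dh)
    }
    if (mode$score_site == "last_col") {
      s <- .col0_score(i, w, mode) + .decode_dh_sum(dh, ctx$vmin)
      if (s > best_col) best_col <- s
    }
  }
  base <- .col0_score(m, w, mode)
  score <- switch(mode$score_site,
    last_cell = base + .decode_dh_sum(dh, ctx$vmin),
    last_row = {
      colv <- .decode_columns(dh, ctx$vmin, n)
      base + (if (n > 0L) max(0L, max(cumsum(colv))) else 0L)
    },
    last_col = best_col)
  list(score = as.integer(score), final_dh = dh, rows = rows, ctx = ctx)
}

#' Bit-parallel optimal alignment score
#'
#' Computes the optimal global or semi-global alignment score of two
#' sequences under integer weights, processing up to a machine word of
#' scoring-matrix columns per primitive operation.  The `"standard"`
#' engine keeps one bit vector per distinct difference value; the
#' `"packed"` engine keeps binary-digit bit planes of the value offsets
#' and replaces most of the per-value work by simultaneous per-column
#' addition.  Both produce exactly the score of the classical dynamic
#' programming recurrence ([nw_score()]).
#'
#' @param x Horizontal sequence (its length is the word dimension).
#' @param y Vertical sequence (processed row by row).
#' @param weights An [alignment_weights()] object or `(M, I, G)` triple.
#' @param mode An [align_mode()].
#' @param variant `"standard"` or `"packed"`.
#' @param word_width Machine word size in bits (positive multiple of 8);
#'   longer sequences are processed in chunks of this many columns with
#'   carries and shifted-out bits chained across chunk boundaries.
#' @return Integer score.
#' @examples
#' align_score("ACGT", "ACGT", alignment_weights(2, -3, -5))   # 8
#' align_score("AC", "AG", alignment_weights(0, -1, -1))       # -1
#' @export
align_score <- function(x, y, weights, mode = align_mode(),
                        variant = c("standard", "packed"),
                        word_width = 64L) {
  variant <- match.arg(variant)
  w <- .as_weights(weights)
  b <- weight_bounds(w)
  stopifnot(inherits(mode, "align_mode"))
  if (variant == "standard")
    .std_align(x, y, w, b, mode, word_width)$score
  else
    .packed_align(x, y, w, b, mode, word_width)$score
}

#' Full per-row state of a bit-parallel alignment
#'
#' Like [align_score()] but retains, for every row, the vertical
#' difference vectors (input- and output-space) and the new horizontal
#' difference vectors, decoded per column.  Intended for verification and
#' illustration; the states are exactly the difference matrices of the
#' classical recurrence.
#'
#' @inheritParams align_score
#' @return List with `score`, `dv` (`m x n` integer matrix of vertical
#'   differences), `dh` (`m x n` horizontal differences, final row last)
#'   and `dv_in` (`m x (n+1)` vertical inputs including the leftmost
#'   initialization value).
#' @export
align_details <- function(x, y, weights, mode = align_mode(),
                          variant = c("standard", "packed"),
                          word_width = 64L) {
  variant <- match.arg(variant)
  w <- .as_weights(weights)
  b <- weight_bounds(w)
  res <- if (variant == "standard")
    .std_align(x, y, w, b, mode, word_width, keep_rows = TRUE)
  else
    .packed_align(x, y, w, b, mode, word_width, keep_rows = TRUE)
  n <- res$ctx$n
  m <- length(res$rows)
  dv <- matrix(0L, m, n)
  dhm <- matrix(0L, m, n)
  dvin <- matrix(0L, m, n + 1L)
  for (i in seq_len(m)) {
    ri <- res$rows[[i]]
    if (variant == "standard") {
      if (n > 0L) {
        dv[i, ] <- .decode_columns(ri$out, b$vmin, n)
        dhm[i, ] <- .decode_columns(ri$dh, b$vmin, n)
      }
      dvin[i, ] <- .decode_columns(ri$sraw, b$vmin, n + 1L)
    } else {
      if (n > 0L) {
        dv[i, ] <- ri$dv_cols
        dhm[i, ] <- ri$dh_cols
      }
      dvin[i, ] <- c(res$ctx$leftmost, dv[i, seq_len(n)])
    }
  }
  list(score = res$score, dv = dv, dh = dhm, dv_in = dvin)
}

#' First step of the standard engine: locate the maximal outputs
#'
#' The columns whose output vertical difference is `vmax` are matches
#' sitting on a horizontal `vmin`, extended through the remainder of each
#' run of `vmin` by one addition.  The result is returned already shifted
#' one position right, as input for the following steps.
#'
#' @param dh_min `bitvec` of columns whose previous-row horizontal
#'   difference is `vmin` (width may include one padding column).
#' @param matches `bitvec` of match columns, same width.
#' @return A `bitvec` of shifted `vmax` locations.
#' @examples
#' dh_min <- bitvec(8, 2:5)
#' step1_dvmax(dh_min, bitvec(8, 2))  # bits 3 4 5 6
#' @export
step1_dvmax <- function(dh_min, matches) {
  .bv_check2(dh_min, matches)
  t1 <- bv_and(matches, dh_min)
  s <- bv_add(dh_min, t1)$sum
  bv_xor(bv_xor(s, dh_min), t1)
}
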