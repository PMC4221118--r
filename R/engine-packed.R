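## Packed bit-parallel engine: instead of one vector per difference value,
## k = packed_width bit planes hold, per column, the binary digits of the
## value offsets.  Vertical offsets (dV - vmin) are non-negative; the
## horizontal mapping is onto non-positive numbers, e = vmin - dH in
## [-span, 0], stored two's-complement.  Adding the two packed sets
## per column gives dV_left - dH_above, which is exactly the output
## offset of the indel-from-left rule; negative sums are Zone D and are
## clamped to offset 0 (vmin).  Zone A still runs in the standard
## representation on a handful of unpacked horizontal vectors.

## two's-complement digits of z at width k, as a 0/1 integer vector
.twoc_digits <- function(z, k) {
  zz <- z %% (2L^k)
  bitwAnd(bitwShiftR(zz, 0:(k - 1L)), 1L)
}

## horizontal values Zone A consumes in unpacked form: vmin for the runs,
## plus every diagonal partner of Steps 2A/2B
.unpack_values <- function(w, b) {
  vals <- b$vmin
  if (b$vmax - 1L >= b$vmid + 1L) {
    lo <- b$vmin + 1L
    hi <- b$vmax + w$G - (b$vmid + 1L)
    if (hi >= lo) vals <- c(vals, lo:hi)
  }
  vals
}

.packed_ctx <- function(n, w, b, mode, word_width) {
  ctx <- .std_ctx(n, w, b, mode, word_width)
  k <- b$packed_width
  ctx$k <- k
  ctx$unpack_vals <- .unpack_values(w, b)
  ## per-value digit patterns used throughout
  ctx$off_digits <- sapply(b$vmin:b$vmax, function(v) .twoc_digits(v - b$vmin, k))
  ctx$e_digits <- sapply(b$vmin:b$vmax, function(v) .twoc_digits(b$vmin - v, k))
  if (is.null(dim(ctx$off_digits))) {
    ctx$off_digits <- matrix(ctx$off_digits, nrow = k)
    ctx$e_digits <- matrix(ctx$e_digits, nrow = k)
  }
  ctx$mid_off <- .twoc_digits(b$vmid - b$vmin, k)   # offset of vmid
  ctx$mid_e <- .twoc_digits(b$vmin - b$vmid, k)     # re-encoded low range
  ctx$max_e <- .twoc_digits(b$vmin - b$vmax, k)     # match columns
  ctx$c0 <- .twoc_digits(b$vmid - b$vmin, k)        # constant for the low test
  ctx$inject <- .twoc_digits(ctx$leftmost - b$vmin, k)
  ctx
}

## digit-serial ripple addition of two packed sets (per-column, no
## horizontal propagation, so it needs no chunk chaining)
.planes_add <- function(a, b, k) {
  s <- a
  carry <- integer(nrow(a))
  for (d in seq_len(k)) {
    ad <- a[, d]; bd <- b[, d]
    x <- bitwXor(ad, bd)
    s[, d] <- bitwXor(x, carry)
    carry <- bitwOr(bitwAnd(ad, bd), bitwAnd(carry, x))
  }
  s
}

## unpack one encoded horizontal value from the planes of a chunk
.unpack_one <- function(dhp_c, ndhp_c, digits, k) {
  acc <- if (digits[1L]) dhp_c[, 1L] else ndhp_c[, 1L]
  if (k > 1L) for (d in 2L:k)
    acc <- bitwAnd(acc, if (digits[d]) dhp_c[, d] else ndhp_c[, d])
  acc
}

## One row of the packed engine.  dhp: L x k planes encoding the previous
## row's horizontal differences.  Returns the new planes plus the packed
## vertical outputs (dvp) for inspection.
.packed_row <- function(dhp, match_lv, ctx) {
  L <- ctx$L; V <- ctx$V; k <- ctx$k
  b <- ctx$b
  dvp <- matrix(0L, L, k)
  dhpnew <- matrix(0L, L, k)
  ch <- .row_chain(ctx)
  pfill <- ctx$inject                     # plane shift fills, chunk 0
  for (idx in ctx$chunks) {
    Lc <- length(idx)
    dhp_c <- dhp[idx, , drop = FALSE]
    mt_c <- match_lv[idx]
    notm <- bitwXor(mt_c, .LIMB_MASK)
    pmask_c <- ctx$pmask[idx]
    nmask_c <- ctx$nmask[idx]

    ## unpack the horizontal vectors Zone A needs
    ndhp_c <- bitwXor(dhp_c, .LIMB_MASK)
    if (is.null(dim(ndhp_c))) ndhp_c <- matrix(ndhp_c, Lc, k)
    dh_c <- matrix(0L, Lc, V)
    for (v in ctx$unpack_vals) {
      vecd <- .unpack_one(dhp_c, ndhp_c, ctx$e_digits[, v - b$vmin + 1L], k)
      dh_c[, v - b$vmin + 1L] <- bitwAnd(vecd, nmask_c)
    }

    za <- .zoneA_chunk(dh_c, mt_c, pmask_c, Lc, ctx, ch)

    ## pack the effective vertical inputs: high values as computed,
    ## match columns already folded into vmax, everything else vmid
    rest <- bitwAnd(bitwXor(za$highun, .LIMB_MASK), pmask_c)
    vp <- matrix(0L, Lc, k)
    highs <- (ctx$vmid - ctx$vmin + 2L):V
    for (d in seq_len(k)) {
      acc <- integer(Lc)
      for (vi in highs)
        if (ctx$off_digits[d, vi]) acc <- bitwOr(acc, za$ein[, vi])
      if (ctx$mid_off[d]) acc <- bitwOr(acc, rest)
      vp[, d] <- acc
    }

    ## Steps 3 and 4 at once: add packed verticals to packed horizontals;
    ## a set sign digit means Zone D, clamped to offset 0 (vmin)
    s1 <- .planes_add(vp, dhp_c, k)
    notneg <- bitwXor(s1[, k], .LIMB_MASK)
    dvp_c <- matrix(0L, Lc, k)
    for (d in seq_len(k))
      dvp_c[, d] <- bitwAnd(bitwAnd(s1[, d], notneg), nmask_c)

    ## Step 5 preparation: re-encode horizontal [vmin, vmid] to vmid and
    ## force match columns to vmax
    cplanes <- matrix(0L, Lc, k)
    for (d in seq_len(k)) if (ctx$c0[d]) cplanes[, d] <- nmask_c
    s2 <- .planes_add(dhp_c, cplanes, k)
    pred <- bitwAnd(bitwXor(s2[, k], .LIMB_MASK), nmask_c)
    npred <- bitwXor(pred, .LIMB_MASK)
    dhd_c <- matrix(0L, Lc, k)
    for (d in seq_len(k)) {
      v <- bitwAnd(dhp_c[, d], npred)
      if (ctx$mid_e[d]) v <- bitwOr(v, pred)
      v <- bitwAnd(v, notm)
      if (ctx$max_e[d]) v <- bitwOr(v, mt_c)
      dhd_c[, d] <- v
    }

    ## Step 5: shift the vertical outputs into input position and add
    tin_c <- matrix(0L, Lc, k)
    for (d in seq_len(k)) {
      sh <- .lv_shift_up(dvp_c[, d], pfill[d]); pfill[d] <- sh$evicted
      tin_c[, d] <- bitwAnd(sh$result, pmask_c)
    }
    s3 <- .planes_add(tin_c, dhd_c, k)
    nz <- .lv_or_fold(as.vector(s3), Lc)
    pos <- bitwAnd(bitwXor(s3[, k], .LIMB_MASK), nz)
    npos <- bitwXor(pos, .LIMB_MASK)
    dn_c <- matrix(0L, Lc, k)
    for (d in seq_len(k))
      dn_c[, d] <- bitwAnd(bitwAnd(s3[, d], npos), nmask_c)

    dvp[idx, ] <- dvp_c
    dhpnew[idx, ] <- dn_c
  }
  list(dvp = dvp, dhpnew = dhpnew)
}

## S[i, n] - S[i, 0] from packed horizontal planes: dH_j = vmin - e_j with
## e_j the two's-complement value of column j's digits
.decode_dhp_sum <- function(planes, vmin, n, k) {
  esum <- 0
  for (d in seq_len(k)) {
    wgt <- if (d == k) -(2^(k - 1L)) else 2^(d - 1L)
    esum <- esum + wgt * .lv_popcount(planes[, d])
  }
  as.integer(n * vmin - esum)
}

## per-column horizontal values from packed planes
.decode_dhp_columns <- function(planes, vmin, n, k) {
  e <- integer(n)
  for (d in seq_len(k)) {
    wgt <- if (d == k) -bitwShiftL(1L, k - 1L) else bitwShiftL(1L, d - 1L)
    bits <- .lv_bits(planes[, d])
    bits <- bits[bits < n]
    if (length(bits)) e[bits + 1L] <- e[bits + 1L] + wgt
  }
  as.integer(vmin - e)
}

## per-column vertical values (non-negative offsets)
.decode_dvp_columns <- function(planes, vmin, n, k) {
  o <- integer(n)
  for (d in seq_len(k)) {
    bits <- .lv_bits(planes[, d])
    bits <- bits[bits < n]
    if (length(bits)) o[bits + 1L] <- o[bits + 1L] + bitwShiftL(1L, d - 1L)
  }
  as.integer(vmin + o)
}

.init_dhp <- function(ctx, mode) {
  planes <- matrix(0L, ctx$L, ctx$k)
  h0 <- if (mode$first_row == "gap") ctx$w$G else 0L
  dig <- .twoc_digits(ctx$b$vmin - h0, ctx$k)
  for (d in seq_len(ctx$k)) if (dig[d]) planes[, d] <- ctx$nmask
  planes
}

.packed_align <- function(x, y, w, b, mode, word_width = 64L,
                          keep_rows = FALSE) {
  xc <- .chars(x); yc <- .chars(y)
  n <- length(xc); m <- length(yc)
  ctx <- .packed_ctx(n, w, b, mode, word_width)
  mm <- .match_limb_matrix(xc, unique(xc), ctx$L)
  zero_match <- integer(ctx$L)
  dhp <- .init_dhp(ctx, mode)
  rows <- if (keep_rows) vector("list", m) else NULL
  best_col <- .col0_score(0L, w, mode) +
    .decode_dhp_sum(dhp, b$vmin, n, ctx$k)
  for (i in seq_len(m)) {
    ml <- if (yc[i] %in% colnames(mm)) mm[, yc[i]] else zero_match
    st <- .packed_row(dhp, ml, ctx)
    dhp <- st$dhpnew
    if (keep_rows) rows[[i]] <- list(dvp = st$dvp, dhp = dhp)
    if (mode$score_site == "last_col") {
      s <- .col0_score(i, w, mode) + .decode_dhp_sum(dhp, b$vmin, n, ctx$k)
      if (s > best_col) best_col <- s
    }
  }
  base <- .col0_score(m, w, mode)
  score <- switch(mode$score_site,
    last_cell = base + .decode_dhp_sum(dhp, b$vmin, n, ctx$k),
    last_row = {
      colv <- .decode_dhp_columns(dhp, b$vmin, n, ctx$k)
      base + (if (n > 0L) max(0L, max(cumsum(colv))) else 0L)
    },
    last_col = best_col)
  if (keep_rows) {
    for (i in seq_len(m)) {
      rows[[i]]$out <- NULL
      rows[[i]]$dv_cols <- .decode_dvp_columns(rows[[i]]$dvp, b$vmin, n, ctx$k)
      rows[[i]]$dh_cols <- .decode_dhp_columns(rows[[i]]$dhp, b$vmin, n, ctx$k)
    }
  }
  list(score = as.integer(score), final_dhp = dhp, rows = rows, ctx = ctx)
}
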