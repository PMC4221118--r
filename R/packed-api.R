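## Public surface of the packed representation, in terms of bitvec
## values.  The engines use the same arithmetic on raw limb matrices;
## these functions are the specification of that arithmetic and are
## cross-checked against the engines in the tests.

.planes_of <- function(planes) {
  stopifnot(length(planes) >= 1L)
  w <- planes[[1L]]$width
  for (p in planes) stopifnot(inherits(p, "bitvec"), p$width == w)
  w
}

#' Pack value-indexed vertical vectors into binary-digit planes
#'
#' Maps the vertical difference values `vmin..vmax` one-to-one onto the
#' non-negative offsets `0..span` and stores, per column, the binary
#' digits of the offset across `packed_width` bit planes.  Following the
#' packed engine's convention, columns not covered by `dv` are encoded as
#' `vmid` and match columns as `vmax`.
#'
#' @param dv Named list of [bitvec()] (names are difference values, e.g.
#'   `"-5"`); vectors must be pairwise disjoint.
#' @param bounds A [weight_bounds()] object.
#' @param matches Optional `bitvec` of match columns.
#' @return List of `packed_width` bitvec planes (low digit first).
#' @export
pack_dv <- function(dv, bounds, matches = NULL) {
  stopifnot(inherits(bounds, "align_bounds"), length(dv) >= 1L)
  wdt <- .planes_of(dv)
  k <- bounds$packed_width
  vals <- as.integer(names(dv))
  stopifnot(!anyNA(vals), all(vals >= bounds$vmin), all(vals <= bounds$vmax))
  ## disjointness
  un <- bitvec(wdt)
  for (v in dv) {
    if (bv_popcount(bv_and(un, v)) > 0L)
      stop("dv vectors are not disjoint: not a partition")
    un <- bv_or(un, v)
  }
  rest <- bv_not(un)
  eff <- stats::setNames(vector("list", bounds$value_count),
                         as.character(bounds$vmin:bounds$vmax))
  for (i in seq_along(dv)) {
    v <- as.character(vals[i])
    vec <- if (!is.null(matches)) bv_and(dv[[i]], bv_not(matches)) else dv[[i]]
    eff[[v]] <- if (is.null(eff[[v]])) vec else bv_or(eff[[v]], vec)
  }
  midc <- as.character(bounds$vmid)
  eff[[midc]] <- if (is.null(eff[[midc]])) rest else bv_or(eff[[midc]], rest)
  if (!is.null(matches)) {
    maxc <- as.character(bounds$vmax)
    eff[[maxc]] <- if (is.null(eff[[maxc]])) matches else
      bv_or(eff[[maxc]], matches)
  }
  planes <- vector("list", k)
  for (d in seq_len(k)) {
    acc <- bitvec(wdt)
    for (v in names(eff)) {
      if (is.null(eff[[v]])) next
      off <- as.integer(v) - bounds$vmin
      if (bitwAnd(bitwShiftR(off, d - 1L), 1L) == 1L)
        acc <- bv_or(acc, eff[[v]])
    }
    planes[[d]] <- acc
  }
  names(planes) <- paste0("p", 0:(k - 1L))
  planes
}

#' Unpack horizontal difference vectors from binary-digit planes
#'
#' The horizontal mapping stores, per column, the two's-complement digits
#' of `vmin - dH` (a value in `[-span, 0]`).  For each requested value
#' the conjunction of the matching plane literals recovers the vector of
#' columns carrying it.  Columns whose digits are all zero decode to
#' `vmin`.
#'
#' @param planes List of `packed_width` bitvec planes (low digit first).
#' @param bounds A [weight_bounds()] object.
#' @param values Integer vector of difference values to unpack (defaults
#'   to all of them).
#' @return Named list of bitvec, one per requested value.
#' @export
unpack_dh <- function(planes, bounds, values = bounds$vmin:bounds$vmax) {
  stopifnot(inherits(bounds, "align_bounds"))
  k <- bounds$packed_width
  stopifnot(length(planes) == k)
  .planes_of(planes)
  nplanes <- lapply(planes, bv_not)
  out <- lapply(values, function(v) {
    stopifnot(v >= bounds$vmin, v <= bounds$vmax)
    dig <- .twoc_digits(bounds$vmin - v, k)
    acc <- if (dig[1L]) planes[[1L]] else nplanes[[1L]]
    for (d in seq_len(k)[-1L])
      acc <- bv_and(acc, if (dig[d]) planes[[d]] else nplanes[[d]])
    acc
  })
  names(out) <- as.character(values)
  out
}

#' Simultaneous per-column addition of two packed sets
#'
#' Adds, per column, a non-negative vertical offset to a non-positive
#' two's-complement horizontal offset using a digit-serial ripple of
#' AND/OR/XOR over the planes.  The result digits encode
#' `dV_left - dH_above`; the high plane is the sign.
#'
#' @param dv_planes,dh_planes Lists of `k` bitvec planes.
#' @return List with `planes` (sum digits) and `sign` (the high plane).
#' @export
packed_add <- function(dv_planes, dh_planes) {
  k <- length(dv_planes)
  stopifnot(length(dh_planes) == k)
  .planes_of(c(dv_planes, dh_planes))
  wdt <- dv_planes[[1L]]$width
  s <- vector("list", k)
  carry <- bitvec(wdt)
  for (d in seq_len(k)) {
    a <- dv_planes[[d]]; b <- dh_planes[[d]]
    x <- bv_xor(a, b)
    s[[d]] <- bv_xor(x, carry)
    carry <- bv_or(bv_and(a, b), bv_and(carry, x))
  }
  names(s) <- paste0("p", 0:(k - 1L))
  list(planes = s, sign = s[[k]])
}

#' Clamp negative packed sums to the minimum value (Zone D)
#'
#' Columns whose sign bit is set hold a negative difference that can
#' never be an output; they are rewritten to offset 0, i.e. `vmin`.
#'
#' @param sum_planes List of sum planes from [packed_add()].
#' @param sign The sign plane.
#' @return List of clamped planes.
#' @export
clamp_negative_to_min <- function(sum_planes, sign) {
  keep <- bv_not(sign)
  out <- lapply(sum_planes, bv_and, b = keep)
  names(out) <- names(sum_planes)
  out
}

#' Re-encode the low horizontal range to the mismatch boundary
#'
#' Every horizontal input in `[vmin, vmid]` produces the same outputs, so
#' before the second packed addition the whole range is collapsed to
#' `vmid`.  Columns are tested by adding the constant `vmid - vmin` and
#' reading the sign; non-negative columns are rewritten.
#'
#' @param dh_planes List of `k` horizontal planes.
#' @param bounds A [weight_bounds()] object.
#' @return List of re-encoded planes.
#' @export
reencode_low_to_mid <- function(dh_planes, bounds) {
  k <- bounds$packed_width
  stopifnot(length(dh_planes) == k)
  wdt <- .planes_of(dh_planes)
  ones <- bv_not(bitvec(wdt))
  zero <- bitvec(wdt)
  c0 <- .twoc_digits(bounds$vmid - bounds$vmin, k)
  cpl <- lapply(seq_len(k), function(d) if (c0[d]) ones else zero)
  s <- packed_add(dh_planes, cpl)
  pred <- bv_not(s$sign)
  npred <- s$sign
  mid_e <- .twoc_digits(bounds$vmin - bounds$vmid, k)
  out <- lapply(seq_len(k), function(d) {
    v <- bv_and(dh_planes[[d]], npred)
    if (mid_e[d]) v <- bv_or(v, pred) else v
  })
  names(out) <- names(dh_planes)
  out
}

#' Decode the final-row score from standard value vectors
#'
#' The score of the last cell equals the score of the zero column plus
#' the popcount-weighted sum of the final row's horizontal vectors:
#' `S[m, n] = m*G + sum_v v * popcount(dh_v)` under a gapped first
#' column (`0` replaces `m*G` when the first column is free).
#'
#' @param dh Named list of bitvec keyed by difference value.
#' @param m Number of rows (length of the vertical sequence).
#' @param weights An [alignment_weights()] object.
#' @param first_column `"gap"` or `"free"`.
#' @return Integer score.
#' @export
decode_last_row <- function(dh, m, weights,
                            first_column = c("gap", "free")) {
  first_column <- match.arg(first_column)
  w <- .as_weights(weights)
  vals <- as.integer(names(dh))
  stopifnot(!anyNA(vals))
  base <- if (first_column == "gap") m * w$G else 0L
  as.integer(base + sum(vals * vapply(dh, bv_popcount, 0L)))
}

#' Decode the final-row score from packed planes
#'
#' Same as [decode_last_row()] but for the packed representation: the
#' horizontal planes encode the non-positive offsets `vmin - dH` in
#' two's complement, so the digit-weighted popcount sum (high plane
#' negative) gives `sum(vmin - dH)` and the score follows as
#' `m*G + n*vmin - sum`.
#'
#' @param planes List of `k` bitvec planes of the final row.
#' @param m,n Sequence lengths (rows, columns).
#' @param bounds A [weight_bounds()] object.
#' @param weights An [alignment_weights()] object.
#' @inheritParams decode_last_row
#' @return Integer score.
#' @export
decode_last_row_packed <- function(planes, m, n, bounds, weights,
                                   first_column = c("gap", "free")) {
  first_column <- match.arg(first_column)
  w <- .as_weights(weights)
  k <- bounds$packed_width
  stopifnot(length(planes) == k)
  base <- if (first_column == "gap") m * w$G else 0L
  pm <- do.call(cbind, lapply(planes, function(p) p$limbs))
  as.integer(base + .decode_dhp_sum(pm, bounds$vmin, n, k))
}
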