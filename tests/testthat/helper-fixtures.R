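## Shared helpers for the suite.  Everything is generated in code; the
## only fixed constants are five benchmark weight sets spanning small to
## large function tables, plus the mismatch-equals-two-gaps boundary set.

benchmark_weights <- list(c(0L, -1L, -1L), c(2L, -3L, -5L), c(3L, -4L, -6L),
                       c(4L, -5L, -9L), c(4L, -7L, -11L))
boundary_weights <- c(1L, -2L, -1L)    # I == 2G
DNA <- c("A", "C", "G", "T")

rand_seq <- function(len, alphabet = DNA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

all_modes <- list(
  align_mode("gap", "gap"), align_mode("free", "gap"),
  align_mode("gap", "free"), align_mode("free", "free"))

## independent cell oracle: realize the three candidates on a 2x2 score
## patch anchored at S[i-1, j-1] = 0 and take the best
patch_cell <- function(dv_left, dh_above, is_match, M, I, G) {
  s <- max(if (is_match) M else I, dh_above + G, dv_left + G)
  c(dv_out = s - dh_above, dh_out = s - dv_left)
}

## decoded per-column horizontal values -> named bitvec list
dh_bitvecs <- function(vals, bounds) {
  n <- length(vals)
  out <- lapply(bounds$vmin:bounds$vmax, function(v)
    bitvec(n, which(vals == v) - 1L))
  names(out) <- as.character(bounds$vmin:bounds$vmax)
  out
}

## per-column horizontal values -> packed two's-complement planes
dh_planes <- function(vals, bounds) {
  k <- bounds$packed_width
  n <- length(vals)
  e <- (bounds$vmin - vals) %% (2^k)
  lapply(seq_len(k), function(d)
    bitvec(n, which(bitwAnd(bitwShiftR(e, d - 1L), 1L) == 1L) - 1L))
}

expect_partition <- function(vecs, width) {
  un <- bitvec(width)
  for (v in vecs) {
    expect_equal(bv_popcount(bv_and(un, v)), 0L)
    un <- bv_or(un, v)
  }
  expect_equal(bv_popcount(un), width)
}

## Drive a whole alignment through the interpreted program, row by row,
## and return the per-row horizontal states (decoded) plus the score.
prog_matrix_run <- function(x, y, w, mode, variant) {
  b <- weight_bounds(w)
  prog <- generate_program(w, variant, mode)
  n <- nchar(x); m <- nchar(y)
  pw <- n + 1L
  mv <- match_vectors(x, unique(strsplit(x, "")[[1]]))
  widen <- function(v) bitvec(pw, bv_bits(v))
  consts <- list(m_cols = bitvec(pw, seq_len(n) - 1L),
                 c_bit0 = bitvec(pw, 0L))
  h0 <- if (mode$first_row == "gap") w$G else 0L
  yc <- strsplit(y, "")[[1]]
  dh_rows <- vector("list", m)
  if (variant == "standard") {
    dh <- setNames(rep(list(bitvec(pw)), b$value_count),
                   paste0("dh_", b$vmin:b$vmax))
    dh[[paste0("dh_", h0)]] <- consts$m_cols
    for (i in seq_len(m)) {
      mt <- if (yc[i] %in% names(mv)) widen(mv[[yc[i]]]) else bitvec(pw)
      out <- run_program(prog, c(dh, list(match = mt), consts))
      dh <- setNames(out[paste0("dhnew_", b$vmin:b$vmax)],
                     paste0("dh_", b$vmin:b$vmax))
      vals <- integer(n)
      for (v in b$vmin:b$vmax)
        vals[bv_bits(dh[[paste0("dh_", v)]]) + 1L] <- v
      dh_rows[[i]] <- as.integer(vals)
    }
    base <- if (mode$first_column == "gap") m * w$G else 0L
    list(score = as.integer(base + sum(b$vmin:b$vmax *
           vapply(dh, bv_popcount, 0L))), dh_rows = dh_rows)
  } else {
    k <- b$packed_width
    e0 <- (b$vmin - h0) %% (2^k)
    dhp <- setNames(lapply(seq_len(k), function(d)
      if (bitwAnd(bitwShiftR(e0, d - 1L), 1L)) consts$m_cols else bitvec(pw)),
      paste0("dhp_", 0:(k - 1L)))
    for (i in seq_len(m)) {
      mt <- if (yc[i] %in% names(mv)) widen(mv[[yc[i]]]) else bitvec(pw)
      out <- run_program(prog, c(dhp, list(match = mt), consts))
      dhp <- setNames(out[paste0("dhpnew_", 0:(k - 1L))],
                      paste0("dhp_", 0:(k - 1L)))
      e <- integer(n)
      for (d in seq_len(k)) {
        wgt <- if (d == k) -2L^(k - 1L) else 2L^(d - 1L)
        bt <- bv_bits(dhp[[d]]); bt <- bt[bt < n]
        e[bt + 1L] <- e[bt + 1L] + wgt
      }
      dh_rows[[i]] <- as.integer(b$vmin - e)
    }
    base <- if (mode$first_column == "gap") m * w$G else 0L
    list(score = as.integer(base + sum(dh_rows[[m]])), dh_rows = dh_rows)
  }
}

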