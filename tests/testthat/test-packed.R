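test_that("pack and unpack are mutually inverse on random partitions", {
  set.seed(31)
  b <- weight_bounds(alignment_weights(2, -3, -5))
  for (rep in 1:40) {
    n <- sample(1:40, 1)
    vals <- sample(b$vmin:b$vmax, n, replace = TRUE)
    dv <- dh_bitvecs(vals, b)            # value-indexed partition
    planes <- pack_dv(dv, b)
    expect_length(planes, b$packed_width)
    ## decode every column back: offsets are the binary digits
    got <- integer(n)
    for (d in seq_along(planes))
      got[bv_bits(planes[[d]]) + 1L] <-
        got[bv_bits(planes[[d]]) + 1L] + 2L^(d - 1L)
    expect_equal(b$vmin + got, vals)
  }
})

test_that("packing encodes the documented worked example", {
  b <- weight_bounds(alignment_weights(2, -3, -5))
  ## dV = 5 at column 3 -> offset 10 = 01010 in binary: planes p1, p3
  dv <- list("5" = bitvec(6, 3))
  ## everything else packs as vmid (offset 7 = 11100... i.e. bits 0,1,2)
  planes <- pack_dv(dv, b)
  expect_true(3L %in% bv_bits(planes$p1))
  expect_true(3L %in% bv_bits(planes$p3))
  expect_false(3L %in% bv_bits(planes$p0))
  expect_false(3L %in% bv_bits(planes$p2))
  expect_false(3L %in% bv_bits(planes$p4))
  ## all columns at vmin -> offset zero -> all planes empty
  allmin <- pack_dv(list("-5" = bv_not(bitvec(4))), b)
  expect_true(all(vapply(allmin, bv_popcount, 0L) == 0L))
  expect_error(pack_dv(list("3" = bitvec(4, 1), "4" = bitvec(4, 1)), b),
               "partition")
})

test_that("unpacking identifies encoded horizontal values", {
  w <- alignment_weights(2, -3, -5)
  b <- weight_bounds(w)
  ## a column whose five planes read 11111 is two's-complement -1,
  ## i.e. dH = vmin + 1 = -4
  planes <- lapply(1:5, function(d) bitvec(3, 1))
  got <- unpack_dh(planes, b, values = -4L)
  expect_equal(bv_bits(got[["-4"]]), 1L)
  ## all planes zero decodes to vmin everywhere
  zero <- lapply(1:5, function(d) bitvec(3))
  expect_equal(bv_bits(unpack_dh(zero, b, values = b$vmin)[["-5"]]), 0:2)
  ## requested-value vectors are disjoint
  set.seed(32)
  vals <- sample(b$vmin:b$vmax, 20, replace = TRUE)
  pl <- dh_planes(vals, b)
  un <- unpack_dh(pl, b)
  expect_partition(un, 20L)
  for (v in names(un))
    expect_equal(bv_bits(un[[v]]), which(vals == as.integer(v)) - 1L)
})

test_that("packed addition realizes dV - dH exactly, exhaustively", {
  for (wt in list(c(2, -3, -5), c(1, -2, -1))) {
    w <- alignment_weights(wt[1], wt[2], wt[3])
    b <- weight_bounds(w)
    k <- b$packed_width
    grid <- expand.grid(v = b$vmin:b$vmax, h = b$vmin:b$vmax)
    n <- nrow(grid)
    voff <- grid$v - b$vmin
    eh <- (b$vmin - grid$h) %% (2^k)
    mk <- function(vals) lapply(seq_len(k), function(d)
      bitvec(n, which(bitwAnd(bitwShiftR(vals, d - 1L), 1L) == 1L) - 1L))
    r <- packed_add(mk(voff), mk(eh))
    dec <- integer(n)
    for (d in seq_len(k)) {
      wgt <- if (d == k) -2L^(k - 1L) else 2L^(d - 1L)
      dec[bv_bits(r$planes[[d]]) + 1L] <- dec[bv_bits(r$planes[[d]]) + 1L] + wgt
    }
    expect_equal(dec, grid$v - grid$h)
    expect_equal(bv_bits(r$sign), which(grid$v < grid$h) - 1L)
  }
})

test_that("negative sums clamp to vmin and positives survive", {
  b <- weight_bounds(alignment_weights(2, -3, -5))
  k <- b$packed_width
  sums <- c(-3L, 0L, 5L, -12L, 12L)
  enc <- sums %% (2^k)
  planes <- lapply(seq_len(k), function(d)
    bitvec(5, which(bitwAnd(bitwShiftR(enc, d - 1L), 1L) == 1L) - 1L))
  cl <- clamp_negative_to_min(planes, planes[[k]])
  dec <- integer(5)
  for (d in seq_len(k))
    dec[bv_bits(cl[[d]]) + 1L] <- dec[bv_bits(cl[[d]]) + 1L] + 2L^(d - 1L)
  expect_equal(dec, c(0L, 0L, 5L, 0L, 12L))
  ## no negative columns: identity
  pos <- lapply(seq_len(k), function(d) bitvec(3, if (d == 1) 0:2 else integer()))
  expect_identical(clamp_negative_to_min(pos, bitvec(3)), pos)
})

test_that("the low horizontal range re-encodes to vmid", {
  w <- alignment_weights(2, -3, -5)
  b <- weight_bounds(w)
  vals <- c(-5L, -4L, 0L, 2L, 3L, 7L)   # low ones collapse, high survive
  out <- reencode_low_to_mid(dh_planes(vals, b), b)
  k <- b$packed_width
  dec <- integer(length(vals))
  for (d in seq_len(k)) {
    wgt <- if (d == k) -2L^(k - 1L) else 2L^(d - 1L)
    dec[bv_bits(out[[d]]) + 1L] <- dec[bv_bits(out[[d]]) + 1L] + wgt
  }
  expect_equal(b$vmin - dec, c(2L, 2L, 2L, 2L, 3L, 7L))
})

test_that("packed engine equals the standard engine and the oracle", {
  set.seed(33)
  wsets <- c(benchmark_weights, list(boundary_weights))
  for (rep in 1:60) {
    wt <- wsets[[((rep - 1L) %% length(wsets)) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
    ww <- c(8L, 64L)[(rep %% 2L) + 1L]
    x <- rand_seq(sample(0:40, 1)); y <- rand_seq(sample(0:40, 1))
    s <- nw_score(x, y, w, md)$score
    expect_identical(align_score(x, y, w, md, "packed", ww), s)
    expect_identical(align_score(x, y, w, md, "standard", ww), s)
  }
})

test_that("packed per-row states decode to the standard states", {
  set.seed(34)
  for (rep in 1:15) {
    wt <- benchmark_weights[[((rep - 1L) %% 5L) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
    x <- rand_seq(sample(1:30, 1)); y <- rand_seq(sample(1:30, 1))
    ds <- align_details(x, y, w, md, "standard")
    dp <- align_details(x, y, w, md, "packed")
    expect_identical(dp$dv, ds$dv)
    expect_identical(dp$dh, ds$dh)
  }
})

test_that("both decode formulas reproduce the last-cell score", {
  set.seed(35)
  for (rep in 1:20) {
    wt <- benchmark_weights[[((rep - 1L) %% 5L) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    b <- weight_bounds(w)
    x <- rand_seq(sample(1:40, 1)); y <- rand_seq(sample(1:40, 1))
    m <- nchar(y); n <- nchar(x)
    s <- nw_score(x, y, w)$score
    lastdh <- align_details(x, y, w)$dh[m, ]
    expect_equal(decode_last_row(dh_bitvecs(lastdh, b), m, w), s)
    expect_equal(decode_last_row_packed(dh_planes(lastdh, b), m, n, b, w), s)
    ## n = 0 degenerates to the column initialization alone
    expect_equal(decode_last_row(dh_bitvecs(integer(0), b), m, w), m * w$G)
  }
})
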