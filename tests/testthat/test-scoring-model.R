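test_that("weight validation enforces the scoring constraints", {
  expect_s3_class(alignment_weights(2, -3, -5), "align_weights")
  expect_s3_class(alignment_weights(0, -1, -1), "align_weights")
  expect_s3_class(alignment_weights(1, -2, -1), "align_weights")  # I == 2G
  expect_s3_class(alignment_weights(0, -3, -2), "align_weights")  # M == 0
  expect_error(alignment_weights(1, -3, -1), "I >= 2G")
  expect_error(alignment_weights(-1, -1, -1), "M >= 0")
  expect_error(alignment_weights(2, 0, -1), "I < 0")
  expect_error(alignment_weights(2, -1, 0), "G < 0")
  expect_error(alignment_weights(2.5, -1, -1), "integer")
})

test_that("derived bounds match direct substitution", {
  b <- weight_bounds(alignment_weights(2, -3, -5))
  expect_equal(b$vmin, -5L)
  expect_equal(b$vmid, 2L)
  expect_equal(b$vmax, 7L)
  expect_equal(b$value_count, 13L)
  expect_equal(b$span, 12L)
  expect_equal(b$packed_width, 5L)

  b2 <- weight_bounds(alignment_weights(0, -1, -1))
  expect_equal(unlist(b2[c("vmin", "vmid", "vmax", "value_count",
                           "packed_width")]),
               c(vmin = -1L, vmid = 0L, vmax = 1L, value_count = 3L,
                 packed_width = 3L))

  b3 <- weight_bounds(alignment_weights(4, -7, -11))
  expect_equal(unlist(b3[c("vmin", "vmid", "vmax", "value_count",
                           "packed_width")]),
               c(vmin = -11L, vmid = 4L, vmax = 15L, value_count = 27L,
                 packed_width = 6L))
  ## the packed width always accommodates both signs of the sum
  expect_gte(2^b3$packed_width, 2L * b3$span + 1L)
})

test_that("the function table equals the 2x2 patch oracle everywhere", {
  set.seed(101)
  for (wt in list(c(2, -3, -5), c(0, -1, -1), c(1, -2, -1), c(4, -7, -11))) {
    w <- alignment_weights(wt[1], wt[2], wt[3])
    b <- weight_bounds(w)
    tab <- delta_v_table(w)
    vals <- b$vmin:b$vmax
    for (rep in 1:500) {
      dv <- sample(vals, 1L); dh <- sample(vals, 1L)
      m <- sample(c(TRUE, FALSE), 1L)
      expect_identical(table_lookup(tab, dv, dh, m),
                       unname(patch_cell(dv, dh, m, w$M, w$I, w$G)["dv_out"]))
    }
    ## output range and match row
    expect_true(all(tab$out_nomatch >= b$vmin & tab$out_nomatch <= b$vmax))
    expect_true(all(tab$out_match >= b$vmin & tab$out_match <= b$vmax))
    for (dh in vals)
      expect_equal(table_lookup(tab, vals, rep(dh, length(vals)), TRUE),
                   rep(w$M - dh, length(vals)))
  }
})

test_that("the vmin column is an identity on high inputs and vmid below", {
  for (wt in list(c(2, -3, -5), c(3, -4, -6), c(1, -2, -1))) {
    w <- alignment_weights(wt[1], wt[2], wt[3])
    b <- weight_bounds(w)
    tab <- delta_v_table(w)
    for (dv in b$vmid:b$vmax)
      expect_equal(table_lookup(tab, dv, b$vmin, FALSE), dv)
    if (b$vmid > b$vmin)
      for (dv in b$vmin:(b$vmid - 1L))
        expect_equal(table_lookup(tab, dv, b$vmin, FALSE), b$vmid)
  }
})

test_that("Zone D totality: high horizontal inputs force vmin", {
  w <- alignment_weights(2, -3, -5)
  b <- weight_bounds(w)
  tab <- delta_v_table(w)
  expect_equal(table_lookup(tab, b$vmin, b$vmid, FALSE), b$vmin)
  ## wherever both inputs exceed the zone thresholds the output is vmin
  for (dv in b$vmin:b$vmax) for (dh in b$vmin:b$vmax) {
    if (dh > b$vmid && dh > dv)
      expect_equal(table_lookup(tab, dv, dh, FALSE), b$vmin)
  }
  ## worked entry: left 5, above -4 -> 4, a high output via the left value
  expect_equal(table_lookup(tab, 5, -4, FALSE), 4L)
  expect_equal(table_lookup(tab, 5, -4, FALSE, "zone"), "A")
})

test_that("zone labels partition the table and borders tie numerically", {
  w <- alignment_weights(2, -3, -5)
  b <- weight_bounds(w)
  tab <- delta_v_table(w)
  expect_true(all(tab$zone_nomatch %in% c("A", "B", "C", "D", "border")))
  ## on borders every achieving candidate yields the same output value
  idx <- which(tab$zone_nomatch == "border", arr.ind = TRUE)
  expect_gt(nrow(idx), 0L)
  for (r in seq_len(nrow(idx))) {
    dv <- b$vmin + idx[r, 1L] - 1L
    dh <- b$vmin + idx[r, 2L] - 1L
    cands <- c(w$I, dh + w$G, dv + w$G)
    mx <- max(cands)
    expect_equal(table_lookup(tab, dv, dh, FALSE), mx - dh)
  }
})

test_that("transposition swaps the input roles and is an involution", {
  w <- alignment_weights(2, -3, -5)
  tab <- delta_v_table(w)
  tt <- transpose_table(tab)
  expect_equal(tt$role, "dh")
  expect_identical(transpose_table(tt)$out_nomatch, tab$out_nomatch)
  expect_equal(table_lookup(tt, -4, 5, FALSE), table_lookup(tab, 5, -4, FALSE))
  for (v in c(-5, 0, 7))
    expect_equal(table_lookup(tt, v, v, FALSE), table_lookup(tab, v, v, FALSE))
})

test_that("standard table-size estimate evaluates and grows with M", {
  expect_equal(standard_table_size(alignment_weights(2, -3, -5)), 60)
  expect_equal(standard_table_size(alignment_weights(0, -1, -1)), 4)
  sizes <- sapply(0:5, function(M)
    standard_table_size(alignment_weights(M, -3, -5)))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the TSV dump reproduces the table", {
  tab <- delta_v_table(alignment_weights(2, -3, -5))
  f <- tempfile(fileext = ".tsv")
  write_table_tsv(tab, f)
  df <- read.delim(f, check.names = FALSE)
  expect_equal(dim(df), c(13L, 14L))
  expect_equal(as.integer(df[["-5"]]), unname(tab$out_nomatch[, "-5"]))
  unlink(f)
})
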