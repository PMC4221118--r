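test_that("alignment scores match forced cases", {
  w <- alignment_weights(2, -3, -5)
  expect_equal(align_score("ACGT", "ACGT", w), 8L)
  expect_equal(align_score("ACGT", "", w), -20L)
  expect_equal(align_score("", "ACG", w), -15L)
  expect_equal(align_score("", "", w), 0L)
  expect_equal(align_score("AC", "AG", alignment_weights(0, -1, -1)), -1L)
  ## self-alignment of length L scores L * M
  expect_equal(align_score("GATTACA", "GATTACA", w), 14L)
})

test_that("finding the maximal outputs: matches on vmin runs, carried", {
  ## run of dh = vmin over columns 2..5 with a match at 2: the shifted
  ## result covers 3..6
  expect_equal(bv_bits(step1_dvmax(bitvec(8, 2:5), bitvec(8, 2))),
               3:6)
  ## no matches, no source of vmax
  expect_equal(bv_popcount(step1_dvmax(bitvec(8, 2:5), bitvec(8))), 0L)
  ## two matches in one run give the same result as one
  expect_equal(bv_bits(step1_dvmax(bitvec(8, 2:5), bitvec(8, c(2, 4)))),
               3:6)
  ## a match outside any vmin run contributes nothing
  expect_equal(bv_popcount(step1_dvmax(bitvec(8, 2:5), bitvec(8, 0))), 0L)
})

test_that("engine equals the DP oracle across weights, modes and widths", {
  set.seed(21)
  wsets <- c(benchmark_weights, list(boundary_weights))
  for (rep in 1:80) {
    wt <- wsets[[((rep - 1L) %% length(wsets)) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
    ww <- c(8L, 64L)[(rep %% 2L) + 1L]
    x <- rand_seq(sample(0:40, 1)); y <- rand_seq(sample(0:40, 1))
    expect_identical(align_score(x, y, w, md, "standard", ww),
                     nw_score(x, y, w, md)$score)
  }
})

test_that("score sites: best in last row / last column", {
  set.seed(22)
  w <- alignment_weights(2, -3, -5)
  for (site in c("last_row", "last_col")) {
    for (fr in c("gap", "free")) {
      md <- align_mode(fr, "gap", site)
      for (rep in 1:10) {
        x <- rand_seq(sample(1:30, 1)); y <- rand_seq(sample(1:30, 1))
        expect_identical(align_score(x, y, w, md), nw_score(x, y, w, md)$score)
      }
    }
  }
})

test_that("per-row decoded states equal the oracle difference matrices", {
  set.seed(23)
  for (rep in 1:25) {
    wt <- benchmark_weights[[((rep - 1L) %% 5L) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
    x <- rand_seq(sample(1:30, 1)); y <- rand_seq(sample(1:30, 1))
    dm <- delta_matrices(nw_score(x, y, w, md)$S)
    d <- align_details(x, y, w, md, "standard")
    expect_identical(unname(d$dv), unname(dm$dv[, -1L, drop = FALSE]))
    expect_identical(unname(d$dh), unname(dm$dh[-1L, , drop = FALSE]))
    ## the leftmost vertical input is the initialization value
    expect_identical(unname(d$dv_in[, 1L]), unname(dm$dv[, 1L]))
    ## bound invariant: only values in [G, M - G] ever occur
    expect_true(all(d$dv >= w$G & d$dv <= w$M - w$G))
    expect_true(all(d$dh >= w$G & d$dh <= w$M - w$G))
  }
})

test_that("unit-cost engine equals the negated edit distance", {
  set.seed(24)
  w <- alignment_weights(0, -1, -1)
  for (rep in 1:30) {
    x <- rand_seq(sample(0:60, 1)); y <- rand_seq(sample(0:60, 1))
    expect_equal(align_score(x, y, w), -as.integer(adist(x, y)))
  }
})

test_that("appending a common character raises the score by at least M", {
  set.seed(25)
  w <- alignment_weights(2, -3, -5)
  for (rep in 1:25) {
    x <- rand_seq(sample(0:25, 1)); y <- rand_seq(sample(0:25, 1))
    ch <- sample(DNA, 1)
    expect_gte(align_score(paste0(x, ch), paste0(y, ch), w),
               align_score(x, y, w) + w$M)
  }
})

test_that("narrow-word chunked runs are identical to wide-word runs", {
  set.seed(26)
  for (rep in 1:12) {
    wt <- benchmark_weights[[((rep - 1L) %% 5L) + 1L]]
    w <- alignment_weights(wt[1], wt[2], wt[3])
    md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
    x <- rand_seq(sample(10:50, 1)); y <- rand_seq(sample(5:25, 1))
    wide <- align_details(x, y, w, md, "standard", word_width = 512L)
    narrow <- align_details(x, y, w, md, "standard", word_width = 8L)
    expect_identical(narrow, wide)
  }
})

test_that("word width must be a positive multiple of eight", {
  w <- alignment_weights(2, -3, -5)
  expect_error(align_score("ACGT", "AC", w, word_width = 12L), "multiple")
  expect_error(align_score("ACGT", "AC", w, word_width = 0L), "multiple")
})
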