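test_that("generation is deterministic and single ops behave primitively", {
  w <- alignment_weights(2, -3, -5)
  p1 <- generate_program(w)
  p2 <- generate_program(w)
  expect_identical(p1$instructions, p2$instructions)
  ## one-instruction program is just the primitive
  xo <- bit_program(list(list(op = "XOR", a = "p", b = "q", dst = "r",
                              step = "s")), c("p", "q"), "r")
  a <- bitvec(6, c(0, 3)); b <- bitvec(6, c(3, 5))
  got <- run_program(xo, list(p = a, q = b))$r
  expect_true(got == bv_xor(a, b))
  ## referential transparency
  expect_identical(run_program(xo, list(p = a, q = b)),
                   run_program(xo, list(p = a, q = b)))
  expect_error(run_program(xo, list(p = a)), "unbound")
})

test_that("interpreted programs reproduce the engines row by row", {
  set.seed(51)
  wsets <- c(benchmark_weights, list(boundary_weights))
  for (variant in c("standard", "packed")) {
    rows_done <- 0L
    for (rep in seq_along(wsets)) {
      wt <- wsets[[rep]]
      w <- alignment_weights(wt[1], wt[2], wt[3])
      md <- all_modes[[((rep - 1L) %% 4L) + 1L]]
      x <- rand_seq(sample(5:25, 1)); y <- rand_seq(sample(8:20, 1))
      got <- prog_matrix_run(x, y, w, md, variant)
      want <- align_details(x, y, w, md, variant)
      for (i in seq_len(nchar(y)))
        expect_identical(got$dh_rows[[i]], unname(want$dh[i, ]))
      expect_identical(got$score, want$score)
      rows_done <- rows_done + nchar(y)
    }
    expect_gte(rows_done, 48L)   # every weight set contributes rows
  }
})

test_that("operation counts track the function-table size", {
  wsets <- list(c(0, -1, -1), c(1, -2, -1), c(1, -1, -2), c(2, -3, -5),
                c(3, -4, -6), c(3, -2, -4), c(4, -5, -9), c(4, -7, -11))
  z <- sapply(wsets, function(wt)
    standard_table_size(alignment_weights(wt[1], wt[2], wt[3])))
  p <- sapply(wsets, function(wt)
    count_ops(generate_program(alignment_weights(wt[1], wt[2], wt[3]),
                               "standard"))$p)
  ## strictly monotone in the interpreted table size
  o <- order(z)
  expect_true(all(diff(z[o]) > 0))
  expect_true(all(diff(p[o]) > 0))
  expect_equal(cor(z, p, method = "spearman"), 1)
  ## smaller table, shorter program
  expect_lt(p[1], p[8])
})

test_that("packed wins on large tables and loses on the unit-cost table", {
  p_std <- function(wt) count_ops(generate_program(
    alignment_weights(wt[1], wt[2], wt[3]), "standard"))$p
  p_pck <- function(wt) count_ops(generate_program(
    alignment_weights(wt[1], wt[2], wt[3]), "packed"))$p
  ## the three largest printed tables: packed needs fewer operations
  for (wt in list(c(3, -4, -6), c(4, -5, -9), c(4, -7, -11)))
    expect_lt(p_pck(wt), p_std(wt))
  ## unit-cost edit distance: the packed machinery does not pay off
  expect_gte(p_pck(c(0, -1, -1)), p_std(c(0, -1, -1)))
  ## packed grows sub-quadratically: ratio to value_count^2 shrinks
  vc <- function(wt) weight_bounds(alignment_weights(wt[1], wt[2], wt[3]))$value_count
  r_small <- p_pck(c(2, -3, -5)) / vc(c(2, -3, -5))^2
  r_big <- p_pck(c(4, -7, -11)) / vc(c(4, -7, -11))^2
  expect_lt(r_big, r_small)
})

test_that("the counting convention calibrates to four-op LCS efficiency", {
  ## a four-operation word recipe at w = 64 computes 16 cells/op
  ins <- list(
    list(op = "AND", a = "m", b = "v", dst = "t1", step = "row"),
    list(op = "ADD", a = "v", b = "t1", dst = "t2", step = "row"),
    list(op = "OR", a = "m", b = "v", dst = "t3", step = "row"),
    list(op = "XOR", a = "t2", b = "t3", dst = "vout", step = "row"))
  rep <- count_ops(bit_program(ins, c("m", "v"), "vout"), 64L)
  expect_equal(rep$p, 4L)
  expect_equal(rep$e, 16)
  expect_equal(sum(rep$breakdown), rep$p)
  ## empty program counts zero
  expect_equal(count_ops(bit_program(list(), character(0), character(0)))$p, 0L)
})

test_that("shared-subexpression packing emits fewer ops than the naive sum", {
  for (wt in list(c(2, -3, -5), c(4, -7, -11))) {
    w <- alignment_weights(wt[1], wt[2], wt[3])
    b <- weight_bounds(w)
    prog <- generate_program(w, "packed")
    steps <- vapply(prog$instructions, `[[`, "", "step")
    ops <- vapply(prog$instructions, `[[`, "", "op")
    ## naive pack: one OR per member of each digit class beyond the first
    offs <- (b$vmid:b$vmax) - b$vmin
    naive_pack <- sum(vapply(seq_len(b$packed_width), function(d) {
      members <- sum(bitwAnd(bitwShiftR(offs, d - 1L), 1L))
      max(members - 1L, 0L)
    }, 0L))
    got_pack <- sum(steps == "pack" & ops == "OR")
    expect_lt(got_pack, naive_pack)
    ## naive unpack: k - 1 ANDs per requested value
    nup <- length(bitalign:::.unpack_values(w, b))
    got_unpack <- sum(steps == "unpack" & ops == "AND") - nup  # minus masking
    expect_lt(got_unpack, nup * (b$packed_width - 1L))
  }
})

test_that("program listings round-trip through the parser", {
  w <- alignment_weights(2, -3, -5)
  prog <- generate_program(w, "standard")
  txt <- program_text(prog)
  back <- parse_program(txt)
  expect_identical(back$inputs, prog$inputs)
  expect_identical(back$outputs, prog$outputs)
  ## the parsed program computes the same outputs
  set.seed(52)
  b <- weight_bounds(w)
  n <- 12L; pw <- n + 1L
  vals <- sample(b$vmin:b$vmax, n, replace = TRUE)
  inputs <- setNames(lapply(b$vmin:b$vmax, function(v)
    bitvec(pw, which(vals == v) - 1L)), paste0("dh_", b$vmin:b$vmax))
  inputs$match <- bitvec(pw, which(runif(n) < 0.3) - 1L)
  inputs$m_cols <- bitvec(pw, seq_len(n) - 1L)
  r1 <- run_program(prog, inputs)
  r2 <- run_program(back, inputs)
  expect_identical(r1, r2)
})
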