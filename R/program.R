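## Straight-line program generation.  Every weight set compiles to its own
## specialized sequence of primitive word operations (AND, OR, XOR, NOT,
## ADD, SHIFT) computing one row of the alignment; the interpreter is the
## normative semantics and must agree bit-for-bit with the handwritten
## engines.  Programs are width-independent: they are generated from the
## weights alone and run at whatever width their inputs have.

.OPCODES <- c("AND", "OR", "XOR", "NOT", "ADD", "SHIFT")

#' Construct a straight-line bit program
#'
#' Normally produced by [generate_program()]; exposed so small programs
#' can be written by hand.  Each instruction is a list with elements
#' `op` (one of AND, OR, XOR, NOT, ADD, SHIFT), `a`, `b` (slot names;
#' `b = NA` for the unary NOT and SHIFT), `dst` and `step` (a label used
#' in the operation-count breakdown).
#'
#' @param instructions List of instruction lists.
#' @param inputs Character vector of input slot names.
#' @param outputs Character vector of output slot names.
#' @param weights,variant,mode Optional provenance metadata.
#' @return An object of class `"bit_program"`.
#' @export
bit_program <- function(instructions, inputs, outputs,
                        weights = NULL, variant = "custom", mode = NULL) {
  for (ins in instructions) {
    stopifnot(ins$op %in% .OPCODES, is.character(ins$dst))
  }
  structure(list(instructions = instructions, inputs = inputs,
                 outputs = outputs, weights = weights, variant = variant,
                 mode = mode),
            class = "bit_program")
}

## Emitter: a tiny assembler with temp naming and write-once slots
.new_emitter <- function() {
  em <- new.env(parent = emptyenv())
  em$ins <- vector("list", 256L); em$n <- 0L
  em$tmp <- 0L
  em$defined <- character(0)
  em
}

.emit <- function(em, op, a, b = NA_character_, dst = NULL,
                  step = "misc") {
  force(a); force(b)        # arguments may themselves emit (recursion)
  if (is.null(dst)) {
    em$tmp <- em$tmp + 1L
    dst <- paste0("t", em$tmp)
  }
  em$n <- em$n + 1L
  if (em$n > length(em$ins)) em$ins <- c(em$ins, vector("list", length(em$ins)))
  em$ins[[em$n]] <- list(op = op, a = a, b = b, dst = dst, step = step)
  dst
}

## OR of several slots, left chain (the fold order is immaterial for OR)
.emit_or_chain <- function(em, slots, step, dst = NULL) {
  acc <- slots[[1L]]
  if (length(slots) > 1L)
    for (s in slots[-1L]) {
      d <- if (identical(s, slots[[length(slots)]])) dst else NULL
      acc <- .emit(em, "OR", acc, s, dst = d, step = step)
    }
  else if (!is.null(dst))
    acc <- .emit(em, "OR", acc, acc, dst = dst, step = step)
  acc
}

## Shared-subexpression OR trees for packing: the vectors carrying offset
## o (0-based, o in `present`) are OR-combined into one target per binary
## digit d: the offsets with digit d set form aligned blocks of size 2^d,
## so a memoized segment tree over the offset axis computes every
## primitive OR at most once.
.emit_pack_tree <- function(em, slot_of, present, k, step) {
  memo <- new.env(parent = emptyenv())
  block <- function(level, start) {
    key <- paste0(level, "_", start)
    if (!is.null(memo[[key]])) return(memo[[key]])
    members <- intersect(start:(start + 2L^level - 1L), present)
    res <- if (length(members) == 0L) NULL
    else if (length(members) == 1L) slot_of(members)
    else if (level == 0L) slot_of(members)
    else {
      lo <- block(level - 1L, start)
      hi <- block(level - 1L, start + 2L^(level - 1L))
      if (is.null(lo)) hi else if (is.null(hi)) lo
      else .emit(em, "OR", lo, hi, step = step)
    }
    memo[[key]] <- res
    res
  }
  planes <- vector("list", k)
  for (d in seq_len(k)) {
    sz <- 2L^(d - 1L)
    starts <- if (max(present) >= sz)
      seq(sz, max(present), by = 2L * sz) else integer(0)
    blocks <- Filter(Negate(is.null), lapply(starts, function(s)
      block(d - 1L, s)))
    planes[d] <- list(if (length(blocks) == 0L) NULL
      else if (length(blocks) == 1L) blocks[[1L]]
      else Reduce(function(x, y) .emit(em, "OR", x, y, step = step), blocks))
  }
  planes
}

## Shared-subexpression AND prefixes for unpacking: each requested value
## is a conjunction of plane literals; common digit prefixes are computed
## once.
.emit_unpack_tree <- function(em, lits, patterns, step) {
  ## lits[[d]] = c(pos_slot, neg_slot); patterns: list of 0/1 vectors
  memo <- new.env(parent = emptyenv())
  get_prefix <- function(pat, d) {
    key <- paste(pat[seq_len(d)], collapse = "")
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (d == 1L) {
      lits[[1L]][pat[1L] + 1L]
    } else {
      .emit(em, "AND", get_prefix(pat, d - 1L), lits[[d]][pat[d] + 1L],
            step = step)
    }
    memo[[key]] <- res
    res
  }
  lapply(patterns, function(p) get_prefix(p, length(p)))
}

#' Generate the specialized row program for a weight set
#'
#' Emits the straight-line sequence of primitive word operations that
#' advances one row of the bit-parallel alignment for the given weights,
#' either in the standard one-vector-per-value representation or in the
#' packed binary-digit representation.  Interpreting the program with
#' [run_program()] reproduces the handwritten engines bit for bit.
#'
#' Input slots: the previous row's horizontal vectors `dh_<v>` (standard)
#' or planes `dhp_<d>` (packed), the row's `match` vector, the
#' `m_cols` mask of real columns (the word carries one padding column
#' past the sequence) and, when the leftmost initialization value needs
#' injecting, the single-bit constant `c_bit0`.  Output slots: the
#' vertical input-space vectors `s_<v>` and new horizontal vectors
#' `dhnew_<v>` (standard), or the packed vertical outputs `dvp_<d>` and
#' new planes `dhpnew_<d>`.
#'
#' @param weights An [alignment_weights()] object or numeric triple.
#' @param variant `"standard"` or `"packed"`.
#' @param mode An [align_mode()] (the initialization fixes the injected
#'   leftmost value; the score site does not affect the row program).
#' @return A `"bit_program"`.
#' @export
generate_program <- function(weights, variant = c("standard", "packed"),
                             mode = align_mode()) {
  variant <- match.arg(variant)
  w <- .as_weights(weights)
  b <- weight_bounds(w)
  stopifnot(inherits(mode, "align_mode"))
  if (variant == "standard") .gen_standard(w, b, mode)
  else .gen_packed(w, b, mode)
}

.sv <- function(v) paste0("s_", v)
.dhv <- function(v) paste0("dh_", v)

## Zone A (steps 1-2), shared by both variants.  Returns slot names.
.gen_zoneA <- function(em, w, b, mode, leftmost) {
  pr <- .pairs_standard(w, b)
  vmin <- b$vmin; vmax <- b$vmax
  t1 <- .emit(em, "AND", "match", .dhv(vmin), step = "step1")
  s <- .emit(em, "ADD", .dhv(vmin), t1, step = "step1")
  x1 <- .emit(em, "XOR", s, .dhv(vmin), step = "step1")
  smax <- .emit(em, "XOR", x1, t1, dst = .sv(vmax), step = "step1")
  einmax <- .emit(em, "OR", smax, "match", step = "step1")
  ein <- list(); ein[[as.character(vmax)]] <- einmax
  highun <- einmax
  notm <- NULL
  s_slots <- list(); s_slots[[as.character(vmax)]] <- smax
  for (p in pr$step2) {
    terms <- lapply(seq_along(p$bi), function(i) {
      bvv <- vmin + p$bi[i] - 1L
      avv <- vmin + p$ai[i] - 1L
      .emit(em, "AND", ein[[as.character(bvv)]], .dhv(avv), step = "step2")
    })
    u <- .emit_or_chain(em, terms, "step2")
    e <- .emit(em, "SHIFT", u, step = "step2")
    if (p$v == leftmost)
      e <- .emit(em, "OR", e, "c_bit0", step = "step2")
    noth <- .emit(em, "NOT", highun, step = "step2")
    rmask <- .emit(em, "AND", .dhv(vmin), noth, step = "step2")
    sm <- .emit(em, "ADD", rmask, e, step = "step2")
    xa <- .emit(em, "XOR", sm, rmask, step = "step2")
    xb <- .emit(em, "XOR", xa, e, step = "step2")
    sv <- .emit(em, "OR", xb, e, dst = .sv(p$v), step = "step2")
    s_slots[[as.character(p$v)]] <- sv
    if (is.null(notm)) notm <- .emit(em, "NOT", "match", step = "step2")
    ei <- .emit(em, "AND", sv, notm, step = "step2")
    ein[[as.character(p$v)]] <- ei
    highun <- .emit(em, "OR", highun, ei, step = "step2")
  }
  list(pr = pr, ein = ein, highun = highun, notm = notm, s_slots = s_slots)
}

.gen_standard <- function(w, b, mode) {
  em <- .new_emitter()
  leftmost <- if (mode$first_column == "gap") w$G else 0L
  vmin <- b$vmin; vmid <- b$vmid; vmax <- b$vmax
  za <- .gen_zoneA(em, w, b, mode, leftmost)
  pr <- za$pr; ein <- za$ein
  allun <- za$s_slots[[as.character(vmax)]]
  for (p in pr$step2)
    allun <- .emit(em, "OR", allun, za$s_slots[[as.character(p$v)]],
                   step = "step4")
  nohigh <- .emit(em, "NOT", za$highun, step = "step3")
  for (p in pr$step3) {
    terms <- lapply(seq_along(p$bi), function(i) {
      bvv <- vmin + p$bi[i] - 1L
      avv <- vmin + p$ai[i] - 1L
      .emit(em, "AND", ein[[as.character(bvv)]], .dhv(avv), step = "step3")
    })
    cterm <- .emit(em, "AND", .dhv(vmin + p$ci - 1L), nohigh, step = "step3")
    u <- .emit_or_chain(em, c(terms, list(cterm)), "step3")
    sv <- if (p$v == leftmost) {
      e0 <- .emit(em, "SHIFT", u, step = "step3")
      .emit(em, "OR", e0, "c_bit0", dst = .sv(p$v), step = "step3")
    } else {
      .emit(em, "SHIFT", u, dst = .sv(p$v), step = "step3")
    }
    allun <- .emit(em, "OR", allun, sv, step = "step4")
  }
  .emit(em, "NOT", allun, dst = .sv(vmin), step = "step4")
  ## Step 5: modified horizontal vectors, then diagonal pairs
  notm <- za$notm
  if (is.null(notm)) notm <- .emit(em, "NOT", "match", step = "step5")
  lowslots <- lapply(vmin:vmid, .dhv)
  dhd <- list()
  dmid <- .emit_or_chain(em, lowslots, "step5")
  dhd[[as.character(vmid)]] <- .emit(em, "AND", dmid, notm, step = "step5")
  if (vmax - 1L >= vmid + 1L)
    for (a in (vmid + 1L):(vmax - 1L))
      dhd[[as.character(a)]] <- .emit(em, "AND", .dhv(a), notm, step = "step5")
  dhd[[as.character(vmax)]] <- .emit(em, "OR", .dhv(vmax), "match",
                                     step = "step5")
  dun <- NULL
  for (u in 2L:b$value_count) {
    p <- pr$step5[[u]]
    uval <- vmin + u - 1L
    if (is.null(p)) next
    terms <- lapply(seq_along(p$ai), function(i) {
      avv <- vmid + p$ai[i] - 1L
      bvv <- vmin + p$bi[i] - 1L
      .emit(em, "AND", dhd[[as.character(avv)]], .sv(bvv), step = "step5")
    })
    dn <- .emit_or_chain(em, terms, "step5", dst = paste0("dhnew_", uval))
    dun <- if (is.null(dun)) dn else .emit(em, "OR", dun, dn, step = "step5")
  }
  nd <- .emit(em, "NOT", dun, step = "step5")
  .emit(em, "AND", nd, "m_cols", dst = paste0("dhnew_", vmin), step = "step5")
  inputs <- c(vapply(vmin:vmax, .dhv, ""), "match", "m_cols",
              if (leftmost > vmin) "c_bit0")
  outputs <- c(vapply(vmin:vmax, .sv, ""),
               paste0("dhnew_", vmin:vmax))
  bit_program(em$ins[seq_len(em$n)], inputs, outputs, w, "standard", mode)
}

## generic emitted ripple adder over k digit slots; operands may be NULL
## or NA (a known-zero digit), in which case the full-adder algebra
## simplifies and no operation is emitted for the vanished terms
.emit_ripple <- function(em, as, bs, k, step) {
  nil <- function(x) is.null(x) || (length(x) == 1L && is.na(x))
  sxor <- function(p, q) {
    if (nil(p)) return(if (nil(q)) NULL else q)
    if (nil(q)) return(p)
    .emit(em, "XOR", p, q, step = step)
  }
  sand <- function(p, q) {
    if (nil(p) || nil(q)) return(NULL)
    .emit(em, "AND", p, q, step = step)
  }
  sor <- function(p, q) {
    if (nil(p)) return(if (nil(q)) NULL else q)
    if (nil(q)) return(p)
    .emit(em, "OR", p, q, step = step)
  }
  s <- vector("list", k)
  carry <- NULL
  for (d in seq_len(k)) {
    a <- as[[d]]; b <- bs[[d]]
    x <- sxor(a, b)
    s[d] <- list(sxor(x, carry))
    g <- sand(a, b)
    t <- sand(carry, x)
    carry <- sor(g, t)
  }
  s
}

.gen_packed <- function(w, b, mode) {
  em <- .new_emitter()
  leftmost <- if (mode$first_column == "gap") w$G else 0L
  k <- b$packed_width
  vmin <- b$vmin; vmid <- b$vmid; vmax <- b$vmax
  dhp <- paste0("dhp_", 0:(k - 1L))
  ndhp <- vapply(dhp, function(p) .emit(em, "NOT", p, step = "unpack"), "")
  lits <- lapply(seq_len(k), function(d) c(ndhp[d], dhp[d]))
  uv <- .unpack_values(w, b)
  pats <- lapply(uv, function(v) .twoc_digits(vmin - v, k))
  raw <- .emit_unpack_tree(em, lits, pats, "unpack")
  for (i in seq_along(uv))
    .emit(em, "AND", raw[[i]], "m_cols", dst = .dhv(uv[i]), step = "unpack")
  za <- .gen_zoneA(em, w, b, mode, leftmost)
  ## pack effective vertical inputs (high values, rest = vmid)
  rest <- .emit(em, "NOT", za$highun, step = "pack")
  offs <- c(vmid - vmin, (vmid + 1L):vmax - vmin)
  slot_of <- function(o) {
    if (o == vmid - vmin) rest else za$ein[[as.character(vmin + o)]]
  }
  vp <- .emit_pack_tree(em, slot_of, offs, k, "pack")
  ## add vertical offsets to packed horizontals; clamp negatives (Zone D)
  s1 <- .emit_ripple(em, vp, as.list(dhp), k, "add_dv")
  notneg <- .emit(em, "NOT", s1[[k]], step = "add_dv")
  dvp <- character(k)
  for (d in seq_len(k)) {
    t <- .emit(em, "AND", s1[[d]], notneg, step = "add_dv")
    dvp[d] <- .emit(em, "AND", t, "m_cols", dst = paste0("dvp_", d - 1L),
                    step = "add_dv")
  }
  ## re-encode horizontal [vmin, vmid] to vmid, match columns to vmax
  c0 <- .twoc_digits(vmid - vmin, k)
  cs <- lapply(seq_len(k), function(d) if (c0[d]) "m_cols" else NA_character_)
  s2 <- .emit_ripple(em, as.list(dhp), cs, k, "reencode")
  nots2 <- .emit(em, "NOT", s2[[k]], step = "reencode")
  pred <- .emit(em, "AND", nots2, "m_cols", step = "reencode")
  npred <- .emit(em, "NOT", pred, step = "reencode")
  notm <- za$notm
  if (is.null(notm)) notm <- .emit(em, "NOT", "match", step = "reencode")
  mid_e <- .twoc_digits(vmin - vmid, k)
  max_e <- .twoc_digits(vmin - vmax, k)
  dhd <- character(k)
  for (d in seq_len(k)) {
    v <- .emit(em, "AND", dhp[d], npred, step = "reencode")
    if (mid_e[d]) v <- .emit(em, "OR", v, pred, step = "reencode")
    v <- .emit(em, "AND", v, notm, step = "reencode")
    if (max_e[d]) v <- .emit(em, "OR", v, "match", step = "reencode")
    dhd[d] <- v
  }
  ## shift vertical outputs into input position and add again
  inj <- .twoc_digits(leftmost - vmin, k)
  tin <- character(k)
  for (d in seq_len(k)) {
    t <- .emit(em, "SHIFT", dvp[d], step = "add_dh")
    tin[d] <- if (inj[d]) .emit(em, "OR", t, "c_bit0", step = "add_dh") else t
  }
  s3 <- .emit_ripple(em, as.list(tin), as.list(dhd), k, "add_dh")
  nz <- .emit_or_chain(em, Filter(Negate(is.null), s3), "add_dh")
  nots3 <- .emit(em, "NOT", s3[[k]], step = "add_dh")
  pos <- .emit(em, "AND", nots3, nz, step = "add_dh")
  npos <- .emit(em, "NOT", pos, step = "add_dh")
  for (d in seq_len(k)) {
    t <- .emit(em, "AND", s3[[d]], npos, step = "add_dh")
    .emit(em, "AND", t, "m_cols", dst = paste0("dhpnew_", d - 1L),
          step = "add_dh")
  }
  inputs <- c(dhp, "match", "m_cols",
              if (any(inj == 1L)) "c_bit0")
  outputs <- c(paste0("dvp_", 0:(k - 1L)), paste0("dhpnew_", 0:(k - 1L)))
  bit_program(em$ins[seq_len(em$n)], inputs, outputs, w, "packed", mode)
}

#' Interpret a straight-line bit program
#'
#' @param program A `"bit_program"`.
#' @param inputs Named list binding every input slot to a [bitvec()] of a
#'   common width.
#' @return Named list binding the program's output slots to `bitvec`s.
#' @export
run_program <- function(program, inputs) {
  stopifnot(inherits(program, "bit_program"))
  missing <- setdiff(program$inputs, names(inputs))
  if (length(missing))
    stop("unbound input slots: ", paste(missing, collapse = ", "))
  env <- new.env(parent = emptyenv())
  for (nm in names(inputs)) env[[nm]] <- inputs[[nm]]
  for (ins in program$instructions) {
    a <- env[[ins$a]]
    if (is.null(a)) stop("read of unbound slot '", ins$a, "'")
    val <- switch(ins$op,
      NOT = bv_not(a),
      SHIFT = bv_shift_in(a, 0L)$result,
      {
        b <- env[[ins$b]]
        if (is.null(b)) stop("read of unbound slot '", ins$b, "'")
        switch(ins$op,
               AND = bv_and(a, b),
               OR = bv_or(a, b),
               XOR = bv_xor(a, b),
               ADD = bv_add(a, b)$sum)
      })
    env[[ins$dst]] <- val
  }
  out <- lapply(program$outputs, function(nm) env[[nm]])
  names(out) <- program$outputs
  out
}

#' Count the primitive operations of a bit program
#'
#' Counts logic and addition operations only — every AND, OR, XOR, NOT,
#' ADD and SHIFT instruction counts one; stores/moves are not represented
#' in the instruction set at all.  The efficiency `e = w / p` is the
#' average number of scoring-matrix cells advanced per operation at word
#' width `w`.
#'
#' @param program A `"bit_program"`.
#' @param word_width Word width used for the efficiency ratio.
#' @return An object of class `"op_report"`: list with `p`, `w`, `e` and
#'   a named `breakdown` by step.
#' @examples
#' p <- generate_program(alignment_weights(0, -1, -1))
#' count_ops(p)$p
#' @export
count_ops <- function(program, word_width = 64L) {
  stopifnot(inherits(program, "bit_program"))
  steps <- vapply(program$instructions, `[[`, "", "step")
  breakdown <- table(factor(steps, levels = unique(steps)))
  p <- length(program$instructions)
  structure(list(p = p, w = as.integer(word_width),
                 e = word_width / p,
                 breakdown = stats::setNames(as.integer(breakdown),
                                             names(breakdown)),
                 variant = program$variant),
            class = "op_report")
}

#' @export
print.op_report <- function(x, ...) {
  cat(sprintf("%s row program: p = %d ops, w = %d, efficiency e = w/p = %.3g\n",
              x$variant, x$p, x$w, x$e))
  cat("  breakdown:", paste(names(x$breakdown), x$breakdown, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.bit_program <- function(x, ...) {
  cat(sprintf("bit program (%s variant), %d instructions, %d inputs\n",
              x$variant, length(x$instructions), length(x$inputs)))
  invisible(x)
}

#' Render a bit program as a readable listing
#'
#' One instruction per line, `dst = OP a b  ; step`.  The listing can be
#' parsed back with [parse_program()].
#'
#' @param program A `"bit_program"`.
#' @return Character vector of lines.
#' @export
program_text <- function(program) {
  stopifnot(inherits(program, "bit_program"))
  hdr <- c(paste0("# inputs: ", paste(program$inputs, collapse = " ")),
           paste0("# outputs: ", paste(program$outputs, collapse = " ")))
  body <- vapply(program$instructions, function(i) {
    rhs <- if (i$op %in% c("NOT", "SHIFT")) paste(i$op, i$a)
           else paste(i$op, i$a, i$b)
    sprintf("%s = %s  ; %s", i$dst, rhs, i$step)
  }, "")
  c(hdr, body)
}

#' Parse a program listing produced by [program_text()]
#'
#' @param lines Character vector of listing lines.
#' @return A `"bit_program"`.
#' @export
parse_program <- function(lines) {
  inp <- sub("^# inputs: ", "", grep("^# inputs: ", lines, value = TRUE))
  outp <- sub("^# outputs: ", "", grep("^# outputs: ", lines, value = TRUE))
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  ins <- lapply(body, function(l) {
    parts <- strsplit(l, ";", fixed = TRUE)[[1L]]
    step <- trimws(parts[2L])
    eq <- strsplit(trimws(parts[1L]), "=", fixed = TRUE)[[1L]]
    dst <- trimws(eq[1L])
    toks <- strsplit(trimws(eq[2L]), " +")[[1L]]
    list(op = toks[1L], a = toks[2L],
         b = if (length(toks) > 2L) toks[3L] else NA_character_,
         dst = dst, step = step)
  })
  bit_program(ins, strsplit(inp, " ")[[1L]], strsplit(outp, " ")[[1L]])
}

## Whole-matrix driver over the interpreter (single word): used to show
## the generated program is a complete alternative compilation path.
.prog_align <- function(x, y, weights, mode = align_mode(),
                        variant = c("standard", "packed")) {
  variant <- match.arg(variant)
  w <- .as_weights(weights)
  b <- weight_bounds(w)
  prog <- generate_program(w, variant, mode)
  xc <- .chars(x); yc <- .chars(y)
  n <- length(xc); m <- length(yc)
  pw <- n + 1L
  mv <- match_vectors(paste(xc, collapse = ""), unique(xc))
  pad <- function(lv) .bv(pw, c(lv, integer(.nlimbs(pw) - length(lv)))[seq_len(.nlimbs(pw))])
  consts <- list(m_cols = .bv(pw, .lv_mask(n, .nlimbs(pw))),
                 c_bit0 = bitvec(pw, 0L))
  zero <- bitvec(pw)
  h0 <- if (mode$first_row == "gap") w$G else 0L
  if (variant == "standard") {
    dh <- stats::setNames(rep(list(zero), b$value_count),
                          vapply(b$vmin:b$vmax, .dhv, ""))
    dh[[.dhv(h0)]] <- consts$m_cols
    for (i in seq_len(m)) {
      mt <- if (yc[i] %in% names(mv)) pad(mv[[yc[i]]]$limbs) else zero
      out <- run_program(prog, c(dh, list(match = mt), consts))
      dh <- stats::setNames(out[paste0("dhnew_", b$vmin:b$vmax)],
                            vapply(b$vmin:b$vmax, .dhv, ""))
    }
    base <- .col0_score(m, w, mode)
    vals <- b$vmin:b$vmax
    as.integer(base + sum(vals * vapply(dh, bv_popcount, 0L)))
  } else {
    k <- b$packed_width
    dig <- .twoc_digits(b$vmin - h0, k)
    dhp <- stats::setNames(lapply(seq_len(k), function(d)
      if (dig[d]) consts$m_cols else zero), paste0("dhp_", 0:(k - 1L)))
    for (i in seq_len(m)) {
      mt <- if (yc[i] %in% names(mv)) pad(mv[[yc[i]]]$limbs) else zero
      out <- run_program(prog, c(dhp, list(match = mt), consts))
      dhp <- stats::setNames(out[paste0("dhpnew_", 0:(k - 1L))],
                             paste0("dhp_", 0:(k - 1L)))
    }
    planes <- do.call(cbind, lapply(dhp, function(v) v$limbs))
    base <- .col0_score(m, w, mode)
    as.integer(base + .decode_dhp_sum(planes, b$vmin, n, k))
  }
}
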