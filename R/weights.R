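#' Validate an integer alignment scoring scheme
#'
#' An integer scoring scheme assigns a match score `M >= 0`, a mismatch
#' penalty `I < 0` and a gap (indel) penalty `G < 0` to each aligned column.
#' The additional constraint `I >= 2G` makes mismatches usable: substituting
#' a character is never penalized more than deleting it from one sequence
#' and inserting into the other.
#'
#' @param match Integer match score `M` (non-negative).
#' @param mismatch Integer mismatch score `I` (negative).
#' @param gap Integer gap score `G` (negative).
#' @return An object of class `"align_weights"`: a list with integer
#'   components `M`, `I` and `G`.
#' @examples
#' alignment_weights(2, -3, -5)
#' alignment_weights(0, -1, -1)   # unit-cost edit distance
#' @export
alignment_weights <- function(match, mismatch, gap) {
  M <- .as_int1(match, "match")
  I <- .as_int1(mismatch, "mismatch")
  G <- .as_int1(gap, "gap")
  if (M < 0)
    stop("invalid weights: match score must satisfy M >= 0 (got M = ", M, ")")
  if (I >= 0)
    stop("invalid weights: mismatch score must satisfy I < 0 (got I = ", I, ")")
  if (G >= 0)
    stop("invalid weights: gap score must satisfy G < 0 (got G = ", G, ")")
  if (I < 2L * G)
    stop("invalid weights: mismatch must satisfy I >= 2G (got I = ", I,
         " < 2G = ", 2L * G, ")")
  structure(list(M = M, I = I, G = G), class = "align_weights")
}

.as_int1 <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x))
    stop("'", what, "' must be a single integer")
  as.integer(x)
}

.as_weights <- function(w) {
  if (inherits(w, "align_weights")) return(w)
  if (is.numeric(w) && length(w) == 3L)
    return(alignment_weights(w[[1L]], w[[2L]], w[[3L]]))
  stop("'weights' must be an 'align_weights' object or a numeric triple (M, I, G)")
}

#' @export
print.align_weights <- function(x, ...) {
  cat(sprintf("integer alignment weights: M = %d, I = %d, G = %d\n",
              x$M, x$I, x$G))
  invisible(x)
}

#' Derived bounds of the difference values for a scoring scheme
#'
#' Differences between adjacent cells of the alignment scoring matrix
#' (vertical `dV = S[i,j] - S[i-1,j]` and horizontal `dH = S[i,j] - S[i,j-1]`)
#' are confined to the integer interval `[G, M - G]`.  This function derives
#' the constants every engine in the package is built around:
#' `vmin = G`, `vmax = M - G`, the mismatch boundary `vmid = I - G`
#' separating the "low" values `[vmin, vmid]` from the "high" values
#' `(vmid, vmax]`, the number of distinct values `M - 2G + 1`, the offset
#' span `vmax - vmin`, and the number of binary-digit planes
#' `ceiling(log2(2 * span + 1))` the packed representation needs so that
#' per-column sums of a value offset and a (negated) offset never overflow.
#'
#' @param weights An [alignment_weights()] object (or numeric triple).
#' @return An object of class `"align_bounds"`: list with `vmin`, `vmid`,
#'   `vmax`, `value_count`, `span` and `packed_width`.
#' @examples
#' weight_bounds(alignment_weights(2, -3, -5))
#' @export
weight_bounds <- function(weights) {
  w <- .as_weights(weights)
  vmin <- w$G
  vmid <- w$I - w$G
  vmax <- w$M - w$G
  span <- vmax - vmin
  structure(list(
    vmin = vmin, vmid = vmid, vmax = vmax,
    value_count = span + 1L,
    span = span,
    packed_width = as.integer(ceiling(log2(2 * span + 1)))
  ), class = "align_bounds")
}

#' @export
print.align_bounds <- function(x, ...) {
  cat(sprintf(paste0(
    "difference-value bounds: vmin = %d, vmid = %d, vmax = %d\n",
    "  %d distinct values, span %d, %d packed bit planes\n"),
    x$vmin, x$vmid, x$vmax, x$value_count, x$span, x$packed_width))
  invisible(x)
}

## Output of one cell of the difference recurrence, by candidate
## enumeration on a 2x2 score patch: anchor S[i-1,j-1] = 0, so
## S[i,j-1] = dv_left, S[i-1,j] = dh_above, and
## S[i,j] = max(substitution, dh_above + G, dv_left + G).
.cell_out <- function(dv_left, dh_above, is_match, w) {
  sub <- ifelse(is_match, w$M, w$I)
  pmax(sub, dh_above + w$G, dv_left + w$G)
}

#' Dense function table for the vertical difference recurrence
#'
#' The output vertical difference of a cell is a function of only three
#' inputs: the vertical difference entering from the left, the horizontal
#' difference coming from above, and whether the two characters match.
#' This function materializes that map densely over the full
#' `[vmin, vmax] x [vmin, vmax]` square (match handled as a separate
#' layer), together with a zone classification:
#'
#' * `A` — best score via the left (vertical) value, output high;
#' * `B` — indel from the left, output low;
#' * `C` — mismatch, output `I - dH` depends only on the horizontal input;
#' * `D` — indel from above, output `vmin`;
#' * `border` — several cases tie (their numeric outputs always agree).
#'
#' Every output is obtained by enumerating the three score candidates
#' (substitution, gap from above, gap from the left) on a two-by-two score
#' patch, so ties on zone borders resolve to a single well-defined number.
#'
#' @param weights An [alignment_weights()] object.
#' @return An object of class `"delta_table"`: list with `values`
#'   (the vector `vmin:vmax`), integer matrices `out_nomatch` and
#'   `out_match` (rows = left vertical input, columns = horizontal input
#'   from above), character matrices `zone_nomatch`/`zone_match`, `role`
#'   (`"dv"` or, after [transpose_table()], `"dh"`), plus `weights` and
#'   `bounds`.
#' @examples
#' tab <- delta_v_table(alignment_weights(2, -3, -5))
#' table_lookup(tab, dv_left = 5, dh_above = -4, is_match = FALSE)  # 4
#' @export
delta_v_table <- function(weights) {
  w <- .as_weights(weights)
  b <- weight_bounds(w)
  vals <- b$vmin:b$vmax
  dv <- matrix(vals, b$value_count, b$value_count, byrow = FALSE)
  dh <- matrix(vals, b$value_count, b$value_count, byrow = TRUE)
  out_nm <- matrix(.cell_out(dv, dh, FALSE, w) - dh, b$value_count,
                   dimnames = list(vals, vals))
  out_m <- matrix(.cell_out(dv, dh, TRUE, w) - dh, b$value_count,
                  dimnames = list(vals, vals))
  zone <- function(dvm, dhm, is_match) {
    sub <- if (is_match) w$M else w$I
    cl <- dvm + w$G            # candidate: gap from the left
    ca <- dhm + w$G            # candidate: gap from above
    mx <- pmax(sub, ca, cl)
    nwin <- (cl == mx) + (ca == mx) + (sub == mx)
    z <- matrix("border", nrow(dvm), ncol(dvm))
    lab_left <- ifelse(mx - dhm > b$vmid, "A", "B")
    z[nwin == 1L & cl == mx] <- lab_left[nwin == 1L & cl == mx]
    z[nwin == 1L & sub == mx] <- "C"
    z[nwin == 1L & ca == mx] <- "D"
    dimnames(z) <- list(vals, vals)
    z
  }
  structure(list(values = vals,
                 out_nomatch = out_nm, out_match = out_m,
                 zone_nomatch = zone(dv, dh, FALSE),
                 zone_match = zone(dv, dh, TRUE),
                 role = "dv", weights = w, bounds = b),
            class = "delta_table")
}

#' Look up one entry of a difference function table
#'
#' @param table A `"delta_table"` from [delta_v_table()] or
#'   [transpose_table()].
#' @param dv_left,dh_above Integer difference inputs in `[vmin, vmax]`.
#' @param is_match Logical; do the two characters of the cell match?
#' @param what `"out"` for the output value, `"zone"` for the zone label.
#' @return Integer output difference, or a zone label.
#' @export
table_lookup <- function(table, dv_left, dh_above, is_match = FALSE,
                         what = c("out", "zone")) {
  what <- match.arg(what)
  b <- table$bounds
  stopifnot(all(dv_left >= b$vmin & dv_left <= b$vmax),
            all(dh_above >= b$vmin & dh_above <= b$vmax))
  ## tables are stored indexed (left input, above input) regardless of role
  i <- dv_left - b$vmin + 1L
  j <- dh_above - b$vmin + 1L
  m <- if (what == "out") {
    if (is_match) table$out_match else table$out_nomatch
  } else {
    if (is_match) table$zone_match else table$zone_nomatch
  }
  m[cbind(i, j)]
}

#' Transpose a difference function table
#'
#' The horizontal difference obeys the same recurrence as the vertical one
#' with the roles of the two inputs swapped (the horizontal table is the
#' transpose of the vertical one).  The transposed table is still indexed
#' `(dv_left, dh_above)`: `transpose(t)(x, y) == t(y, x)`.
#'
#' @param table A `"delta_table"`.
#' @return A `"delta_table"` with the input roles swapped and `role`
#'   flipped between `"dv"` and `"dh"`.
#' @export
transpose_table <- function(table) {
  stopifnot(inherits(table, "delta_table"))
  table$out_nomatch <- t(table$out_nomatch)
  table$out_match <- t(table$out_match)
  table$zone_nomatch <- t(table$zone_nomatch)
  table$zone_match <- t(table$zone_match)
  table$role <- if (identical(table$role, "dv")) "dh" else "dv"
  table
}

#' @export
print.delta_table <- function(x, ...) {
  cat(sprintf("%s function table for M = %d, I = %d, G = %d (%d x %d)\n",
              if (x$role == "dv") "vertical-difference" else
                "horizontal-difference",
              x$weights$M, x$weights$I, x$weights$G,
              x$bounds$value_count, x$bounds$value_count))
  print(x$out_nomatch)
  invisible(x)
}

#' A-priori size estimate of the standard function table workload
#'
#' The number of word operations of the standard engine grows with the
#' combined size of zones A, B and C of the function table (zone C reduced
#' to a single row).  For weights `(M, I, G)` that area is
#' `((M - 2G + 1)^2 - (I - 2G)^2) / 2`.  This is an analytic scaling
#' estimate used to study how operation counts grow with the weights; the
#' reported operation counts themselves are always measured on the emitted
#' program, never taken from this formula.
#'
#' @param weights An [alignment_weights()] object.
#' @return A single number (may be a half-integer).
#' @examples
#' standard_table_size(alignment_weights(2, -3, -5))  # 60
#' @export
standard_table_size <- function(weights) {
  w <- .as_weights(weights)
  ((w$M - 2 * w$G + 1)^2 - (w$I - 2 * w$G)^2) / 2
}

#' Write a function table as TSV (debug/documentation dump)
#'
#' Rows are the left vertical input, columns the horizontal input from
#' above; the first column holds the row value.
#'
#' @param table A `"delta_table"`.
#' @param path File path to write to.
#' @param layer `"nomatch"` (default) or `"match"`.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path, layer = c("nomatch", "match")) {
  layer <- match.arg(layer)
  m <- if (layer == "nomatch") table$out_nomatch else table$out_match
  df <- data.frame(dv_left = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
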