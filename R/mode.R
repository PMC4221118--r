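#' Alignment initialization and score-site mode
#'
#' Global alignment charges a gap penalty along both the first row and the
#' first column of the scoring matrix and reads the score in the last
#' cell.  Semi-global variants make the first row and/or first column free
#' (zero initialization, so a leading gap in one sequence costs nothing)
#' and may read the best score anywhere in the last row or last column.
#'
#' @param first_row `"gap"` (initialize `S[0, j] = j * G`) or `"free"`
#'   (`S[0, j] = 0`).
#' @param first_column `"gap"` (`S[i, 0] = i * G`) or `"free"` (`S[i, 0] = 0`).
#' @param score_site Where the reported score is read: the `"last_cell"`
#'   `S[m, n]`, the best of the `"last_row"` `S[m, ]`, or the best of the
#'   `"last_col"` `S[, n]`.
#' @return An object of class `"align_mode"`.
#' @examples
#' align_mode()                       # global
#' align_mode("free", "gap", "last_row")
#' @export
align_mode <- function(first_row = c("gap", "free"),
                       first_column = c("gap", "free"),
                       score_site = c("last_cell", "last_row", "last_col")) {
  structure(list(first_row = match.arg(first_row),
                 first_column = match.arg(first_column),
                 score_site = match.arg(score_site)),
            class = "align_mode")
}

#' @export
print.align_mode <- function(x, ...) {
  cat(sprintf("alignment mode: first row %s, first column %s, score at %s\n",
              x$first_row, x$first_column, x$score_site))
  invisible(x)
}

.chars <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (nchar(x) == 0L) character(0) else strsplit(toupper(x), "", fixed = TRUE)[[1L]]
}
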