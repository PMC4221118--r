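#' Read sequences from a FASTA file
#'
#' Record identifiers are the header text up to the first whitespace;
#' sequences are uppercased and multi-line records concatenated.  An
#' empty file yields an empty vector; a sequence line appearing before
#' any header is rejected with its line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA: sequence line before any header at line ",
         nonblank[1L])
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(unname(seqs), ids)
}

#' Score every query against every target
#'
#' Batch driver: one row per (query, target) pair in query-major input
#' order.  The `"oracle"` variant scores with the classical dynamic
#' programming recurrence instead of a bit-parallel engine and is meant
#' for ground-truth runs.
#'
#' @param queries,targets Named character vectors of sequences (as from
#'   [read_fasta()]); unnamed vectors get positional names.
#' @param weights An [alignment_weights()] object or numeric triple.
#' @param mode An [align_mode()].
#' @param variant `"standard"`, `"packed"` or `"oracle"`.
#' @param word_width Word size for the bit-parallel variants.
#' @return `data.frame` with columns `query_id`, `target_id`, `score`,
#'   `variant`.
#' @examples
#' score_batch(c(q = "ACGT"), c(t1 = "ACGT", t2 = "ACCT"),
#'             alignment_weights(2, -3, -5))
#' @export
score_batch <- function(queries, targets, weights, mode = align_mode(),
                        variant = c("standard", "packed", "oracle"),
                        word_width = 64L) {
  variant <- match.arg(variant)
  w <- .as_weights(weights)
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  nq <- length(queries); nt <- length(targets)
  out <- data.frame(
    query_id = rep(names(queries), each = nt),
    target_id = rep(names(targets), times = nq),
    score = integer(nq * nt),
    variant = variant,
    stringsAsFactors = FALSE)
  r <- 0L
  for (q in seq_len(nq)) for (t in seq_len(nt)) {
    r <- r + 1L
    ## the query is the horizontal (word-packed) sequence
    out$score[r] <- if (variant == "oracle")
      nw_score(queries[[q]], targets[[t]], w, mode)$score
    else
      align_score(queries[[q]], targets[[t]], w, mode, variant, word_width)
  }
  out
}

#' Write a batch score table as headered TSV
#'
#' @param scores Data frame from [score_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_batch <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Emit a specialized row program with its operation report
#'
#' Renders the straight-line program [generate_program()] builds for a
#' weight set, either as a plain-text listing followed by the operation
#' counts or as JSON.
#'
#' @param weights An [alignment_weights()] object or numeric triple.
#' @param variant `"standard"` or `"packed"`.
#' @param format `"text"` or `"json"`.
#' @param mode An [align_mode()].
#' @param word_width Word width for the efficiency ratio.
#' @return Character scalar (the listing or the JSON document).
#' @export
emit_program <- function(weights, variant = c("standard", "packed"),
                         format = c("text", "json"), mode = align_mode(),
                         word_width = 64L) {
  variant <- match.arg(variant)
  format <- match.arg(format)
  w <- .as_weights(weights)
  prog <- generate_program(w, variant, mode)
  rep <- count_ops(prog, word_width)
  if (format == "text") {
    paste(c(sprintf("# weights M=%d I=%d G=%d, %s variant", w$M, w$I, w$G,
                    variant),
            program_text(prog),
            sprintf("# p = %d operations, w = %d, e = w/p = %.4f",
                    rep$p, rep$w, rep$e),
            sprintf("# breakdown: %s",
                    paste(names(rep$breakdown), rep$breakdown, sep = "=",
                          collapse = ", "))),
          collapse = "\n")
  } else {
    jsonlite::toJSON(list(
      weights = list(M = w$M, I = w$I, G = w$G),
      variant = variant,
      p = rep$p, w = rep$w, e = rep$e,
      breakdown = as.list(rep$breakdown),
      instructions = lapply(prog$instructions, function(i)
        list(dst = i$dst, op = i$op, a = i$a,
             b = if (is.na(i$b)) NULL else i$b, step = i$step))),
      auto_unbox = TRUE, digits = NA)
  }
}
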