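#' Run-length edit scripts (CIGAR)
#'
#' An edit script is the run-length encoded sequence of edit operations an
#' aligner reports for one alignment: `M` (align), `=` (sequence match),
#' `X` (mismatch), `I` (insertion to the reference), `D` (deletion from the
#' reference), `S`/`H` (soft/hard clip), `N` (reference skip) and `P` (pad).
#' Scripts are stored as parallel vectors of operation codes and positive run
#' lengths, and round-trip losslessly to CIGAR strings.
#'
#' @param ops character vector of single-character operation codes.
#' @param lengths integer vector of run lengths, same length as `ops`.
#' @return An object of class `edit_script`.
#' @examples
#' s <- edit_script(c("S", "M", "I", "M"), c(2L, 5L, 1L, 3L))
#' script_to_cigar(s)
#' query_width(s)
#' @export
edit_script <- function(ops, lengths) {
  ops <- as.character(ops)
  lengths <- as.integer(lengths)
  stopifnot(length(ops) == length(lengths))
  if (length(lengths) && any(lengths < 1L))
    stop("edit script run lengths must be >= 1")
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S", "H", "N", "P"))
  if (length(bad))
    stop("unknown edit operations: ", paste(bad, collapse = ", "))
  structure(list(ops = ops, lengths = lengths), class = "edit_script")
}

#' @rdname edit_script
#' @param cigar a CIGAR string such as `"5M1I3M"`.
#' @export
cigar_to_script <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  edit_script(ops, lens)
}

#' @rdname edit_script
#' @param script an `edit_script`.
#' @export
script_to_cigar <- function(script) {
  if (!length(script$ops)) return("*")
  paste0(script$lengths, script$ops, collapse = "")
}

#' @export
print.edit_script <- function(x, ...) {
  cat("<edit_script> ", script_to_cigar(x), "\n", sep = "")
  invisible(x)
}

QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS <- c("M", "=", "X", "D", "N")

#' Widths of an edit script
#'
#' `query_width()` sums the runs that consume read bases (`M`, `=`, `X`, `I`,
#' `S`); `ref_width()` sums the runs that consume reference bases
#' (`M`, `=`, `X`, `D`, `N`).
#'
#' @param script an `edit_script`.
#' @return integer width.
#' @export
query_width <- function(script) {
  sum(script$lengths[script$ops %in% QUERY_OPS])
}

#' @rdname query_width
#' @export
ref_width <- function(script) {
  sum(script$lengths[script$ops %in% REF_OPS])
}

## Merge adjacent runs of the same operation; drop zero-length runs.
script_merge <- function(script) {
  keep <- script$lengths > 0L
  ops <- script$ops[keep]
  lens <- script$lengths[keep]
  if (length(ops) < 2L) return(edit_script(ops, lens))
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  edit_script(ops[!duplicated(grp)],
              as.integer(tapply(lens, grp, sum)))
}

## Expand a script to one op code per consumed unit (for oracles/pileup).
script_expand <- function(script) {
  rep(script$ops, script$lengths)
}

check_script_read_length <- function(script, read_length, what = "alignment") {
  qw <- query_width(script)
  if (qw != read_length)
    stop(sprintf("%s: query-consuming CIGAR width (%d) != read length (%d)",
                 what, qw, read_length))
  invisible(TRUE)
}
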