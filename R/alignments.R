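#' Alignment record tables
#'
#' Alignments are kept in a plain `data.frame` (class `pg_alignments`) with
#' one row per alignment record, mirroring the SAM fields the pipeline needs:
#'
#' * `read_id` — query name
#' * `target` — target sequence name (founder or reference contig)
#' * `pos` — 0-based leftmost aligned reference/founder position
#' * `cigar` — CIGAR string
#' * `mapq` — mapping quality, 0..255
#' * `flag` — SAM bitwise flag
#' * `seq`, `qual` — read bases and Phred+33 quality string
#' * `AS`, `XS`, `NM`, `MD` — optional tags (NA when absent)
#'
#' Positions are 0-based half-open internally; SAM emission converts to
#' 1-based `POS`.
#'
#' @param read_id,target,pos,cigar,mapq,flag,seq,qual,AS,XS,NM,MD record
#'   fields, recycled per `data.frame` rules.
#' @return a `pg_alignments` data frame.
#' @export
alignments <- function(read_id, target, pos, cigar, mapq = 255L, flag = 0L,
                       seq = NA_character_, qual = NA_character_,
                       AS = NA_real_, XS = NA_real_, NM = NA_integer_,
                       MD = NA_character_) {
  out <- data.frame(
    read_id = as.character(read_id),
    target = as.character(target),
    pos = as.integer(pos),
    cigar = as.character(cigar),
    mapq = as.integer(mapq),
    flag = as.integer(flag),
    seq = as.character(seq),
    qual = as.character(qual),
    AS = as.numeric(AS),
    XS = as.numeric(XS),
    NM = as.integer(NM),
    MD = as.character(MD),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pg_alignments", "data.frame")
  out
}

SAM_FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
              reverse = 16L, mreverse = 32L, first = 64L, second = 128L,
              secondary = 256L, qcfail = 512L, duplicate = 1024L,
              supplementary = 2048L)

flag_has <- function(flag, bit) bitwAnd(flag, SAM_FLAG[[bit]]) != 0L
flag_set <- function(flag, bit) bitwOr(flag, SAM_FLAG[[bit]])
flag_clear <- function(flag, bit) bitwAnd(flag, bitwNot(SAM_FLAG[[bit]]))

#' @export
print.pg_alignments <- function(x, ...) {
  cat(sprintf("<pg_alignments> %d record(s), %d read(s)\n",
              nrow(x), length(unique(x$read_id))))
  NextMethod()
}

aln_strand <- function(flag) ifelse(flag_has(flag, "reverse"), "-", "+")

## End position (0-based, exclusive) of each alignment on its target.
aln_end <- function(aln) {
  aln$pos + vapply(aln$cigar,
                   function(cg) ref_width(cigar_to_script(cg)), integer(1),
                   USE.NAMES = FALSE)
}
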