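#' Alignment scoring schemes
#'
#' Parameters of the end-to-end alignment scoring reimplemented from the
#' short-read aligner the pipeline targets: a per-match bonus (0 end-to-end),
#' a base-quality-dependent mismatch penalty interpolated between
#' `mismatch_min` and `mismatch_max`, an ambiguous-base penalty, affine gap
#' penalties, and the linear minimum/perfect score functions of read length
#' used by the mapping-quality model.
#'
#' @param match_bonus per matched base (default 0, end-to-end).
#' @param mismatch_min,mismatch_max penalty bounds `MN`, `MX`; the penalty at
#'   base quality `q` is `MN + floor((MX - MN) * min(q, cap) / cap)`.
#' @param n_penalty penalty when read or reference base is `N`.
#' @param gap_open,gap_extend affine gap penalties; a gap of length `k`
#'   costs `gap_open + k * gap_extend`.
#' @param quality_cap base-quality ceiling `cap` (default 40).
#' @param min_score_intercept,min_score_slope minimum acceptable score as a
#'   linear function of read length (defaults `-0.6 - 0.6 * len`).
#' @param perfect_intercept,perfect_slope perfect score as a linear function
#'   of read length (0 end-to-end).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match_bonus = 0, mismatch_min = 2,
                           mismatch_max = 6, n_penalty = 1, gap_open = 5,
                           gap_extend = 3, quality_cap = 40,
                           min_score_intercept = -0.6,
                           min_score_slope = -0.6,
                           perfect_intercept = 0, perfect_slope = 0) {
  stopifnot(mismatch_max >= mismatch_min, mismatch_min >= 0,
            gap_open > 0, gap_extend > 0, quality_cap > 0)
  structure(list(match_bonus = match_bonus, mismatch_min = mismatch_min,
                 mismatch_max = mismatch_max, n_penalty = n_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 quality_cap = quality_cap,
                 min_score_intercept = min_score_intercept,
                 min_score_slope = min_score_slope,
                 perfect_intercept = perfect_intercept,
                 perfect_slope = perfect_slope),
            class = "scoring_scheme")
}

min_score <- function(scheme, read_length) {
  scheme$min_score_intercept + scheme$min_score_slope * read_length
}

perfect_score <- function(scheme, read_length) {
  scheme$perfect_intercept + scheme$perfect_slope * read_length
}

#' Score one alignment
#'
#' Recomputes the alignment score of a record from its CIGAR, read bases and
#' base qualities: `match_bonus` per matched base, the quality-scaled
#' mismatch penalty per mismatch, `n_penalty` per ambiguous base, and affine
#' penalties per gap run. Soft-clipped bases contribute nothing. Mismatch
#' positions are identified against the supplied reference sequence, or
#' reconstructed from the record's `MD` tag when no reference is given.
#'
#' @param rec a single-row [alignments()] table.
#' @param scheme a [scoring_scheme()].
#' @param reference the target's sequence (plain string), or `NULL` to use
#'   the `MD` tag.
#' @return numeric score.
#' @export
alignment_score <- function(rec, scheme = scoring_scheme(),
                            reference = NULL) {
  stopifnot(nrow(rec) == 1L)
  script <- cigar_to_script(rec$cigar)
  read <- toupper(rec$seq)
  quals <- if (is.na(rec$qual) || rec$qual == "*")
    rep(scheme$quality_cap, nchar(read))
  else utf8ToInt(rec$qual) - 33L

  ref_bases <- NULL
  if (!is.null(reference)) {
    ref_bases <- aligned_ref_bases(script, reference, rec$pos)
  } else if (!is.na(rec$MD)) {
    ref_bases <- md_ref_bases(script, read, rec$MD)
  } else {
    stop("cannot identify mismatches: supply a reference or an MD tag")
  }

  score <- 0
  q <- 0L
  ri <- 0L   # index into ref_bases (aligned columns only)
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      qb <- strsplit(substr(read, q + 1L, q + n), "")[[1L]]
      rb <- ref_bases[(ri + 1L):(ri + n)]
      qq <- quals[(q + 1L):(q + n)]
      amb <- qb == "N" | rb == "N"
      mism <- !amb & qb != rb
      mm_pen <- scheme$mismatch_min +
        floor((scheme$mismatch_max - scheme$mismatch_min) *
                pmin(qq, scheme$quality_cap) / scheme$quality_cap)
      score <- score +
        sum(!amb & !mism) * scheme$match_bonus -
        sum(mm_pen[mism]) -
        sum(amb) * scheme$n_penalty
      q <- q + n; ri <- ri + n
    } else if (op == "I") {
      score <- score - (scheme$gap_open + n * scheme$gap_extend)
      q <- q + n
    } else if (op %in% c("D", "N")) {
      if (op == "D")
        score <- score - (scheme$gap_open + n * scheme$gap_extend)
    } else if (op == "S") {
      q <- q + n
    }
  }
  score
}

## Reference bases under the aligned (M/=/X) columns, in alignment order.
aligned_ref_bases <- function(script, reference, pos) {
  r <- as.integer(pos)
  out <- character(0)
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, strsplit(toupper(substr(reference, r + 1L, r + n)),
                             "")[[1L]])
      r <- r + n
    } else if (op %in% c("D", "N")) {
      r <- r + n
    }
  }
  out
}

## Reconstruct aligned-column reference bases from the MD tag.
md_ref_bases <- function(script, read, md) {
  qb <- strsplit(read, "")[[1L]]
  # read bases under aligned columns, in order
  aligned_q <- character(0)
  q <- 0L
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      aligned_q <- c(aligned_q, qb[(q + 1L):(q + n)])
      q <- q + n
    } else if (op %in% c("I", "S")) {
      q <- q + n
    }
  }
  out <- aligned_q
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  i <- 0L
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      i <- i + as.integer(t)
    } else if (startsWith(t, "^")) {
      # deleted reference bases: not aligned columns, skip
    } else {
      i <- i + 1L
      out[i] <- toupper(t)
    }
  }
  out
}

#' Bowtie2-style mapping-quality model (end-to-end, max 42)
#'
#' A data-driven reimplementation of the piecewise mapping-quality function
#' used by the targeted aligner in end-to-end mode. With `diff = max(perfect
#' - min, 1)` and `bestOver = best - min`, a unique alignment's MAPQ depends
#' on where `bestOver` falls in `diff` fractions; with a second-best score
#' the gap `best - second` selects a row and `bestOver` a column. The
#' returned object carries the tables so alternative models can be swapped.
#'
#' @return an object of class `mapq_model`.
#' @export
mapq_model_bt2 <- function() {
  unique_tbl <- data.frame(
    frac = c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3, -Inf),
    mapq = c(42L, 40L, 24L, 23L, 8L, 3L, 0L))
  # one row per best-vs-second gap bin: MAPQ when best equals the perfect
  # score, and fallback thresholds on bestOver otherwise
  gap_tbl <- list(
    list(frac = 0.9, at_perfect = 39L, other = list(c(-Inf, 33L))),
    list(frac = 0.8, at_perfect = 38L, other = list(c(-Inf, 27L))),
    list(frac = 0.7, at_perfect = 37L, other = list(c(-Inf, 26L))),
    list(frac = 0.6, at_perfect = 36L, other = list(c(-Inf, 22L))),
    list(frac = 0.5, at_perfect = 35L,
         other = list(c(0.84, 25L), c(0.68, 16L), c(-Inf, 5L))),
    list(frac = 0.4, at_perfect = 34L,
         other = list(c(0.84, 21L), c(0.68, 14L), c(-Inf, 4L))),
    list(frac = 0.3, at_perfect = 32L,
         other = list(c(0.88, 18L), c(0.67, 15L), c(-Inf, 3L))),
    list(frac = 0.2, at_perfect = 31L,
         other = list(c(0.88, 17L), c(0.67, 11L), c(-Inf, 0L))),
    list(frac = 0.1, at_perfect = 30L,
         other = list(c(0.88, 12L), c(0.67, 7L), c(-Inf, 0L))),
    list(frac = 0,   at_perfect = NA,
         other = list(c(0.67, 6L), c(-Inf, 2L))),   # gap > 0
    list(frac = -Inf, at_perfect = NA,
         other = list(c(0.67, 1L), c(-Inf, 0L))))   # gap == 0
  structure(list(name = "bowtie2-v3-end-to-end", max_mapq = 42L,
                 unique_tbl = unique_tbl, gap_tbl = gap_tbl),
            class = "mapq_model")
}

#' Compute a MAPQ from best/second-best scores
#'
#' @param model a [mapq_model_bt2()]-style model.
#' @param best best alignment score.
#' @param second second-best score, or `NA` for a unique alignment.
#' @param minimum minimum acceptable score for the read length.
#' @param perfect perfect score for the read length.
#' @return integer MAPQ in `[0, model$max_mapq]`.
#' @export
mapq_compute <- function(model, best, second, minimum, perfect) {
  diff <- max(perfect - minimum, 1)
  best_over <- best - minimum
  at_perfect <- abs(best_over - diff) < 1e-9
  pick_other <- function(other) {
    for (row in other)
      if (best_over >= row[1L] * diff) return(as.integer(row[2L]))
    0L
  }
  if (is.na(second)) {
    hit <- which(best_over >= model$unique_tbl$frac * diff)[1L]
    ret <- model$unique_tbl$mapq[hit]
  } else {
    gap <- abs(best - second)
    ret <- 0L
    for (row in model$gap_tbl) {
      sel <- if (is.infinite(row$frac)) TRUE
             else if (row$frac == 0) gap > 0
             else gap >= row$frac * diff
      if (sel) {
        ret <- if (at_perfect && !is.na(row$at_perfect)) row$at_perfect
               else pick_other(row$other)
        break
      }
    }
  }
  max(0L, min(as.integer(ret), model$max_mapq))
}

#' Partition one read's projected alignments by placement
#'
#' Matching founder regions can be identical, so one read can have several
#' equally scored alignments that project to the same leftmost reference
#' coordinate; an aligner unaware of the projection assigns them all a very
#' low mapping quality. Grouping the alignments by (target, projected
#' leftmost, strand) restores placement uniqueness: each group keeps its
#' best-scoring member as representative.
#'
#' @param aln [alignments()] rows of a single read, already projected.
#' @param scores numeric alignment scores parallel to `aln` rows.
#' @return list of partitions ordered by representative score (descending),
#'   each with `rows` (row indices), `rep` (representative row index) and
#'   `rep_score`.
#' @export
partition_alignments <- function(aln, scores) {
  if (nrow(aln) == 0L) return(list())
  if (length(unique(aln$read_id)) != 1L)
    stop("partition_alignments expects the alignments of one read")
  key <- paste(aln$target, aln$pos, aln_strand(aln$flag), sep = "\r")
  parts <- split(seq_len(nrow(aln)), factor(key, levels = unique(key)))
  out <- lapply(parts, function(rows) {
    rep_row <- rows[which.max(scores[rows])]   # tie -> first in input order
    list(rows = rows, rep = rep_row, rep_score = scores[rep_row])
  })
  out[order(-vapply(out, `[[`, numeric(1), "rep_score"))]
}

#' Recalculate mapping qualities over alignment partitions
#'
#' Feeds the representative scores of the best and second-best partitions to
#' the mapping-quality model. All members of the best partition receive the
#' recalculated MAPQ; members of other partitions get MAPQ 0 and the
#' secondary flag.
#'
#' @param aln [alignments()] rows of one read.
#' @param scores numeric scores parallel to rows.
#' @param partitions result of [partition_alignments()].
#' @param scheme a [scoring_scheme()].
#' @param model a [mapq_model_bt2()]-style model.
#' @return `aln` with updated `mapq`, `AS` and secondary flags.
#' @export
recalculate_mapq <- function(aln, scores,
                             partitions = partition_alignments(aln, scores),
                             scheme = scoring_scheme(),
                             model = mapq_model_bt2()) {
  if (!length(partitions)) return(aln)
  read_length <- nchar(aln$seq[1L])
  best <- partitions[[1L]]$rep_score
  second <- if (length(partitions) >= 2L) partitions[[2L]]$rep_score
            else NA_real_
  q <- mapq_compute(model, best, second,
                    min_score(scheme, read_length),
                    perfect_score(scheme, read_length))
  aln$AS <- scores
  aln$mapq <- 0L
  aln$mapq[partitions[[1L]]$rows] <- q
  for (i in seq_along(partitions)) {
    rows <- partitions[[i]]$rows
    aln$flag[rows] <- if (i == 1L)
      flag_clear(aln$flag[rows], "secondary")
    else flag_set(aln$flag[rows], "secondary")
  }
  if (length(partitions) >= 2L)
    aln$XS[partitions[[1L]]$rows] <- second
  aln
}

#' Rescore and recalculate MAPQ for a whole alignment table
#'
#' Groups projected records by read, recomputes alignment scores against the
#' reference, partitions by projected placement and applies the
#' mapping-quality model. Unmapped records pass through with MAPQ 0.
#'
#' @param aln projected [alignments()] table (any number of reads).
#' @param reference reference sequence (plain string).
#' @param scheme a [scoring_scheme()].
#' @param model a [mapq_model_bt2()]-style model.
#' @return the updated alignments table.
#' @export
rescore_alignments <- function(aln, reference, scheme = scoring_scheme(),
                               model = mapq_model_bt2()) {
  mapped <- !flag_has(aln$flag, "unmapped")
  idx <- split(which(mapped), aln$read_id[mapped])
  for (rows in idx) {
    sub <- aln[rows, , drop = FALSE]
    scores <- vapply(seq_len(nrow(sub)), function(i)
      alignment_score(sub[i, , drop = FALSE], scheme, reference),
      numeric(1))
    aln[rows, ] <- recalculate_mapq(sub, scores, scheme = scheme,
                                    model = model)
  }
  aln$mapq[!mapped] <- 0L
  aln
}

#' Keep each read's maximum-MAPQ alignment (MM filtering)
#'
#' Retains one record per read: highest MAPQ, ties broken by higher
#' alignment score (`AS`), then lowest (target, position). The kept record's
#' secondary flag is cleared. Unmapped-only reads keep their unmapped record.
#'
#' @param aln an [alignments()] table.
#' @return filtered alignments table, one row per read.
#' @export
filter_max_mapq <- function(aln) {
  pick <- function(rows) {
    sub <- aln[rows, , drop = FALSE]
    as_key <- ifelse(is.na(sub$AS), -Inf, sub$AS)
    ord <- order(-sub$mapq, -as_key, sub$target, sub$pos)
    rows[ord[1L]]
  }
  keep <- vapply(split(seq_len(nrow(aln)), aln$read_id), pick, integer(1))
  out <- aln[sort(keep), , drop = FALSE]
  out$flag <- flag_clear(out$flag, "secondary")
  class(out) <- c("pg_alignments", "data.frame")
  out
}
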