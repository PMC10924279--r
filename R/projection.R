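#' Reference-guided multiple sequence alignments
#'
#' A `ref_msa` holds equal-length gapped rows over `{A,C,G,T,N,-}`: the
#' reference row plus one row per alternative sequence (founder or donor
#' haplotype). It is the sole input the coordinate projection needs.
#'
#' @param rows named character vector of gapped rows.
#' @param reference_name name of the reference row.
#' @return an object of class `ref_msa`.
#' @export
ref_msa <- function(rows, reference_name) {
  rows <- toupper(rows)
  if (is.null(names(rows)) || anyNA(names(rows)))
    stop("MSA rows must be named")
  if (!reference_name %in% names(rows))
    stop("reference row '", reference_name, "' not present")
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows must have equal length")
  if (any(grepl("[^ACGTN-]", rows)))
    stop("MSA rows may only contain A, C, G, T, N and '-'")
  if (!grepl("[ACGTN]", rows[[reference_name]]))
    stop("reference row has no non-gap symbol")
  structure(list(rows = rows, reference_name = reference_name),
            class = "ref_msa")
}

#' @export
print.ref_msa <- function(x, ...) {
  cat(sprintf("<ref_msa> %d row(s) x %d column(s); reference: %s\n",
              length(x$rows), nchar(x$rows[[1L]]), x$reference_name))
  invisible(x)
}

## Ungapped sequence of one MSA row.
msa_ungap <- function(msa, name) gsub("-", "", msa$rows[[name]], fixed = TRUE)

#' Read/write an aligned FASTA as a `ref_msa`
#'
#' @param path aligned FASTA path (gap character `-`).
#' @param reference_name name of the reference row; defaults to the first
#'   record.
#' @return a [ref_msa()].
#' @export
read_msa <- function(path, reference_name = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  rows <- as.character(x)
  names(rows) <- sub("\\s.*", "", names(x))
  if (is.null(reference_name)) reference_name <- names(rows)[1L]
  ref_msa(rows, reference_name)
}

#' Coordinate projection index from an MSA
#'
#' For each ungapped position `f` of one founder row, stores the projected
#' 0-based reference position and whether the MSA column is an insertion
#' relative to the reference (reference row holds a gap there). For insertion
#' columns the stored position is the number of reference bases strictly
#' before the column. Built in a single left-to-right column walk.
#'
#' @param msa a [ref_msa()].
#' @param founder_name a non-reference row name.
#' @return an object of class `projection_index`.
#' @examples
#' m <- ref_msa(c(ref = "AC--GT", f = "ACTTG-"), "ref")
#' idx <- build_projection_index(m, "f")
#' project_position(idx, 3)  # inside the insertion
#' @export
build_projection_index <- function(msa, founder_name) {
  stopifnot(inherits(msa, "ref_msa"))
  if (!founder_name %in% names(msa$rows))
    stop("unknown founder row '", founder_name, "'")
  if (founder_name == msa$reference_name)
    stop("'", founder_name, "' is the reference row")
  refv <- strsplit(msa$rows[[msa$reference_name]], "")[[1L]]
  fv <- strsplit(msa$rows[[founder_name]], "")[[1L]]
  ref_base <- refv != "-"
  cum <- cumsum(ref_base)
  fmask <- fv != "-"
  structure(list(
    founder_name = founder_name,
    reference_name = msa$reference_name,
    ref_pos = ifelse(ref_base, cum - 1L, cum)[fmask],
    in_insertion = !ref_base[fmask],
    ref_length = sum(ref_base),
    founder_length = sum(fmask)
  ), class = "projection_index")
}

#' @export
print.projection_index <- function(x, ...) {
  cat(sprintf(
    "<projection_index> %s (%d bp) -> %s (%d bp); %d inserted base(s)\n",
    x$founder_name, x$founder_length, x$reference_name, x$ref_length,
    sum(x$in_insertion)))
  invisible(x)
}

#' Project a single founder position
#'
#' @param index a [build_projection_index()] result.
#' @param f_pos 0-based ungapped founder position(s).
#' @return a data frame with `ref_pos` (0-based) and `in_insertion`.
#' @export
project_position <- function(index, f_pos) {
  if (any(f_pos < 0L) || any(f_pos >= index$founder_length))
    stop("founder position out of range [0, ", index$founder_length, ")")
  data.frame(ref_pos = index$ref_pos[f_pos + 1L],
             in_insertion = index$in_insertion[f_pos + 1L])
}

#' Rewrite an edit script from founder to reference coordinates
#'
#' Composes a read-vs-founder edit script with the founder-vs-reference gap
#' structure held by the projection index. Founder bases aligned by
#' `M`/`=`/`X` that fall in insertion columns become `I`; reference bases
#' skipped where the founder row has gaps become `D`; a read `I` stays `I`;
#' a read `D` over inserted founder bases is elided (consumes neither side);
#' clips are preserved. Runtime is linear in the script length plus the MSA
#' columns spanned. The result is normalized with [normalize_projected()]
#' unless `normalize = FALSE`.
#'
#' @param script an [edit_script()] in founder coordinates.
#' @param index a [build_projection_index()] result.
#' @param founder_leftmost 0-based leftmost aligned founder position.
#' @param normalize normalize the rewritten script (default `TRUE`).
#' @return a list with `ref_leftmost` (0-based, `NA` when the alignment
#'   covers no reference base at all) and `script`.
#' @export
project_edit_script <- function(script, index, founder_leftmost,
                                normalize = TRUE) {
  f <- as.integer(founder_leftmost)
  if (f < 0L) stop("founder_leftmost must be >= 0")
  acc_o <- vector("list", length(script$ops) * 2L)
  acc_l <- vector("list", length(script$ops) * 2L)
  na <- 0L
  app <- function(o, l) {
    na <<- na + 1L
    acc_o[[na]] <<- o
    acc_l[[na]] <<- l
  }
  last_ref <- NA_integer_
  ref_left <- NA_integer_

  for (k in seq_along(script$ops)) {
    op <- script$ops[k]
    n <- script$lengths[k]
    if (op %in% c("S", "H", "P")) { app(op, n); next }
    if (op == "I") { app("I", n); next }
    if (!op %in% c("M", "=", "X", "D", "N"))
      stop("cannot project operation '", op, "'")
    if (f + n > index$founder_length)
      stop("alignment overruns founder end (position ", f + n, " > ",
           index$founder_length, ")")
    ii <- (f + 1L):(f + n)
    rp <- index$ref_pos[ii]
    ins <- index$in_insertion[ii]
    consumes_read <- op %in% c("M", "=", "X")
    mids <- which(!ins)

    # per-base stream: an optional D run (reference bases the founder row
    # skips) before each mapped base, then the base's own op
    base_op <- rep(if (consumes_read) "I" else NA_character_, n)
    base_op[mids] <- op
    dgap <- integer(n)
    if (length(mids)) {
      rpm <- rp[mids]
      prior <- c(last_ref, rpm[-length(rpm)])
      dg <- rpm - prior - 1L
      if (is.na(last_ref)) dg[1L] <- 0L
      dgap[mids] <- dg
      if (is.na(ref_left)) ref_left <- rpm[1L]
      last_ref <- rpm[length(rpm)]
    }
    o2 <- as.vector(rbind(rep("D", n), base_op))
    l2 <- as.vector(rbind(dgap, rep(1L, n)))
    keep <- !is.na(o2) & l2 > 0L
    if (any(keep)) app(o2[keep], l2[keep])
    f <- f + n
  }

  out <- script_merge(edit_script(unlist(acc_o[seq_len(na)]),
                                  unlist(acc_l[seq_len(na)])))
  if (normalize) out <- normalize_projected(out)
  list(ref_leftmost = ref_left, script = out)
}

#' Normalize a projected edit script
#'
#' Applies, in order: (1) adjacent `I`/`D` (or `D`/`I`) runs are paired
#' base-for-base into `M` up to the shorter length, keeping any remainder,
#' repeated until stable (a deterministic stand-in for local realignment);
#' (2) adjacent runs of the same operation are merged; (3) leading/trailing
#' `I` runs become soft clips, since SAM cannot anchor an alignment on an
#' insertion; (4) with a reference and `extended = TRUE`, `M` runs are
#' re-split into `=`/`X` by base comparison — otherwise `=`/`X` collapse to
#' `M`. The function is idempotent.
#'
#' @param script an [edit_script()].
#' @param read read sequence (needed only for `extended = TRUE`).
#' @param reference reference sequence (needed only for `extended = TRUE`).
#' @param ref_leftmost 0-based leftmost reference position (for `extended`).
#' @param extended emit `=`/`X` instead of `M`.
#' @return a normalized [edit_script()].
#' @export
normalize_projected <- function(script, read = NULL, reference = NULL,
                                ref_leftmost = NULL, extended = FALSE) {
  cur <- script_merge(script)
  # (1) pair adjacent I/D into M
  repeat {
    ops <- cur$ops
    hit <- which(ops[-length(ops)] %in% c("I", "D") &
                   ops[-1L] %in% c("I", "D") &
                   ops[-length(ops)] != ops[-1L])
    if (!length(hit)) break
    i <- hit[1L]
    l1 <- cur$lengths[i]; l2 <- cur$lengths[i + 1L]
    m <- min(l1, l2)
    mid_ops <- c("M",
                 if (l1 > m) ops[i],
                 if (l2 > m) ops[i + 1L])
    mid_len <- c(m,
                 if (l1 > m) l1 - m,
                 if (l2 > m) l2 - m)
    cur <- script_merge(edit_script(
      c(ops[seq_len(i - 1L)], mid_ops, ops[-seq_len(i + 1L)]),
      c(cur$lengths[seq_len(i - 1L)], mid_len,
        cur$lengths[-seq_len(i + 1L)])))
  }
  # (3) boundary insertions become soft clips
  ops <- cur$ops
  inner <- which(!ops %in% c("S", "H"))
  if (length(inner)) {
    if (ops[inner[1L]] == "I") ops[inner[1L]] <- "S"
    inner <- which(!ops %in% c("S", "H"))
    if (length(inner) && ops[inner[length(inner)]] == "I")
      ops[inner[length(inner)]] <- "S"
  }
  cur <- script_merge(edit_script(ops, cur$lengths))
  # (4) op granularity
  if (extended) {
    if (is.null(read) || is.null(reference) || is.null(ref_leftmost))
      stop("extended CIGAR requires read, reference and ref_leftmost")
    cur <- split_matches(cur, read, reference, ref_leftmost)
  } else {
    ops <- cur$ops
    ops[ops %in% c("=", "X")] <- "M"
    cur <- script_merge(edit_script(ops, cur$lengths))
  }
  cur
}

## Re-split M runs into =/X by comparing read and reference bases.
split_matches <- function(script, read, reference, ref_leftmost) {
  q <- 0L; r <- as.integer(ref_leftmost)
  o <- character(0); l <- integer(0)
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      rb <- strsplit(substr(reference, r + 1L, r + n), "")[[1L]]
      qb <- strsplit(substr(read, q + 1L, q + n), "")[[1L]]
      eq <- ifelse(toupper(qb) == toupper(rb), "=", "X")
      rl <- rle(eq)
      o <- c(o, rl$values); l <- c(l, rl$lengths)
      q <- q + n; r <- r + n
    } else {
      o <- c(o, op); l <- c(l, n)
      if (op %in% c("I", "S")) q <- q + n
      if (op %in% c("D", "N")) r <- r + n
    }
  }
  script_merge(edit_script(o, l))
}

#' Project one alignment record to reference coordinates
#'
#' Rewrites the record's position and CIGAR from founder to reference
#' coordinates, renames the target to the reference, and recomputes `NM`/`MD`
#' when the reference sequence is supplied (they are dropped otherwise, to
#' avoid stale values). An alignment lying wholly inside a founder-only
#' insertion covers no reference base and is returned flagged unmapped rather
#' than dropped, preserving read accounting. The `AS` tag is preserved.
#'
#' @param rec a single-row [alignments()] table.
#' @param index a [build_projection_index()] result.
#' @param reference optional reference sequence (plain string).
#' @param extended emit `=`/`X` CIGARs (requires `reference`).
#' @return the projected single-row alignments table.
#' @export
project_alignment <- function(rec, index, reference = NULL,
                              extended = FALSE) {
  stopifnot(nrow(rec) == 1L)
  if (flag_has(rec$flag, "unmapped"))
    stop("record is unmapped; nothing to project")
  if (rec$target != index$founder_name)
    stop("record target '", rec$target, "' does not match index founder '",
         index$founder_name, "'")
  script <- cigar_to_script(rec$cigar)
  pr <- project_edit_script(script, index, rec$pos, normalize = FALSE)
  out <- rec
  out$target <- index$reference_name
  if (is.na(pr$ref_leftmost)) {
    out$flag <- flag_set(rec$flag, "unmapped")
    out$pos <- NA_integer_
    out$cigar <- "*"
    out$mapq <- 0L
    out$NM <- NA_integer_
    out$MD <- NA_character_
    return(out)
  }
  norm <- normalize_projected(pr$script, read = rec$seq,
                              reference = reference,
                              ref_leftmost = pr$ref_leftmost,
                              extended = extended)
  out$pos <- pr$ref_leftmost
  out$cigar <- script_to_cigar(norm)
  if (!is.null(reference)) {
    tags <- compute_nm_md(norm, rec$seq, reference, pr$ref_leftmost)
    out$NM <- tags$NM
    out$MD <- tags$MD
  } else {
    out$NM <- NA_integer_
    out$MD <- NA_character_
  }
  out
}

#' @rdname project_alignment
#' @param aln a multi-row [alignments()] table, all on the index's founder.
#' @export
project_alignments <- function(aln, index, reference = NULL,
                               extended = FALSE) {
  rows <- lapply(seq_len(nrow(aln)), function(i)
    project_alignment(aln[i, , drop = FALSE], index, reference, extended))
  out <- do.call(rbind, rows)
  class(out) <- c("pg_alignments", "data.frame")
  out
}

## NM (edit distance) and MD tag from a normalized script + reference.
compute_nm_md <- function(script, read, reference, ref_leftmost) {
  q <- 0L; r <- as.integer(ref_leftmost)
  nm <- 0L
  md <- character(0)
  run_match <- 0L
  flush <- function() {
    md <<- c(md, as.character(run_match))
    run_match <<- 0L
  }
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      rb <- strsplit(substr(reference, r + 1L, r + n), "")[[1L]]
      qb <- strsplit(substr(read, q + 1L, q + n), "")[[1L]]
      same <- toupper(rb) == toupper(qb)
      for (i in seq_len(n)) {
        if (same[i]) run_match <- run_match + 1L
        else { flush(); md <- c(md, rb[i]); nm <- nm + 1L }
      }
      q <- q + n; r <- r + n
    } else if (op == "I") {
      nm <- nm + n; q <- q + n
    } else if (op %in% c("D", "N")) {
      if (op == "D") {
        flush()
        md <- c(md, paste0("^", substr(reference, r + 1L, r + n)))
        nm <- nm + n
      }
      r <- r + n
    } else if (op == "S") {
      q <- q + n
    }
  }
  flush()
  list(NM = nm, MD = paste(md, collapse = ""))
}
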