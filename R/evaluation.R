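#' Heterozygous variant site tables
#'
#' @param contig,pos,ref,alt site fields; `pos` is 0-based.
#' @return a `variant_sites` data frame with a `length_diff` column
#'   (`nchar(alt) - nchar(ref)`).
#' @export
variant_sites <- function(contig, pos, ref, alt) {
  out <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    stringsAsFactors = FALSE)
  if (any(nchar(out$ref) == 0L) || any(nchar(out$alt) == 0L))
    stop("alleles must be non-empty")
  out$length_diff <- nchar(out$alt) - nchar(out$ref)
  class(out) <- c("variant_sites", "data.frame")
  out
}

#' Per-site allele balance from a pileup
#'
#' For each heterozygous site, counts the aligned reads supporting the
#' reference allele (`R`) and the correct alternative allele (`A`) and
#' reports the balance `R / (R + A)`. A read contributes only if its
#' alignment fully encloses the site: at least one aligned (`M`/`=`/`X`)
#' reference base strictly before the site start and at least one at or
#' after the site end. Sites with coverage below `min_coverage` (enclosing
#' reads, whether or not they support either allele) are excluded, as are
#' sites where `R + A = 0`.
#'
#' Allele support is called on the expanded alignment: the read bases laid
#' over the site's reference span (including insertions anchored strictly
#' inside the span or at its right edge) must reproduce the reference or the
#' alternative allele exactly; reads reproducing neither count toward
#' coverage only.
#'
#' @param aln projected [alignments()] on reference coordinates.
#' @param sites a [variant_sites()] table, sorted by position.
#' @param min_coverage minimum enclosing-read coverage (default 20).
#' @return a `balance_table` data frame with columns `contig`, `pos`, `ref`,
#'   `alt`, `length_diff`, `coverage`, `R`, `A` and `balance`.
#' @export
pileup_balance <- function(aln, sites, min_coverage = 20L) {
  if (nrow(sites) > 1L && is.unsorted(sites$pos, strictly = FALSE))
    stop("sites must be sorted by position")
  aln <- aln[!flag_has(aln$flag, "unmapped"), , drop = FALSE]
  starts <- aln$pos
  scripts <- lapply(aln$cigar, cigar_to_script)
  ends <- starts + vapply(scripts, ref_width, integer(1))

  rows <- vector("list", nrow(sites))
  for (j in seq_len(nrow(sites))) {
    p <- sites$pos[j]
    e <- p + nchar(sites$ref[j])
    cand <- which(aln$target == sites$contig[j] & starts < p & ends > e)
    if (!length(cand)) next
    R <- 0L; A <- 0L; cov <- 0L
    for (i in cand) {
      ext <- site_read_bases(scripts[[i]], aln$seq[i], starts[i], p, e)
      if (!ext$enclosed) next
      cov <- cov + 1L
      if (ext$bases == sites$ref[j]) R <- R + 1L
      else if (ext$bases == sites$alt[j]) A <- A + 1L
    }
    if (cov >= min_coverage && (R + A) > 0L)
      rows[[j]] <- data.frame(contig = sites$contig[j], pos = p,
                              ref = sites$ref[j], alt = sites$alt[j],
                              length_diff = sites$length_diff[j],
                              coverage = cov, R = R, A = A,
                              balance = R / (R + A))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      length_diff = integer(0), coverage = integer(0),
                      R = integer(0), A = integer(0), balance = numeric(0))
  class(out) <- c("balance_table", "data.frame")
  out
}

## Read bases laid over the reference span [p, e), plus enclosure check:
## >= 1 aligned base strictly before p and >= 1 at or after e.
site_read_bases <- function(script, seq, start, p, e) {
  r <- as.integer(start)   # reference cursor
  q <- 0L                  # read cursor
  bases <- character(0)
  aligned_before <- FALSE
  aligned_after <- FALSE
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]; n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      rpos <- r:(r + n - 1L)
      if (any(rpos < p)) aligned_before <- TRUE
      if (any(rpos >= e)) aligned_after <- TRUE
      inside <- rpos >= p & rpos < e
      if (any(inside))
        bases <- c(bases,
                   strsplit(substr(seq, q + 1L, q + n), "")[[1L]][inside])
      r <- r + n; q <- q + n
    } else if (op == "I") {
      # insertion anchored between r-1 and r: belongs to the site when the
      # anchor lies strictly inside the span or at its right edge
      if (r > p && r <= e)
        bases <- c(bases, strsplit(substr(seq, q + 1L, q + n), "")[[1L]])
      q <- q + n
    } else if (op %in% c("D", "N")) {
      r <- r + n
    } else if (op == "S") {
      q <- q + n
    }
  }
  list(bases = paste(bases, collapse = ""),
       enclosed = aligned_before && aligned_after)
}

#' Mean absolute error of balances around 0.5
#'
#' `(1/n) * sum(|x_i - 0.5|)` over the per-site balances `x_i`. With reads
#' simulated in equal numbers from both haplotypes the balances should sit
#' near 0.5; deviation summarizes reference bias.
#'
#' @param balances numeric vector of balances in `[0, 1]`.
#' @return the mean absolute error, in `[0, 0.5]`.
#' @export
mean_absolute_error <- function(balances) {
  if (!length(balances)) stop("no balances supplied")
  mean(abs(balances - 0.5))
}

#' Summarize balances by allele length difference
#'
#' Buckets a balance table by `length_diff` (alternative minus reference
#' allele length: negative = deletion, 0 = SNP, positive = insertion) and
#' reports per bucket the site count, median, quartiles and mean absolute
#' error, plus the overall MAE.
#'
#' @param table a [pileup_balance()] result.
#' @return list with `by_diff` (one row per length difference) and
#'   `overall_mae`.
#' @export
balance_by_length_diff <- function(table) {
  if (!nrow(table)) stop("empty balance table")
  groups <- split(table$balance, table$length_diff)
  by_diff <- data.frame(
    length_diff = as.integer(names(groups)),
    n = lengths(groups),
    median = vapply(groups, stats::median, numeric(1)),
    q1 = vapply(groups, function(x) unname(stats::quantile(x, 0.25)),
                numeric(1)),
    q3 = vapply(groups, function(x) unname(stats::quantile(x, 0.75)),
                numeric(1)),
    mae = vapply(groups, mean_absolute_error, numeric(1)),
    row.names = NULL)
  by_diff <- by_diff[order(by_diff$length_diff), , drop = FALSE]
  list(by_diff = by_diff, overall_mae = mean_absolute_error(table$balance))
}

#' Alignment precision and recall against truth positions
#'
#' An alignment is a true positive when its leftmost position is within
#' `tolerance` bases of the read's true position on the correct contig. A
#' read aligned elsewhere counts as a false positive and a false negative; a
#' read unaligned or missing counts as a false negative only, so
#' `TP + FN` always equals the number of reads in the truth table.
#'
#' @param aln [alignments()] with at most one evaluated placement per read.
#' @param truth data frame with `read_id`, `contig`, `pos` (0-based true
#'   leftmost) and `strand`.
#' @param tolerance maximum distance, in bases, for a true positive
#'   (default 5).
#' @return list with `precision`, `recall`, `TP`, `FP`, `FN` and `n_reads`.
#' @export
alignment_precision_recall <- function(aln, truth, tolerance = 5L) {
  if (anyDuplicated(truth$read_id))
    stop("truth table has duplicate read ids")
  if (anyDuplicated(aln$read_id))
    stop("more than one placement per read; filter alignments first")
  hit <- match(truth$read_id, aln$read_id)
  placed <- !is.na(hit) & !flag_has(aln$flag[hit], "unmapped") &
    !is.na(aln$pos[hit])
  tp_ok <- placed &
    aln$target[hit] == truth$contig &
    abs(aln$pos[hit] - truth$pos) <= tolerance
  TP <- sum(tp_ok, na.rm = TRUE)
  FP <- sum(placed & !tp_ok, na.rm = TRUE)
  FN <- nrow(truth) - TP
  list(precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = TP / nrow(truth),
       TP = TP, FP = FP, FN = FN, n_reads = nrow(truth))
}
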