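# Independent oracles used by the property tests. These deliberately take a
# different route from the package implementation: the projection oracle
# composes alignments column by column over the MSA instead of walking a
# precomputed index, and the scoring oracle expands the alignment into
# per-base columns before summing penalties.

# Compose a read-vs-founder edit script with the founder-vs-reference MSA,
# one MSA column at a time. Returns the unnormalized projected script and
# the 0-based reference leftmost (NA when no reference base is covered).
oracle_project <- function(ref_row, founder_row, script, founder_leftmost) {
  refv <- strsplit(ref_row, "")[[1L]]
  fv <- strsplit(founder_row, "")[[1L]]
  fcols <- which(fv != "-")            # MSA column of each founder base
  ref_before <- cumsum(refv != "-")    # ref bases up to and incl. column

  ops <- character(0)
  lens <- integer(0)
  emit <- function(o) { ops <<- c(ops, o); lens <<- c(lens, 1L) }

  f <- founder_leftmost                # 0-based founder cursor
  last_ref_col <- NA_integer_          # column of last reference-consuming op
  ref_left <- NA_integer_
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]
    n <- script$lengths[k]
    if (op %in% c("S", "H")) { ops <- c(ops, op); lens <- c(lens, n); next }
    if (op == "I") { ops <- c(ops, "I"); lens <- c(lens, n); next }
    for (u in seq_len(n)) {
      col <- fcols[f + 1L]
      ref_here <- refv[col] != "-"
      if (ref_here) {
        # reference bases in founder-gap columns between two consumed
        # reference bases are deletions; skipped columns before the first
        # consumed reference base are upstream of the alignment
        if (!is.na(last_ref_col) && col > last_ref_col + 1L) {
          skipped <- sum(refv[(last_ref_col + 1L):(col - 1L)] != "-")
          if (skipped > 0L) { ops <- c(ops, "D"); lens <- c(lens, skipped) }
        }
        emit(op)
        if (is.na(ref_left)) ref_left <- ref_before[col] - 1L
        last_ref_col <- col
      } else if (op %in% c("M", "=", "X")) {
        emit("I")
      }
      # a founder base in an insertion column deleted from the read
      # consumes neither read nor reference -> elided
      f <- f + 1L
    }
  }
  list(ref_leftmost = ref_left,
       script = panproject:::script_merge(edit_script(ops, lens)))
}

# Brute-force rescoring: expand the alignment into aligned base pairs and
# gap runs, then sum bonuses and penalties term by term.
oracle_score <- function(rec, scheme, reference) {
  script <- cigar_to_script(rec$cigar)
  read <- strsplit(toupper(rec$seq), "")[[1L]]
  quals <- if (is.na(rec$qual) || rec$qual == "*")
    rep(scheme$quality_cap, length(read))
  else utf8ToInt(rec$qual) - 33L
  refv <- strsplit(toupper(reference), "")[[1L]]
  q <- 0L
  r <- rec$pos
  total <- 0
  for (k in seq_along(script$ops)) {
    op <- script$ops[k]
    n <- script$lengths[k]
    if (op %in% c("M", "=", "X")) {
      for (u in seq_len(n)) {
        qb <- read[q + u]
        rb <- refv[r + u]
        if (qb == "N" || rb == "N") {
          total <- total - scheme$n_penalty
        } else if (qb == rb) {
          total <- total + scheme$match_bonus
        } else {
          qq <- min(quals[q + u], scheme$quality_cap)
          total <- total - (scheme$mismatch_min +
            floor((scheme$mismatch_max - scheme$mismatch_min) * qq /
                    scheme$quality_cap))
        }
      }
      q <- q + n
      r <- r + n
    } else if (op == "I") {
      total <- total - (scheme$gap_open + n * scheme$gap_extend)
      q <- q + n
    } else if (op == "D") {
      total <- total - (scheme$gap_open + n * scheme$gap_extend)
      r <- r + n
    } else if (op == "N") {
      r <- r + n
    } else if (op == "S") {
      q <- q + n
    }
  }
  total
}

# Exhaustive minimum segmentation on tiny panels: smallest number of
# segments such that every segment spans >= min_sites sites and has at most
# `cap` distinct haplotype strings. Returns Inf when impossible.
oracle_min_segments <- function(m, cap, min_sites) {
  ns <- ncol(m)
  distinct <- function(a, b)
    length(unique(apply(m[, a:b, drop = FALSE], 1L, paste, collapse = ",")))
  best <- rep(Inf, ns + 1L)
  best[1L] <- 0
  for (e in seq_len(ns)) {
    for (s in seq_len(e)) {
      if (e - s + 1L < min_sites && !(s == 1L && e == ns && ns < min_sites))
        next
      if (distinct(s, e) > cap) next
      best[e + 1L] <- min(best[e + 1L], best[s] + 1)
    }
  }
  best[ns + 1L]
}

# Random MSA (reference + one founder) for projection properties.
random_msa <- function(n_cols = sample(10:60, 1L)) {
  bases <- c("A", "C", "G", "T")
  refv <- character(n_cols)
  fv <- character(n_cols)
  for (j in seq_len(n_cols)) {
    kind <- sample(c("both", "ref_only", "founder_only"), 1L,
                   prob = c(0.7, 0.15, 0.15))
    refv[j] <- if (kind == "founder_only") "-" else sample(bases, 1L)
    fv[j] <- if (kind == "ref_only") "-" else sample(bases, 1L)
  }
  # both rows need at least one base
  if (all(refv == "-")) refv[sample(n_cols, 1L)] <- "A"
  if (all(fv == "-")) fv[sample(n_cols, 1L)] <- "A"
  ref_msa(c(ref = paste(refv, collapse = ""),
            founder = paste(fv, collapse = "")), "ref")
}

# Random read-vs-founder edit script fitting within founder_length bases
# starting at a random leftmost. Starts and ends with an aligned base.
random_alignment <- function(founder_length) {
  f0 <- sample.int(max(founder_length - 2L, 1L), 1L) - 1L
  avail <- founder_length - f0
  ops <- "M"
  lens <- sample.int(min(3L, avail), 1L)
  used <- lens                                   # founder bases consumed
  while (used < avail && stats::runif(1) < 0.6) {
    nxt <- sample(c("M", "I", "D"), 1L, prob = c(0.6, 0.2, 0.2))
    n <- sample.int(3L, 1L)
    if (nxt != "I") n <- min(n, avail - used)
    if (n == 0L) break
    ops <- c(ops, nxt)
    lens <- c(lens, n)
    if (nxt != "I") used <- used + n
  }
  if (ops[length(ops)] != "M") {                 # end on an aligned base
    if (used < avail) {
      ops <- c(ops, "M")
      lens <- c(lens, 1L)
      used <- used + 1L
    } else {
      while (length(ops) && ops[length(ops)] != "M") {
        if (ops[length(ops)] != "I") used <- used - lens[length(ops)]
        ops <- ops[-length(ops)]
        lens <- lens[-length(lens)]
      }
    }
  }
  if (stats::runif(1) < 0.2) { ops <- c("S", ops); lens <- c(2L, lens) }
  if (stats::runif(1) < 0.2) { ops <- c(ops, "S"); lens <- c(lens, 1L) }
  list(script = panproject:::script_merge(edit_script(ops, lens)),
       leftmost = f0)
}

# Random biallelic panel for founder properties.
random_panel <- function(n_hap, n_sites, contig = "c1") {
  pos <- sort(sample.int(n_sites * 10L, n_sites))
  sites <- data.frame(pos = pos - 1L,
                      ref = sample(c("A", "C", "G", "T"), n_sites,
                                   replace = TRUE))
  sites$alt <- lapply(sites$ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L))
  m <- matrix(stats::rbinom(n_hap * n_sites, 1L, 0.5), nrow = n_hap)
  haplotype_panel(contig, sites, m, paste0("h", seq_len(n_hap)))
}
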