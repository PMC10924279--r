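#' Greedy minimum segmentation of a haplotype panel
#'
#' Partitions the panel's variant sites into consecutive segments so that
#' within each segment the haplotypes collapse to at most `n_founders - 1`
#' distinct allele strings. `n_founders` counts the reference sequence, so
#' the panel itself contributes at most `n_founders - 1` founders. The scan
#' is greedy left-to-right: the current segment is extended site by site and
#' closed at the earliest position where it already spans at least
#' `min_sites` sites and taking the next site would push the number of
#' distinct strings above capacity.
#'
#' When a segment is forced past capacity by `min_sites` (diversity exceeded
#' the limit before the segment was long enough to close), the
#' `n_founders - 1` most frequent strings are retained (ties broken toward
#' the earlier string) and every remaining haplotype is reassigned to the
#' retained string with minimum Hamming distance over the segment's allele
#' indices (ties toward the lower retained index). Such collapsed haplotypes
#' are no longer exactly representable as founder mosaics.
#'
#' @param panel a [haplotype_panel()].
#' @param n_founders founder count including the reference; must be >= 2.
#' @param min_sites minimum number of variant sites per segment (the last
#'   segment is merged into its predecessor rather than left short).
#' @return an object of class `segmentation`: the panel, the parameters, and
#'   one entry per segment holding the retained distinct allele-index
#'   strings, the per-haplotype string assignment, and whether a collapse
#'   occurred.
#' @export
minimum_segmentation <- function(panel, n_founders, min_sites = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_founders < 2L)
    stop("n_founders must be >= 2 (the count includes the reference)")
  if (min_sites < 1L) stop("min_sites must be >= 1")
  cap <- n_founders - 1L
  m <- panel$matrix
  ns <- ncol(m)
  if (ns == 0L) stop("panel has no sites")

  bounds <- list()
  s <- 1L
  cur <- as.character(m[, 1L])
  i <- 1L
  repeat {
    if (i == ns) {
      bounds[[length(bounds) + 1L]] <- c(s, i)
      break
    }
    ext <- paste(cur, m[, i + 1L], sep = ",")
    if ((i - s + 1L) >= min_sites && length(unique(ext)) > cap) {
      bounds[[length(bounds) + 1L]] <- c(s, i)
      s <- i + 1L
      cur <- as.character(m[, s])
      i <- s
    } else {
      cur <- ext
      i <- i + 1L
    }
  }
  # A trailing segment shorter than min_sites is merged into its predecessor
  # (a short final segment is only allowed when the whole panel is short).
  nb <- length(bounds)
  if (nb > 1L) {
    last <- bounds[[nb]]
    if (last[2L] - last[1L] + 1L < min_sites) {
      bounds[[nb - 1L]][2L] <- last[2L]
      bounds[[nb]] <- NULL
    }
  }

  segments <- lapply(bounds, function(b)
    build_segment(m, b[1L], b[2L], cap))
  structure(list(panel = panel, n_founders = n_founders,
                 min_sites = min_sites, segments = segments),
            class = "segmentation")
}

## One segment: distinct allele strings (rows of `alleles`), per-haplotype
## assignment, support sets; collapse to `cap` strings if needed.
build_segment <- function(m, start, end, cap) {
  sub <- m[, start:end, drop = FALSE]
  keys <- apply(sub, 1L, paste, collapse = ",")
  uk <- unique(keys)                       # first-occurrence order
  assign <- match(keys, uk)
  collapsed <- FALSE
  if (length(uk) > cap) {
    collapsed <- TRUE
    counts <- tabulate(assign, nbins = length(uk))
    keep <- order(-counts, seq_along(uk))[seq_len(cap)]
    keep <- sort(keep)                     # keep original relative order
    rows_kept <- sub[match(uk[keep], keys), , drop = FALSE]
    new_assign <- integer(length(assign))
    for (h in seq_along(assign)) {
      hit <- match(assign[h], keep)
      if (!is.na(hit)) {
        new_assign[h] <- hit
      } else {
        d <- rowSums(rows_kept != matrix(sub[h, ], nrow = nrow(rows_kept),
                                         ncol = ncol(sub), byrow = TRUE))
        new_assign[h] <- which.min(d)      # ties -> lower retained index
      }
    }
    assign <- new_assign
    uk <- uk[keep]
  }
  alleles <- do.call(rbind, lapply(strsplit(uk, ",", fixed = TRUE),
                                   as.integer))
  support <- split(seq_along(assign), factor(assign,
                                             levels = seq_along(uk)))
  list(start = start, end = end, alleles = alleles, assignment = assign,
       support = unname(support), collapsed = collapsed)
}

#' @export
print.segmentation <- function(x, ...) {
  lens <- vapply(x$segments, function(s) s$end - s$start + 1L, integer(1))
  nd <- vapply(x$segments, function(s) nrow(s$alleles), integer(1))
  cat(sprintf(
    "<segmentation> %d segment(s) over %d site(s); F=%d, L=%d\n",
    length(x$segments), n_sites(x$panel), x$n_founders, x$min_sites))
  cat("  sites/segment: ", paste(lens, collapse = " "), "\n", sep = "")
  cat("  distinct strings: ", paste(nd, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct founder sequences from a segmentation
#'
#' Chains each segment's distinct allele strings across segment boundaries
#' into founders. Within a segment, strings are ordered by descending
#' haplotype support (ties toward first occurrence). Across each consecutive
#' segment pair, strings are matched greedily by descending joint support
#' (the number of haplotypes carrying both strings; ties toward the lower
#' index pair). A matched pair with zero joint support is a possible
#' discontinuation (recombination) position and increments
#' `recombination_count`. Founder `k` is the concatenation of the `k`-th
#' chained string of every segment; segments with fewer distinct strings
#' than founders are padded with the all-reference string.
#'
#' @param seg a [minimum_segmentation()] result.
#' @return an object of class `founder_set` with the founder allele-index
#'   matrix (founders x sites), per-founder per-segment source string ids
#'   and supporting haplotype names, and the total `recombination_count`.
#' @export
reconstruct_founders <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  panel <- seg$panel
  segs <- seg$segments
  nseg <- length(segs)
  nf <- max(vapply(segs, function(s) nrow(s$alleles), integer(1)))

  # per segment: slots 1..nf = strings ordered by support desc, padded with
  # the reference string (support = empty)
  slots <- lapply(segs, function(s) {
    counts <- lengths(s$support)
    ord <- order(-counts, seq_along(counts))
    len <- s$end - s$start + 1L
    alle <- s$alleles[ord, , drop = FALSE]
    supp <- s$support[ord]
    src <- ord
    while (nrow(alle) < nf) {
      alle <- rbind(alle, rep(0L, len))
      supp <- c(supp, list(integer(0)))
      src <- c(src, NA_integer_)
    }
    list(alleles = alle, support = supp, source = src)
  })

  # chain: founder k starts in slot k of segment 1
  founder_slot <- seq_len(nf)
  per_seg_slot <- matrix(NA_integer_, nrow = nf, ncol = nseg)
  per_seg_slot[, 1L] <- founder_slot
  recomb <- 0L
  if (nseg > 1L) {
    for (j in seq_len(nseg - 1L)) {
      mt <- match_slots(slots[[j]]$support, slots[[j + 1L]]$support)
      recomb <- recomb + mt$zero_support
      # founder whose current slot is a gets next-segment slot mt$map[a]
      founder_slot <- mt$map[founder_slot]
      per_seg_slot[, j + 1L] <- founder_slot
    }
  }

  len_total <- n_sites(panel)
  fmat <- matrix(0L, nrow = nf, ncol = len_total)
  provenance <- vector("list", nf)
  hn <- panel$haplotype_names
  for (k in seq_len(nf)) {
    prov <- vector("list", nseg)
    for (j in seq_len(nseg)) {
      sl <- per_seg_slot[k, j]
      fmat[k, segs[[j]]$start:segs[[j]]$end] <- slots[[j]]$alleles[sl, ]
      prov[[j]] <- list(segment = j,
                        source_string = slots[[j]]$source[sl],
                        haplotypes = hn[slots[[j]]$support[[sl]]])
    }
    provenance[[k]] <- prov
  }

  structure(list(panel = panel, alleles = fmat,
                 founder_names = paste0("founder-", seq_len(nf)),
                 provenance = provenance, recombination_count = recomb,
                 n_founders = seg$n_founders, min_sites = seg$min_sites,
                 segments = lapply(segs, function(s)
                   c(start = s$start, end = s$end))),
            class = "founder_set")
}

## Greedy maximum-joint-support matching between the slots of two
## consecutive segments. Returns map[a] = b and the number of matched pairs
## with zero joint support.
match_slots <- function(suppA, suppB) {
  n <- length(suppA)
  J <- matrix(0L, n, n)
  for (a in seq_len(n))
    for (b in seq_len(n))
      J[a, b] <- length(intersect(suppA[[a]], suppB[[b]]))
  map <- rep(NA_integer_, n)
  usedB <- rep(FALSE, n)
  zero <- 0L
  for (step in seq_len(n)) {
    bestJ <- -1L; ba <- 0L; bb <- 0L
    for (a in seq_len(n)) {
      if (!is.na(map[a])) next
      for (b in seq_len(n)) {
        if (usedB[b]) next
        if (J[a, b] > bestJ) { bestJ <- J[a, b]; ba <- a; bb <- b }
      }
    }
    map[ba] <- bb
    usedB[bb] <- TRUE
    if (bestJ == 0L) zero <- zero + 1L
  }
  list(map = map, zero_support = zero)
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf(
    "<founder_set> %d founder(s) over %d site(s), %d segment(s), %d recombination(s)\n",
    nrow(x$alleles), ncol(x$alleles), length(x$segments),
    x$recombination_count))
  invisible(x)
}

#' Can every panel haplotype be read as a founder mosaic?
#'
#' Checks, segment by segment, that each haplotype's allele string over the
#' segment equals some founder's string there; switches between founders are
#' allowed at every segment boundary, so per-segment membership suffices for
#' a mosaic path to exist.
#'
#' @param fs a [reconstruct_founders()] result.
#' @return logical vector, one entry per panel haplotype.
#' @export
haplotypes_representable <- function(fs) {
  m <- fs$panel$matrix
  ok <- rep(TRUE, nrow(m))
  for (seg in fs$segments) {
    cols <- seg["start"]:seg["end"]
    fk <- apply(fs$alleles[, cols, drop = FALSE], 1L, paste, collapse = ",")
    hk <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = ",")
    ok <- ok & hk %in% fk
  }
  ok
}

#' Reference-guided MSA of the reference and derived haplotype rows
#'
#' Lays the reference and a set of allele-index rows (founders or donor
#' haplotypes) into equal-length gapped rows. Each variant site contributes a
#' column block as wide as the longest allele used by any row there
#' (including the reference allele); alleles are left-aligned within the
#' block and right-padded with `-`. Reference stretches between sites are
#' copied gap-free into every row, so ungapping the reference row reproduces
#' the input reference exactly.
#'
#' @param sites site table as in [haplotype_panel()].
#' @param allele_mat integer matrix rows x sites of allele indices.
#' @param reference reference sequence (plain string over the region).
#' @param row_names names for the non-reference rows.
#' @param reference_name name for the reference row.
#' @return a [ref_msa()].
#' @export
gapped_rows_from_alleles <- function(sites, allele_mat, reference,
                                     row_names, reference_name = "REF") {
  nr <- nrow(allele_mat)
  ns <- nrow(sites)
  pieces <- vector("list", nr + 1L)       # row 1 = reference
  for (r in seq_len(nr + 1L)) pieces[[r]] <- character(0)
  cursor <- 0L                            # 0-based ref bases emitted
  add <- function(r, s) pieces[[r]] <<- c(pieces[[r]], s)
  for (j in seq_len(ns)) {
    p <- sites$pos[j]
    if (p > cursor) {
      between <- substr(reference, cursor + 1L, p)
      for (r in seq_len(nr + 1L)) add(r, between)
    }
    used <- unique(c(0L, allele_mat[, j]))
    alleles <- vapply(used, function(a) site_allele(sites, j, a),
                      character(1))
    width <- max(nchar(alleles))
    pad <- function(a) paste0(a, strrep("-", width - nchar(a)))
    add(1L, pad(sites$ref[j]))
    for (r in seq_len(nr)) {
      a <- allele_mat[r, j]
      add(r + 1L, pad(site_allele(sites, j, a)))
    }
    cursor <- p + nchar(sites$ref[j])
  }
  tail_len <- nchar(reference)
  if (cursor < tail_len) {
    rest <- substr(reference, cursor + 1L, tail_len)
    for (r in seq_len(nr + 1L)) add(r, rest)
  }
  rows <- vapply(pieces, paste, character(1), collapse = "")
  names(rows) <- c(reference_name, row_names)
  ref_msa(rows, reference_name)
}

#' @rdname gapped_rows_from_alleles
#' @param fs a [reconstruct_founders()] result.
#' @param panel the panel the founders were built from.
#' @param reference_name name for the reference row (contig name by default
#'   in `founders_to_msa()`).
#' @export
founders_to_msa <- function(fs, panel = fs$panel,
                            reference, reference_name = panel$contig) {
  refseq <- as_contig_seq(reference, panel$contig)
  gapped_rows_from_alleles(panel$sites, fs$alleles, refseq,
                           fs$founder_names, reference_name)
}

#' Write founder outputs
#'
#' Writes (1) the unaligned founder FASTA (input for an external aligner's
#' index), (2) the aligned FASTA of the reference-guided MSA, and (3) a
#' tab-separated provenance table mapping each founder segment to its source
#' haplotypes. Record order is deterministic; FASTA lines are wrapped at 80
#' columns.
#'
#' @param fs a [reconstruct_founders()] result.
#' @param msa the matching [founders_to_msa()] result.
#' @param out_prefix path prefix; writes `<prefix>.founders.fa`,
#'   `<prefix>.msa.fa` and `<prefix>.provenance.tsv`.
#' @return invisibly, the three paths written.
#' @export
write_founders <- function(fs, msa, out_prefix) {
  if (length(unique(nchar(msa$rows))) != 1L)
    stop("refusing to write: MSA rows have unequal lengths")
  paths <- paste0(out_prefix, c(".founders.fa", ".msa.fa",
                                ".provenance.tsv"))
  unaligned <- Biostrings::DNAStringSet(gsub("-", "", msa$rows, fixed = TRUE))
  founders_only <- unaligned[names(unaligned) != msa$reference_name]
  Biostrings::writeXStringSet(founders_only, paths[1L], width = 80L)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(msa$rows), paths[2L],
                              width = 80L)
  prov <- do.call(rbind, lapply(seq_along(fs$provenance), function(k) {
    do.call(rbind, lapply(fs$provenance[[k]], function(p)
      data.frame(founder = fs$founder_names[k], segment = p$segment,
                 source_string = p$source_string,
                 haplotypes = paste(p$haplotypes, collapse = ","))))
  }))
  utils::write.table(prov, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
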