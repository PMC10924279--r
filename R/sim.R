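#' Simulation configuration
#'
#' Parameters of the deterministic synthetic diploid fixture: a uniform
#' random reference, a phased panel of SNPs and small indels over
#' `n_haplotypes` haplotypes (the last sample's two haplotypes form a
#' held-out donor excluded from the emitted panel), and error-bearing reads
#' drawn in equal numbers from both donor haplotypes with recorded true
#' reference positions.
#'
#' @param seed global seed; per-stage seeds are derived from it so each
#'   stage is individually reproducible.
#' @param ref_length reference length in bases.
#' @param n_haplotypes total haplotypes including the donor's two (even).
#' @param snp_rate,indel_rate per-base Bernoulli rates for placing a SNP or
#'   an indel site.
#' @param max_indel_len maximum indel length; lengths are uniform on
#'   `1..max_indel_len`, insertions and deletions equiprobable.
#' @param read_length,coverage read length and mean coverage; the total read
#'   count `coverage * ref_length / read_length` is forced even and split
#'   equally between the two donor haplotypes.
#' @param error_rate per-base substitution error rate. Base qualities are
#'   Phred 40 except at injected errors (Phred 10), so quality-aware
#'   mismatch penalties are exercised deterministically.
#' @param contig contig name used throughout.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ref_length = 100000L,
                       n_haplotypes = 16L, snp_rate = 1e-3,
                       indel_rate = 1e-4, max_indel_len = 10L,
                       read_length = 100L, coverage = 40,
                       error_rate = 0.002, contig = "chrS") {
  stopifnot(ref_length > 0, n_haplotypes >= 4L, n_haplotypes %% 2L == 0L,
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            max_indel_len >= 1L, read_length > 0, coverage > 0,
            error_rate >= 0, error_rate <= 1)
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 n_haplotypes = as.integer(n_haplotypes),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, contig = contig),
            class = "sim_config")
}

## Independent per-stage seed derived from the global seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483587)
}

#' Simulate a random reference sequence
#'
#' I.i.d. uniform A/C/G/T of `ref_length` bases; identical for identical
#' seeds.
#'
#' @param cfg a [sim_config()].
#' @return a single character string.
#' @export
make_reference <- function(cfg) {
  set.seed(stage_seed(cfg$seed, 1L))
  paste(sample(c("A", "C", "G", "T"), cfg$ref_length, replace = TRUE),
        collapse = "")
}

#' Simulate a phased panel with a held-out donor
#'
#' Places SNP and indel sites Bernoulli per base with non-overlapping
#' reference spans, assigns alleles per haplotype Bernoulli(0.5), and holds
#' the last sample out as the diploid donor: its two haplotypes are removed
#' from the returned panel (take-one-out) and its sequences, heterozygous
#' sites and haplotype-to-reference projection indexes are returned as
#' truth.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [make_reference()] (or any string).
#' @return list with `panel` (a [haplotype_panel()] without the donor),
#'   `sites` (all site definitions), `donor` (name, allele matrix, the two
#'   haplotype sequences, heterozygous [variant_sites()], and per-haplotype
#'   [build_projection_index()] objects) and `reference`.
#' @export
make_panel <- function(cfg, reference) {
  set.seed(stage_seed(cfg$seed, 2L))
  n <- nchar(reference)
  u <- stats::runif(n)
  is_snp <- u < cfg$snp_rate
  is_indel <- !is_snp & u < cfg$snp_rate + cfg$indel_rate
  cand <- which(is_snp | is_indel)

  pos <- integer(0); refs <- character(0); alts <- character(0)
  last_end <- 0L
  bases <- c("A", "C", "G", "T")
  for (p1 in cand) {                      # p1 is 1-based
    p <- p1 - 1L
    if (p < last_end) next
    b <- substr(reference, p1, p1)
    if (is_snp[p1]) {
      alt <- sample(setdiff(bases, b), 1L)
      ra <- b
    } else {
      k <- sample.int(cfg$max_indel_len, 1L)
      if (stats::runif(1) < 0.5) {        # insertion
        ra <- b
        alt <- paste0(b, paste(sample(bases, k, replace = TRUE),
                               collapse = ""))
      } else {                            # deletion
        if (p1 + k > n) next
        ra <- substr(reference, p1, p1 + k)
        alt <- b
      }
    }
    pos <- c(pos, p); refs <- c(refs, ra); alts <- c(alts, alt)
    last_end <- p + nchar(ra)
  }
  if (!length(pos)) stop("no variant sites generated; raise the rates")
  sites <- data.frame(pos = pos, ref = refs)
  sites$alt <- as.list(alts)

  mat <- matrix(stats::rbinom(cfg$n_haplotypes * length(pos), 1L, 0.5),
                nrow = cfg$n_haplotypes)
  n_samples <- cfg$n_haplotypes %/% 2L
  sample_names <- sprintf("S%02d", seq_len(n_samples))
  hap_names <- as.vector(rbind(paste0(sample_names, "/1"),
                               paste0(sample_names, "/2")))
  donor_rows <- c(cfg$n_haplotypes - 1L, cfg$n_haplotypes)
  panel <- haplotype_panel(cfg$contig, sites,
                           mat[-donor_rows, , drop = FALSE],
                           hap_names[-donor_rows])

  donor_alleles <- mat[donor_rows, , drop = FALSE]
  donor_msa <- gapped_rows_from_alleles(
    sites, donor_alleles, reference,
    c("donor/1", "donor/2"), cfg$contig)
  het <- which(donor_alleles[1L, ] != donor_alleles[2L, ])
  het_sites <- variant_sites(cfg$contig, sites$pos[het], sites$ref[het],
                             unlist(sites$alt[het]))
  donor <- list(
    name = sample_names[n_samples],
    alleles = donor_alleles,
    haplotypes = c(msa_ungap(donor_msa, "donor/1"),
                   msa_ungap(donor_msa, "donor/2")),
    het_sites = het_sites,
    index = list(build_projection_index(donor_msa, "donor/1"),
                 build_projection_index(donor_msa, "donor/2")))
  list(panel = panel, sites = sites, donor = donor, reference = reference)
}

#' Simulate error-bearing reads from the donor haplotypes
#'
#' Draws an equal number of reads from each donor haplotype at uniform start
#' positions, injects per-base substitution errors at `error_rate`, and
#' records each read's true reference leftmost: the reference position of
#' the first read base that sits on a reference base, obtained through the
#' haplotype's projection index.
#'
#' @param cfg a [sim_config()].
#' @param donor the `donor` element of [make_panel()].
#' @return list with `reads` (data frame: `read_id`, `hap`, `hap_pos`,
#'   `seq`, `qual`) and `truth` (data frame: `read_id`, `contig`, `pos`,
#'   `strand`).
#' @export
simulate_reads <- function(cfg, donor) {
  set.seed(stage_seed(cfg$seed, 3L))
  rl <- cfg$read_length
  total <- 2L * ceiling(cfg$coverage * cfg$ref_length / rl / 2)
  per_hap <- total %/% 2L
  out <- vector("list", 2L)
  for (h in 1:2) {
    hap <- donor$haplotypes[h]
    hl <- nchar(hap)
    if (rl > hl) stop("read_length exceeds haplotype length")
    starts <- sample.int(hl - rl + 1L, per_hap, replace = TRUE) - 1L
    seqs <- substring(hap, starts + 1L, starts + rl)
    quals <- rep(strrep(rawToChar(as.raw(33L + 40L)), rl), per_hap)
    err <- which(stats::runif(per_hap * rl) < cfg$error_rate)
    if (length(err)) {
      ri <- (err - 1L) %/% rl + 1L
      bi <- (err - 1L) %% rl + 1L
      for (k in seq_along(err)) {
        old <- substr(seqs[ri[k]], bi[k], bi[k])
        substr(seqs[ri[k]], bi[k], bi[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(quals[ri[k]], bi[k], bi[k]) <- rawToChar(as.raw(33L + 10L))
      }
    }
    idx <- donor$index[[h]]
    mapped <- !idx$in_insertion
    # reference position of the first non-inserted haplotype base at or
    # after each position (truth leftmost for reads starting in insertions)
    nxt_map <- integer(idx$founder_length)
    run <- NA_integer_
    for (i in rev(seq_len(idx$founder_length))) {
      if (mapped[i]) run <- i
      nxt_map[i] <- run
    }
    first_mapped <- nxt_map[starts + 1L]
    truth_pos <- ifelse(!is.na(first_mapped) & first_mapped <= starts + rl,
                        idx$ref_pos[first_mapped], NA_integer_)
    out[[h]] <- list(
      reads = data.frame(
        read_id = sprintf("read-h%d-%06d", h, seq_len(per_hap)),
        hap = h, hap_pos = starts, seq = seqs, qual = quals,
        stringsAsFactors = FALSE),
      truth = data.frame(
        read_id = sprintf("read-h%d-%06d", h, seq_len(per_hap)),
        contig = cfg$contig, pos = as.integer(truth_pos), strand = "+",
        stringsAsFactors = FALSE))
  }
  list(reads = rbind(out[[1L]]$reads, out[[2L]]$reads),
       truth = rbind(out[[1L]]$truth, out[[2L]]$truth))
}

#' Oracle aligner: place each read at its true reference position
#'
#' Projects each read's all-match script from donor-haplotype coordinates to
#' the reference through the donor's projection index, yielding the edit
#' script induced by the haplotype's variants over the read span. Every
#' record gets MAPQ 42. Reads lying wholly inside a donor insertion are
#' returned unmapped.
#'
#' @param reads,truth output of [simulate_reads()].
#' @param donor the `donor` element of [make_panel()].
#' @param contig reference contig name.
#' @return an [alignments()] table, one record per read.
#' @export
oracle_align <- function(reads, truth, donor, contig) {
  if (!all(reads$read_id %in% truth$read_id))
    stop("truth positions missing for some reads")
  n <- nrow(reads)
  pos <- integer(n); cig <- character(n); flag <- integer(n)
  rl <- nchar(reads$seq[1L])
  script <- edit_script("M", rl)
  for (i in seq_len(n)) {
    idx <- donor$index[[reads$hap[i]]]
    pr <- project_edit_script(script, idx, reads$hap_pos[i])
    if (is.na(pr$ref_leftmost)) {
      flag[i] <- SAM_FLAG[["unmapped"]]
      pos[i] <- NA_integer_
      cig[i] <- "*"
    } else {
      pos[i] <- pr$ref_leftmost
      cig[i] <- script_to_cigar(pr$script)
    }
  }
  alignments(read_id = reads$read_id, target = contig, pos = pos,
             cigar = cig, mapq = ifelse(flag == 0L, 42L, 0L), flag = flag,
             seq = reads$seq, qual = reads$qual)
}

#' Generate the full synthetic fixture in one call
#'
#' @param cfg a [sim_config()].
#' @return list with `reference`, `panel`, `sites`, `donor`, `reads`,
#'   `truth` and `oracle` (the oracle-placed alignments).
#' @export
simulate_fixture <- function(cfg = sim_config()) {
  reference <- make_reference(cfg)
  pan <- make_panel(cfg, reference)
  rd <- simulate_reads(cfg, pan$donor)
  oracle <- oracle_align(rd$reads, rd$truth, pan$donor, cfg$contig)
  c(pan, rd, list(oracle = oracle, config = cfg))
}
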