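#' Read alignments from SAM/BAM
#'
#' SAM input is converted to BAM with Rsamtools first; fields and the `AS`,
#' `XS`, `NM`, `MD` tags are pulled with `scanBam`. Positions are converted
#' to the package's 0-based convention.
#'
#' @param path a `.sam` or `.bam` file.
#' @return an [alignments()] table.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual"),
    tag = c("AS", "XS", "NM", "MD"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  alignments(
    read_id = x$qname,
    target = as.character(x$rname),
    pos = x$pos - 1L,
    cigar = x$cigar,
    mapq = x$mapq,
    flag = x$flag,
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    AS = if (is.null(x$tag$AS)) NA_real_ else x$tag$AS,
    XS = if (is.null(x$tag$XS)) NA_real_ else x$tag$XS,
    NM = if (is.null(x$tag$NM)) NA_integer_ else x$tag$NM,
    MD = if (is.null(x$tag$MD)) NA_character_ else x$tag$MD)
}

#' Write alignments to SAM
#'
#' Emits a minimal SAM file: `@HD`, one `@SQ` per target, a `@PG` line, then
#' one record per row with 1-based `POS` and the optional tags that are set.
#' Mate fields are left unset (`RNEXT *`).
#'
#' @param aln an [alignments()] table.
#' @param path output `.sam` path.
#' @param seq_lengths named integer vector of target lengths for `@SQ`.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path, seq_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)),
           sprintf("@PG\tID:panproject\tPN:panproject\tVN:%s",
                   as.character(utils::packageVersion("panproject"))))
  unmapped <- flag_has(aln$flag, "unmapped")
  tags <- vapply(seq_len(nrow(aln)), function(i) {
    t <- character(0)
    if (!is.na(aln$AS[i])) t <- c(t, sprintf("AS:i:%d", as.integer(aln$AS[i])))
    if (!is.na(aln$XS[i])) t <- c(t, sprintf("XS:i:%d", as.integer(aln$XS[i])))
    if (!is.na(aln$NM[i])) t <- c(t, sprintf("NM:i:%d", aln$NM[i]))
    if (!is.na(aln$MD[i])) t <- c(t, sprintf("MD:Z:%s", aln$MD[i]))
    if (length(t)) paste0("\t", paste(t, collapse = "\t")) else ""
  }, character(1))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                 aln$read_id, aln$flag,
                 ifelse(unmapped & is.na(aln$pos), "*", aln$target),
                 ifelse(unmapped & is.na(aln$pos), 0L, aln$pos + 1L),
                 aln$mapq,
                 ifelse(unmapped, "*", aln$cigar),
                 ifelse(is.na(aln$seq), "*", aln$seq),
                 ifelse(is.na(aln$qual), "*", aln$qual),
                 tags)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a phased panel as a VCF
#'
#' Minimal VCF 4.2 with phased `GT` genotypes, one sample per haplotype
#' pair, suitable for reading back with [load_panel()].
#'
#' @param panel a [haplotype_panel()].
#' @param path output `.vcf` path.
#' @param contig_length contig length for the `##contig` header line.
#' @return invisibly, `path`.
#' @export
write_panel_vcf <- function(panel, path, contig_length) {
  hap <- panel$haplotype_names
  samples <- unique(sub("/[12]$", "", hap))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", panel$contig,
                   as.integer(contig_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  m <- panel$matrix
  recs <- vapply(seq_len(nrow(panel$sites)), function(j) {
    gts <- vapply(samples, function(s) {
      a1 <- m[match(paste0(s, "/1"), hap), j]
      a2 <- m[match(paste0(s, "/2"), hap), j]
      sprintf("%d|%d", a1, a2)
    }, character(1))
    paste(c(panel$contig, panel$sites$pos[j] + 1L, ".",
            panel$sites$ref[j],
            paste(panel$sites$alt[[j]], collapse = ","),
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the complete synthetic fixture to files
#'
#' Writes `reference.fa`, `panel.vcf` (donor excluded), `donor.vcf` (the
#' donor's phased genotypes), `donor_hap1.fa`/`donor_hap2.fa`, `reads.fq`
#' and `truth.tsv` into a directory.
#'
#' @param fx a [simulate_fixture()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of paths.
#' @export
write_fixtures <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- fx$config
  paths <- c(reference = file.path(dir, "reference.fa"),
             panel = file.path(dir, "panel.vcf"),
             donor = file.path(dir, "donor.vcf"),
             hap1 = file.path(dir, "donor_hap1.fa"),
             hap2 = file.path(dir, "donor_hap2.fa"),
             reads = file.path(dir, "reads.fq"),
             truth = file.path(dir, "truth.tsv"))
  ref <- Biostrings::DNAStringSet(fx$reference)
  names(ref) <- cfg$contig
  Biostrings::writeXStringSet(ref, paths["reference"], width = 80L)
  write_panel_vcf(fx$panel, paths["panel"], cfg$ref_length)
  donor_panel <- haplotype_panel(cfg$contig, fx$sites, fx$donor$alleles,
                                 paste0(fx$donor$name, c("/1", "/2")))
  write_panel_vcf(donor_panel, paths["donor"], cfg$ref_length)
  for (h in 1:2) {
    hs <- Biostrings::DNAStringSet(fx$donor$haplotypes[h])
    names(hs) <- sprintf("%s_hap%d", fx$donor$name, h)
    Biostrings::writeXStringSet(hs, paths[[paste0("hap", h)]], width = 80L)
  }
  fq <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(fx$reads$seq),
    Biostrings::PhredQuality(fx$reads$qual))
  names(fq) <- fx$reads$read_id
  Biostrings::writeQualityScaledXStringSet(fq, paths["reads"])
  utils::write.table(fx$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
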