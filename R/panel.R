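#' Phased haplotype panels
#'
#' A haplotype panel holds the phased variation of a set of samples over one
#' contig as an allele-index matrix: one row per haplotype (sample x phase),
#' one column per variant site, entries indexing the site's alleles
#' (0 = reference). Sites are 0-based, strictly increasing, with
#' non-overlapping reference spans.
#'
#' @param contig contig name.
#' @param sites data frame with columns `pos` (0-based reference position),
#'   `ref` (reference allele) and `alt` (list column of alternative alleles).
#' @param matrix integer matrix, haplotypes x sites, of allele indices.
#' @param haplotype_names character vector naming the matrix rows.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(contig, sites, matrix, haplotype_names) {
  stopifnot(is.data.frame(sites),
            all(c("pos", "ref", "alt") %in% names(sites)))
  matrix <- base::matrix(as.integer(matrix), nrow = NROW(matrix),
                         dimnames = list(haplotype_names, NULL))
  if (ncol(matrix) != nrow(sites))
    stop("allele matrix has ", ncol(matrix), " columns but there are ",
         nrow(sites), " sites")
  if (nrow(sites) > 1L) {
    if (any(diff(sites$pos) <= 0L))
      stop("sites must be strictly increasing by position")
    ends <- sites$pos + nchar(sites$ref)
    if (any(sites$pos[-1L] < ends[-length(ends)]))
      stop("site reference spans overlap")
  }
  n_alleles <- 1L + lengths(sites$alt)
  for (j in seq_len(nrow(sites))) {
    if (any(matrix[, j] < 0L) || any(matrix[, j] >= n_alleles[j]))
      stop("allele index out of range at site ", j)
  }
  structure(list(contig = contig, sites = sites, matrix = matrix,
                 haplotype_names = haplotype_names),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d haplotype(s) x %d site(s)\n",
              x$contig, nrow(x$matrix), nrow(x$sites)))
  invisible(x)
}

n_sites <- function(panel) nrow(panel$sites)
n_haplotypes <- function(panel) nrow(panel$matrix)

## Allele sequence for allele index a at site i (0 = ref).
site_allele <- function(sites, i, a) {
  if (a == 0L) sites$ref[i] else sites$alt[[i]][a]
}

#' Load a phased haplotype panel from a VCF
#'
#' Reads a phased multi-sample VCF over one contig into a
#' [haplotype_panel()]. Multiallelic records contribute all their alternative
#' alleles to the site's allele list. Records whose reference span overlaps a
#' previously accepted record are skipped with a warning (first record wins).
#' Missing genotype calls are treated as the reference allele.
#'
#' @param vcf path to a VCF file (optionally gzipped) or a `vcfR` object.
#' @param reference the contig's reference sequence: a bare character string,
#'   a named [Biostrings::DNAStringSet], or a FASTA path.
#' @param contig contig to load.
#' @param start,end optional 0-based half-open interval restricting the sites.
#' @param samples_exclude optional character vector of sample names to drop.
#' @return a [haplotype_panel()].
#' @export
load_panel <- function(vcf, reference, contig = NULL, start = NULL, end = NULL,
                       samples_exclude = NULL) {
  v <- if (inherits(vcf, "vcfR")) vcf else
    vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(contig)) contig <- fix[1L, "CHROM"]
  refseq <- as_contig_seq(reference, contig)

  keep <- unname(fix[, "CHROM"]) == contig
  pos0 <- as.integer(fix[, "POS"]) - 1L
  refs <- unname(fix[, "REF"])
  if (!is.null(start)) keep <- keep & pos0 >= start
  if (!is.null(end)) keep <- keep & (pos0 + nchar(refs)) <= end
  idx <- which(keep)
  idx <- idx[order(pos0[idx])]

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(NULL, colnames(v@gt)[-1L]))
  samples <- setdiff(colnames(gt), samples_exclude)
  if (!length(samples)) stop("no samples left after exclusion")

  sites <- list()
  rows <- list()
  last_end <- -1L
  for (i in idx) {
    p <- pos0[i]
    ra <- refs[i]
    if (p < last_end) {
      warning(sprintf(
        "skipping %s:%d (%s): reference span overlaps previous record",
        contig, p + 1L, ra))
      next
    }
    ref_here <- substr(refseq, p + 1L, p + nchar(ra))
    if (!identical(toupper(ref_here), toupper(ra)))
      stop(sprintf("record %s:%d REF '%s' does not match reference '%s'",
                   contig, p + 1L, ra, ref_here))
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1L]]
    g <- gt[i, samples]
    alleles <- integer(2L * length(samples))
    for (s in seq_along(samples)) {
      call <- g[[s]]
      if (is.na(call) || call %in% c(".", ".|.", "./.")) {
        a <- c(0L, 0L)
      } else {
        if (grepl("/", call, fixed = TRUE))
          stop(sprintf("record %s:%d sample %s: genotype '%s' is not phased",
                       contig, p + 1L, samples[s], call))
        parts <- strsplit(call, "|", fixed = TRUE)[[1L]]
        if (length(parts) != 2L)
          stop(sprintf("record %s:%d sample %s: expected diploid genotype",
                       contig, p + 1L, samples[s]))
        a <- ifelse(parts == ".", 0L, suppressWarnings(as.integer(parts)))
        if (anyNA(a))
          stop(sprintf("record %s:%d sample %s: malformed genotype '%s'",
                       contig, p + 1L, samples[s], call))
      }
      alleles[c(2L * s - 1L, 2L * s)] <- a
    }
    sites[[length(sites) + 1L]] <- list(pos = p, ref = ra, alt = alts)
    rows[[length(rows) + 1L]] <- alleles
    last_end <- p + nchar(ra)
  }
  if (!length(sites)) stop("no usable sites for ", contig)

  site_df <- data.frame(pos = vapply(sites, `[[`, integer(1), "pos"),
                        ref = vapply(sites, `[[`, character(1), "ref"))
  site_df$alt <- lapply(sites, `[[`, "alt")
  mat <- do.call(cbind, rows)
  hap_names <- as.vector(rbind(paste0(samples, "/1"), paste0(samples, "/2")))
  haplotype_panel(contig, site_df, mat, hap_names)
}

## Resolve the reference sequence for one contig from a string, a
## DNAStringSet, or a FASTA path.
as_contig_seq <- function(reference, contig) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && grepl("[.](fa|fasta|fna)(\\.gz)?$", reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*", "", names(reference))
    hit <- match(contig, nm)
    if (is.na(hit)) stop("reference does not contain contig ", contig)
    return(as.character(reference[[hit]]))
  }
  if (is.character(reference) && length(reference) == 1L)
    return(toupper(reference))
  stop("cannot interpret `reference`")
}
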