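small_cfg <- sim_config(seed = 11L, ref_length = 8000L, n_haplotypes = 8L,
                        snp_rate = 2e-3, indel_rate = 5e-4,
                        max_indel_len = 6L, read_length = 80L,
                        coverage = 15, error_rate = 0.01)

test_that("the reference generator is seed-deterministic and uniform A/C/G/T", {
  r1 <- make_reference(small_cfg)
  r2 <- make_reference(small_cfg)
  expect_identical(r1, r2)
  expect_identical(nchar(r1), small_cfg$ref_length)
  expect_false(grepl("[^ACGT]", r1))
  other <- make_reference(sim_config(seed = 12L, ref_length = 8000L))
  expect_false(identical(r1, other))
})

test_that("panels hold out the donor and respect site constraints", {
  ref <- make_reference(small_cfg)
  px <- make_panel(small_cfg, ref)
  expect_identical(nrow(px$panel$matrix),
                   small_cfg$n_haplotypes - 2L)
  expect_false(any(grepl(px$donor$name, px$panel$haplotype_names)))
  # non-overlapping spans, strictly increasing
  ends <- px$sites$pos + nchar(px$sites$ref)
  expect_true(all(px$sites$pos[-1L] >= ends[-length(ends)]))
  # VCF round trip reproduces the panel matrix
  vcf <- tempfile(fileext = ".vcf")
  write_panel_vcf(px$panel, vcf, small_cfg$ref_length)
  back <- load_panel(vcf, ref, small_cfg$contig)
  expect_identical(unname(back$matrix), unname(px$panel$matrix))
  expect_identical(back$sites$pos, px$sites$pos)
})

test_that("SNP-only configurations emit no indel alleles", {
  cfg <- sim_config(seed = 3L, ref_length = 5000L, snp_rate = 2e-3,
                    indel_rate = 0)
  px <- make_panel(cfg, make_reference(cfg))
  expect_true(all(nchar(px$sites$ref) == 1L))
  expect_true(all(nchar(unlist(px$sites$alt)) == 1L))
})

test_that("applying the donor's variants reproduces its haplotype sequences", {
  ref <- make_reference(small_cfg)
  px <- make_panel(small_cfg, ref)
  # independent apply-variants oracle: splice alleles into the reference
  apply_variants <- function(reference, sites, alleles) {
    out <- character(0)
    cursor <- 0L
    for (j in seq_len(nrow(sites))) {
      p <- sites$pos[j]
      if (p > cursor) out <- c(out, substr(reference, cursor + 1L, p))
      a <- alleles[j]
      out <- c(out, if (a == 0L) sites$ref[j] else sites$alt[[j]][a])
      cursor <- p + nchar(sites$ref[j])
    }
    paste0(paste(out, collapse = ""),
           substr(reference, cursor + 1L, nchar(reference)))
  }
  for (h in 1:2)
    expect_identical(px$donor$haplotypes[h],
                     apply_variants(ref, px$sites, px$donor$alleles[h, ]))
})

test_that("reads come equally from both haplotypes with truthful positions", {
  fx <- simulate_fixture(small_cfg)
  expect_identical(sum(fx$reads$hap == 1L), sum(fx$reads$hap == 2L))
  expect_identical(nrow(fx$reads),
                   2L * as.integer(ceiling(small_cfg$coverage *
                     small_cfg$ref_length / small_cfg$read_length / 2)))
  # determinism
  fx2 <- simulate_fixture(small_cfg)
  expect_identical(fx$reads$seq, fx2$reads$seq)
  expect_identical(fx$truth$pos, fx2$truth$pos)
})

test_that("error-free reads substring-match their haplotype", {
  cfg <- sim_config(seed = 5L, ref_length = 4000L, error_rate = 0,
                    coverage = 5, read_length = 60L)
  px <- make_panel(cfg, make_reference(cfg))
  rd <- simulate_reads(cfg, px$donor)
  for (i in sample.int(nrow(rd$reads), 50L)) {
    r <- rd$reads[i, ]
    expect_identical(substr(px$donor$haplotypes[r$hap], r$hap_pos + 1L,
                            r$hap_pos + cfg$read_length), r$seq)
  }
})

test_that("oracle alignments land on the truth and carry induced indels", {
  fx <- simulate_fixture(small_cfg)
  res <- alignment_precision_recall(fx$oracle, fx$truth, tolerance = 5L)
  expect_identical(res$TP + res$FN, nrow(fx$truth))
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  # reads spanning donor insertions show I runs; SNP-only reads are all-M
  has_ins <- any(grepl("I", fx$oracle$cigar))
  ins_sites <- nchar(unlist(fx$sites$alt)) > nchar(fx$sites$ref)
  het_ins <- any(ins_sites &
                   (fx$donor$alleles[1L, ] + fx$donor$alleles[2L, ] > 0L))
  expect_identical(has_ins, het_ins)
})

test_that("a read over a donor insertion projects with the inserted bases as I", {
  sites <- data.frame(pos = 8L, ref = "A")   # reference base at 8 is 'A'
  sites$alt <- list("ATT")
  ref <- strrep("ACGT", 10L)
  msa <- gapped_rows_from_alleles(sites, matrix(1L, 1, 1), ref, "d1", "ref")
  expect_identical(panproject:::msa_ungap(msa, "ref"), ref)
  idx <- build_projection_index(msa, "d1")
  pr <- project_edit_script(edit_script("M", 20L), idx, 5L)
  expect_identical(script_to_cigar(pr$script), "4M2I14M")
})

test_that("fixture files land on disk in standard formats", {
  cfg <- sim_config(seed = 9L, ref_length = 3000L, coverage = 4,
                    read_length = 50L, snp_rate = 2e-3)
  fx <- simulate_fixture(cfg)
  dir <- tempfile()
  paths <- write_fixtures(fx, dir)
  expect_true(all(file.exists(paths)))
  ref <- Biostrings::readDNAStringSet(paths["reference"])
  expect_identical(as.character(ref[[1L]]), fx$reference)
  # readQualityScaledDNAStringSet warns about dropped metadata columns
  fq <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(paths["reads"]))
  expect_identical(length(fq), nrow(fx$reads))
  expect_identical(as.character(fq[[1L]]), fx$reads$seq[1L])
  truth <- read.delim(paths["truth"])
  expect_identical(nrow(truth), nrow(fx$truth))
  donor_back <- load_panel(paths["donor"], fx$reference, cfg$contig)
  expect_identical(unname(donor_back$matrix), unname(fx$donor$alleles))
})

test_that("the full pipeline composes: founders, projection, rescoring, evaluation", {
  cfg <- sim_config(seed = 21L, ref_length = 6000L, n_haplotypes = 8L,
                    snp_rate = 3e-3, indel_rate = 5e-4, read_length = 60L,
                    coverage = 2)
  fx <- simulate_fixture(cfg)
  fs <- reconstruct_founders(minimum_segmentation(fx$panel, 4L, 2L))
  msa <- founders_to_msa(fs, fx$panel, fx$reference)

  # draw reads from the founder sequences themselves: exact founder-space
  # placements, then project, rescore and evaluate
  set.seed(31)
  recs <- list()
  truth <- list()
  for (k in seq_len(nrow(fs$alleles))) {
    fseq <- panproject:::msa_ungap(msa, fs$founder_names[k])
    idx <- build_projection_index(msa, fs$founder_names[k])
    starts <- sample.int(nchar(fseq) - 60L, 40L) - 1L
    for (i in seq_along(starts)) {
      id <- sprintf("f%d-%03d", k, i)
      rec <- alignments(id, fs$founder_names[k], starts[i], "60M",
                        seq = substr(fseq, starts[i] + 1L, starts[i] + 60L),
                        qual = strrep("I", 60L))
      pr <- project_alignment(rec, idx, reference = fx$reference)
      recs[[length(recs) + 1L]] <- pr
      want <- project_edit_script(edit_script("M", 60L), idx, starts[i])
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = id, contig = cfg$contig,
        pos = want$ref_leftmost, strand = "+")
    }
  }
  aln <- do.call(rbind, recs)
  class(aln) <- c("pg_alignments", "data.frame")
  truth <- do.call(rbind, truth)
  aln <- rescore_alignments(aln, fx$reference)
  expect_true(all(aln$mapq >= 0L & aln$mapq <= 42L))
  res <- alignment_precision_recall(filter_max_mapq(aln), truth)
  expect_identical(res$TP + res$FN, nrow(truth))
  expect_equal(res$recall, 1)
})
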