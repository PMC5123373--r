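test_that("P-site adjustment applies the offset from the correct read end", {
  tab <- default_psite_offsets()
  # plus strand: 5' end + offset
  expect_equal(as.integer(adjust_to_psite(1000L, 1027L, "+", 28L, tab)), 1012L)
  # minus strand read spanning [1000, 1028): 3' end (1027) - offset
  expect_equal(as.integer(adjust_to_psite(1000L, 1027L, "-", 28L, tab)), 1015L)
  # length outside the table: skipped unless a default offset is given
  out <- adjust_to_psite(1000L, 1034L, "+", 35L, tab)
  expect_true(is.na(out))
  expect_equal(attr(out, "n_skipped"), 1L)
  out <- adjust_to_psite(1000L, 1034L, "+", 35L, tab, default_offset = 12L)
  expect_equal(as.integer(out), 1012L)
  expect_equal(attr(out, "n_skipped"), 0L)
})

test_that("profile extraction tallies P-sites on the region coordinate set", {
  # 3 reads with P-sites at CDS positions 0, 0, 5 of the toy transcript
  # (CDS starts at genomic 130), plus one read whose P-site (125) falls
  # in the 5'UTR, i.e. outside the CDS coordinate set
  model <- toy_model("+")
  reads <- data.frame(chrom = "chr1",
                      start = c(130L, 130L, 135L, 125L) - 12L,
                      strand = "+", length = 28L)
  bam <- write_toy_bam(reads)
  prof <- extract_psite_profile(bam, model, "CDS")
  expected <- integer(60)
  expected[c(1L, 6L)] <- c(2L, 1L)
  expect_equal(prof$counts, expected)
  expect_equal(prof$n_assigned, 3L)
  expect_equal(prof$length_histogram, c(`28` = 3L))
  # the same read set seen from the full-transcript region picks up the
  # UTR read as well
  full <- extract_psite_profile(bam, model, "full")
  expect_equal(sum(full$counts), 4L)
})

test_that("reads on the wrong strand or in introns are not counted", {
  model <- transcript_model("tx2", "g2", "chr1", "+",
                            exons = rbind(c(100L, 160L), c(400L, 460L)))
  reads <- data.frame(
    chrom = "chr1",
    start = c(130L - 12L,   # exonic, counted
              200L - 12L,   # P-site in the intron
              140L + 12L - 28L + 1L),  # minus-strand read, strand mismatch
    strand = c("+", "+", "-"), length = 28L)
  bam <- write_toy_bam(reads)
  prof <- extract_psite_profile(bam, model, "full")
  expect_equal(sum(prof$counts), 1L)
  expect_equal(which(prof$counts == 1L), 31L)  # transcript position 30
})

test_that("chromosome missing from the BAM header yields an empty profile", {
  bam <- write_toy_bam(data.frame(chrom = "chr1", start = 100L,
                                  strand = "+", length = 28L))
  model <- transcript_model("tx", "g", "chrZ", "+", cbind(0L, 90L),
                            biotype = "lincRNA")
  expect_warning(prof <- extract_psite_profile(bam, model, "full"),
                 "absent from BAM header")
  expect_equal(sum(prof$counts), 0L)
})

test_that("extraction recovers simulator ground truth exactly", {
  fx <- small_fixture()
  models <- parse_annotation(fx$txome$gtf_path)
  for (i in seq_len(nrow(fx$sim$truth))) {
    id <- fx$sim$truth$transcript_id[i]
    prof <- extract_psite_profile(fx$sim$bam_path, models[[id]],
                                  fx$sim$truth$region[i])
    expect_equal(prof$counts, as.integer(fx$sim$counts[[id]]))
  }
})

test_that("mirrored minus-strand placement leaves count vectors unchanged", {
  # place the same transcript-space P-sites on a plus- and a mirrored
  # minus-strand copy of one transcript; profiles must agree
  plus <- toy_model("+")
  minus <- toy_model("-")
  tx_pos <- c(0L, 5L, 5L, 40L)
  cp <- region_coords(plus, "CDS")
  cm <- region_coords(minus, "CDS")
  bam_p <- write_toy_bam(data.frame(chrom = "chr1",
                                    start = cp[tx_pos + 1L] - 12L,
                                    strand = "+", length = 28L))
  bam_m <- write_toy_bam(data.frame(chrom = "chr1",
                                    start = cm[tx_pos + 1L] + 12L - 27L,
                                    strand = "-", length = 28L))
  prof_p <- extract_psite_profile(bam_p, plus, "CDS")
  prof_m <- extract_psite_profile(bam_m, minus, "CDS")
  expect_equal(prof_p$counts, prof_m$counts)
})

test_that("FPKM follows its definition and scaling invariance", {
  prof <- structure(list(transcript_id = "t", region = "full",
                         counts = c(rep(0L, 900), rep(1L, 100)),
                         length_histogram = c(`28` = 100L)),
                    class = "PSiteProfile")
  expect_equal(compute_fpkm(prof, 1e6)$fpkm, 100)
  # 50 reads, 500 nt, 2e6 total -> 50 * 1e9 / (500 * 2e6) = 50
  prof2 <- structure(list(transcript_id = "t", region = "full",
                          counts = c(rep(1L, 50), rep(0L, 450)),
                          length_histogram = c(`28` = 50L)),
                     class = "PSiteProfile")
  expect_equal(compute_fpkm(prof2, 2e6)$fpkm, 50)
  # zero reads -> 0; invariance under doubling reads and library together
  prof0 <- structure(list(counts = integer(100)), class = "PSiteProfile")
  expect_equal(compute_fpkm(prof0, 1e6)$fpkm, 0)
  prof2x <- prof2
  prof2x$counts <- prof2$counts * 2L
  expect_equal(compute_fpkm(prof2x, 4e6)$fpkm, compute_fpkm(prof2, 2e6)$fpkm)
  expect_error(compute_fpkm(prof2, 0), "positive")
})
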