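test_that("transcriptome simulation is deterministic and well-formed", {
  cfg <- sim_config(n_coding = 8L, n_noncoding = 8L, seed = 5L)
  g1 <- tempfile(fileext = ".gtf")
  g2 <- tempfile(fileext = ".gtf")
  tx1 <- simulate_transcriptome(cfg, g1)
  tx2 <- simulate_transcriptome(cfg, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_length(tx1$models, 16L)
  # requested structure: coding transcripts carry a CDS, others do not
  coding <- vapply(tx1$models, function(m) !is.null(m$cds), logical(1))
  expect_equal(sum(coding), 8L)
  expect_true(all(vapply(tx1$models[coding], function(m)
    region_length(m, "CDS") %% 3L == 0L, logical(1))))
  # some multi-exon structure is present
  expect_gt(sum(vapply(tx1$models, function(m) nrow(m$exons), integer(1)) > 1), 0)

  # forced single transcript honors requested lengths
  cfg1 <- sim_config(n_coding = 1L, n_noncoding = 0L,
                     cds_length_range = c(300L, 300L),
                     utr5_length_range = c(50L, 50L),
                     utr3_length_range = c(70L, 70L),
                     multi_exon_prob = 0, seed = 9L)
  tx <- simulate_transcriptome(cfg1)
  m <- tx$models[[1]]
  expect_equal(region_length(m, "5UTR"), 50L)
  expect_equal(region_length(m, "CDS"), 300L)
  expect_equal(region_length(m, "3UTR"), 70L)
})

test_that("simulated reads are deterministic and recoverable", {
  cfg <- sim_config(n_coding = 5L, n_noncoding = 5L, library_size = 3e6,
                    seed = 17L)
  txome <- simulate_transcriptome(cfg)
  s1 <- tempfile(fileext = ".sam")
  s2 <- tempfile(fileext = ".sam")
  sim1 <- simulate_ribo_reads(cfg, txome, sam_path = s1)
  sim2 <- simulate_ribo_reads(cfg, txome, sam_path = s2)
  expect_identical(readLines(s1), readLines(s2))
  # truth table is consistent with the emitted reads
  expect_equal(sum(sim1$truth$n_reads), nrow(sim1$reads))
  expect_equal(vapply(sim1$counts, sum, numeric(1)),
               setNames(as.numeric(sim1$truth$n_reads),
                        sim1$truth$transcript_id))
  # P-sites recoverable from read placement by the default +12 offset
  with(sim1$reads, expect_equal(
    ifelse(strand == "+", start + 12L, start + length - 1L - 12L), psite))
})

test_that("perfect periodicity lands every CDS P-site in frame 0", {
  cfg <- sim_config(n_coding = 4L, n_noncoding = 0L, periodicity = 1,
                    library_size = 3e6, seed = 2L)
  txome <- simulate_transcriptome(cfg)
  sim <- simulate_ribo_reads(cfg, txome)
  for (id in names(sim$counts)) {
    fc <- frame_counts(sim$counts[[id]], exclude_terminal_codons = FALSE)
    expect_equal(fc[2:3], c(0, 0))
  }
})

test_that("periodicity 1/3 spreads P-sites evenly across frames", {
  cfg <- sim_config(n_coding = 10L, n_noncoding = 0L, periodicity = 1 / 3,
                    cds_length_range = c(900L, 900L),
                    fpkm_meanlog = log(60), library_size = 1e8, seed = 29L)
  txome <- simulate_transcriptome(cfg)
  sim <- simulate_ribo_reads(cfg, txome)
  fc <- Reduce(`+`, lapply(sim$counts, frame_counts,
                           exclude_terminal_codons = FALSE))
  expect_gt(sum(fc), 30000)
  expect_gt(chisq.test(fc)$p.value, 0.001)
})

test_that("metagene coverage of periodic regions peaks at lag-3
           autocorrelation", {
  cfg <- sim_config(n_coding = 20L, n_noncoding = 0L,
                    cds_length_range = c(600L, 600L), seed = 31L)
  txome <- simulate_transcriptome(cfg)
  sim <- simulate_ribo_reads(cfg, txome)
  meta <- Reduce(`+`, lapply(sim$counts, function(v) v[1:600]))
  ac <- acf(meta, lag.max = 6, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 3L)
})

test_that("biased resampling flattens the length distribution monotonically", {
  set.seed(37)
  mix <- c(`26` = 0.02, `27` = 0.08, `28` = 0.35, `29` = 0.35, `30` = 0.15,
           `31` = 0.04, `32` = 0.01)
  lens <- as.integer(sample(names(mix), 5e4, replace = TRUE, prob = mix))
  tv_uniform <- function(l) {
    f <- tabulate(factor(l, levels = 26:32)) / length(l)
    sum(abs(f - 1 / 7)) / 2
  }
  # unbiased limit: resample matches the population distribution
  idx0 <- biased_resample(lens, bias = 0, n_sample = 1e4, n_trials = 1,
                          seed = 1)[[1]]
  f_pop <- tabulate(factor(lens, levels = 26:32)) / length(lens)
  f_res <- tabulate(factor(lens[idx0], levels = 26:32)) / 1e4
  expect_lt(sum(abs(f_pop - f_res)) / 2, 0.02)
  # moderate increasing bias moves the resampled lengths toward uniform
  # (extreme bias overshoots toward the rare tail lengths, so the
  # flattening claim is checked over the moderate range)
  tvs <- vapply(c(0, 0.5, 1), function(b) {
    tv_uniform(lens[biased_resample(lens, bias = b, n_sample = 1e4,
                                    n_trials = 1, seed = 2)[[1]]])
  }, numeric(1))
  expect_lt(tvs[3], tv_uniform(lens))  # flatter than the population
  expect_true(all(diff(tvs) <= 0.02))  # monotone flattening (small slack)
  # determinism and bounds checking
  expect_identical(biased_resample(lens, 2, 100, 3, seed = 7),
                   biased_resample(lens, 2, 100, 3, seed = 7))
  expect_error(biased_resample(lens, 2, length(lens) + 1), "exceeds")
  expect_error(biased_resample(numeric(0), 0, 1), "nonempty")
})
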