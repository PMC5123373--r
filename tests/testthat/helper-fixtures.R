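# Shared small fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# small simulated dataset with GTF + indexed BAM on disk
small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  dir <- file.path(tempdir(), "ribospec-fixture")
  dir.create(dir, showWarnings = FALSE)
  cfg <- sim_config(n_coding = 10L, n_noncoding = 10L,
                    library_size = 5e6, seed = 42L)
  txome <- simulate_transcriptome(cfg, file.path(dir, "anno.gtf"))
  sim <- simulate_ribo_reads(cfg, txome,
                             sam_path = file.path(dir, "reads.sam"),
                             bam = TRUE)
  .fixture_cache$small <- list(dir = dir, cfg = cfg, txome = txome, sim = sim)
  .fixture_cache$small
}

# hand-built single-exon coding transcript: exon [100, 200), CDS [130, 190)
toy_model <- function(strand = "+") {
  transcript_model("tx1", "g1", "chr1", strand,
                   exons = cbind(100L, 200L), cds = cbind(130L, 190L))
}

# write a tiny SAM + BAM from a read table (chrom, start0, strand, length)
write_toy_bam <- function(reads, chrom_sizes = c(chr1 = 100000L),
                          stem = tempfile()) {
  sam <- paste0(stem, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  body <- sprintf("q%04d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(reads)),
                  ifelse(reads$strand == "+", 0L, 16L),
                  reads$chrom, reads$start + 1L, reads$length,
                  vapply(reads$length, function(l) strrep("A", l),
                         character(1)))
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, stem, overwrite = TRUE, indexDestination = TRUE)
}

# per-transcript read-length histograms from a simulated read table
sim_length_histograms <- function(sim) {
  h <- lapply(split(sim$reads$length, sim$reads$transcript_id), table)
  h[sim$truth$transcript_id]
}
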