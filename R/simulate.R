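#' Simulation configuration
#'
#' Defines the conditions under which synthetic ribosome-profiling fixtures
#' are generated: how many coding and non-coding transcripts, their length
#' structure, the abundance distribution, the strength of tri-nucleotide
#' periodicity in translated regions, and the footprint-length mixture.
#'
#' Periodicity `p` is the probability that a translated read's P-site falls
#' in frame 0 of its codon (the remaining mass split evenly over frames 1
#' and 2); `p = 1/3` is no periodicity, `p = 1` perfect periodicity. The
#' default `p = 0.9` reflects the strong sub-codon phasing of good
#' cycloheximide-treated libraries. Footprint lengths default to the
#' canonical 28-30 nt enrichment; abundances are log-normal with median
#' 20 FPKM against a 20 M read library, giving a few hundred P-sites on a
#' typical CDS.
#'
#' @param n_coding,n_noncoding Numbers of transcripts per class.
#' @param cds_length_range CDS length range in nt (rounded to codons).
#' @param utr5_length_range,utr3_length_range UTR length ranges in nt.
#' @param noncoding_length_range Length range for non-coding transcripts.
#' @param multi_exon_prob Probability a transcript is multi-exon (2-4
#'   exons).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal abundance parameters.
#' @param library_size Nominal mapped-library size used to convert FPKM to
#'   expected read counts.
#' @param periodicity In-frame probability `p` for translated regions, in
#'   \[1/3, 1\].
#' @param length_mix Named probability vector over footprint lengths.
#' @param length_mix_noncoding Optional separate length mixture for
#'   non-coding transcripts (default: same as `length_mix`).
#' @param bias Default bias strength for [biased_resample()].
#' @param seed Integer seed; every simulation output is a deterministic
#'   function of it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_coding = 40L, n_noncoding = 40L,
                       cds_length_range = c(300L, 900L),
                       utr5_length_range = c(30L, 150L),
                       utr3_length_range = c(50L, 300L),
                       noncoding_length_range = c(300L, 900L),
                       multi_exon_prob = 0.4,
                       fpkm_meanlog = log(20), fpkm_sdlog = 1,
                       library_size = 2e7,
                       periodicity = 0.9,
                       length_mix = c(`28` = 0.35, `29` = 0.40, `30` = 0.25),
                       length_mix_noncoding = NULL,
                       bias = 0, seed = 1L) {
  if (periodicity < 1 / 3 || periodicity > 1) {
    stop("periodicity must be in [1/3, 1]")
  }
  if (abs(sum(length_mix) - 1) > 1e-8) stop("length_mix must sum to 1")
  if (any(cds_length_range < 60L)) stop("CDS lengths must be >= 60 nt")
  structure(list(
    n_coding = as.integer(n_coding), n_noncoding = as.integer(n_noncoding),
    cds_length_range = as.integer(cds_length_range),
    utr5_length_range = as.integer(utr5_length_range),
    utr3_length_range = as.integer(utr3_length_range),
    noncoding_length_range = as.integer(noncoding_length_range),
    multi_exon_prob = multi_exon_prob,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    library_size = library_size, periodicity = periodicity,
    length_mix = length_mix, length_mix_noncoding = length_mix_noncoding,
    bias = bias, seed = as.integer(seed)), class = "SimConfig")
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# split a transcript of tx_len nt into n_exons exon widths, each >= min_w
.split_exons <- function(tx_len, n_exons, min_w = 30L) {
  if (n_exons == 1L || tx_len < n_exons * min_w * 2L) return(tx_len)
  cuts <- sort(sample(seq.int(min_w, tx_len - min_w), n_exons - 1L))
  while (any(diff(c(0L, cuts, tx_len)) < min_w)) {
    cuts <- sort(sample(seq.int(min_w, tx_len - min_w), n_exons - 1L))
  }
  diff(c(0L, cuts, tx_len))
}

#' Simulate an annotated transcriptome
#'
#' Generates a synthetic genome layout of non-overlapping single- and
#' multi-exon transcripts over two chromosomes: protein-coding ones with
#' 5'UTR/CDS/3'UTR structure and non-coding (`lincRNA`) ones, on random
#' strands. Writes a GENCODE-style GTF when `gtf_path` is given. All output
#' is a deterministic function of `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param gtf_path Optional path for the GTF file.
#' @return List with `models` (named list of [transcript_model()]),
#'   `chrom_sizes` (named integer vector), `gtf_path`, and a `truth`
#'   skeleton data.frame (`transcript_id`, `gene_id`, `biotype`,
#'   `translated`).
#' @export
simulate_transcriptome <- function(cfg, gtf_path = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_coding + cfg$n_noncoding
  if (n < 1L) stop("need at least one transcript")
  coding <- rep(c(TRUE, FALSE), c(cfg$n_coding, cfg$n_noncoding))
  chroms <- rep(c("chr1", "chr2"), length.out = n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  cursor <- c(chr1 = 1000L, chr2 = 1000L)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    if (coding[i]) {
      u5 <- .runif_int(1L, cfg$utr5_length_range)
      cds_len <- 3L * (.runif_int(1L, cfg$cds_length_range) %/% 3L)
      u3 <- .runif_int(1L, cfg$utr3_length_range)
      tx_len <- u5 + cds_len + u3
    } else {
      u5 <- cds_len <- u3 <- 0L
      tx_len <- .runif_int(1L, cfg$noncoding_length_range)
    }
    n_exons <- if (stats::runif(1) < cfg$multi_exon_prob) sample(2:4, 1L) else 1L
    widths <- .split_exons(tx_len, n_exons)
    introns <- if (length(widths) > 1L) {
      .runif_int(length(widths) - 1L, c(50L, 300L))
    } else integer(0)
    start0 <- cursor[[chroms[i]]]
    ex_start <- start0 + c(0L, cumsum(widths[-length(widths)] + introns))
    exons <- cbind(ex_start, ex_start + widths)
    cursor[[chroms[i]]] <- max(exons[, 2L]) + .runif_int(1L, c(500L, 2000L))

    tid <- sprintf("TX%04d", i)
    gid <- sprintf("GENE%04d", i)
    if (coding[i]) {
      shell <- transcript_model(tid, gid, chroms[i], strands[i], exons,
                                biotype = "protein_coding")
      pos <- region_coords(shell, "full")
      cds_pos <- sort(pos[(u5 + 1L):(u5 + cds_len)])
      brk <- c(0L, which(diff(cds_pos) != 1L), length(cds_pos))
      cds <- cbind(cds_pos[brk[-length(brk)] + 1L], cds_pos[brk[-1L]] + 1L)
      models[[i]] <- transcript_model(tid, gid, chroms[i], strands[i], exons,
                                      cds = cds, biotype = "protein_coding")
    } else {
      models[[i]] <- transcript_model(tid, gid, chroms[i], strands[i], exons,
                                      biotype = "lincRNA")
    }
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  chrom_sizes <- cursor + 1000L
  if (!is.null(gtf_path)) .write_gtf(models, gtf_path)
  list(models = models, chrom_sizes = chrom_sizes, gtf_path = gtf_path,
       truth = data.frame(
         transcript_id = names(models),
         gene_id = vapply(models, `[[`, character(1), "gene_id"),
         biotype = vapply(models, `[[`, character(1), "biotype"),
         translated = coding, row.names = NULL, stringsAsFactors = FALSE))
}

.write_gtf <- function(models, path) {
  fmt <- function(m, type, iv) {
    sprintf(paste0('%s\tribospec_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; ',
                   'transcript_id "%s"; transcript_biotype "%s";'),
            m$chrom, type, iv[, 1L] + 1L, iv[, 2L], m$strand,
            m$gene_id, m$transcript_id, m$biotype)
  }
  lines <- unlist(lapply(models, function(m) {
    span <- cbind(min(m$exons[, 1L]), max(m$exons[, 2L]))
    c(fmt(m, "transcript", span), fmt(m, "exon", m$exons),
      if (!is.null(m$cds)) fmt(m, "CDS", m$cds))
  }), use.names = FALSE)
  writeLines(c("##description: synthetic transcriptome (ribospec simulator)",
               lines), path)
  invisible(path)
}

#' Simulate ribosome-profiling reads with known ground truth
#'
#' Draws P-site placements for every transcript: per-codon with frame
#' probabilities `(p, (1-p)/2, (1-p)/2)` over the CDS for translated
#' (coding) transcripts, uniform over the full transcript for untranslated
#' ones. Read counts follow Poisson sampling of the transcript's log-normal
#' FPKM against the nominal library size; footprint lengths follow the
#' configured mixture. Reads are emitted as unspliced alignments placed so
#' that the default P-site offset recovers the drawn P-site exactly
#' (splice-straddling footprints are not generated, keeping the truth
#' table exact). Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param txome Output of [simulate_transcriptome()].
#' @param sam_path Optional path; when given, alignments are written as SAM.
#' @param bam Also convert to a coordinate-sorted, indexed BAM (requires
#'   `sam_path`).
#' @return List with `reads` (data.frame: `qname`, `chrom`, `start`
#'   (0-based), `strand`, `length`, `psite`, `transcript_id`), `truth`
#'   (per-region data.frame with `translated`, `p`, `n_reads`, `fpkm`,
#'   `region_length`), `counts` (named list of ground-truth per-position
#'   P-site count vectors), `total_reads`, `sam_path`, `bam_path`.
#' @export
simulate_ribo_reads <- function(cfg, txome, sam_path = NULL, bam = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  models <- txome$models
  n <- length(models)
  translated <- txome$truth$translated
  fpkm_nominal <- stats::rlnorm(n, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
  p <- cfg$periodicity

  reads_list <- vector("list", n)
  counts <- vector("list", n)
  info <- vector("list", n)
  read_no <- 0L
  for (i in seq_len(n)) {
    m <- models[[i]]
    region <- if (translated[i]) "CDS" else "full"
    coords <- region_coords(m, region)
    len <- length(coords)
    n_i <- stats::rpois(1L, fpkm_nominal[i] * len / 1000 * cfg$library_size / 1e6)
    if (translated[i]) {
      codon <- sample.int(len %/% 3L, n_i, replace = TRUE) - 1L
      frame <- sample(0:2, n_i, replace = TRUE,
                      prob = c(p, (1 - p) / 2, (1 - p) / 2))
      pos <- 3L * codon + frame
    } else {
      pos <- sample.int(len, n_i, replace = TRUE) - 1L
    }
    counts[[i]] <- tabulate(pos + 1L, nbins = len)
    mix <- cfg$length_mix
    if (!translated[i] && !is.null(cfg$length_mix_noncoding)) {
      mix <- cfg$length_mix_noncoding
    }
    rl <- as.integer(sample(names(mix), n_i, replace = TRUE, prob = mix))
    g <- coords[pos + 1L]
    off <- 12L
    start0 <- if (m$strand == "+") g - off else g + off - rl + 1L
    reads_list[[i]] <- data.frame(
      qname = sprintf("r%08d", read_no + seq_len(n_i)),
      chrom = m$chrom, start = as.integer(start0), strand = m$strand,
      length = rl, psite = as.integer(g), transcript_id = m$transcript_id,
      stringsAsFactors = FALSE)
    read_no <- read_no + n_i
    info[[i]] <- data.frame(
      transcript_id = m$transcript_id, region = region,
      biotype = m$biotype, translated = translated[i],
      p = if (translated[i]) p else 1 / 3,
      n_reads = n_i, region_length = len, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads_list)
  truth <- do.call(rbind, info)
  names(counts) <- truth$transcript_id
  total <- nrow(reads)
  truth$fpkm <- truth$n_reads * 1e9 / (truth$region_length * total)

  bam_path <- NULL
  if (!is.null(sam_path)) {
    .write_sam(reads, txome$chrom_sizes, sam_path)
    if (bam) {
      dest <- sub("\\.sam$", "", sam_path)
      bam_path <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                                   indexDestination = TRUE)
    }
  }
  list(reads = reads, truth = truth, counts = counts, total_reads = total,
       sam_path = sam_path, bam_path = bam_path)
}

.write_sam <- function(reads, chrom_sizes, path) {
  ord <- order(reads$chrom, reads$start, reads$qname)
  reads <- reads[ord, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  reads$qname, ifelse(reads$strand == "+", 0L, 16L),
                  reads$chrom, reads$start + 1L, reads$length,
                  vapply(reads$length, function(l) strrep("A", l), character(1)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Biased resampling of reads by footprint length
#'
#' Repeatedly samples reads without replacement with weight proportional to
#' `exp(b * |length - 28.5|)`: `b = 0` is uniform resampling, larger `b`
#' up-weights lengths far from the canonical 28-29 nt enrichment so the
#' resampled length distribution progressively flattens toward uniform.
#' The exponential weighting scheme is a synthetic stand-in chosen to
#' reproduce that qualitative flattening; it is not a published weighting.
#' Used to probe robustness of periodicity scores to fragment-length
#' variance.
#'
#' @param reads data.frame with a `length` column (e.g. from
#'   [simulate_ribo_reads()]) or a bare numeric vector of read lengths.
#' @param bias Bias strength `b >= 0`.
#' @param n_sample Reads per trial (must not exceed the population).
#' @param n_trials Number of resampling trials.
#' @param seed Integer seed.
#' @return List of `n_trials` sorted integer index vectors into `reads`.
#' @export
biased_resample <- function(reads, bias = 0, n_sample, n_trials = 1L,
                            seed = 1L) {
  lens <- if (is.data.frame(reads)) reads$length else as.numeric(reads)
  n <- length(lens)
  if (n == 0L) stop("reads must be nonempty")
  if (n_sample > n) stop("n_sample exceeds the population size")
  if (bias < 0) stop("bias must be >= 0")
  w <- exp(bias * abs(lens - 28.5))
  set.seed(as.integer(seed))
  lapply(seq_len(n_trials), function(t) {
    # weighted sampling without replacement via the exponential race:
    # smallest Exp(w_i) draws win
    sort(order(stats::rexp(n) / w)[seq_len(n_sample)])
  })
}
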