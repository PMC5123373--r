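#' Fragment-length distribution of a region
#'
#' Normalizes a read-length histogram to fractions over a fixed length
#' range; lengths outside the range are dropped and tallied.
#'
#' @param histogram Named integer vector (names = read lengths in nt).
#' @param lengths Integer range of lengths the distribution is defined over
#'   (default 20-40 nt).
#' @return A `LengthDistribution`: list with `fractions` (named, summing to
#'   1 when reads are present), `total_reads`, `n_out_of_range`.
#' @export
length_distribution <- function(histogram, lengths = 20:40) {
  counts <- stats::setNames(numeric(length(lengths)), as.character(lengths))
  inr <- names(histogram) %in% names(counts)
  counts[names(histogram)[inr]] <- as.numeric(histogram[inr])
  total <- sum(counts)
  structure(list(
    fractions = if (total > 0) counts / total else counts,
    total_reads = as.integer(total),
    n_out_of_range = as.integer(sum(as.numeric(histogram[!inr])))),
    class = "LengthDistribution")
}

#' Pooled coding reference length distribution for FLOSS
#'
#' Pools the fragment-length histograms of CDS profiles from annotated
#' protein-coding transcripts into the reference distribution that FLOSS
#' compares each region against.
#'
#' @param profiles List of `PSiteProfile`s restricted to annotated CDS
#'   regions (or bare named histograms).
#' @param lengths Length range, as in [length_distribution()].
#' @return A `LengthDistribution`.
#' @export
floss_reference <- function(profiles, lengths = 20:40) {
  if (length(profiles) == 0L) stop("profiles must be nonempty")
  pooled <- integer(0)
  for (p in profiles) {
    h <- if (inherits(p, "PSiteProfile")) p$length_histogram else p
    for (l in names(h)) {
      pooled[l] <- (if (l %in% names(pooled)) pooled[[l]] else 0L) + h[[l]]
    }
  }
  d <- length_distribution(pooled, lengths)
  if (d$total_reads == 0L) stop("reference has zero reads in the length range")
  d
}

#' FLOSS: fragment length organization similarity score
#'
#' Half the L1 distance (total-variation distance) between a region's
#' fragment-length distribution and the coding reference: 0 for identical
#' distributions, 1 for disjoint supports. Low FLOSS means coding-like
#' fragment lengths.
#'
#' @param dist,ref `LengthDistribution`s over the same length range.
#' @return FLOSS in \[0,1\]; `NA` (unscorable) when `dist` has no reads.
#' @export
floss_score <- function(dist, ref) {
  stopifnot(inherits(dist, "LengthDistribution"),
            inherits(ref, "LengthDistribution"))
  if (!identical(names(dist$fractions), names(ref$fractions))) {
    stop("distributions are defined over different length ranges")
  }
  if (dist$total_reads == 0L) return(NA_real_)
  sum(abs(dist$fractions - ref$fractions)) / 2
}

#' Extreme-outlier FLOSS cutoff as a function of read depth
#'
#' Bins reference (coding) regions by log10 read count, computes the Tukey
#' upper fence `Q3 + multiplier * IQR` of FLOSS within each bin, enforces a
#' monotone non-increasing fence across bins (deeper regions have tighter
#' length distributions), and interpolates. A query region is flagged
#' non-coding-like when its FLOSS exceeds the fence at its read count.
#'
#' @param read_counts,floss Numeric vectors over the coding reference set
#'   (at least 200 points).
#' @param bin_width Bin width in log10 read-count units (default 0.5).
#' @param min_per_bin Bins with fewer points are merged rightwards.
#' @param multiplier Tukey fence multiplier (default 3, "extreme outlier").
#' @return Function `fence(read_count)` returning the cutoff; call
#'   `attr(, "is_outlier")(read_count, floss)` for the boolean rule.
#' @export
floss_outlier_cutoff <- function(read_counts, floss, bin_width = 0.5,
                                 min_per_bin = 20L, multiplier = 3) {
  ok <- !is.na(floss) & read_counts > 0
  read_counts <- read_counts[ok]
  floss <- floss[ok]
  if (length(floss) < 200L) stop("need at least 200 reference points")
  lx <- log10(read_counts)
  edges <- seq(floor(min(lx) / bin_width) * bin_width,
               max(lx) + bin_width, by = bin_width)
  bin <- findInterval(lx, edges, rightmost.closed = TRUE)
  # merge sparse bins into their right neighbor
  repeat {
    sizes <- table(bin)
    small <- names(sizes)[sizes < min_per_bin]
    if (length(small) == 0L || length(sizes) == 1L) break
    b <- as.integer(small[1L])
    ids <- sort(unique(bin))
    nb <- ids[ids != b]
    target <- if (any(nb > b)) min(nb[nb > b]) else max(nb[nb < b])
    bin[bin == b] <- target
  }
  ids <- sort(unique(bin))
  centers <- vapply(ids, function(b) mean(lx[bin == b]), numeric(1))
  fences <- vapply(ids, function(b) {
    q <- stats::quantile(floss[bin == b], c(0.25, 0.75), names = FALSE)
    q[2L] + multiplier * (q[2L] - q[1L])
  }, numeric(1))
  if (length(fences) > 1L) {
    # non-increasing in depth via isotonic regression on the negated fence
    fences <- -stats::isoreg(centers, -fences)$yf
  }
  fence_fun <- function(read_count) {
    if (length(fences) == 1L) return(rep(fences, length(read_count)))
    stats::approx(centers, fences, xout = log10(pmax(read_count, 1)),
                  rule = 2)$y
  }
  attr(fence_fun, "is_outlier") <- function(read_count, floss) {
    floss > fence_fun(read_count)
  }
  fence_fun
}

#' P-site counts by codon frame
#'
#' Sums a CDS P-site count vector into the three codon frames relative to
#' the annotated start (region position 0 = first base of the start codon).
#' The first and last codons are excluded by default because initiating and
#' terminating ribosomes pile up there and distort frame enrichment.
#'
#' @param counts Integer count vector over a CDS region (5' to 3').
#' @param exclude_terminal_codons Drop the first and last codon (default
#'   TRUE).
#' @return Integer triple `(F1, F2, F3)` of counts in frames 0, 1, 2.
#' @export
frame_counts <- function(counts, exclude_terminal_codons = TRUE) {
  n <- length(counts)
  if (exclude_terminal_codons && n >= 9L) {
    n3 <- n - n %% 3L
    drop <- c(1:3, (n3 - 2L):n3)
    counts <- counts[-drop]
    frames <- (seq_len(length(counts)) + 2L) %% 3L  # positions 3..: frame 0
  } else {
    frames <- (seq_len(n) - 1L) %% 3L
  }
  vapply(0:2, function(f) sum(counts[frames == f]), numeric(1))
}

#' ORFscore: reading-frame enrichment statistic
#'
#' A signed, log-scaled chi-square-like statistic of P-site counts across
#' the three codon frames: with mean count `Fbar`,
#' `X = sum_i (F_i - Fbar)^2 / Fbar` and `score = log2(X + 1)`, negated
#' when frame 2 or 3 carries more reads than the annotated frame 1.
#' Translated ORFs read in frame give large positive values; uniform or
#' out-of-frame occupancy gives values near zero or negative.
#'
#' @param fc Numeric triple `(F1, F2, F3)` from [frame_counts()].
#' @return The ORFscore; `NA` (unscorable) for all-zero counts.
#' @export
orfscore <- function(fc) {
  stopifnot(length(fc) == 3L, all(fc >= 0))
  total <- sum(fc)
  if (total == 0) return(NA_real_)
  fbar <- total / 3
  x <- sum((fc - fbar)^2 / fbar)
  s <- log2(x + 1)
  if (fc[2L] > fc[1L] || fc[3L] > fc[1L]) -s else s
}
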