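#' Sliding-window / Welch-segment specification
#'
#' Scoring parameters for the windowed coherence score: coverage is scanned
#' in sliding windows of `window_length` nt advanced by `step` nt; within
#' each window the coherence estimate averages periodograms of overlapping
#' Welch segments of `segment_length` nt overlapping by `segment_overlap`
#' nt. Window and segment lengths must be divisible by 3 so the
#' 1/3 cycles-per-nt target frequency falls exactly on a DFT bin
#' (`segment_length / 3`), and at least two segments must fit per window —
#' the coherence of two deterministic signals estimated from a single
#' segment is identically 1 and carries no information.
#'
#' @param window_length Window size N in nt (default 30).
#' @param step Step L between window starts in nt (default 3).
#' @param segment_length Welch segment size in nt (default 12).
#' @param segment_overlap Overlap between consecutive segments (default 6).
#' @return A `WindowSpec` list.
#' @export
window_spec <- function(window_length = 30L, step = 3L,
                        segment_length = 12L, segment_overlap = 6L) {
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  segment_length <- as.integer(segment_length)
  segment_overlap <- as.integer(segment_overlap)
  if (window_length %% 3L != 0L) stop("window_length must be divisible by 3")
  if (step < 1L) stop("step must be >= 1")
  if (segment_length %% 3L != 0L) stop("segment_length must be divisible by 3")
  if (segment_length > window_length) stop("segment_length must be <= window_length")
  if (segment_overlap < 0L || segment_overlap >= segment_length) {
    stop("segment_overlap must be in [0, segment_length)")
  }
  n_seg <- length(seq.int(0L, window_length - segment_length,
                          by = segment_length - segment_overlap))
  if (n_seg < 2L) stop("at least 2 Welch segments must fit per window")
  structure(list(window_length = window_length, step = step,
                 segment_length = segment_length,
                 segment_overlap = segment_overlap),
            class = "WindowSpec")
}

#' Idealized tri-nucleotide reference signal
#'
#' The (1,0,0,1,0,0,...) reference with exact period 3:
#' `values[i] = 1` iff `(i - frame_offset) mod 3 == 0` for 0-based `i`.
#'
#' @param length Signal length in nt.
#' @param frame_offset Frame of the ones, in `{0, 1, 2}`.
#' @return Numeric 0/1 vector.
#' @export
ideal_signal <- function(length, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  as.numeric((seq_len(length) - 1L - frame_offset) %% 3L == 0L)
}

#' Normalize a coverage vector to its maximum
#'
#' Divides P-site counts elementwise by the position with the highest
#' coverage so values span 0 (no coverage) to 1 (highest coverage). A
#' region with no coverage at all cannot be normalized and is flagged
#' unscorable.
#'
#' @param counts Non-negative integer/numeric vector (length >= 1).
#' @return A `NormalizedCoverage` list: `values` in \[0,1\], `source_max`
#'   (pre-normalization maximum), `scorable` flag.
#' @export
normalize_coverage <- function(counts) {
  if (length(counts) == 0L) stop("counts must have length >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  mx <- max(counts)
  structure(list(values = if (mx > 0) counts / mx else as.numeric(counts),
                 source_max = mx, scorable = mx > 0),
            class = "NormalizedCoverage")
}

# complex DFT weights for one segment at the target bin
.dft_weights <- function(segment_length, bin) {
  exp(-2i * pi * bin * (seq_len(segment_length) - 1L) / segment_length)
}

.segment_starts <- function(spec) {
  seq.int(0L, spec$window_length - spec$segment_length,
          by = spec$segment_length - spec$segment_overlap)
}

#' Welch coherence of two equal-length windows at one frequency bin
#'
#' Splits both signals into overlapping mean-subtracted segments, takes the
#' DFT of each segment at frequency bin `bin`, averages cross- and
#' auto-power across segments, and returns the magnitude-squared coherence
#' `|P_xy|^2 / (P_xx * P_yy)` at that bin, clamped to \[0,1\] against
#' round-off. The default bin is `segment_length / 3`, i.e. 1/3 cycles per
#' nucleotide — the codon frequency. If either signal has (numerically)
#' zero power at the bin (e.g. a constant signal) the estimate is
#' undefined; 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of length `spec$window_length`.
#' @param spec A [window_spec()].
#' @param bin DFT bin index (cycles per segment), default the codon bin.
#' @return Coherence in \[0,1\] with attribute `degenerate`.
#' @export
coherence_at_frequency <- function(x, y, spec = window_spec(),
                                   bin = spec$segment_length / 3) {
  N <- spec$window_length
  if (length(x) != N || length(y) != N) {
    stop("x and y must have length spec$window_length = ", N)
  }
  S <- spec$segment_length
  w <- .dft_weights(S, bin)
  starts <- .segment_starts(spec)
  zx <- zy <- complex(length(starts))
  for (k in seq_along(starts)) {
    xs <- x[starts[k] + seq_len(S)]
    ys <- y[starts[k] + seq_len(S)]
    zx[k] <- sum((xs - mean(xs)) * w)
    zy[k] <- sum((ys - mean(ys)) * w)
  }
  pxx <- mean(Mod(zx)^2)
  pyy <- mean(Mod(zy)^2)
  tol <- 1e-14 * S^2
  if (pxx <= tol || pyy <= tol) {
    return(structure(0, degenerate = TRUE))
  }
  pxy <- mean(zx * Conj(zy))
  structure(min(1, max(0, Mod(pxy)^2 / (pxx * pyy))), degenerate = FALSE)
}

#' Windowed spectral coherence (SPECtre) score of a coverage region
#'
#' Scores the tri-nucleotide periodicity of a normalized coverage region as
#' the mean Welch coherence, at the codon frequency, between the coverage
#' and an idealized period-3 reference over sliding windows. Window starts
#' are `m = 0, L, 2L, ...` with `m + N <= |C|`, giving
#' `M = floor((|C| - N)/L) + 1` windows; the reference signal's phase is
#' anchored to the region's first coordinate (`frame_offset`, frame 0 at
#' the annotated start codon for CDS regions) and advances with `m`, so
#' every window probes the same absolute reading frame. Windows in which
#' the coverage has no power at the codon frequency contribute coherence 0.
#'
#' @param coverage A [normalize_coverage()] result (or a raw count vector,
#'   which is normalized first).
#' @param spec A [window_spec()].
#' @param frame_offset Absolute frame of the reference signal at region
#'   position 0.
#' @return A `SpectreScore` list: `score` (mean window coherence, in
#'   \[0,1\]), `window_scores` (data.frame `window_start`, `coherence`),
#'   `n_windows`, `scorable`, `reason` (`NA` when scorable; `"too short"`
#'   or `"no coverage"` otherwise, with `score = NA`).
#' @export
spectre_score <- function(coverage, spec = window_spec(), frame_offset = 0L) {
  if (!inherits(coverage, "NormalizedCoverage")) {
    coverage <- normalize_coverage(coverage)
  }
  v <- coverage$values
  unscorable <- function(reason) {
    structure(list(score = NA_real_,
                   window_scores = data.frame(window_start = integer(0),
                                              coherence = numeric(0)),
                   n_windows = 0L, scorable = FALSE, reason = reason),
              class = "SpectreScore")
  }
  if (!coverage$scorable) return(unscorable("no coverage"))
  N <- spec$window_length
  if (length(v) < N) return(unscorable("too short"))

  m <- seq.int(0L, length(v) - N, by = spec$step)
  S <- spec$segment_length
  offs <- .segment_starts(spec)
  K <- length(offs)
  w <- .dft_weights(S, S / 3)

  # all (window, segment) absolute starts at once; DFT at the codon bin via
  # one matrix product (per-segment mean subtraction is a no-op at bins > 0
  # but kept for fidelity with coherence_at_frequency)
  a <- as.vector(outer(m, offs, "+"))                       # length M*K
  seg <- matrix(v[outer(a, seq_len(S) - 1L, "+") + 1L], nrow = length(a))
  seg <- seg - rowMeans(seg)
  zx <- as.vector(seg %*% w)
  # reference DFT: ideal signal sliced at absolute start a has ones at
  # positions t == (frame_offset - a) mod 3; at the codon bin its DFT is
  # (S/3) * exp(-2*pi*i*r/3) with r that residue (mean term vanishes)
  r <- (as.integer(frame_offset) - a) %% 3L
  zy <- (S / 3) * exp(-2i * pi * r / 3)

  dim(zx) <- c(length(m), K)
  dim(zy) <- c(length(m), K)
  pxx <- rowMeans(Mod(zx)^2)
  pyy <- rowMeans(Mod(zy)^2)
  pxy <- rowMeans(zx * Conj(zy))
  tol <- 1e-14 * S^2
  coh <- ifelse(pxx <= tol | pyy <= tol, 0,
                pmin(1, pmax(0, Mod(pxy)^2 / (pxx * pyy))))
  structure(list(score = mean(coh),
                 window_scores = data.frame(window_start = m, coherence = coh),
                 n_windows = length(m), scorable = TRUE, reason = NA_character_),
            class = "SpectreScore")
}

#' @export
print.SpectreScore <- function(x, ...) {
  if (x$scorable) {
    cat(sprintf("SpectreScore %.6f over %d windows\n", x$score, x$n_windows))
  } else {
    cat(sprintf("SpectreScore: unscorable (%s)\n", x$reason))
  }
  invisible(x)
}

#' Lift per-window scores to genomic intervals
#'
#' Maps each window's transcript-space interval through the exon structure
#' to genomic intervals (split at exon junctions), carrying the window's
#' coherence value, for bedGraph-style browser tracks.
#'
#' @param score A [spectre_score()] result with at least one window.
#' @param model The [transcript_model()] the coverage came from.
#' @param region Region name the coverage was extracted over.
#' @param spec The [window_spec()] used (for the window length).
#' @param values Optional numeric vector overriding the per-window values
#'   (e.g. posterior probabilities); defaults to the window coherences.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `value`,
#'   sorted by genomic start. Interval widths of one window sum to the
#'   window length.
#' @export
window_track <- function(score, model, region = "full", spec = window_spec(),
                         values = NULL) {
  if (score$n_windows == 0L) stop("score has no windows")
  coords <- region_coords(model, region)
  vals <- if (is.null(values)) score$window_scores$coherence else values
  stopifnot(length(vals) == score$n_windows)
  N <- spec$window_length
  rows <- lapply(seq_len(score$n_windows), function(i) {
    m <- score$window_scores$window_start[i]
    g <- sort(coords[(m + 1L):(m + N)])
    brk <- c(0L, which(diff(g) != 1L), length(g))
    data.frame(chrom = model$chrom,
               start = g[brk[-length(brk)] + 1L],
               end = g[brk[-1L]] + 1L,
               value = vals[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}
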