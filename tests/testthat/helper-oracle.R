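# Independent straight-line oracles, deliberately sharing no code with the
# package: explicit real/imaginary DFT sums, explicit loops.

oracle_welch_coherence <- function(x, y, seg_len = 12, overlap = 6,
                                   bin = seg_len / 3) {
  step <- seg_len - overlap
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  ang <- 2 * pi * bin * (0:(seg_len - 1)) / seg_len
  xr <- xi <- yr <- yi <- numeric(length(starts))
  for (k in seq_along(starts)) {
    xs <- x[starts[k]:(starts[k] + seg_len - 1)]
    ys <- y[starts[k]:(starts[k] + seg_len - 1)]
    xs <- xs - sum(xs) / seg_len
    ys <- ys - sum(ys) / seg_len
    xr[k] <- sum(xs * cos(ang)); xi[k] <- -sum(xs * sin(ang))
    yr[k] <- sum(ys * cos(ang)); yi[k] <- -sum(ys * sin(ang))
  }
  pxx <- mean(xr^2 + xi^2)
  pyy <- mean(yr^2 + yi^2)
  if (pxx <= 1e-14 * seg_len^2 || pyy <= 1e-14 * seg_len^2) return(0)
  # cross-power P_xy averaged across segments: zx * conj(zy)
  cr <- mean(xr * yr + xi * yi)
  ci <- mean(xi * yr - xr * yi)
  min(1, max(0, (cr^2 + ci^2) / (pxx * pyy)))
}

oracle_windowed_score <- function(v, N = 30, L = 3, seg_len = 12,
                                  overlap = 6, frame_offset = 0) {
  v <- v / max(v)
  ideal <- as.numeric(((seq_along(v) - 1) - frame_offset) %% 3 == 0)
  starts <- seq(0, length(v) - N, by = L)
  coh <- numeric(length(starts))
  for (k in seq_along(starts)) {
    m <- starts[k]
    coh[k] <- oracle_welch_coherence(v[(m + 1):(m + N)],
                                     ideal[(m + 1):(m + N)],
                                     seg_len, overlap)
  }
  mean(coh)
}

# exhaustive pair-counting AUC (ties count 1/2)
oracle_pair_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
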