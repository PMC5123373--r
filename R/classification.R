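#' Calibrate scores to an FDR threshold and posterior machinery
#'
#' Partitions scored regions by an abundance cutoff into an "active" sample
#' (protein-coding regions with FPKM at or above the cutoff — regions
#' confidently under translation) and a "null" sample (regions below the
#' cutoff, or annotated non-coding regions when `null_mode = "biotype"`).
#' The translation threshold is the empirical `(1 - fdr)` quantile of the
#' null scores, so at most a fraction `fdr` of null-like regions exceed it;
#' kernel density estimates of both samples (Gaussian kernel on the logit
#' scale, since scores live in \[0,1\]) and the empirical class prior
#' support posterior evaluation.
#'
#' @param scores data.frame with columns `id`, `score`, `fpkm`, `biotype`
#'   (rows with `NA` score are ignored).
#' @param fpkm_cutoff Abundance cutoff separating the samples (default 5).
#' @param fdr Tolerated false-discovery rate in (0,1) (default 0.05).
#' @param null_mode `"fpkm"` (default: null = FPKM below cutoff) or
#'   `"biotype"` (null = non-protein-coding regions).
#' @param min_n Minimum sample size required on each side (default 50).
#' @param bandwidth Optional kernel bandwidth on the logit scale; default
#'   is the Sheather-Jones plug-in (falling back to Silverman's rule for
#'   degenerate samples).
#' @param coding_biotypes Biotypes counted as protein coding.
#' @return A `ScoreCalibration` object.
#' @export
build_calibration <- function(scores, fpkm_cutoff = 5, fdr = 0.05,
                              null_mode = c("fpkm", "biotype"), min_n = 50L,
                              bandwidth = NULL,
                              coding_biotypes = "protein_coding") {
  null_mode <- match.arg(null_mode)
  stopifnot(is.data.frame(scores),
            all(c("id", "score", "fpkm", "biotype") %in% names(scores)))
  if (!(fdr > 0 && fdr < 1)) stop("fdr must be in (0, 1)")
  ok <- !is.na(scores$score)
  scores <- scores[ok, , drop = FALSE]
  coding <- scores$biotype %in% coding_biotypes
  active <- scores$score[coding & scores$fpkm >= fpkm_cutoff]
  null <- if (null_mode == "fpkm") {
    scores$score[scores$fpkm < fpkm_cutoff]
  } else {
    scores$score[!coding]
  }
  if (length(active) < min_n || length(null) < min_n) {
    stop("calibration needs at least ", min_n, " scores on each side of the ",
         "cutoff (got ", length(active), " active, ", length(null), " null); ",
         "choose a different fpkm_cutoff or null_mode")
  }
  structure(list(
    fpkm_cutoff = fpkm_cutoff, fdr = fdr, null_mode = null_mode,
    active_scores = active, null_scores = null,
    threshold = unname(stats::quantile(null, 1 - fdr)),
    prior_active = length(active) / (length(active) + length(null)),
    active_kde = .logit_kde(active, bandwidth),
    null_kde = .logit_kde(null, bandwidth)),
    class = "ScoreCalibration")
}

#' @export
print.ScoreCalibration <- function(x, ...) {
  cat(sprintf(paste0(
    "ScoreCalibration: FPKM cutoff %.3g (null = %s), FDR %.3g\n",
    "  threshold %.6f | %d active, %d null | prior(active) %.3f\n"),
    x$fpkm_cutoff, x$null_mode, x$fdr, x$threshold,
    length(x$active_scores), length(x$null_scores), x$prior_active))
  invisible(x)
}

.logit <- function(s, eps = 1e-6) {
  s <- pmin(1 - eps, pmax(eps, s))
  log(s / (1 - s))
}

# Gaussian KDE fit on the logit of scores; returns a closure evaluating the
# density back on the score scale (logit-normal Jacobian)
.logit_kde <- function(sample, bandwidth = NULL, eps = 1e-6) {
  t <- .logit(sample, eps)
  h <- bandwidth
  if (is.null(h)) {
    h <- tryCatch(stats::bw.SJ(t), error = function(e) stats::bw.nrd0(t))
    if (!is.finite(h) || h <= 0) h <- 0.1
  }
  function(s) {
    ts <- .logit(s, eps)
    f <- vapply(ts, function(ti) mean(stats::dnorm((ti - t) / h)) / h,
                numeric(1))
    sc <- pmin(1 - eps, pmax(eps, s))
    f / (sc * (1 - sc))
  }
}

#' Posterior probability that a region is actively translated
#'
#' Evaluates the two-class Bayes posterior
#' `f_a(s) * pi / (f_a(s) * pi + f_n(s) * (1 - pi))` with `f_a`, `f_n` the
#' smoothed score densities of the active and null calibration samples and
#' `pi` the empirical active prior. Densities are floored at a small
#' epsilon so scores outside both supports do not produce 0/0.
#'
#' @param score Score(s) in \[0,1\].
#' @param cal A [build_calibration()] result.
#' @param eps Density floor (default 1e-10).
#' @return Posterior probabilities in \[0,1\], vectorized over `score`.
#' @export
posterior_probability <- function(score, cal, eps = 1e-10) {
  stopifnot(inherits(cal, "ScoreCalibration"))
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    stop("score must be in [0, 1]")
  }
  out <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  if (any(ok)) {
    fa <- pmax(eps, cal$active_kde(score[ok]))
    fn <- pmax(eps, cal$null_kde(score[ok]))
    p <- cal$prior_active
    out[ok] <- fa * p / (fa * p + fn * (1 - p))
  }
  out
}

#' Call translation status for scored regions
#'
#' Applies the calibrated threshold (inclusive: a score exactly at the
#' threshold is called translated) and attaches posterior probabilities.
#' Unscorable regions are kept in the output with `translated = FALSE` and
#' their reason, so every input region appears exactly once.
#'
#' @param scores data.frame with columns `id`, `score`, `fpkm` and
#'   optionally `region`, `reason`.
#' @param cal A [build_calibration()] result.
#' @return data.frame of translation calls: `id`, `region`, `score`,
#'   `fpkm`, `posterior`, `translated`, `threshold_used`, `reason`.
#' @export
classify <- function(scores, cal) {
  stopifnot(inherits(cal, "ScoreCalibration"), is.data.frame(scores))
  data.frame(
    id = scores$id,
    region = if ("region" %in% names(scores)) scores$region else NA_character_,
    score = scores$score,
    fpkm = scores$fpkm,
    posterior = posterior_probability(scores$score, cal),
    translated = !is.na(scores$score) & scores$score >= cal$threshold,
    threshold_used = cal$threshold,
    reason = if ("reason" %in% names(scores)) scores$reason else
      ifelse(is.na(scores$score), "unscorable", NA_character_),
    stringsAsFactors = FALSE)
}
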