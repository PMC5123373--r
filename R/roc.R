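#' ROC curve and AUC of a score against binary labels
#'
#' AUC is computed by the rank statistic (Mann-Whitney U divided by
#' `n_pos * n_neg`, midranks for ties), the curve by a threshold sweep over
#' the observed scores. Rows with `NA` scores are dropped.
#'
#' @param score Numeric scores (higher = more positive-like).
#' @param label Logical (or 0/1) class labels; both classes must occur.
#' @return A `RocResult`: list with `auc`, `curve` (data.frame `fpr`,
#'   `tpr`, monotone non-decreasing in both), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]
  label <- label[ok]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc needs both classes present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  }
  r <- rank(score)  # midranks
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  l <- label[ord]
  grp <- cumsum(!duplicated(s))           # tie groups share a threshold
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n_neg),
                      tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Benchmark metrics by ROC over a series of abundance cutoffs
#'
#' Mirrors the usual classifier benchmark for translation callers: regions
#' are labelled "actively translated" when their FPKM reaches each cutoff
#' in turn (the abundance proxy for truth), or by an explicit truth column
#' when one is supplied, and each metric column is scored by AUC. FLOSS is
#' negated before ranking (low FLOSS is coding-like).
#'
#' @param tbl data.frame carrying `fpkm` plus the metric columns.
#' @param cutoffs FPKM cutoffs (default `c(0.5, 1, 3, 5, 10)`).
#' @param metrics Metric column names (default those of the main results
#'   table that are present).
#' @param negate Metric names ranked low-to-high (default `"floss"`).
#' @param label_col Optional logical truth column; when given, it replaces
#'   the FPKM labelling and `cutoff` is reported as `NA`.
#' @return Tidy data.frame: `metric`, `cutoff`, `auc`, `n_pos`, `n_neg`;
#'   `auc` is `NA` where a cutoff yields a single class.
#' @export
benchmark_over_cutoffs <- function(tbl, cutoffs = c(0.5, 1, 3, 5, 10),
                                   metrics = intersect(
                                     c("spectre_score", "orfscore", "floss"),
                                     names(tbl)),
                                   negate = "floss", label_col = NULL) {
  stopifnot(is.data.frame(tbl), length(metrics) > 0L)
  label_sets <- if (is.null(label_col)) {
    stats::setNames(lapply(cutoffs, function(ct) tbl$fpkm >= ct),
                    as.character(cutoffs))
  } else {
    stats::setNames(list(as.logical(tbl[[label_col]])), NA_character_)
  }
  rows <- list()
  for (ci in seq_along(label_sets)) {
    lab <- label_sets[[ci]]
    for (metric in metrics) {
      v <- tbl[[metric]]
      if (metric %in% negate) v <- -v
      res <- tryCatch(roc_auc(v, lab), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric,
        cutoff = if (is.null(label_col)) cutoffs[ci] else NA_real_,
        auc = if (is.null(res)) NA_real_ else res$auc,
        n_pos = if (is.null(res)) sum(lab, na.rm = TRUE) else res$n_pos,
        n_neg = if (is.null(res)) sum(!lab, na.rm = TRUE) else res$n_neg,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
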