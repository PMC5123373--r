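#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline with its default. The
#' configuration is serialized alongside every run (`run_manifest.json`).
#'
#' @param bam Coordinate-sorted, indexed BAM of ribosome-profiling
#'   alignments.
#' @param gtf Transcript annotation (GENCODE-style GTF).
#' @param outdir Output directory (created if missing).
#' @param offsets P-site offset table ([default_psite_offsets()]).
#' @param default_offset Offset for read lengths missing from the table
#'   (`NULL`: skip such reads).
#' @param mapq_min Minimum mapping quality.
#' @param window A [window_spec()].
#' @param region_mode `"auto"` (CDS for coding transcripts, full transcript
#'   otherwise), `"full"`, or `"CDS"` (coding transcripts only).
#' @param fpkm_cutoff,fdr,null_mode,min_calibration_n Calibration
#'   parameters, see [build_calibration()].
#' @param comparators Also compute FLOSS and ORFscore columns.
#' @param floss_lengths Length range for FLOSS distributions.
#' @param filter_conflicts Drop transcripts conflicting with a different
#'   biotype class ([filter_conflicting_transcripts()]).
#' @param flank Flank distance for the conflict filter.
#' @param benchmark_cutoffs FPKM cutoffs for the ROC benchmark table
#'   (`NULL` to skip).
#' @param threads Worker count; work is chunked by chromosome and merged in
#'   a fixed order, so results are identical for any thread count.
#' @param seed Integer seed recorded in the manifest (the scoring path is
#'   deterministic; the seed governs any downstream resampling).
#' @return A `RunConfig` list.
#' @export
run_config <- function(bam, gtf, outdir,
                       offsets = default_psite_offsets(),
                       default_offset = NULL, mapq_min = 0L,
                       window = window_spec(),
                       region_mode = c("auto", "full", "CDS"),
                       fpkm_cutoff = 5, fdr = 0.05,
                       null_mode = c("fpkm", "biotype"),
                       min_calibration_n = 50L,
                       comparators = TRUE, floss_lengths = 20:40,
                       filter_conflicts = TRUE, flank = 0L,
                       benchmark_cutoffs = c(0.5, 1, 3, 5, 10),
                       threads = 1L, seed = 1L) {
  structure(list(bam = bam, gtf = gtf, outdir = outdir, offsets = offsets,
                 default_offset = default_offset,
                 mapq_min = as.integer(mapq_min), window = window,
                 region_mode = match.arg(region_mode),
                 fpkm_cutoff = fpkm_cutoff, fdr = fdr,
                 null_mode = match.arg(null_mode),
                 min_calibration_n = as.integer(min_calibration_n),
                 comparators = isTRUE(comparators),
                 floss_lengths = floss_lengths,
                 filter_conflicts = isTRUE(filter_conflicts),
                 flank = as.integer(flank),
                 benchmark_cutoffs = benchmark_cutoffs,
                 threads = as.integer(threads), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full translation-calling pipeline
#'
#' Executes annotation parsing, conflict filtering, P-site coverage
#' extraction, windowed coherence scoring, FDR calibration, translation
#' classification, comparator metrics and the output writers. Work is
#' partitioned by chromosome and merged by `(chrom, start,
#' transcript_id)`, so the output is identical for 1 or `k` workers.
#'
#' Files written to `cfg$outdir`: `results.tsv` (one row per scored
#' region), `windows_coherence.bedGraph` and `windows_posterior.bedGraph`
#' (per-window tracks, 0-based half-open), `calibration.json`,
#' `benchmark.tsv` (when requested), `run_manifest.json`, `run.log`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `results` (the main table),
#'   `calibration`, `benchmark`, and `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!file.exists(cfg$bam)) stop("BAM file not found: ", cfg$bam)
  if (!file.exists(paste0(cfg$bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", cfg$bam))) {
    stop("BAM index (.bai) not found for ", cfg$bam,
         "; index the BAM before running")
  }
  if (!file.exists(cfg$gtf)) stop("GTF file not found: ", cfg$gtf)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  log("[annotation] parsing %s", cfg$gtf)
  models <- parse_annotation(cfg$gtf)
  log("[annotation] %d transcript model(s)", length(models))
  if (cfg$filter_conflicts) {
    models <- filter_conflicting_transcripts(models, flank = cfg$flank)
    removed <- attr(models, "removed")
    log("[filter] removed %d conflicting transcript(s)%s", length(removed),
        if (length(removed)) paste0(": ", paste(removed, collapse = ", "))
        else "")
  }
  if (cfg$region_mode == "CDS") {
    models <- Filter(function(m) !is.null(m$cds), models)
  }
  if (length(models) == 0L) stop("[annotation] no transcripts left to score")

  stats_tab <- Rsamtools::idxstatsBam(cfg$bam)
  total_mapped <- sum(stats_tab$mapped)
  log("[coverage] %d mapped reads in %s", total_mapped, cfg$bam)
  if (total_mapped == 0L) stop("[coverage] BAM contains no mapped reads")

  score_one <- function(m) {
    region <- switch(cfg$region_mode,
                     auto = if (is.null(m$cds)) "full" else "CDS",
                     full = "full", CDS = "CDS")
    prof <- extract_psite_profile(cfg$bam, m, region,
                                  offset_table = cfg$offsets,
                                  default_offset = cfg$default_offset,
                                  mapq_min = cfg$mapq_min)
    ab <- compute_fpkm(prof, total_mapped)
    sc <- spectre_score(normalize_coverage(prof$counts), cfg$window)
    list(model = m, region = region, profile = prof, abundance = ab,
         score = sc)
  }
  chroms <- sort(unique(vapply(models, `[[`, character(1), "chrom")))
  by_chrom <- lapply(chroms, function(ch) {
    Filter(function(m) m$chrom == ch, models)
  })
  worker <- function(ms) lapply(ms, score_one)
  chunks <- if (cfg$threads > 1L) {
    parallel::mclapply(by_chrom, worker, mc.cores = cfg$threads)
  } else {
    lapply(by_chrom, worker)
  }
  scored <- unlist(chunks, recursive = FALSE)
  ord <- order(vapply(scored, function(x) x$model$chrom, character(1)),
               vapply(scored, function(x) min(x$model$exons[, 1L]), integer(1)),
               vapply(scored, function(x) x$model$transcript_id, character(1)))
  scored <- scored[ord]
  log("[score] scored %d region(s)", length(scored))

  tbl <- do.call(rbind, lapply(scored, function(x) {
    m <- x$model
    data.frame(
      transcript_id = m$transcript_id, gene_id = m$gene_id,
      chrom = m$chrom, start = min(m$exons[, 1L]), end = max(m$exons[, 2L]),
      strand = m$strand, biotype = m$biotype, region = x$region,
      length = x$abundance$region_length_nt,
      read_count = x$abundance$read_count, fpkm = x$abundance$fpkm,
      spectre_score = x$score$score, reason = x$score$reason,
      stringsAsFactors = FALSE)
  }))

  if (cfg$comparators) {
    coding <- vapply(scored, function(x) !is.null(x$model$cds), logical(1))
    ref <- tryCatch(
      floss_reference(lapply(scored[coding], function(x) x$profile),
                      lengths = cfg$floss_lengths),
      error = function(e) NULL)
    tbl$floss <- vapply(scored, function(x) {
      if (is.null(ref)) return(NA_real_)
      floss_score(length_distribution(x$profile$length_histogram,
                                      cfg$floss_lengths), ref)
    }, numeric(1))
    tbl$orfscore <- vapply(scored, function(x) {
      orfscore(frame_counts(x$profile$counts))
    }, numeric(1))
    fence <- tryCatch(
      floss_outlier_cutoff(tbl$read_count[coding], tbl$floss[coding]),
      error = function(e) NULL)
    tbl$floss_outlier <- if (is.null(fence)) NA else {
      attr(fence, "is_outlier")(tbl$read_count, tbl$floss)
    }
    if (is.null(fence)) {
      log("[comparators] too few coding reference points for the FLOSS fence")
    }
  }

  cal <- tryCatch(
    build_calibration(
      data.frame(id = tbl$transcript_id, score = tbl$spectre_score,
                 fpkm = tbl$fpkm, biotype = tbl$biotype,
                 stringsAsFactors = FALSE),
      fpkm_cutoff = cfg$fpkm_cutoff, fdr = cfg$fdr,
      null_mode = cfg$null_mode, min_n = cfg$min_calibration_n),
    error = function(e) {
      log("[calibration] skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(cal)) {
    log("[calibration] threshold %.6f at FDR %.3g (FPKM cutoff %.3g)",
        cal$threshold, cal$fdr, cal$fpkm_cutoff)
    calls <- classify(
      data.frame(id = tbl$transcript_id, region = tbl$region,
                 score = tbl$spectre_score, fpkm = tbl$fpkm,
                 reason = tbl$reason, stringsAsFactors = FALSE), cal)
    tbl$posterior <- calls$posterior
    tbl$translated <- calls$translated
  } else {
    tbl$posterior <- NA_real_
    tbl$translated <- NA
  }

  files <- list(results = file.path(cfg$outdir, "results.tsv"))
  .write_results_tsv(tbl, files$results)
  files$coherence_track <- file.path(cfg$outdir, "windows_coherence.bedGraph")
  files$posterior_track <- file.path(cfg$outdir, "windows_posterior.bedGraph")
  .write_tracks(scored, cal, cfg, files$coherence_track,
                files$posterior_track)
  if (!is.null(cal)) {
    files$calibration <- file.path(cfg$outdir, "calibration.json")
    jsonlite::write_json(
      list(fpkm_cutoff = cal$fpkm_cutoff, fdr = cal$fdr,
           null_mode = cal$null_mode, threshold = cal$threshold,
           n_active = length(cal$active_scores),
           n_null = length(cal$null_scores),
           prior_active = cal$prior_active),
      files$calibration, auto_unbox = TRUE, digits = NA)
  }
  bench <- NULL
  if (!is.null(cfg$benchmark_cutoffs) && cfg$comparators) {
    bench <- benchmark_over_cutoffs(tbl, cutoffs = cfg$benchmark_cutoffs)
    files$benchmark <- file.path(cfg$outdir, "benchmark.tsv")
    utils::write.table(bench, files$benchmark, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files$manifest <- file.path(cfg$outdir, "run_manifest.json")
  manifest <- cfg
  manifest$window <- unclass(manifest$window)
  manifest$offsets <- as.list(manifest$offsets)
  jsonlite::write_json(unclass(manifest), files$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files$log <- file.path(cfg$outdir, "run.log")
  writeLines(log_lines, files$log)
  invisible(list(results = tbl, calibration = cal, benchmark = bench,
                 files = files))
}

.fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

.write_results_tsv <- function(tbl, path) {
  out <- tbl
  for (col in intersect(c("spectre_score", "posterior", "floss", "orfscore"),
                        names(out))) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  out$fpkm <- ifelse(is.na(out$fpkm), "NA",
                     formatC(out$fpkm, digits = 4L, format = "f"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ribospec results; genomic start/end are 0-based half-open",
               paste(names(out), collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

.write_tracks <- function(scored, cal, cfg, coh_path, post_path) {
  coh_lines <- character(0)
  post_lines <- character(0)
  for (x in scored) {
    if (!x$score$scorable || x$score$n_windows == 0L) next
    trk <- window_track(x$score, x$model, x$region, cfg$window)
    coh_lines <- c(coh_lines, sprintf("%s\t%d\t%d\t%s", trk$chrom, trk$start,
                                      trk$end, .fmt_num(trk$value)))
    if (!is.null(cal)) {
      post <- posterior_probability(x$score$window_scores$coherence, cal)
      trk <- window_track(x$score, x$model, x$region, cfg$window,
                          values = post)
      post_lines <- c(post_lines, sprintf("%s\t%d\t%d\t%s", trk$chrom,
                                          trk$start, trk$end,
                                          .fmt_num(trk$value)))
    }
  }
  writeLines(c(paste0("track type=bedGraph name=ribospec_coherence ",
                      "description=\"per-window coherence (0-based half-open)\""),
               coh_lines), coh_path)
  writeLines(c(paste0("track type=bedGraph name=ribospec_posterior ",
                      "description=\"per-window posterior (0-based half-open)\""),
               post_lines), post_path)
  invisible(NULL)
}
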