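#' Parse a GTF annotation into transcript models
#'
#' Reads a GENCODE-style GTF (1-based closed intervals, converted internally
#' to 0-based half-open) and builds one [transcript_model()] per transcript
#' from its `exon` and, where present, `CDS` features. Biotypes are taken
#' from the `transcript_biotype` or `transcript_type` attribute (falling back
#' to `gene_biotype`/`gene_type`, then `"unknown"`).
#'
#' @param gtf_path Path to a GTF file.
#' @param biotype_filter Optional character vector; when given, only
#'   transcripts whose biotype is in the set are returned.
#' @return Named list of `TranscriptModel` objects (names = transcript ids).
#'   Transcripts with zero exon features are dropped with a warning.
#' @export
parse_annotation <- function(gtf_path, biotype_filter = NULL) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  .check_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "CDS", "transcript")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id)) stop("GTF carries no transcript_id attribute")

  biotype_of <- function(idx) {
    for (field in c("transcript_biotype", "transcript_type",
                    "gene_biotype", "gene_type")) {
      v <- meta[[field]]
      if (!is.null(v) && !is.na(v[idx][1L])) return(as.character(v[idx][1L]))
    }
    "unknown"
  }

  tx_ids <- unique(stats::na.omit(meta$transcript_id))
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  skipped <- character(0)
  for (tid in tx_ids) {
    idx <- which(meta$transcript_id == tid)
    ex <- idx[meta$type[idx] == "exon"]
    if (length(ex) == 0L) {
      skipped <- c(skipped, tid)
      next
    }
    cd <- idx[meta$type[idx] == "CDS"]
    exons <- cbind(GenomicRanges::start(gr)[ex] - 1L, GenomicRanges::end(gr)[ex])
    cds <- if (length(cd)) {
      cbind(GenomicRanges::start(gr)[cd] - 1L, GenomicRanges::end(gr)[cd])
    } else NULL
    gid <- if (!is.null(meta$gene_id)) as.character(meta$gene_id[idx[1L]]) else NA_character_
    models[[tid]] <- transcript_model(
      transcript_id = tid, gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[idx[1L]],
      strand = as.character(GenomicRanges::strand(gr))[idx[1L]],
      exons = exons, cds = cds, biotype = biotype_of(idx[1L]))
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped), " transcript(s) with zero exons: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "")
    models <- models[!names(models) %in% skipped]
  }
  models <- Filter(Negate(is.null), models)
  if (!is.null(biotype_filter)) {
    models <- Filter(function(m) m$biotype %in% biotype_filter, models)
  }
  models
}

# cheap structural validation so malformed rows fail with a line number
# rather than deep inside the importer
.check_gtf_lines <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield < 9L]
  if (length(bad)) {
    stop("malformed GTF line ", bad[1L], " in ", gtf_path,
         " (expected 9 tab-separated fields, found ", nfield[which(which(body) %in% bad)[1L]], ")")
  }
  invisible(TRUE)
}

#' Remove transcripts that conflict with a different biotype class
#'
#' Drops every transcript whose genomic span (padded by `flank`) overlaps —
#' on either strand, so antisense pairs count — the span of a transcript of
#' the other biotype class (coding vs. non-coding). Conflicts between
#' transcripts of the same class (e.g. two isoforms of one gene) are kept.
#' This mirrors the usual pre-filter applied before benchmarking translation
#' classifiers, where ambiguous signal from overlapping coding/non-coding
#' loci would contaminate both score distributions.
#'
#' @param models List of [transcript_model()] objects.
#' @param flank Non-negative flank distance in nt (default 0: pure
#'   overlap/antisense conflicts only).
#' @param coding_biotypes Biotypes treated as the coding class.
#' @return The surviving subset of `models`, with the removed ids stored in
#'   `attr(, "removed")`.
#' @export
filter_conflicting_transcripts <- function(models, flank = 0L,
                                           coding_biotypes = "protein_coding") {
  if (length(models) == 0L) return(models)
  is_coding <- vapply(models, function(m) m$biotype %in% coding_biotypes,
                      logical(1))
  flank <- as.integer(flank)
  spans <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = pmax(1L, vapply(models, function(m) min(m$exons[, 1L]),
                              integer(1)) + 1L - flank),
      end = vapply(models, function(m) max(m$exons[, 2L]),
                   integer(1)) + flank),
    strand = vapply(models, `[[`, character(1), "strand"))
  hits <- GenomicRanges::findOverlaps(spans, spans, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  conflict <- q != s & is_coding[q] != is_coding[s]
  drop <- unique(c(q[conflict], s[conflict]))
  out <- models[setdiff(seq_along(models), drop)]
  attr(out, "removed") <- vapply(models[drop], `[[`, character(1),
                                 "transcript_id")
  out
}
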