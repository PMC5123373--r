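#' Transcript model
#'
#' A `TranscriptModel` describes the exon/CDS structure of one transcript and
#' defines the coordinate sets over which coverage is extracted and scored.
#' All coordinates are 0-based half-open in genomic space; transcript-space
#' coordinates run 0..len-1 from the 5' end of the transcript (so exon order
#' is reversed relative to the genome on the minus strand).
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (`start`, `end`), 0-based half-open,
#'   non-overlapping, sorted by genomic start.
#' @param cds Optional two-column matrix of CDS intervals (same convention),
#'   a subset of the exonic space; `NULL` for non-coding transcripts.
#' @param biotype Transcript biotype string (e.g. `"protein_coding"`,
#'   `"lincRNA"`).
#'
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  exons <- .as_interval_matrix(exons)
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("transcript '", transcript_id, "' has overlapping exons")
  }
  if (!is.null(cds) && nrow(.as_interval_matrix(cds)) == 0L) cds <- NULL
  if (!is.null(cds)) {
    cds <- .as_interval_matrix(cds)
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
  }
  obj <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         cds = cds,
         biotype = as.character(biotype)),
    class = "TranscriptModel"
  )
  if (!is.null(cds)) {
    pos <- .genomic_positions(exons)
    if (!all(.genomic_positions(cds) %in% pos)) {
      stop("transcript '", transcript_id, "' has CDS outside its exons")
    }
  }
  obj
}

.as_interval_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  x <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  x
}

# all genomic positions (0-based) covered by a set of half-open intervals,
# ascending
.genomic_positions <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    seq.int(intervals[i, 1L], intervals[i, 2L] - 1L)
  }), use.names = FALSE)
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%s strand %s\n", x$transcript_id,
              x$biotype, x$chrom,
              paste0(min(x$exons[, 1]), "-", max(x$exons[, 2])), x$strand))
  cat(sprintf("  %d exon(s), length %d nt%s\n", nrow(x$exons), tx_length(x),
              if (is.null(x$cds)) "" else
                sprintf(", CDS %d nt", region_length(x, "CDS"))))
  invisible(x)
}

#' Total exonic length of a transcript
#' @param model A [transcript_model()].
#' @return Integer length in nucleotides.
#' @export
tx_length <- function(model) {
  sum(model$exons[, 2L] - model$exons[, 1L])
}

#' Genomic coordinates of a scored sub-region
#'
#' Returns the ordered coordinate set C of a named sub-region: the genomic
#' position (0-based) of every nucleotide of the region, ordered 5' to 3' in
#' transcript orientation (descending genomic order on the minus strand).
#' Coordinate `C[i]` is transcript/region position `i - 1`.
#'
#' @param model A [transcript_model()].
#' @param region One of `"full"`, `"CDS"`, `"5UTR"`, `"3UTR"`. UTR and CDS
#'   regions require an annotated CDS.
#' @return Integer vector of genomic positions; length 0 if the region is
#'   empty (e.g. a transcript without a 5'UTR).
#' @export
region_coords <- function(model, region = "full") {
  region <- match.arg(region, c("full", "CDS", "5UTR", "3UTR"))
  pos <- .genomic_positions(model$exons)          # ascending genomic
  if (model$strand == "-") pos <- rev(pos)        # now 5' -> 3'
  if (region == "full") return(pos)
  if (is.null(model$cds)) {
    stop("transcript '", model$transcript_id,
         "' has no CDS; region '", region, "' is undefined")
  }
  in_cds <- pos %in% .genomic_positions(model$cds)
  switch(region,
         CDS = pos[in_cds],
         `5UTR` = pos[seq_len(which(in_cds)[1L] - 1L)],
         `3UTR` = {
           last <- which(in_cds)[sum(in_cds)]
           if (last == length(pos)) integer(0) else pos[(last + 1L):length(pos)]
         })
}

#' Length of a named sub-region
#' @inheritParams region_coords
#' @return Integer number of nucleotides.
#' @export
region_length <- function(model, region = "full") {
  length(region_coords(model, region))
}

#' Genomic span of a transcript as a GRanges
#' @param model A [transcript_model()].
#' @param flank Non-negative integer padding added on both sides.
#' @return A length-1 [GenomicRanges::GRanges] (1-based, as usual for GRanges).
#' @keywords internal
tx_span <- function(model, flank = 0L) {
  GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(
      start = max(1L, min(model$exons[, 1L]) + 1L - flank),
      end = max(model$exons[, 2L]) + flank),
    strand = model$strand)
}
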