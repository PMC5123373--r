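#' Default P-site offset table
#'
#' Ribosome-protected fragments from cycloheximide-treated libraries are
#' typically 28-30 nt with the P-site 12 nt downstream of the 5' read end;
#' the default table applies the +12 offset over the commonly accepted
#' 26-32 nt footprint range. Reads whose length is absent from the table are
#' skipped unless a global `default_offset` is supplied to the extraction
#' functions.
#'
#' @param lengths Integer read lengths covered by the table.
#' @param offset Offset in nt from the 5' end of the read.
#' @return Named integer vector mapping read length to offset.
#' @export
default_psite_offsets <- function(lengths = 26:32, offset = 12L) {
  stats::setNames(rep(as.integer(offset), length(lengths)),
                  as.character(lengths))
}

#' P-site position of aligned reads
#'
#' Collapses each aligned read to the genomic coordinate of its inferred
#' ribosomal P-site: 5' end + offset for plus-strand reads, 3' end - offset
#' for minus-strand reads, with the offset looked up by read length.
#'
#' @param start 0-based leftmost aligned genomic position(s).
#' @param end 0-based position(s) of the last aligned base (inclusive), i.e.
#'   `start + reference_width - 1`.
#' @param strand `"+"`/`"-"` per read.
#' @param length Read length(s) in nt used for the offset lookup.
#' @param offset_table Named vector from [default_psite_offsets()].
#' @param default_offset Offset applied to lengths missing from the table;
#'   `NULL` (default) skips such reads.
#' @return Integer vector of 0-based P-site genomic positions, `NA` for
#'   skipped reads; the number skipped is in `attr(, "n_skipped")`.
#' @export
adjust_to_psite <- function(start, end, strand, length,
                            offset_table = default_psite_offsets(),
                            default_offset = NULL) {
  off <- unname(offset_table[as.character(length)])
  if (!is.null(default_offset)) off[is.na(off)] <- as.integer(default_offset)
  pos <- ifelse(strand == "+", start + off, end - off)
  pos <- as.integer(pos)
  structure(pos, n_skipped = sum(is.na(off)))
}

#' Extract a P-site coverage profile over a transcript region
#'
#' Pulls primary, mapped, strand-matched alignments over the region from an
#' indexed BAM file, collapses each to its P-site with [adjust_to_psite()],
#' and tallies P-sites falling on the region's coordinate set C. Element
#' `i` of `counts` is the number of P-sites at region position `i - 1`
#' (transcript orientation), so reads landing in introns or outside the
#' region contribute nothing.
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param model A [transcript_model()].
#' @param region Region name passed to [region_coords()].
#' @param offset_table,default_offset See [adjust_to_psite()].
#' @param mapq_min Minimum mapping quality (default 0).
#' @return A `PSiteProfile`: list with `transcript_id`, `region`, `counts`
#'   (integer, length = region length), `length_histogram` (table of read
#'   lengths among counted reads), `n_assigned`, `n_skipped_length`.
#' @export
extract_psite_profile <- function(bam_path, model, region = "full",
                                  offset_table = default_psite_offsets(),
                                  default_offset = NULL, mapq_min = 0L) {
  coords <- region_coords(model, region)
  prof <- list(transcript_id = model$transcript_id, region = region,
               counts = integer(length(coords)),
               length_histogram = integer(0),
               n_assigned = 0L, n_skipped_length = 0L)
  class(prof) <- "PSiteProfile"
  if (length(coords) == 0L) return(prof)

  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  if (!model$chrom %in% names(hdr)) {
    warning("chromosome '", model$chrom, "' absent from BAM header of ",
            bam_path, "; returning empty profile")
    return(prof)
  }
  pad <- 60L  # generous: max footprint length + offset
  which <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(start = max(1L, min(coords) + 1L - pad),
                     end = max(coords) + 1L + pad))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = which, mapqFilter = as.integer(mapq_min))
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param)
  if (length(aln) == 0L) return(prof)

  str <- as.character(GenomicAlignments::strand(aln))
  keep <- str == model$strand
  aln <- aln[keep]
  if (length(aln) == 0L) return(prof)

  qw <- GenomicAlignments::qwidth(aln)
  psite <- adjust_to_psite(
    start = GenomicAlignments::start(aln) - 1L,
    end = GenomicAlignments::end(aln) - 1L,
    strand = as.character(GenomicAlignments::strand(aln)),
    length = qw,
    offset_table = offset_table, default_offset = default_offset)
  prof$n_skipped_length <- attr(psite, "n_skipped")

  idx <- match(psite, coords)
  hit <- !is.na(idx)
  prof$counts <- tabulate(idx[hit], nbins = length(coords))
  prof$n_assigned <- sum(hit)
  lh <- table(qw[hit])
  prof$length_histogram <- stats::setNames(as.integer(lh), names(lh))
  prof
}

#' @export
print.PSiteProfile <- function(x, ...) {
  cat(sprintf("PSiteProfile %s [%s]: %d nt, %d P-sites assigned\n",
              x$transcript_id, x$region, length(x$counts), x$n_assigned))
  invisible(x)
}

#' FPKM of a region profile
#'
#' Fragments per kilobase of region per million mapped reads:
#' `read_count * 1e9 / (region_length * total_mapped_reads)`, with
#' `read_count` the P-sites assigned to the region — abundance and scoring
#' thus describe the same evidence.
#'
#' @param profile A `PSiteProfile` from [extract_psite_profile()].
#' @param total_mapped_reads Positive integer library size.
#' @return An `AbundanceRecord`: list with `transcript_id`, `region`,
#'   `read_count`, `region_length_nt`, `fpkm`.
#' @export
compute_fpkm <- function(profile, total_mapped_reads) {
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be a positive number")
  }
  rc <- sum(profile$counts)
  len <- length(profile$counts)
  list(transcript_id = profile$transcript_id, region = profile$region,
       read_count = rc, region_length_nt = len,
       fpkm = if (len == 0L) 0 else rc * 1e9 / (len * total_mapped_reads))
}
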