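#' Per-nucleotide coverage from a read set
#'
#' Converts interval reads into a depth vector over the read set's
#' region: the value at position p is the number of reads whose interval
#' contains p.  Reads spanning a region boundary contribute only their
#' overlapping part (clipping, not exclusion), which makes chunked
#' whole-chromosome scans exact.
#'
#' @param readset a [ReadSet-class].
#' @param strand_mode `"same"` keeps reads whose strand equals the
#'   region strand (unstranded `"."` reads are always kept, the
#'   protocol-agnostic default); `"ignore"` piles up all reads.
#' @return A [CoverageTrack-class] of kind `"counts"` for the read set's
#'   sample.
#' @examples
#' reg <- GenomicInterval("chr1", 0, 100, "+")
#' rs <- ReadSet(reg, data.frame(start = 10, end = 60, strand = "+"), "s1")
#' cov <- pileup_coverage(rs)
#' sum(track_values(cov))  # 50: one read, 50 nt of overlap
#' @export
pileup_coverage <- function(readset, strand_mode = c("same", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  region <- readset@region
  if (strand_mode == "same" && region@strand == ".")
    stop("strand_mode = 'same' requires a stranded ('+' or '-') region")
  rd <- readset@reads
  if (strand_mode == "same" && nrow(rd))
    rd <- rd[rd$strand == region@strand | rd$strand == ".", , drop = FALSE]
  len <- interval_length(region)
  if (!nrow(rd)) {
    vals <- numeric(len)
  } else {
    s <- pmax(rd$start - region@start, 0L)
    e <- pmin(rd$end - region@start, len)
    # difference-array pileup: +1 at each clipped start, -1 past each end
    vals <- cumsum(tabulate(s + 1L, nbins = len) -
                   tabulate(e + 1L, nbins = len))
    # reads ending at the region end decrement past the vector; tabulate
    # with nbins = len drops those, as intended for a half-open region
  }
  CoverageTrack(region, vals, samples = readset@sample_id, kind = "counts")
}

#' Count reads in an interval
#'
#' @param readset a [ReadSet-class].
#' @param interval a [GenomicInterval-class] on the same chromosome as
#'   the read set's region.
#' @param rule `"any_overlap"` (default) counts reads overlapping the
#'   interval by at least one nucleotide; `"contained"` counts only
#'   reads lying fully inside it.
#' @details Reads are strand-matched against `interval` unless the
#'   interval's strand is `"."`; unstranded (`"."`) reads always count.
#' @return Integer read count.
#' @export
region_count <- function(readset, interval, rule = c("any_overlap", "contained")) {
  rule <- match.arg(rule)
  if (interval@chrom != readset@region@chrom)
    stop(sprintf("chromosome mismatch: interval on '%s', reads on '%s'",
                 interval@chrom, readset@region@chrom))
  rd <- readset@reads
  if (!nrow(rd)) return(0L)
  if (interval@strand != ".")
    rd <- rd[rd$strand == interval@strand | rd$strand == ".", , drop = FALSE]
  hit <- if (rule == "any_overlap")
    rd$start < interval@end & rd$end > interval@start
  else
    rd$start >= interval@start & rd$end <= interval@end
  sum(hit)
}

#' Restrict a track to a sub-interval
#'
#' @param track a [CoverageTrack-class].
#' @param sub a [GenomicInterval-class] fully inside the track's region.
#' @return A [CoverageTrack-class] over `sub` with the same samples and
#'   kind.
#' @export
slice_track <- function(track, sub) {
  region <- track@region
  if (sub@chrom != region@chrom || sub@start < region@start ||
      sub@end > region@end)
    stop("sub-interval must lie fully inside the track region")
  idx <- (sub@start - region@start + 1L):(sub@end - region@start)
  CoverageTrack(sub, track@values[idx, , drop = FALSE],
                samples = track@samples, kind = track@kind)
}
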