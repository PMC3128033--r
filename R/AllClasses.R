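#' @import methods
NULL

VALID_STRANDS <- c("+", "-", ".")
TRACK_KINDS <- c("counts", "normalized", "smoothed", "fold_change",
                 "splicing_index", "region_based")

#' Strand-aware genomic interval
#'
#' The universal coordinate currency of the package: a half-open,
#' 0-based interval `[start, end)` on a named chromosome with strand
#' `"+"`, `"-"` or `"."` (unstranded).  1-based formats (SAM, GTF/GFF,
#' the read TSV) are converted at I/O boundaries only.
#'
#' @slot chrom chromosome name.
#' @slot start 0-based inclusive start (>= 0).
#' @slot end exclusive end; `end - start` is the interval length.
#' @slot strand one of `"+"`, `"-"`, `"."`.
#' @export
setClass("GenomicInterval",
         representation(chrom = "character", start = "integer",
                        end = "integer", strand = "character"))

setValidity("GenomicInterval", function(object) {
  if (length(object@chrom) != 1L || length(object@start) != 1L ||
      length(object@end) != 1L || length(object@strand) != 1L)
    return("all slots must have length 1")
  if (is.na(object@start) || object@start < 0L)
    return("start must be a non-negative integer")
  if (is.na(object@end) || object@start >= object@end)
    return("start must be < end (intervals are half-open, length >= 1)")
  if (!object@strand %in% VALID_STRANDS)
    return("strand must be one of '+', '-', '.'")
  TRUE
})

#' Construct a GenomicInterval
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @param strand `"+"`, `"-"` or `"."` (default, unstranded).
#' @return A [GenomicInterval-class] object.
#' @examples
#' gi <- GenomicInterval("chr1", 100, 200, "+")
#' interval_length(gi)
#' @export
GenomicInterval <- function(chrom, start, end, strand = ".") {
  new("GenomicInterval", chrom = as.character(chrom),
      start = as.integer(start), end = as.integer(end),
      strand = as.character(strand))
}

#' Length of a genomic interval in nucleotides
#' @param x a [GenomicInterval-class].
#' @return integer, `end - start`.
#' @export
interval_length <- function(x) x@end - x@start

setMethod("show", "GenomicInterval", function(object) {
  cat(sprintf("GenomicInterval %s:%d-%d(%s) [%d nt]\n", object@chrom,
              object@start, object@end, object@strand,
              interval_length(object)))
})

#' Minimally-attributed aligned reads for one sample in one region
#'
#' Reads carry only chromosome (implied by the region), start, end and
#' strand -- no sequence, quality or CIGAR information.  Every read
#' overlaps the region by at least one nucleotide and reads are kept
#' sorted by (start, end).
#'
#' @slot region the [GenomicInterval-class] the reads were fetched for.
#' @slot reads data.frame with integer columns `start`, `end` (0-based
#'   half-open) and character `strand`.
#' @slot sample_id sample identifier.
#' @export
setClass("ReadSet",
         representation(region = "GenomicInterval", reads = "data.frame",
                        sample_id = "character"))

setValidity("ReadSet", function(object) {
  rd <- object@reads
  if (!all(c("start", "end", "strand") %in% names(rd)))
    return("reads must have columns start, end, strand")
  if (nrow(rd)) {
    if (any(rd$start >= rd$end)) return("reads must satisfy start < end")
    if (!all(rd$strand %in% VALID_STRANDS))
      return("read strand must be one of '+', '-', '.'")
    if (any(rd$end <= object@region@start | rd$start >= object@region@end))
      return("every read must overlap the region by >= 1 nt")
  }
  TRUE
})

#' Construct a ReadSet
#'
#' @param region [GenomicInterval-class] the reads belong to.
#' @param reads data.frame with columns `start`, `end` (0-based,
#'   half-open) and `strand`; reads not overlapping `region` are an error.
#' @param sample_id sample identifier.
#' @return A [ReadSet-class]; reads are sorted by (start, end).
#' @export
ReadSet <- function(region, reads = empty_reads(), sample_id = "sample") {
  reads <- as.data.frame(reads)[, c("start", "end", "strand")]
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  reads$strand <- as.character(reads$strand)
  reads <- reads[order(reads$start, reads$end, reads$strand), , drop = FALSE]
  rownames(reads) <- NULL
  new("ReadSet", region = region, reads = reads,
      sample_id = as.character(sample_id))
}

#' @rdname ReadSet
#' @export
empty_reads <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d reads, sample '%s' in %s:%d-%d(%s)\n",
              nrow(object@reads), object@sample_id, object@region@chrom,
              object@region@start, object@region@end, object@region@strand))
})

#' Per-nucleotide value track over a region
#'
#' One column per sample, one row per nucleotide of the region.  The
#' `kind` tag records what the values are: raw `"counts"`, library-size
#' `"normalized"`, lowess-`"smoothed"`, `"fold_change"`,
#' `"splicing_index"` or discretized `"region_based"` coverage.
#'
#' @slot region [GenomicInterval-class] the values span.
#' @slot samples ordered sample ids (the column names).
#' @slot values numeric matrix, `interval_length(region)` x `length(samples)`.
#' @slot kind one of the kinds above.
#' @export
setClass("CoverageTrack",
         representation(region = "GenomicInterval", samples = "character",
                        values = "matrix", kind = "character"))

setValidity("CoverageTrack", function(object) {
  if (nrow(object@values) != interval_length(object@region))
    return("values must have one row per nucleotide of the region")
  if (ncol(object@values) != length(object@samples))
    return("values must have one column per sample")
  if (!object@kind %in% TRACK_KINDS)
    return(paste("kind must be one of:", paste(TRACK_KINDS, collapse = ", ")))
  if (object@kind == "counts") {
    v <- object@values
    if (any(v < 0) || any(v != round(v)))
      return("counts tracks must hold non-negative integers")
  }
  TRUE
})

#' Construct a CoverageTrack
#'
#' @param region [GenomicInterval-class].
#' @param values numeric vector (single sample) or matrix with one row
#'   per nucleotide and one column per sample.
#' @param samples sample ids; defaults to the matrix column names.
#' @param kind value kind tag (see [CoverageTrack-class]).
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(region, values, samples = NULL, kind = "counts") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) {
    samples <- colnames(values)
    if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(values)))
  }
  colnames(values) <- samples
  new("CoverageTrack", region = region, samples = as.character(samples),
      values = values, kind = kind)
}

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack (%s): %d nt x %d sample(s) in %s:%d-%d(%s)\n",
              object@kind, nrow(object@values), ncol(object@values),
              object@region@chrom, object@region@start, object@region@end,
              object@region@strand))
})

#' Extract one sample's value vector from a track
#' @param track a [CoverageTrack-class].
#' @param sample sample id; defaults to the first sample.
#' @return numeric vector of length `interval_length(track@region)`.
#' @export
track_values <- function(track, sample = NULL) {
  if (is.null(sample)) sample <- track@samples[1L]
  if (!sample %in% track@samples)
    stop(sprintf("sample '%s' not present in track (has: %s)", sample,
                 paste(track@samples, collapse = ", ")))
  track@values[, match(sample, track@samples)]
}

#' Gene annotations plus chromosome lengths
#'
#' @slot genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @slot chrom_lengths named integer vector of chromosome lengths.
#' @export
setClass("AnnotationSet",
         representation(genes = "data.frame", chrom_lengths = "integer"))

setValidity("AnnotationSet", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("gene_id must be unique")
  if (nrow(g)) {
    if (any(g$start < 0L | g$start >= g$end))
      return("gene intervals must satisfy 0 <= start < end")
    if (!all(g$chrom %in% names(object@chrom_lengths)))
      return("every gene chromosome needs an entry in chrom_lengths")
    if (any(g$end > object@chrom_lengths[g$chrom]))
      return("gene intervals must lie within their chromosome length")
    if (!all(g$strand %in% VALID_STRANDS))
      return("gene strand must be one of '+', '-', '.'")
  }
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return An [AnnotationSet-class].
#' @export
AnnotationSet <- function(genes, chrom_lengths) {
  genes <- as.data.frame(genes)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  cl <- as.integer(chrom_lengths)
  names(cl) <- names(chrom_lengths)
  new("AnnotationSet", genes = genes, chrom_lengths = cl)
}

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d genes on %d chromosome(s)\n",
              nrow(object@genes), length(object@chrom_lengths)))
})

#' Regions-by-samples table of read counts
#'
#' The export format consumed by count-based differential-expression
#' tools: one row per region (gene or discovered locus), one column per
#' sample, integer read counts.
#'
#' @slot regions data.frame with columns `label`, `chrom`, `start`,
#'   `end`, `strand` (coordinates 0-based half-open; may be `NA` for
#'   tables read back from disk with opaque labels).
#' @slot samples ordered sample ids.
#' @slot counts integer matrix, regions x samples.
#' @export
setClass("CountTable",
         representation(regions = "data.frame", samples = "character",
                        counts = "matrix"))

setValidity("CountTable", function(object) {
  if (nrow(object@counts) != nrow(object@regions))
    return("counts must have one row per region")
  if (ncol(object@counts) != length(object@samples))
    return("counts must have one column per sample")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Construct a CountTable
#' @param regions data.frame with at least a `label` column (plus
#'   `chrom`, `start`, `end`, `strand` when known).
#' @param samples sample ids.
#' @param counts integer matrix, regions x samples.
#' @return A [CountTable-class].
#' @export
CountTable <- function(regions, samples, counts) {
  regions <- as.data.frame(regions)
  for (col in c("chrom", "start", "end", "strand"))
    if (!col %in% names(regions)) regions[[col]] <- rep(NA, nrow(regions))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(regions$label, samples)
  new("CountTable", regions = regions, samples = as.character(samples),
      counts = counts)
}

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d regions x %d samples\n",
              nrow(object@counts), ncol(object@counts)))
})
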