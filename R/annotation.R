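#' Gene intervals on one chromosome and strand
#'
#' @param ann an [AnnotationSet-class].
#' @param chrom chromosome name (must be known to `ann`).
#' @param strand `"+"` or `"-"` to select one strand, `"."` for both.
#' @return data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`)
#'   sorted by start; 0-based half-open coordinates.
#' @export
gene_regions <- function(ann, chrom, strand = ".") {
  if (!chrom %in% names(ann@chrom_lengths))
    stop(sprintf("unknown chromosome '%s'", chrom))
  g <- ann@genes[ann@genes$chrom == chrom, , drop = FALSE]
  if (strand != ".") g <- g[g$strand == strand, , drop = FALSE]
  g <- g[order(g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Gene intervals widened by a flank
#'
#' Widens every gene by `flank` nucleotides on both sides, clamped to
#' the chromosome bounds, to check for expression immediately up- or
#' downstream of the annotated boundaries.
#'
#' @param ann an [AnnotationSet-class].
#' @param flank non-negative flank width in nucleotides (default 1000,
#'   a typical UTR-extension range).
#' @return data.frame in the layout of [gene_regions()], all
#'   chromosomes, sorted by (chrom, start).
#' @export
extended_gene_regions <- function(ann, flank = 1000L) {
  if (flank < 0L) stop("flank must be >= 0")
  g <- ann@genes
  g$start <- pmax(g$start - as.integer(flank), 0L)
  g$end <- pmin(g$end + as.integer(flank), ann@chrom_lengths[g$chrom])
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Intergenic complement on one chromosome and strand
#'
#' Overlapping genes are merged per strand before taking the
#' complement, so the result together with [gene_regions()] covers
#' `[0, chrom_length)` exactly once per (chrom, strand).
#'
#' @param ann an [AnnotationSet-class].
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."` (complement of all genes).
#' @return data.frame (`chrom`, `start`, `end`, `strand`) of sorted,
#'   disjoint, non-empty intervals.
#' @export
intergenic_regions <- function(ann, chrom, strand = ".") {
  len <- ann@chrom_lengths[chrom]
  if (is.na(len)) stop(sprintf("unknown chromosome '%s'", chrom))
  g <- gene_regions(ann, chrom, strand)
  if (!nrow(g)) {
    gap <- data.frame(start = 0L, end = as.integer(len))
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gp <- IRanges::gaps(ir, start = 1L, end = as.integer(len))
    gap <- data.frame(start = IRanges::start(gp) - 1L, end = IRanges::end(gp))
  }
  gap <- gap[gap$end > gap$start, , drop = FALSE]
  out <- data.frame(chrom = rep(chrom, nrow(gap)), start = gap$start,
                    end = gap$end, strand = rep(strand, nrow(gap)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split an interval into overlapping chunks
#'
#' Produces ordered chunks covering the interval, consecutive chunks
#' sharing exactly `overlap` nucleotides, for bounded-memory scans of
#' long regions.  Mined regions from the chunks are deduplicated by the
#' caller (see [merge_chunk_regions()]).
#'
#' @param interval a [GenomicInterval-class].
#' @param chunk_size chunk width; must exceed `2 * overlap`.
#' @param overlap nucleotides shared by consecutive chunks.
#' @return data.frame (`chrom`, `start`, `end`, `strand`) of chunks; a
#'   single row equal to the interval when it is shorter than
#'   `chunk_size`.
#' @export
chunk_iterator <- function(interval, chunk_size = 2e6, overlap = 1e4) {
  chunk_size <- as.integer(chunk_size); overlap <- as.integer(overlap)
  if (overlap < 0L || chunk_size <= 2L * overlap)
    stop("chunk_size must exceed 2 * overlap")
  starts <- seq.int(interval@start, interval@end - 1L,
                    by = chunk_size - overlap)
  ends <- pmin(starts + chunk_size, interval@end)
  keep <- c(TRUE, ends[-length(ends)] < interval@end)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(chrom = interval@chrom, start = as.integer(starts),
             end = as.integer(ends), strand = interval@strand,
             stringsAsFactors = FALSE)
}

#' Merge mined regions from overlapping chunks
#'
#' Removes duplicates and chunk-truncation artifacts after mining a
#' long interval chunk by chunk: a region is dropped when it is equal
#' to, or strictly contained in, another region of the same sample,
#' chromosome, strand and parameters.  Because irreducibility depends
#' only on an interval's own values, every maximal region shorter than
#' the chunk overlap appears intact in at least one chunk, and every
#' chunk-boundary fragment is a strict sub-interval of one -- so the
#' merged result equals the unchunked mining result.
#'
#' @param regions row-bound mined-region data.frame from several chunks.
#' @return The deduplicated, sorted region data.frame.
#' @export
merge_chunk_regions <- function(regions) {
  if (!nrow(regions)) return(regions)
  key <- paste(regions$sample, regions$chrom, regions$strand,
               regions$mu, regions$minsup)
  out <- lapply(split(regions, key), function(df) {
    df <- df[order(df$start, -df$end), , drop = FALSE]
    run_end <- -1L
    keep <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      if (df$end[r] > run_end) { keep[r] <- TRUE; run_end <- df$end[r] }
    }
    df[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sample, out$chrom, out$strand, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene annotations from GFF3 or a gene TSV
#'
#' The TSV layout is five tab-separated columns: `gene_id`, `chrom`,
#' `start` (1-based inclusive), `end` (inclusive), `strand`.  GFF3
#' files are filtered to `gene` features; chromosome lengths are taken
#' from `##sequence-region` pragmas when present.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param chrom_lengths named vector of chromosome lengths; required
#'   for TSV input without a length source, overrides pragmas for GFF3.
#' @return An [AnnotationSet-class].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    lines <- readLines(path)
    prag <- lines[startsWith(lines, "##sequence-region")]
    if (is.null(chrom_lengths) && length(prag)) {
      parts <- strsplit(trimws(prag), "[ \t]+")
      chrom_lengths <- stats::setNames(
        vapply(parts, function(p) as.integer(p[4L]), integer(1)),
        vapply(parts, function(p) p[2L], character(1)))
    }
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    fields <- fields[vapply(fields, function(f) f[3L] == "gene", logical(1))]
    genes <- data.frame(
      gene_id = vapply(fields, function(f)
        sub("^.*ID=([^;]+).*$", "\\1", f[9L]), character(1)),
      chrom = vapply(fields, `[`, character(1), 1L),
      start = vapply(fields, function(f) as.integer(f[4L]), integer(1)) - 1L,
      end = vapply(fields, function(f) as.integer(f[5L]), integer(1)),
      strand = vapply(fields, `[`, character(1), 7L),
      stringsAsFactors = FALSE)
  } else {
    tb <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    names(tb)[seq_len(5L)] <- c("gene_id", "chrom", "start", "end", "strand")
    genes <- data.frame(gene_id = as.character(tb$gene_id),
                        chrom = as.character(tb$chrom),
                        start = as.integer(tb$start) - 1L,
                        end = as.integer(tb$end),
                        strand = as.character(tb$strand),
                        stringsAsFactors = FALSE)
  }
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
  AnnotationSet(genes, chrom_lengths)
}
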