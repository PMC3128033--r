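#' Read-level data back-end
#'
#' A back-end serves minimally-attributed reads for one sample from a
#' BAM file (indexed, random access via Rsamtools), a plain read TSV
#' (loaded once and cached), or an in-memory read table.  It replaces
#' heavier storage layers: any pipeline result is identical whichever
#' back-end serves the same reads.
#'
#' @param source file path (BAM or TSV) or, for `format = "memory"`, a
#'   data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` and optionally `sample_id`.
#' @param format `"auto"` (by extension), `"bam"`, `"tsv"` or
#'   `"memory"`.
#' @param sample_id sample this back-end serves; defaults to the file
#'   name stem.
#' @param min_mapq BAM only: minimum mapping quality (default 0, i.e.
#'   all primary mapped reads; mapper stringency is left to the user).
#' @param include_secondary BAM only: keep secondary/supplementary
#'   alignments (default `FALSE`).
#' @return A back-end object for [fetch_reads()].
#' @export
backend <- function(source, format = c("auto", "bam", "tsv", "memory"),
                    sample_id = NULL, min_mapq = 0L,
                    include_secondary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    if (is.data.frame(source)) format <- "memory"
    else if (grepl("\\.bam$", source, ignore.case = TRUE)) format <- "bam"
    else format <- "tsv"
  }
  if (format != "memory" && !file.exists(source))
    stop(sprintf("back-end source '%s' does not exist", source))
  if (is.null(sample_id))
    sample_id <- if (is.data.frame(source)) "sample"
                 else sub("\\.(bam|tsv|txt)$", "", basename(source),
                          ignore.case = TRUE)
  structure(list(source = source, format = format,
                 sample_id = sample_id, min_mapq = as.integer(min_mapq),
                 include_secondary = include_secondary,
                 cache = new.env(parent = emptyenv())),
            class = "covmine_backend")
}

#' @export
print.covmine_backend <- function(x, ...) {
  src <- if (is.data.frame(x$source)) sprintf("<%d reads in memory>",
                                              nrow(x$source)) else x$source
  cat(sprintf("covmine back-end [%s] sample '%s': %s\n", x$format,
              x$sample_id, src))
  invisible(x)
}

# Per-chromosome start-sorted index over the cached read table, so that
# interval queries cost O(log n + hits) rather than a full scan.
backend_index <- function(cfg) {
  if (!is.null(cfg$cache$index)) return(cfg$cache$index)
  if (cfg$format == "memory") {
    df <- cfg$source
    if ("sample_id" %in% names(df) && nrow(df)) {
      ss <- unique(df$sample_id)
      if (cfg$sample_id %in% ss)
        df <- df[df$sample_id == cfg$sample_id, , drop = FALSE]
      else if (length(ss) > 1L)
        stop(sprintf("sample '%s' not found in multi-sample read table",
                     cfg$sample_id))
    }
  } else {
    df <- parse_read_tsv(cfg$source)
    ss <- unique(df$sample_id)
    if (cfg$sample_id %in% ss)
      df <- df[df$sample_id == cfg$sample_id, , drop = FALSE]
    else if (length(ss) > 1L)
      stop(sprintf("sample '%s' not found in multi-sample TSV '%s'",
                   cfg$sample_id, cfg$source))
  }
  idx <- lapply(split(df[, c("start", "end", "strand")], df$chrom),
                function(d) {
                  d <- d[order(d$start), , drop = FALSE]
                  list(start = as.integer(d$start), end = as.integer(d$end),
                       strand = d$strand,
                       max_width = if (nrow(d)) max(d$end - d$start) else 0L)
                })
  cfg$cache$index <- idx
  idx
}

#' Fetch reads overlapping an interval
#'
#' Reads are reduced to the minimal attribute set (start, end, strand)
#' and converted to internal 0-based half-open coordinates.  For BAM
#' sources, unmapped reads are always excluded, secondary and
#' supplementary alignments are excluded unless the back-end was opened
#' with `include_secondary = TRUE`, and reads below `min_mapq` are
#' dropped.  A query on a chromosome absent from the source yields an
#' empty ReadSet, not an error.
#'
#' @param cfg a back-end from [backend()].
#' @param interval a [GenomicInterval-class] to query.
#' @return A [ReadSet-class] over `interval`.
#' @export
fetch_reads <- function(cfg, interval) {
  stopifnot(inherits(cfg, "covmine_backend"))
  if (cfg$format == "bam") return(fetch_reads_bam(cfg, interval))
  idx <- backend_index(cfg)[[interval@chrom]]
  if (is.null(idx))
    return(ReadSet(interval, empty_reads(), cfg$sample_id))
  # candidates by sorted start: start in [query_start - max_width, query_end)
  lo <- findInterval(interval@start - idx$max_width - 1L, idx$start) + 1L
  hi <- findInterval(interval@end - 1L, idx$start)
  if (hi < lo)
    return(ReadSet(interval, empty_reads(), cfg$sample_id))
  sel <- lo:hi
  keep <- idx$end[sel] > interval@start
  df <- data.frame(start = idx$start[sel][keep], end = idx$end[sel][keep],
                   strand = idx$strand[sel][keep], stringsAsFactors = FALSE)
  ReadSet(interval, df, cfg$sample_id)
}

fetch_reads_bam <- function(cfg, interval) {
  bai <- paste0(cfg$source, ".bai")
  if (!file.exists(bai) &&
      !file.exists(sub("\\.bam$", ".bai", cfg$source)))
    stop(sprintf("BAM index not found for '%s'; create one with %s",
                 cfg$source, "Rsamtools::indexBam() or `samtools index`"))
  hdr <- Rsamtools::scanBamHeader(cfg$source)[[1L]]$targets
  if (!interval@chrom %in% names(hdr))
    return(ReadSet(interval, empty_reads(), cfg$sample_id))
  which <- GenomicRanges::GRanges(
    interval@chrom, IRanges::IRanges(interval@start + 1L, interval@end))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (cfg$include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (cfg$include_secondary) NA else FALSE)
  param <- Rsamtools::ScanBamParam(
    which = which, flag = flag,
    what = c("pos", "qwidth", "strand", "mapq"))
  res <- Rsamtools::scanBam(cfg$source, param = param)[[1L]]
  keep <- !is.na(res$pos)
  if (cfg$min_mapq > 0L) {
    mq <- res$mapq
    mq[is.na(mq)] <- 0L
    keep <- keep & mq >= cfg$min_mapq
  }
  strand <- as.character(res$strand)[keep]
  strand[is.na(strand) | strand == "*"] <- "."
  df <- data.frame(start = res$pos[keep] - 1L,
                   end = res$pos[keep] - 1L + res$qwidth[keep],
                   strand = strand, stringsAsFactors = FALSE)
  ReadSet(interval, df, cfg$sample_id)
}

#' Write / read the plain-text read table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `strand`,
#' `sample_id`, with SAM-style 1-based inclusive coordinates (an
#' internal read `[10, 60)` is written as start 11, end 60), as a
#' trimmed-SAM dump produced with samtools/AWK would look.  The first
#' line is a `#` comment documenting the convention.  Write-then-read
#' is lossless.
#'
#' @param readset a [ReadSet-class].
#' @param path output file.
#' @return `write_read_tsv` returns `path` invisibly.
#' @export
write_read_tsv <- function(readset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# covmine read table; coordinates are 1-based inclusive",
               "chrom\tstart\tend\tstrand\tsample_id"), con)
  rd <- readset@reads
  if (nrow(rd))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", readset@region@chrom,
                       rd$start + 1L, rd$end, rd$strand,
                       readset@sample_id), con)
  invisible(path)
}

#' @rdname write_read_tsv
#' @param interval optional [GenomicInterval-class] to restrict to; by
#'   default the span of the reads in the file is used.
#' @param sample_id optional sample filter for multi-sample files.
#' @return `read_read_tsv` returns a [ReadSet-class].
#' @export
read_read_tsv <- function(path, interval = NULL, sample_id = NULL) {
  df <- parse_read_tsv(path)
  if (!is.null(sample_id))
    df <- df[df$sample_id == sample_id, , drop = FALSE]
  else sample_id <- if (nrow(df)) df$sample_id[1L] else "sample"
  if (is.null(interval)) {
    if (nrow(df)) {
      chroms <- unique(df$chrom)
      if (length(chroms) > 1L)
        stop("multi-chromosome read TSV needs an explicit interval")
      interval <- GenomicInterval(chroms, min(df$start), max(df$end))
    } else interval <- GenomicInterval(".", 0L, 1L)
  } else {
    df <- df[df$chrom == interval@chrom & df$start < interval@end &
             df$end > interval@start, , drop = FALSE]
  }
  ReadSet(interval, df[, c("start", "end", "strand")], sample_id)
}

# Parse the 5-column read TSV into a data.frame with internal 0-based
# half-open coordinates; errors report the offending line number.
parse_read_tsv <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (!length(body_idx)) stop("read TSV has no header line")
  data_idx <- body_idx[-1L]
  data_idx <- data_idx[nzchar(lines[data_idx])]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop(sprintf("malformed read TSV line %d in '%s'", data_idx[bad[1L]],
                 path))
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 2L))) - 1L,
    end = suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 3L))),
    strand = vapply(fields, `[`, character(1), 4L),
    sample_id = vapply(fields, `[`, character(1), 5L),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1L]
    stop(sprintf("malformed coordinates at read TSV line %d in '%s'",
                 data_idx[bad], path))
  }
  df
}
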