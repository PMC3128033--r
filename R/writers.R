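#' Write a coverage track as bedGraph
#'
#' Standard 4-column bedGraph (0-based half-open): runs of equal value
#' are merged and, by default, zero runs are suppressed.  The track
#' line names the value kind and sample so a round-trip preserves both.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @param sample sample to export (default first).
#' @param zero_suppress omit zero-valued runs (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, sample = NULL,
                           zero_suppress = TRUE) {
  v <- track_values(track, sample)
  if (is.null(sample)) sample <- track@samples[1L]
  r <- rle(v)
  ends <- track@region@start + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- if (zero_suppress) r$values != 0 else rep(TRUE, length(r$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    'track type=bedGraph name="covmine:%s:%s"', track@kind, sample), con)
  if (any(keep))
    writeLines(sprintf("%s\t%d\t%d\t%s", track@region@chrom, starts[keep],
                       ends[keep], format(r$values[keep], trim = TRUE,
                                          scientific = FALSE, digits = 15)),
               con)
  invisible(path)
}

#' Read a covmine bedGraph back into a track
#'
#' @param path bedGraph written by [write_bedgraph()].
#' @param region [GenomicInterval-class] to reconstruct over (needed
#'   because zero runs may be suppressed); defaults to the span of the
#'   records in the file.
#' @return A [CoverageTrack-class]; kind and sample are recovered from
#'   the track line when present.
#' @export
read_bedgraph <- function(path, region = NULL) {
  lines <- readLines(path)
  kind <- "normalized"; sample <- "sample"
  tl <- grep("^track", lines, value = TRUE)
  if (length(tl)) {
    m <- regmatches(tl[1L], regexec('name="covmine:([^:]+):([^"]+)"', tl[1L]))[[1L]]
    if (length(m) == 3L) { kind <- m[2L]; sample <- m[3L] }
  }
  body <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, character(1), 1L)
  starts <- as.integer(vapply(fields, `[`, character(1), 2L))
  ends <- as.integer(vapply(fields, `[`, character(1), 3L))
  vals <- as.numeric(vapply(fields, `[`, character(1), 4L))
  if (is.null(region)) {
    if (!length(starts)) stop("empty bedGraph needs an explicit region")
    region <- GenomicInterval(chrom[1L], min(starts), max(ends))
  }
  v <- numeric(interval_length(region))
  for (i in seq_along(starts)) {
    if (chrom[i] != region@chrom) next
    a <- max(starts[i], region@start); b <- min(ends[i], region@end)
    if (b > a) v[(a - region@start + 1L):(b - region@start)] <- vals[i]
  }
  CoverageTrack(region, v, samples = sample, kind = kind)
}

#' Write mined regions as BED6
#'
#' One line per region: name is `sample:mu:minsup`, score is the
#' rounded mean value (capped at 1000 per the BED spec), strand from
#' the region.
#'
#' @param regions mined-region data.frame
#'   (see [find_irreducible_regions()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions)) {
    score <- pmin(pmax(round(regions$mean_value), 0), 1000)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", regions$chrom,
                       regions$start, regions$end,
                       sprintf("%s:%s:%d", regions$sample,
                               format(regions$mu, trim = TRUE),
                               regions$minsup),
                       as.integer(score), regions$strand), con)
  }
  invisible(path)
}

#' Write / read a count table as TSV
#'
#' Layout consumed directly by count-based differential-expression
#' tools: a header row of sample ids, a first column (`region`) of
#' region labels, integer counts.
#'
#' @param table a [CountTable-class].
#' @param path output file.
#' @return `write_counts_tsv` returns `path` invisibly;
#'   `read_counts_tsv` returns a [CountTable-class] (coordinates are
#'   re-parsed from labels of the form `chrom:start-end(strand)` where
#'   possible, otherwise `NA`).
#' @export
write_counts_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", table@samples), collapse = "\t"), con)
  if (nrow(table@counts))
    writeLines(paste(table@regions$label,
                     apply(table@counts, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(tb[[1L]])
  counts <- as.matrix(tb[, -1L, drop = FALSE])
  m <- regmatches(labels, regexec("^(.+):(\\d+)-(\\d+)\\(([+.-])\\)$", labels))
  parsed <- lengths(m) == 5L
  regions <- data.frame(
    label = labels,
    chrom = ifelse(parsed, vapply(m, function(x) x[2L][1L], character(1)), NA),
    start = ifelse(parsed,
                   suppressWarnings(as.integer(
                     vapply(m, function(x) x[3L][1L], character(1)))), NA),
    end = ifelse(parsed,
                 suppressWarnings(as.integer(
                   vapply(m, function(x) x[4L][1L], character(1)))), NA),
    strand = ifelse(parsed, vapply(m, function(x) x[5L][1L], character(1)), NA),
    stringsAsFactors = FALSE)
  CountTable(regions, colnames(counts), counts)
}
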