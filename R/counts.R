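region_label <- function(df) {
  if ("gene_id" %in% names(df) && !anyNA(df$gene_id)) df$gene_id
  else if ("label" %in% names(df)) df$label
  else sprintf("%s:%d-%d(%s)", df$chrom, df$start, df$end, df$strand)
}

#' Build a regions-by-samples read count table
#'
#' Counts reads per region per sample using [region_count()], the input
#' format required by count-based differential-expression tools.
#'
#' @param backends named list of back-ends from [backend()]; names are
#'   the sample ids (defaulting to each back-end's `sample_id`).
#' @param regions data.frame of intervals with columns `chrom`,
#'   `start`, `end`, `strand` and optionally `gene_id`/`label` used as
#'   row labels (discovered regions fall back to coordinate labels).
#' @param rule counting rule, `"any_overlap"` (default: every mapped
#'   read in the locus contributes) or `"contained"`.
#' @return A [CountTable-class].
#' @export
build_count_table <- function(backends, regions,
                              rule = c("any_overlap", "contained")) {
  rule <- match.arg(rule)
  if (!length(backends)) stop("need at least one sample back-end")
  if (!nrow(regions)) stop("need at least one region")
  if (is.null(names(backends)))
    names(backends) <- vapply(backends, `[[`, character(1), "sample_id")
  labels <- region_label(regions)
  counts <- matrix(0L, nrow(regions), length(backends))
  for (j in seq_along(backends)) {
    for (i in seq_len(nrow(regions))) {
      gi <- GenomicInterval(regions$chrom[i], regions$start[i],
                            regions$end[i], regions$strand[i])
      rs <- fetch_reads(backends[[j]], gi)
      counts[i, j] <- region_count(rs, gi, rule)
    }
  }
  reg <- data.frame(label = labels, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    strand = regions$strand, stringsAsFactors = FALSE)
  CountTable(reg, names(backends), counts)
}
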