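#' Library-size normalization of a coverage track
#'
#' Scales every value by `1e6 / total_reads` (reads-per-million
#' convention) so tracks from libraries of different depth are
#' comparable.
#'
#' @param track a [CoverageTrack-class].
#' @param total_reads total mapped reads in the sample's library (> 0).
#' @return A [CoverageTrack-class] of kind `"normalized"`.
#' @export
normalize_library_size <- function(track, total_reads) {
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be a positive number")
  CoverageTrack(track@region, track@values * (1e6 / total_reads),
                samples = track@samples, kind = "normalized")
}

#' Lowess smoothing of a coverage track
#'
#' Locally-weighted regression of value against position, applied per
#' sample.  Recommended before region mining to stabilize the outcome:
#' it damps over-amplification peaks and small non-expressed gaps that
#' would otherwise perturb region boundaries.  Negative fitted values
#' are clipped to 0 so smoothed tracks remain valid coverage inputs.
#'
#' @param track a [CoverageTrack-class] over a region of length >= 10.
#' @param f lowess span as a fraction of the region (default 0.1).
#' @param iterations robustness iterations (default 3).
#' @return A [CoverageTrack-class] of kind `"smoothed"`.
#' @export
lowess_smooth <- function(track, f = 0.1, iterations = 3L) {
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  if (iterations < 1L) stop("iterations must be >= 1")
  n <- nrow(track@values)
  if (n < 10L) stop("region too short to smooth (length must be >= 10)")
  x <- seq_len(n)
  sm <- apply(track@values, 2L, function(v)
    pmax(stats::lowess(x, v, f = f, iter = iterations)$y, 0))
  CoverageTrack(track@region, sm, samples = track@samples, kind = "smoothed")
}

check_same_region <- function(r1, r2) {
  if (r1@chrom != r2@chrom || r1@start != r2@start || r1@end != r2@end)
    stop("tracks must cover the same region")
}

#' Nucleotide-level fold change between two tracks
#'
#' Per position, `log2((v1 + pseudocount) / (v2 + pseudocount))`.
#'
#' @param t1,t2 single-sample [CoverageTrack-class] objects over the
#'   same region.
#' @param pseudocount positive additive constant guarding zero coverage
#'   (default 1).
#' @return A [CoverageTrack-class] of kind `"fold_change"`.
#' @export
fold_change <- function(t1, t2, pseudocount = 1) {
  check_same_region(t1@region, t2@region)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  v <- log2((t1@values[, 1L] + pseudocount) / (t2@values[, 1L] + pseudocount))
  CoverageTrack(t1@region, v,
                samples = paste0(t1@samples[1L], "_vs_", t2@samples[1L]),
                kind = "fold_change")
}

#' Nucleotide-level splicing index
#'
#' Per position n, `SI_n = log2(((E1n + p) / G1) / ((E2n + p) / G2))`:
#' the log2 ratio of the two samples' coverages after normalizing each
#' by its read count in the enclosing gene or region.  Positions (most
#' usefully exons) whose relative inclusion differs between the
#' conditions stand out even when overall gene expression differs by
#' orders of magnitude.
#'
#' @param E1,E2 single-sample [CoverageTrack-class] coverages over the
#'   same interval.
#' @param G1,G2 read counts of the enclosing gene/region in each sample
#'   (positive; a zero count signals an unexpressed gene, which the
#'   caller should filter out).
#' @param pseudocount positive additive constant for zero-coverage
#'   positions (default 1).
#' @return A [CoverageTrack-class] of kind `"splicing_index"`.
#' @examples
#' reg <- GenomicInterval("chr1", 0, 1, "+")
#' e1 <- CoverageTrack(reg, 19, "a"); e2 <- CoverageTrack(reg, 4, "b")
#' track_values(splicing_index(e1, e2, 100, 100))  # log2((20/100)/(5/100)) = 2
#' @export
splicing_index <- function(E1, E2, G1, G2, pseudocount = 1) {
  check_same_region(E1@region, E2@region)
  if (G1 <= 0 || G2 <= 0)
    stop("gene counts G1 and G2 must be positive (unexpressed gene?)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  v <- log2(((E1@values[, 1L] + pseudocount) / G1) /
            ((E2@values[, 1L] + pseudocount) / G2))
  CoverageTrack(E1@region, v,
                samples = paste0(E1@samples[1L], "_vs_", E2@samples[1L]),
                kind = "splicing_index")
}

#' Mine significant regions of a splicing-index track
#'
#' The region miner needs a non-negative magnitude, so the absolute
#' splicing index is mined at threshold `mu_si` (default 1: at least a
#' two-fold relative inclusion change) and each region is reported with
#' the sign of its mean SI.
#'
#' @param si_track a `"splicing_index"` [CoverageTrack-class].
#' @param mu_si threshold on |SI| (default 1.0).
#' @param minsup minimum region width (default 51).
#' @return Mined-region data.frame with an extra `sign` column (+1 /
#'   -1) and `mean_value` holding the mean signed SI of the region.
#' @export
si_regions <- function(si_track, mu_si = 1.0, minsup = 51L) {
  v <- si_track@values[, 1L]
  abs_track <- CoverageTrack(si_track@region, abs(v),
                             samples = si_track@samples, kind = "normalized")
  regs <- find_irreducible_regions(abs_track, mu = mu_si, minsup = minsup)
  if (nrow(regs)) {
    off <- si_track@region@start
    signed_mean <- vapply(seq_len(nrow(regs)), function(r)
      mean(v[(regs$start[r] - off + 1L):(regs$end[r] - off)]), numeric(1))
    regs$mean_value <- signed_mean
    regs$sign <- ifelse(signed_mean >= 0, 1L, -1L)
  } else {
    regs$sign <- integer(0)
  }
  regs
}
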