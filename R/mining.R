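MINE_EPS <- 1e-9

#' Test whether a value vector is irreducible at threshold mu
#'
#' A vector is irreducible at level `mu` when every split into two
#' parts leaves both parts with mean at or above `mu`; equivalently,
#' every prefix mean and every suffix mean is >= `mu`.  A single value
#' is irreducible iff it is >= `mu`.  Irreducible regions therefore
#' always start and end with a value at or above `mu`.
#'
#' @param values non-empty numeric vector.
#' @param mu coverage threshold (>= 0).
#' @param strict use strict comparisons (> `mu`) instead of the default
#'   non-strict ones; the non-strict form is the stable choice on
#'   integer coverage where ties with `mu` are common.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_irreducible(c(10, 2, 10), 5)  # TRUE: splits give means 10,6 and 6,10
#' is_irreducible(c(10, 2), 5)      # FALSE: the right part has mean 2
#' @export
is_irreducible <- function(values, mu, strict = FALSE) {
  n <- length(values)
  if (n == 0L) stop("values must be non-empty")
  pref <- cumsum(values) / seq_len(n)
  suff <- rev(cumsum(rev(values))) / (n - seq_len(n) + 1)
  if (strict) all(pref > mu + MINE_EPS) && all(suff > mu + MINE_EPS)
  else all(pref >= mu - MINE_EPS) && all(suff >= mu - MINE_EPS)
}

empty_regions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             width = integer(0), strand = character(0), sample = character(0),
             mean_value = numeric(0), mu = numeric(0), minsup = integer(0),
             stringsAsFactors = FALSE)
}

regions_frame <- function(mat, region, sample, mu, minsup) {
  if (!nrow(mat)) return(empty_regions())
  data.frame(chrom = region@chrom,
             start = unname(as.integer(mat[, 1L])) + region@start,
             end = unname(as.integer(mat[, 2L])) + region@start,
             width = unname(as.integer(mat[, 2L] - mat[, 1L])),
             strand = region@strand, sample = sample,
             mean_value = unname(mat[, 3L]), mu = mu,
             minsup = as.integer(minsup), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mine maximal irreducible regions from a coverage track
#'
#' Finds the maximal irreducible sub-intervals of one sample's value
#' vector (irreducible intervals contained in no longer irreducible
#' interval), then filters them to width >= `minsup`.  Maximality is
#' applied before the width filter, so sub-intervals of a long maximal
#' region are never reported just to satisfy `minsup`.  Returned regions
#' are sorted, pairwise disjoint and carry genome coordinates.
#'
#' @param track a [CoverageTrack-class]; values must be non-negative
#'   (mine `abs()` of signed tracks, see [si_regions()]).
#' @param sample sample id (default: first sample of the track).
#' @param mu coverage threshold; either a number or a resolver created
#'   by [mu_fixed()], [mu_fraction_of_max()] or [mu_fraction_of_min()],
#'   evaluated on the current track slice.  Default 5, a common
#'   detection threshold for coverage.
#' @param minsup minimum region width in nucleotides; default 51
#'   (read length 50 + 1), which suppresses single-stack artifact peaks.
#' @param strict use strict (> mu) comparisons; see [is_irreducible()].
#' @return data.frame with columns `chrom`, `start`, `end`, `width`,
#'   `strand`, `sample`, `mean_value`, `mu`, `minsup`.
#' @examples
#' reg <- GenomicInterval("chr1", 0, 6, "+")
#' tr <- CoverageTrack(reg, c(10, 2, 10, 0, 0, 8), "s1")
#' find_irreducible_regions(tr, mu = 5, minsup = 1)  # [0,3) and [5,6)
#' @export
find_irreducible_regions <- function(track, sample = NULL, mu = 5,
                                     minsup = 51L, strict = FALSE) {
  v <- track_values(track, sample)
  if (is.null(sample)) sample <- track@samples[1L]
  if (any(v < 0))
    stop("negative values: mine abs() of signed tracks instead")
  mu <- resolve_mu(mu, v)
  if (mu < 0) stop("mu must be >= 0")
  if (minsup < 1L) stop("minsup must be >= 1")
  mat <- .mine_maximal(v, mu, MINE_EPS, strict)
  mat <- mat[mat[, 2L] - mat[, 1L] >= minsup, , drop = FALSE]
  regions_frame(mat, track@region, sample, mu, minsup)
}

#' Exhaustive-oracle region mining
#'
#' Test oracle for the mining contract: enumerates every sub-interval,
#' tests the irreducibility definition on it directly (all prefix means
#' and all suffix means at/above `mu`), keeps the maximal irreducible
#' intervals and filters by `minsup`.  Independent of the scanning
#' implementation behind [find_irreducible_regions()]; intended for
#' tests on short vectors.
#'
#' @param values non-negative numeric vector, length <= `guard`.
#' @param mu coverage threshold.
#' @param minsup minimum region width.
#' @param strict strict comparisons, as in [is_irreducible()].
#' @param guard refuse vectors longer than this (default 10000); the
#'   enumeration is quadratic in length.
#' @return data.frame in the layout of [find_irreducible_regions()]
#'   with 0-based coordinates relative to the vector (chrom `"."`).
#' @export
brute_force_regions <- function(values, mu, minsup = 1L, strict = FALSE,
                                guard = 10000L) {
  n <- length(values)
  if (n == 0L) stop("values must be non-empty")
  if (n > guard)
    stop(sprintf("vector length %d exceeds the oracle guard (%d)", n, guard))
  cmp <- if (strict) function(x, y) x > y + MINE_EPS
         else function(x, y) x >= y - MINE_EPS
  # suffix condition per end j: B[i, j] <=> all k in i..j have
  # mean(values[k..j]) at/above mu
  B <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    sums <- rev(cumsum(rev(values[seq_len(j)])))  # sums of values[k..j]
    lens <- j - seq_len(j) + 1
    ok <- cmp(sums, mu * lens)
    B[seq_len(j), j] <- rev(as.logical(cummin(rev(ok))))
  }
  # prefix condition per start i, then the largest irreducible end jmax(i)
  jmax <- integer(n)
  for (i in seq_len(n)) {
    sums <- cumsum(values[i:n])
    lens <- seq_along(sums)
    ok <- as.logical(cummin(cmp(sums, mu * lens)))  # prefix cond on [i, j]
    irr <- ok & B[i, i:n]
    jmax[i] <- if (any(irr)) (i:n)[max(which(irr))] else 0L
  }
  # maximality: (i, jmax(i)) is contained in an earlier candidate iff
  # some i' < i has jmax(i') >= jmax(i)
  run <- 0L
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (jmax[i] > run) { keep[i] <- TRUE; run <- jmax[i] }
  }
  starts <- which(keep)
  ends <- jmax[keep]
  w <- ends - starts + 1L
  sel <- w >= minsup
  starts <- starts[sel]; ends <- ends[sel]
  means <- vapply(seq_along(starts),
                  function(r) mean(values[starts[r]:ends[r]]), numeric(1))
  mat <- cbind(start = starts - 1L, end = ends, mean = means)
  regions_frame(mat, GenomicInterval(".", 0L, max(n, 1L), "."),
                "oracle", mu, minsup)
}

#' Multi-threshold region-based coverage transform
#'
#' Runs the region miner at each level of an increasing mu ladder and
#' assigns every position the largest mu at which it falls inside an
#' irreducible region of width >= `minsup` (0 where none).  The
#' resulting discrete coverage function is easier to read and removes
#' over-amplification peaks and minor local minima.
#'
#' @param track a [CoverageTrack-class].
#' @param sample sample id (default first).
#' @param mu_ladder strictly increasing positive thresholds.
#' @param minsup minimum region width per level.
#' @param strict strict comparisons, as in [is_irreducible()].
#' @return A [CoverageTrack-class] of kind `"region_based"` whose values
#'   all lie in `mu_ladder` or are 0.
#' @export
region_based_coverage <- function(track, sample = NULL,
                                  mu_ladder = c(1, 2, 5, 10, 20, 50, 100),
                                  minsup = 51L, strict = FALSE) {
  if (!length(mu_ladder) || any(mu_ladder <= 0) ||
      any(diff(mu_ladder) <= 0))
    stop("mu_ladder must be strictly increasing and positive")
  v <- track_values(track, sample)
  if (is.null(sample)) sample <- track@samples[1L]
  out <- numeric(length(v))
  for (mu in mu_ladder) {  # ascending: later levels overwrite = max rule
    mat <- .mine_maximal(v, mu, MINE_EPS, strict)
    mat <- mat[mat[, 2L] - mat[, 1L] >= minsup, , drop = FALSE]
    for (r in seq_len(nrow(mat)))
      out[(mat[r, 1L] + 1L):mat[r, 2L]] <- mu
  }
  CoverageTrack(track@region, out, samples = sample, kind = "region_based")
}

#' Cross-sample support of a gene
#'
#' @param per_sample_regions named list (one entry per sample) of mined
#'   region data.frames as returned by [find_irreducible_regions()].
#' @param gene a [GenomicInterval-class].
#' @param min_samples minimum number of samples (>= 1) that must have at
#'   least one region overlapping the gene.
#' @return `TRUE` iff the gene has mined regions in at least
#'   `min_samples` samples.
#' @export
support_filter <- function(per_sample_regions, gene, min_samples = 1L) {
  if (min_samples < 1L) stop("min_samples must be >= 1")
  hits <- vapply(per_sample_regions, function(df) {
    if (is.null(df) || !nrow(df)) return(FALSE)
    any(df$chrom == gene@chrom & df$start < gene@end & df$end > gene@start &
        (df$strand == "." | gene@strand == "." | df$strand == gene@strand))
  }, logical(1))
  sum(hits) >= min_samples
}

#' Threshold resolvers for region mining
#'
#' Adaptive strategies for choosing the mining threshold from the data:
#' a fixed detection level, or a fraction of the maximum (or minimum)
#' coverage of the current track slice.
#'
#' @param value,fraction the fixed threshold, or the fraction applied to
#'   the slice maximum/minimum.
#' @return A resolver function accepted by the `mu` argument of
#'   [find_irreducible_regions()].
#' @export
mu_fixed <- function(value) {
  force(value)
  structure(function(values) value, class = "mu_resolver")
}

#' @rdname mu_fixed
#' @export
mu_fraction_of_max <- function(fraction) {
  force(fraction)
  structure(function(values) fraction * max(values), class = "mu_resolver")
}

#' @rdname mu_fixed
#' @export
mu_fraction_of_min <- function(fraction) {
  force(fraction)
  structure(function(values) fraction * min(values), class = "mu_resolver")
}

resolve_mu <- function(mu, values) {
  if (is.function(mu)) mu <- mu(values)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu))
    stop("mu must resolve to a single number")
  mu
}
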