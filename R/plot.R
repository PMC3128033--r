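#' Plot coverage, transformed tracks and mined regions for a region
#'
#' Stacked panels over a shared x axis: one panel per track (coverage
#' per sample, optionally a splicing-index or other transformed track)
#' and, when given, a bottom panel drawing mined irreducible regions as
#' horizontal bars per sample.  Rendering is deterministic for fixed
#' inputs.
#'
#' @param tracks a [CoverageTrack-class] or list of them, all over the
#'   same region.
#' @param regions optional mined-region data.frame
#'   (see [find_irreducible_regions()]).
#' @param path optional PNG output path; when `NULL` the current device
#'   is used.
#' @param width,height device size in pixels when `path` is given.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_region <- function(tracks, regions = NULL, path = NULL,
                        width = 900, height = 600) {
  if (methods::is(tracks, "CoverageTrack")) tracks <- list(tracks)
  if (!length(tracks)) stop("need at least one track to plot")
  reg <- tracks[[1L]]@region
  for (tr in tracks) check_same_region(reg, tr@region)
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  n_panels <- length(tracks) + as.integer(!is.null(regions))
  op <- graphics::par(mfrow = c(n_panels, 1L),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  x <- seq.int(reg@start, reg@end - 1L)
  for (tr in tracks) {
    ylim <- range(tr@values, 0)
    graphics::plot(NA, xlim = c(reg@start, reg@end), ylim = ylim,
                   xlab = "", ylab = tr@kind, main = sprintf(
                     "%s:%d-%d(%s)", reg@chrom, reg@start, reg@end,
                     reg@strand))
    for (j in seq_along(tr@samples))
      graphics::lines(x, tr@values[, j], col = j, type = "s")
    if (length(tr@samples) > 1L)
      graphics::legend("topright", legend = tr@samples,
                       col = seq_along(tr@samples), lty = 1, bty = "n")
  }
  if (!is.null(regions)) {
    samples <- unique(regions$sample)
    graphics::plot(NA, xlim = c(reg@start, reg@end),
                   ylim = c(0.5, max(length(samples), 1L) + 0.5),
                   xlab = "position", ylab = "regions", yaxt = "n")
    if (length(samples))
      graphics::axis(2, at = seq_along(samples), labels = samples,
                     las = 1, cex.axis = 0.7)
    for (i in seq_len(nrow(regions))) {
      y <- match(regions$sample[i], samples)
      graphics::rect(regions$start[i], y - 0.3, regions$end[i], y + 0.3,
                     col = y, border = NA)
    }
  }
  invisible(path)
}
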