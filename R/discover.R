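# Pileup + optional smoothing + mining for one interval and one back-end.
mine_interval_sample <- function(be, gi, mu, minsup, strand_mode, smooth, f) {
  rs <- fetch_reads(be, gi)
  tr <- pileup_coverage(rs, strand_mode)
  if (smooth && interval_length(gi) >= 10L) tr <- lowess_smooth(tr, f = f)
  find_irreducible_regions(tr, mu = mu, minsup = minsup)
}

# Union of per-sample regions into loci with their cross-sample support.
region_loci <- function(regs) {
  if (!nrow(regs)) return(data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), strand = character(0),
                                     support = integer(0)))
  out <- lapply(split(regs, paste(regs$chrom, regs$strand)), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    loci <- data.frame(chrom = df$chrom[1L],
                       start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir), strand = df$strand[1L],
                       stringsAsFactors = FALSE)
    loci$support <- vapply(seq_len(nrow(loci)), function(i) {
      hit <- df$start < loci$end[i] & df$end > loci$start[i]
      length(unique(df$sample[hit]))
    }, integer(1))
    loci
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotation-guided and annotation-free expression discovery
#'
#' The full exploratory pipeline: per (chromosome, strand) and per
#' requested category, iterate regions (chunked where long), pile up
#' coverage per sample, optionally lowess-smooth, mine irreducible
#' regions, keep loci supported by at least `min_samples` samples, and
#' export the surviving regions together with a read-count table for
#' downstream differential-expression tools and a Table-1-shaped
#' per-gene support summary.
#'
#' Categories: `"genic"` scans annotated gene bodies, `"extended"`
#' scans gene bodies widened by `flank` to catch expression just up- or
#' downstream of the annotated boundaries, and `"intergenic"` scans the
#' per-strand complement of the (merged) genes for novel transcription.
#' A discovered region overlapping any annotated gene is labeled
#' `genic` regardless of the scan that found it, and duplicates across
#' categories are dropped.
#'
#' @param backends named list of back-ends ([backend()]), one per
#'   sample.
#' @param ann an [AnnotationSet-class].
#' @param mu mining threshold (default 5).
#' @param minsup minimum region width (default 51 = read length + 1).
#' @param categories subset of `c("genic", "extended", "intergenic")`.
#' @param min_samples minimum cross-sample support for a gene or novel
#'   locus to be reported (default 1).
#' @param flank extension width for the `"extended"` category (default
#'   1000 nt).
#' @param chunk_size,chunk_overlap chunking of long intergenic
#'   intervals (defaults 2 Mb / 10 kb, bounding memory while keeping
#'   the overlap far above plausible region lengths).
#' @param smooth lowess-smooth coverage before mining (default
#'   `FALSE`).
#' @param f lowess span when `smooth = TRUE`.
#' @param strand_mode `"same"` (default, strand-aware) or `"ignore"`.
#' @return A list with elements `regions` (mined-region data.frame with
#'   `category` and `support` columns), `counts` (a [CountTable-class]
#'   over supported genes and novel loci) and `support` (named integer
#'   vector: number of genes with irreducible regions in at least X of
#'   N samples, X = 1..N).
#' @export
discover <- function(backends, ann, mu = 5, minsup = 51L,
                     categories = c("genic", "extended", "intergenic"),
                     min_samples = 1L, flank = 1000L,
                     chunk_size = 2e6, chunk_overlap = 1e4,
                     smooth = FALSE, f = 0.1,
                     strand_mode = c("same", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  categories <- match.arg(categories, several.ok = TRUE)
  if (!length(backends)) stop("need at least one sample back-end")
  if (is.null(names(backends)))
    names(backends) <- vapply(backends, `[[`, character(1), "sample_id")
  n_samples <- length(backends)
  chroms <- names(ann@chrom_lengths)
  strands <- if (strand_mode == "same") c("+", "-") else "."

  all_regs <- list()
  gene_support <- integer(0)  # per gene: number of samples with a region
  supported_genes <- list()

  scan_intervals <- function(ivals, category) {
    regs <- list()
    for (i in seq_len(nrow(ivals))) {
      gi <- GenomicInterval(ivals$chrom[i], ivals$start[i], ivals$end[i],
                            ivals$strand[i])
      chunks <- if (interval_length(gi) > chunk_size)
        chunk_iterator(gi, chunk_size, chunk_overlap)
      else data.frame(chrom = gi@chrom, start = gi@start, end = gi@end,
                      strand = gi@strand, stringsAsFactors = FALSE)
      for (k in seq_len(nrow(chunks))) {
        ck <- GenomicInterval(chunks$chrom[k], chunks$start[k],
                              chunks$end[k], chunks$strand[k])
        for (s in names(backends)) {
          r <- mine_interval_sample(backends[[s]], ck, mu, minsup,
                                    strand_mode, smooth, f)
          if (nrow(r)) regs[[length(regs) + 1L]] <- r
        }
      }
    }
    if (!length(regs)) return(empty_regions())
    merge_chunk_regions(do.call(rbind, regs))
  }

  # --- genic ---------------------------------------------------------------
  if ("genic" %in% categories) {
    for (chrom in chroms) for (std in strands) {
      genes <- gene_regions(ann, chrom, std)
      for (g in seq_len(nrow(genes))) {
        gi <- GenomicInterval(genes$chrom[g], genes$start[g], genes$end[g],
                              if (std == ".") "." else genes$strand[g])
        per_sample <- lapply(backends, mine_interval_sample, gi = gi,
                             mu = mu, minsup = minsup,
                             strand_mode = strand_mode, smooth = smooth,
                             f = f)
        supp <- sum(vapply(per_sample, nrow, integer(1)) > 0L)
        gene_support[genes$gene_id[g]] <- supp
        if (supp >= min_samples) {
          df <- do.call(rbind, per_sample)
          if (nrow(df)) {
            df$category <- "genic"
            df$support <- supp
            df$locus <- genes$gene_id[g]
            all_regs[[length(all_regs) + 1L]] <- df
          }
          supported_genes[[length(supported_genes) + 1L]] <- genes[g, ]
        }
      }
    }
  }

  # --- extended ------------------------------------------------------------
  novel_loci <- list()
  classify_novel <- function(regs, category) {
    if (!nrow(regs)) return()
    ov_gene <- vapply(seq_len(nrow(regs)), function(i) {
      g <- ann@genes
      any(g$chrom == regs$chrom[i] & g$start < regs$end[i] &
          g$end > regs$start[i] &
          (regs$strand[i] == "." | g$strand == regs$strand[i]))
    }, logical(1))
    regs$category <- ifelse(ov_gene, "genic", category)
    novel <- regs[!ov_gene, , drop = FALSE]
    loci <- region_loci(novel)
    loci <- loci[loci$support >= min_samples, , drop = FALSE]
    if (nrow(loci))
      novel_loci[[length(novel_loci) + 1L]] <<- loci
    keep <- ov_gene
    for (i in which(!ov_gene))
      keep[i] <- any(loci$chrom == regs$chrom[i] & loci$start < regs$end[i] &
                     loci$end > regs$start[i] & loci$strand == regs$strand[i])
    regs <- regs[keep, , drop = FALSE]
    if (nrow(regs)) {
      regs$support <- NA_integer_
      regs$locus <- NA_character_
      all_regs[[length(all_regs) + 1L]] <<- regs
    }
  }

  if ("extended" %in% categories) {
    ext <- extended_gene_regions(ann, flank)
    if (strand_mode == "ignore") ext$strand <- "."
    classify_novel(scan_intervals(ext, "extended"), "extended")
  }

  # --- intergenic ----------------------------------------------------------
  if ("intergenic" %in% categories) {
    for (chrom in chroms) for (std in strands) {
      inter <- intergenic_regions(ann, chrom, std)
      classify_novel(scan_intervals(inter, "intergenic"), "intergenic")
    }
  }

  regions <- if (length(all_regs)) {
    out <- do.call(rbind, all_regs)
    key <- paste(out$sample, out$chrom, out$start, out$end, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
    out[order(out$chrom, out$start, out$sample), , drop = FALSE]
  } else {
    er <- empty_regions()
    er$category <- character(0); er$support <- integer(0)
    er$locus <- character(0)
    er
  }
  rownames(regions) <- NULL

  # Table-1-shaped support summary: genes with regions in >= X samples
  support <- stats::setNames(
    vapply(seq_len(n_samples), function(x) sum(gene_support >= x),
           integer(1)),
    paste0("X>=", seq_len(n_samples)))

  # counts over supported genes + novel loci
  count_regions <- NULL
  if (length(supported_genes)) {
    sg <- do.call(rbind, supported_genes)
    count_regions <- data.frame(label = sg$gene_id, chrom = sg$chrom,
                                start = sg$start, end = sg$end,
                                strand = sg$strand, stringsAsFactors = FALSE)
  }
  if (length(novel_loci)) {
    nl <- unique(do.call(rbind, novel_loci)[, c("chrom", "start", "end",
                                                "strand")])
    nl <- data.frame(label = sprintf("%s:%d-%d(%s)", nl$chrom, nl$start,
                                     nl$end, nl$strand),
                     nl, stringsAsFactors = FALSE)
    count_regions <- rbind(count_regions, nl)
  }
  counts <- if (!is.null(count_regions) && nrow(count_regions))
    build_count_table(backends, count_regions)
  else CountTable(data.frame(label = character(0)), names(backends),
                  matrix(0L, 0L, n_samples))

  list(regions = regions, counts = counts, support = support)
}

#' Cross-sample support summary over a parameter grid
#'
#' For every combination of `mu` and `minsup`, counts the genes that
#' contain at least one mined irreducible region in at least X of the N
#' samples (X = 1..N) -- the shape of a per-gene support table, one row
#' per (mu, minsup, X).  A gene counts once per sample no matter how
#' many regions it contains.  The counts are monotone non-increasing in
#' X, in mu and in minsup.
#'
#' @param backends named list of back-ends, one per sample.
#' @param ann an [AnnotationSet-class].
#' @param mu_values,minsup_values parameter grids.
#' @param strand_mode `"same"` (default) or `"ignore"`.
#' @param smooth,f optional lowess smoothing before mining.
#' @return data.frame with columns `mu`, `minsup`, `X`, `genes`.
#' @export
support_table <- function(backends, ann, mu_values = c(5, 10, 15),
                          minsup_values = c(1L, 51L),
                          strand_mode = c("same", "ignore"),
                          smooth = FALSE, f = 0.1) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(names(backends)))
    names(backends) <- vapply(backends, `[[`, character(1), "sample_id")
  n_samples <- length(backends)
  genes <- ann@genes
  n_genes <- nrow(genes)
  # presence[gene, sample, mu, minsup]
  pres <- array(FALSE, c(n_genes, n_samples, length(mu_values),
                         length(minsup_values)))
  for (g in seq_len(n_genes)) {
    std <- if (strand_mode == "same") genes$strand[g] else "."
    gi <- GenomicInterval(genes$chrom[g], genes$start[g], genes$end[g], std)
    for (s in seq_len(n_samples)) {
      rs <- fetch_reads(backends[[s]], gi)
      tr <- pileup_coverage(rs, strand_mode)
      if (smooth && interval_length(gi) >= 10L) tr <- lowess_smooth(tr, f = f)
      v <- track_values(tr)
      for (m in seq_along(mu_values)) {
        mat <- .mine_maximal(v, mu_values[m], MINE_EPS, FALSE)
        if (!nrow(mat)) next
        widths <- mat[, 2L] - mat[, 1L]
        for (w in seq_along(minsup_values))
          pres[g, s, m, w] <- any(widths >= minsup_values[w])
      }
    }
  }
  grid <- expand.grid(X = seq_len(n_samples), minsup = minsup_values,
                      mu = mu_values)
  grid$genes <- vapply(seq_len(nrow(grid)), function(i) {
    m <- match(grid$mu[i], mu_values); w <- match(grid$minsup[i],
                                                  minsup_values)
    sum(rowSums(pres[, , m, w, drop = FALSE]) >= grid$X[i])
  }, integer(1))
  grid[, c("mu", "minsup", "X", "genes")]
}
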