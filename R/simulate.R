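#' Simulation configuration
#'
#' Defaults describe a compact but realistic bulk RNA-seq study on one
#' 2 Mb chromosome: 50 non-overlapping multi-exon genes on both
#' strands, 6 samples, 50 bp reads, negative-binomial per-exon read
#' counts (variance = mean + dispersion * mean^2), uniform background
#' noise on both strands, and occasional amplification-artifact stacks
#' of duplicate reads.  With the default expression mean the exon
#' coverage plateau is about 100x while per-strand background coverage
#' is about 0.5x, so mining at the default threshold (mu = 5) is
#' operating at 20x the detection level inside exons and a tenth of it
#' outside.  Introns and intergenic gaps are at least 10 kb so that
#' distinct exons can never be bridged by the miner at these expression
#' levels.
#'
#' @param seed RNG seed; a fixed seed yields identical output.
#' @param n_genes number of genes.
#' @param n_samples number of samples.
#' @param chrom_length chromosome length (nt).
#' @param read_length read length (nt).
#' @param exons_per_gene inclusive integer range, e.g. `c(2, 4)`.
#' @param exon_length inclusive range of exon lengths; the minimum must
#'   be at least `read_length` (reads lie fully inside their exon).
#' @param intron_length inclusive range of intron lengths.
#' @param expression_mean mean reads per exon per sample.
#' @param dispersion negative-binomial dispersion (0.2 is typical for
#'   over-dispersed RNA-seq counts).
#' @param background_rate background noise reads per kb of chromosome
#'   (split over both strands).
#' @param artifact_peak_rate per-gene, per-sample probability of one
#'   position receiving a stack of `artifact_stack` duplicate reads.
#' @param artifact_stack duplicate reads per artifact peak.
#' @param chrom chromosome name.
#' @return A config list for [simulate_reads()].
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, n_samples = 6L,
                       chrom_length = 2e6, read_length = 50L,
                       exons_per_gene = c(2L, 4L),
                       exon_length = c(150L, 300L),
                       intron_length = c(10000L, 15000L),
                       expression_mean = 350, dispersion = 0.2,
                       background_rate = 20, artifact_peak_rate = 0.1,
                       artifact_stack = 25L, chrom = "chr1") {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              chrom_length = as.integer(chrom_length),
              read_length = as.integer(read_length),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              expression_mean = expression_mean, dispersion = dispersion,
              background_rate = background_rate,
              artifact_peak_rate = artifact_peak_rate,
              artifact_stack = as.integer(artifact_stack), chrom = chrom)
  stopifnot(cfg$n_genes >= 1L, cfg$n_samples >= 1L, cfg$read_length >= 1L,
            cfg$exon_length[1L] >= cfg$read_length,
            cfg$expression_mean > 0, cfg$dispersion >= 0,
            cfg$background_rate >= 0, cfg$artifact_peak_rate >= 0,
            cfg$artifact_peak_rate <= 1)
  cfg
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) +
    range[1L] - 1L
}

# Gene/exon layout: genes placed left to right, separated by intergenic
# gaps of at least min_gap, alternating strand at random.
sim_layout <- function(cfg, min_gap = 10000L) {
  n_ex <- rint(cfg$n_genes, cfg$exons_per_gene)
  exon_lens <- lapply(n_ex, function(k) rint(k, cfg$exon_length))
  intron_lens <- lapply(n_ex, function(k)
    if (k > 1L) rint(k - 1L, cfg$intron_length) else integer(0))
  spans <- vapply(seq_len(cfg$n_genes), function(g)
    sum(exon_lens[[g]]) + sum(intron_lens[[g]]), numeric(1))
  leftover <- cfg$chrom_length - sum(spans) - (cfg$n_genes + 1L) * min_gap
  if (leftover < 0)
    stop("chromosome too short for the requested gene layout")
  w <- stats::runif(cfg$n_genes + 1L)
  gaps <- min_gap + floor(w / sum(w) * leftover)
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- vector("list", cfg$n_genes)
  exons <- vector("list", cfg$n_genes)
  pos <- 0L
  for (g in seq_len(cfg$n_genes)) {
    pos <- pos + as.integer(gaps[g])
    gstart <- pos
    ex <- integer(0)
    for (e in seq_len(n_ex[g])) {
      ex_start <- pos
      pos <- pos + exon_lens[[g]][e]
      exons[[g]] <- rbind(exons[[g]],
                          data.frame(gene_id = sprintf("gene%03d", g),
                                     exon = e, start = ex_start, end = pos,
                                     strand = strands[g],
                                     stringsAsFactors = FALSE))
      if (e < n_ex[g]) pos <- pos + intron_lens[[g]][e]
    }
    genes[[g]] <- data.frame(gene_id = sprintf("gene%03d", g),
                             chrom = cfg$chrom, start = gstart, end = pos,
                             strand = strands[g], stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Simulate an RNA-seq read dataset with known ground truth
#'
#' Generates annotations, per-sample reads and a truth manifest with
#' the statistical structure the package's analyses assume: each exon
#' receives a negative-binomial read count (read starts uniform inside
#' the exon, read strand = gene strand), background reads fall
#' uniformly over the chromosome on both strands, and with probability
#' `artifact_peak_rate` per gene and sample one exon position receives
#' a stack of duplicate reads mimicking over-amplification.  Introns
#' receive no reads from their gene (no junction reads).
#'
#' @param cfg configuration from [sim_config()].
#' @param outdir output directory (created if needed); `NULL` skips all
#'   file output and returns the in-memory dataset only.
#' @param formats subset of `c("tsv", "bam", "gff3", "json")`: which
#'   files to write (`<sample>.reads.tsv`, coordinate-sorted indexed
#'   `<sample>.bam`, `genes.gff3` + `genes.tsv`, `manifest.json`).
#' @return (invisibly) a list: `config`, `genes`, `exons`, `reads`
#'   (named list of per-sample read data.frames, 0-based half-open),
#'   `exon_counts` (per sample x exon planted read counts),
#'   `artifacts`, `files` (paths written).
#' @export
simulate_reads <- function(cfg = sim_config(), outdir = NULL,
                           formats = c("tsv", "bam", "gff3", "json")) {
  withr::with_seed(cfg$seed, {
    layout <- sim_layout(cfg)
    genes <- layout$genes
    exons <- layout$exons
    r <- cfg$read_length
    reads <- list()
    exon_counts <- list()
    artifacts <- list()
    for (s in seq_len(cfg$n_samples)) {
      sid <- sprintf("s%d", s)
      counts <- if (cfg$dispersion > 0)
        stats::rnbinom(nrow(exons), size = 1 / cfg$dispersion,
                       mu = cfg$expression_mean)
      else stats::rpois(nrow(exons), cfg$expression_mean)
      starts <- integer(0); strands <- character(0)
      for (e in seq_len(nrow(exons))) {
        if (counts[e] == 0L) next
        span <- exons$end[e] - exons$start[e] - r + 1L
        st <- exons$start[e] + rint(counts[e], c(1L, span)) - 1L
        starts <- c(starts, st)
        strands <- c(strands, rep(exons$strand[e], counts[e]))
      }
      # amplification artifacts: a duplicate-read stack at one exon position
      for (g in seq_len(cfg$n_genes)) {
        if (stats::runif(1L) >= cfg$artifact_peak_rate) next
        gex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
        pick <- gex[rint(1L, c(1L, nrow(gex))), ]
        span <- pick$end - pick$start - r + 1L
        pos <- pick$start + rint(1L, c(1L, span)) - 1L
        starts <- c(starts, rep(pos, cfg$artifact_stack))
        strands <- c(strands, rep(pick$strand, cfg$artifact_stack))
        artifacts[[length(artifacts) + 1L]] <-
          data.frame(sample = sid, gene_id = genes$gene_id[g], pos = pos,
                     n_dup = cfg$artifact_stack, stringsAsFactors = FALSE)
      }
      # uniform background noise on both strands
      n_bg <- stats::rpois(1L, cfg$background_rate * cfg$chrom_length / 1000)
      if (n_bg > 0L) {
        starts <- c(starts, rint(n_bg, c(0L, cfg$chrom_length - r)))
        strands <- c(strands, sample(c("+", "-"), n_bg, replace = TRUE))
      }
      df <- data.frame(chrom = cfg$chrom, start = as.integer(starts),
                       end = as.integer(starts) + r, strand = strands,
                       sample_id = sid, stringsAsFactors = FALSE)
      df <- df[order(df$start, df$end), , drop = FALSE]
      rownames(df) <- NULL
      reads[[sid]] <- df
      exon_counts[[sid]] <- data.frame(sample = sid,
                                       gene_id = exons$gene_id,
                                       exon = exons$exon,
                                       count = as.integer(counts),
                                       stringsAsFactors = FALSE)
    }
    artifacts <- if (length(artifacts)) do.call(rbind, artifacts)
      else data.frame(sample = character(0), gene_id = character(0),
                      pos = integer(0), n_dup = integer(0))
    files <- character(0)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      files <- write_sim_files(cfg, genes, exons, reads, exon_counts,
                               artifacts, outdir, formats)
    }
    invisible(list(config = cfg, genes = genes, exons = exons,
                   reads = reads,
                   exon_counts = do.call(rbind, exon_counts),
                   artifacts = artifacts, files = files))
  })
}

write_sim_files <- function(cfg, genes, exons, reads, exon_counts,
                            artifacts, outdir, formats) {
  files <- character(0)
  if ("gff3" %in% formats) {
    gff <- file.path(outdir, "genes.gff3")
    con <- file(gff, "w")
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", cfg$chrom,
                         cfg$chrom_length)), con)
    writeLines(sprintf("%s\tcovmine_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start + 1L, genes$end,
                       genes$strand, genes$gene_id), con)
    writeLines(sprintf(
      "%s\tcovmine_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      cfg$chrom, exons$start + 1L, exons$end, exons$strand, exons$gene_id,
      exons$exon, exons$gene_id), con)
    close(con)
    tsv <- file.path(outdir, "genes.tsv")
    con <- file(tsv, "w")
    writeLines("gene_id\tchrom\tstart\tend\tstrand", con)
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s", genes$gene_id, genes$chrom,
                       genes$start + 1L, genes$end, genes$strand), con)
    close(con)
    files <- c(files, gff, tsv)
  }
  for (sid in names(reads)) {
    df <- reads[[sid]]
    if ("tsv" %in% formats) {
      path <- file.path(outdir, sprintf("%s.reads.tsv", sid))
      region <- GenomicInterval(cfg$chrom, 0L, cfg$chrom_length)
      rs <- ReadSet(region, df[, c("start", "end", "strand")], sid)
      write_read_tsv(rs, path)
      files <- c(files, path)
    }
    if ("bam" %in% formats) {
      files <- c(files, write_sim_bam(cfg, df, sid, outdir))
    }
  }
  if ("json" %in% formats) {
    path <- file.path(outdir, "manifest.json")
    manifest <- list(config = cfg, genes = genes, exons = exons,
                     exon_counts = do.call(rbind, exon_counts),
                     artifacts = artifacts,
                     n_reads = vapply(reads, nrow, integer(1)))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, path)
  }
  files
}

# Coordinate-sorted, indexed BAM via a SAM text intermediate.
write_sim_bam <- function(cfg, df, sid, outdir) {
  sam <- file.path(outdir, sprintf("%s.sam", sid))
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom, cfg$chrom_length)),
             con)
  if (nrow(df)) {
    flag <- ifelse(df$strand == "-", 16L, 0L)
    writeLines(sprintf("r%07d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(df)), flag, df$chrom, df$start + 1L,
                       df$end - df$start), con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, file.path(outdir, sid), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
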