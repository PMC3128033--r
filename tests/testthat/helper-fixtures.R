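# Shared fixtures: everything is generated in code at test time.

make_track <- function(values, start = 0L, chrom = "chr1", strand = "+",
                       sample = "s1", kind = "counts") {
  reg <- GenomicInterval(chrom, start, start + length(values), strand)
  CoverageTrack(reg, values, samples = sample, kind = kind)
}

random_reads <- function(n, region_len, read_len = 20L,
                         strands = c("+", "-", ".")) {
  start <- sample.int(region_len + read_len - 1L, n, replace = TRUE) - read_len
  data.frame(start = start, end = start + read_len,
             strand = sample(strands, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Position-by-position membership count: the pileup oracle.
brute_pileup <- function(reads, region, strand = NULL) {
  if (!is.null(strand))
    reads <- reads[reads$strand == strand | reads$strand == ".", ,
                   drop = FALSE]
  vapply(seq.int(region@start, region@end - 1L), function(p)
    sum(reads$start <= p & reads$end > p), numeric(1))
}

# Compare mined-region frames on the fields that define the contract.
expect_same_regions <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$mean_value, b$mean_value, tolerance = 1e-12)
  }
}

tiny_sim <- function(seed = 1L, ...) {
  simulate_reads(sim_config(seed = seed, n_genes = 4L, n_samples = 2L,
                            chrom_length = 3e5,
                            intron_length = c(10000L, 12000L),
                            background_rate = 5, ...),
                 outdir = NULL, formats = character(0))
}

sim_backends <- function(sim) {
  bes <- lapply(names(sim$reads), function(s)
    backend(sim$reads[[s]], format = "memory", sample_id = s))
  names(bes) <- names(sim$reads)
  bes
}

sim_annotation <- function(sim) {
  AnnotationSet(sim$genes,
                stats::setNames(sim$config$chrom_length, sim$config$chrom))
}

# Base-level sensitivity/precision of mined regions against planted exons
# on one strand of the simulated chromosome.
score_recovery <- function(sim, regs, exons, strand) {
  cl <- sim$config$chrom_length
  ex <- exons[exons$strand == strand, , drop = FALSE]
  truth <- logical(cl)
  for (i in seq_len(nrow(ex))) truth[(ex$start[i] + 1L):ex$end[i]] <- TRUE
  mined <- logical(cl)
  for (i in seq_len(nrow(regs))) mined[(regs$start[i] + 1L):regs$end[i]] <- TRUE
  c(sensitivity = sum(mined & truth) / max(sum(truth), 1L),
    precision = if (sum(mined)) sum(mined & truth) / sum(mined) else 1)
}
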