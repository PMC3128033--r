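make_ann <- function(genes, len = 1000L, chrom = "chr1") {
  AnnotationSet(genes, stats::setNames(len, chrom))
}

test_that("gene, extended and intergenic region sets behave as documented", {
  empty <- make_ann(data.frame(gene_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0)))
  expect_equal(nrow(gene_regions(empty, "chr1", "+")), 0L)
  expect_equal(intergenic_regions(empty, "chr1", "+"),
               data.frame(chrom = "chr1", start = 0L, end = 1000L,
                          strand = "+"))
  expect_error(gene_regions(empty, "chrX", "+"), "unknown chromosome")

  genes <- data.frame(
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = c(100L, 500L, 700L, 300L, 650L),
    end = c(200L, 600L, 800L, 400L, 720L),
    strand = c("+", "+", "+", "-", "-"))
  ann <- make_ann(genes)
  gp <- gene_regions(ann, "chr1", "+")
  expect_equal(gp$gene_id, c("g1", "g2", "g3"))
  expect_true(all(diff(gp$start) > 0))

  # flank = 0 is the identity; clamping at chromosome bounds
  ext0 <- extended_gene_regions(ann, 0L)
  expect_equal(ext0$start, sort(genes$start))
  one <- make_ann(data.frame(gene_id = "g", chrom = "chr1", start = 100L,
                             end = 200L, strand = "+"), len = 10000L)
  ext <- extended_gene_regions(one, 1000L)
  expect_equal(c(ext$start, ext$end), c(0L, 1200L))

  inter <- intergenic_regions(make_ann(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(100L, 500L),
    end = c(200L, 600L), strand = "+")), "chr1", "+")
  expect_equal(inter$start, c(0L, 200L, 600L))
  expect_equal(inter$end, c(100L, 500L, 1000L))

  # overlapping genes are merged before the complement
  inter2 <- intergenic_regions(make_ann(data.frame(
    gene_id = c("a", "b"), chrom = "chr1", start = c(100L, 250L),
    end = c(300L, 400L), strand = "+")), "chr1", "+")
  expect_equal(inter2$start, c(0L, 400L))
  expect_equal(inter2$end, c(100L, 1000L))

  # partition: genic union + intergenic covers [0, len) exactly once
  for (std in c("+", "-")) {
    g <- gene_regions(ann, "chr1", std)
    i <- intergenic_regions(ann, "chr1", std)
    covered <- integer(1000)
    for (r in seq_len(nrow(g)))
      covered[(g$start[r] + 1):g$end[r]] <- covered[(g$start[r] + 1):g$end[r]] + 1L
    for (r in seq_len(nrow(i)))
      covered[(i$start[r] + 1):i$end[r]] <- covered[(i$start[r] + 1):i$end[r]] + 1L
    expect_true(all(covered >= 1))
    # intergenic never overlaps a gene
    for (r in seq_len(nrow(i)))
      expect_false(any(g$start < i$end[r] & g$end > i$start[r]))
  }
})

test_that("chunk_iterator covers the interval with exact overlaps", {
  short <- chunk_iterator(GenomicInterval("chr1", 0, 50, "+"), 100, 10)
  expect_equal(nrow(short), 1L)
  expect_equal(c(short$start, short$end), c(0L, 50L))

  ch <- chunk_iterator(GenomicInterval("chr1", 0, 250, "+"), 100, 10)
  expect_equal(ch$start, c(0L, 90L, 180L))
  expect_equal(ch$end, c(100L, 190L, 250L))

  expect_error(chunk_iterator(GenomicInterval("chr1", 0, 250, "+"), 20, 10),
               "chunk_size")
})

test_that("chunked mining equals unchunked mining after merging", {
  set.seed(111)
  # several short expressed blocks over a long vector
  v <- numeric(5000)
  starts <- c(200, 1100, 1950, 3000, 4400)
  for (s in starts) v[s:(s + 120)] <- rpois(121, 30)
  v <- v + rpois(5000, 0.2)
  tr <- make_track(v)
  whole <- find_irreducible_regions(tr, mu = 5, minsup = 20)

  for (chunk in c(600L, 1000L, 2600L)) {
    chunks <- chunk_iterator(tr@region, chunk, 200L)
    pieces <- lapply(seq_len(nrow(chunks)), function(k) {
      sub <- slice_track(tr, GenomicInterval(chunks$chrom[k],
                                             chunks$start[k], chunks$end[k],
                                             chunks$strand[k]))
      find_irreducible_regions(sub, mu = 5, minsup = 20)
    })
    merged <- merge_chunk_regions(do.call(rbind, pieces))
    expect_same_regions(merged, whole)
  }
})

test_that("discover recovers genes, respects support, finds planted intergenic loci", {
  sim <- tiny_sim(seed = 5)
  bes <- sim_backends(sim)
  ann <- sim_annotation(sim)

  res <- discover(bes, ann, mu = 5, minsup = 51, min_samples = 1)
  # every simulated gene is expressed far above mu in both samples
  expect_equal(unname(res$support), rep(nrow(sim$genes), 2L))
  expect_true(all(res$regions$category == "genic"))
  expect_setequal(unique(res$regions$locus), sim$genes$gene_id)
  # counts has one row per gene, all strongly expressed
  expect_equal(sort(res$counts@regions$label), sort(sim$genes$gene_id))
  expect_true(all(res$counts@counts > 100))

  # support monotone in X by construction
  expect_true(all(diff(res$support) <= 0))

  # single expressed sample cannot satisfy min_samples = 2
  one <- list(s1 = bes$s1,
              empty = backend(data.frame(chrom = character(0),
                                         start = integer(0),
                                         end = integer(0),
                                         strand = character(0)),
                              format = "memory", sample_id = "empty"))
  res2 <- discover(one, ann, mu = 5, minsup = 51, min_samples = 2,
                   categories = "genic")
  expect_equal(nrow(res2$regions), 0L)
  expect_equal(unname(res2$support), c(nrow(sim$genes), 0L))

  # a planted intergenic transcript is discovered at its locus
  gap_mid <- 5000L  # inside the first intergenic gap by construction
  width <- 300L
  extra <- data.frame(chrom = "chr1",
                      start = gap_mid + seq_len(400) %% 250,
                      end = gap_mid + seq_len(400) %% 250 + 50L,
                      strand = "+")
  reads3 <- rbind(sim$reads$s1[, c("chrom", "start", "end", "strand")], extra)
  bes3 <- list(s1 = backend(reads3, format = "memory", sample_id = "s1"))
  res3 <- discover(bes3, ann, mu = 5, minsup = 51, min_samples = 1,
                   categories = "intergenic")
  novel <- res3$regions[res3$regions$category == "intergenic", ]
  expect_equal(nrow(novel), 1L)
  expect_lt(abs(novel$start - gap_mid), 55)
  expect_lt(abs(novel$end - (gap_mid + width)), 55)
})

test_that("support table is monotone in X, mu and minsup", {
  sim <- tiny_sim(seed = 9, expression_mean = 60)
  tab <- support_table(sim_backends(sim), sim_annotation(sim),
                       mu_values = c(2, 5, 10, 25),
                       minsup_values = c(1L, 51L, 120L))
  expect_true(all(tab$genes >= 0))
  for (mu in unique(tab$mu)) for (ms in unique(tab$minsup)) {
    g <- tab$genes[tab$mu == mu & tab$minsup == ms]
    expect_true(all(diff(g) <= 0))  # in X
  }
  for (ms in unique(tab$minsup)) for (x in unique(tab$X)) {
    g <- tab$genes[tab$minsup == ms & tab$X == x]
    expect_true(all(diff(g) <= 0))  # in mu (mu_values are ascending)
  }
  for (mu in unique(tab$mu)) for (x in unique(tab$X)) {
    g <- tab$genes[tab$mu == mu & tab$X == x]
    expect_true(all(diff(g) <= 0))  # in minsup
  }
})
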