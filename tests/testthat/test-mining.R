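test_that("irreducibility predicate follows the split definition", {
  expect_true(is_irreducible(7, 5))
  expect_false(is_irreducible(3, 5))
  expect_true(is_irreducible(c(10, 2, 10), 5))  # splits: {10|2,10}, {10,2|10}
  expect_false(is_irreducible(c(10, 2), 5))     # right part mean 2 < 5
  expect_true(is_irreducible(c(5, 5, 5), 5))    # equality is accepted
  expect_false(is_irreducible(c(5, 5, 5), 5, strict = TRUE))
  expect_error(is_irreducible(numeric(0), 5), "non-empty")
})

test_that("find_irreducible_regions returns the documented examples", {
  expect_equal(nrow(find_irreducible_regions(make_track(numeric(40)),
                                             mu = 5, minsup = 1)), 0L)

  regs <- find_irreducible_regions(make_track(rep(7, 50)), mu = 5,
                                   minsup = 10)
  expect_equal(regs[, c("start", "end", "mean_value")],
               data.frame(start = 0L, end = 50L, mean_value = 7))

  tr <- make_track(c(10, 2, 10, 0, 0, 8))
  r1 <- find_irreducible_regions(tr, mu = 5, minsup = 1)
  expect_equal(r1$start, c(0L, 5L))
  expect_equal(r1$end, c(3L, 6L))
  r2 <- find_irreducible_regions(tr, mu = 5, minsup = 2)
  expect_equal(r2$start, 0L)
  expect_equal(r2$end, 3L)

  # boundary equality: constant vector at exactly mu
  r3 <- brute_force_regions(c(5, 5, 5), mu = 5, minsup = 1)
  expect_equal(r3$start, 0L)
  expect_equal(r3$end, 3L)

  # genome offset is applied
  off <- make_track(c(10, 2, 10), start = 1000L)
  expect_equal(find_irreducible_regions(off, mu = 5, minsup = 1)$start, 1000L)

  expect_error(find_irreducible_regions(make_track(c(1, -1, 1),
                                                   kind = "normalized"),
                                        mu = 0.5), "negative")
  expect_error(find_irreducible_regions(make_track(1:5), sample = "nope"),
               "not present")
})

test_that("fast miner is equivalent to the exhaustive oracle", {
  set.seed(404)
  for (t in 1:150) {
    n <- sample(1:150, 1)
    v <- if (t %% 2) rpois(n, sample(c(2, 5, 9), 1))
         else rnbinom(n, size = 3, mu = 6)
    for (mu in c(2, 5, 10)) for (ms in c(1L, 5L, 25L)) {
      fast <- find_irreducible_regions(make_track(v), mu = mu, minsup = ms)
      slow <- brute_force_regions(v, mu, ms)
      expect_same_regions(fast, slow)
    }
  }
})

test_that("every mined region satisfies the irreducibility invariants", {
  set.seed(505)
  for (t in 1:40) {
    v <- rpois(sample(30:200, 1), 5)
    mu <- sample(c(2, 5, 8), 1)
    ms <- sample(c(1L, 5L, 20L), 1)
    regs <- find_irreducible_regions(make_track(v), mu = mu, minsup = ms)
    if (!nrow(regs)) next
    for (i in seq_len(nrow(regs))) {
      seg <- v[(regs$start[i] + 1):regs$end[i]]
      expect_gte(mean(seg), mu)
      expect_gte(seg[1], mu)
      expect_gte(seg[length(seg)], mu)
      expect_true(is_irreducible(seg, mu))
      expect_gte(length(seg), ms)
      # one-position-extension maximality
      if (regs$start[i] > 0)
        expect_false(is_irreducible(v[regs$start[i]:regs$end[i]], mu))
      if (regs$end[i] < length(v))
        expect_false(is_irreducible(v[(regs$start[i] + 1):(regs$end[i] + 1)],
                                    mu))
    }
    # sorted and pairwise disjoint
    expect_true(all(diff(regs$start) > 0))
    if (nrow(regs) > 1)
      expect_true(all(regs$start[-1] >= regs$end[-nrow(regs)]))
  }
})

test_that("region-based coverage follows the max-mu rule", {
  # constant 12 supports mu=10 but not mu=15
  tr <- make_track(rep(12, 30))
  out <- region_based_coverage(tr, mu_ladder = c(5, 10, 15), minsup = 1)
  expect_equal(as.numeric(out@values), rep(10, 30))
  expect_equal(out@kind, "region_based")

  expect_equal(as.numeric(region_based_coverage(make_track(numeric(20)),
                                                mu_ladder = c(5, 10),
                                                minsup = 1)@values),
               numeric(20))

  tr2 <- make_track(c(10, 2, 10, 0, 0, 8))
  expect_equal(as.numeric(region_based_coverage(tr2, mu_ladder = c(5, 8),
                                                minsup = 1)@values),
               c(8, 5, 8, 0, 0, 8))

  # values come from the ladder; removing a level never raises any value
  set.seed(606)
  for (t in 1:10) {
    v <- rpois(100, 8)
    tr3 <- make_track(v)
    ladder <- c(2, 5, 9, 12)
    full <- as.numeric(region_based_coverage(tr3, mu_ladder = ladder,
                                             minsup = 3)@values)
    expect_true(all(full %in% c(0, ladder)))
    reduced <- as.numeric(region_based_coverage(tr3, mu_ladder = c(2, 9),
                                                minsup = 3)@values)
    expect_true(all(reduced <= full + 1e-12))
  }

  expect_error(region_based_coverage(tr, mu_ladder = c(5, 3)), "increasing")
  expect_error(region_based_coverage(tr, mu_ladder = c(-1, 3)), "positive")
})

test_that("adaptive mu resolvers are evaluated on the track slice", {
  v <- c(rep(0, 10), rep(100, 20), rep(0, 10))
  tr <- make_track(v)
  regs <- find_irreducible_regions(tr, mu = mu_fraction_of_max(0.5),
                                   minsup = 1)
  expect_equal(regs$mu, 50)
  expect_equal(regs$start, 10L)
  expect_equal(regs$end, 30L)
  expect_equal(find_irreducible_regions(tr, mu = mu_fixed(5),
                                        minsup = 1)$mu, 5)
  expect_equal(find_irreducible_regions(tr, mu = mu_fraction_of_min(1),
                                        minsup = 1)$mu, 0)
})

test_that("support_filter counts samples with an overlapping region", {
  gene <- GenomicInterval("chr1", 100, 200, "+")
  mk <- function(start, end, strand = "+")
    data.frame(chrom = "chr1", start = start, end = end, width = end - start,
               strand = strand, sample = "x", mean_value = 10, mu = 5,
               minsup = 1L, stringsAsFactors = FALSE)
  none <- list(a = mk(300, 400))
  expect_false(support_filter(none, gene, 1))

  four <- list(a = mk(150, 180), b = mk(90, 110), c = mk(199, 250),
               d = mk(100, 200), e = mk(0, 50), f = mk(200, 300))
  for (ms in 1:4) expect_true(support_filter(four, gene, ms))
  for (ms in 5:6) expect_false(support_filter(four, gene, ms))

  # opposite strand does not count; unstranded does
  expect_false(support_filter(list(a = mk(150, 180, "-")), gene, 1))
  expect_true(support_filter(list(a = mk(150, 180, ".")), gene, 1))
  expect_error(support_filter(four, gene, 0), "min_samples")
})

test_that("the exhaustive oracle refuses vectors beyond its guard", {
  expect_error(brute_force_regions(rpois(50, 3), 5, guard = 20L), "guard")
})
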