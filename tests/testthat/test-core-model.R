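test_that("interval invariants are enforced", {
  gi <- GenomicInterval("chr1", 10, 60, "+")
  expect_equal(interval_length(gi), 50L)
  expect_error(GenomicInterval("chr1", 10, 10), "half-open")
  expect_error(GenomicInterval("chr1", -1, 10), "non-negative")
  expect_error(GenomicInterval("chr1", 0, 10, "x"), "strand")
})

test_that("pileup matches per-position membership counting", {
  reg <- GenomicInterval("chr1", 0, 100, "+")

  # identity case: no reads
  expect_equal(track_values(pileup_coverage(ReadSet(reg, sample_id = "s1"))),
               numeric(100))

  # single read [10, 60)
  rs <- ReadSet(reg, data.frame(start = 10L, end = 60L, strand = "+"), "s1")
  v <- track_values(pileup_coverage(rs))
  expect_equal(v[11:60], rep(1, 50))
  expect_equal(sum(v), 50)

  # random reads vs brute-force oracle, both strand modes
  set.seed(101)
  for (rep in 1:5) {
    reg2 <- GenomicInterval("chr1", 1000, 1500, "+")
    rd <- random_reads(50, 500, read_len = 30L)
    rd$start <- rd$start + 1000L
    rd$end <- rd$end + 1000L
    rs2 <- ReadSet(reg2, rd, "s1")
    expect_equal(track_values(pileup_coverage(rs2, "ignore")),
                 brute_pileup(rd, reg2))
    expect_equal(track_values(pileup_coverage(rs2, "same")),
                 brute_pileup(rd, reg2, "+"))
  }
})

test_that("pileup conservation, strand decomposition and permutation invariance", {
  set.seed(202)
  reg <- GenomicInterval("chr1", 0, 400, "+")
  rd <- random_reads(80, 400, read_len = 25L)
  rs <- ReadSet(reg, rd, "s1")
  v <- track_values(pileup_coverage(rs, "ignore"))

  # conservation: sum of pileup == total overlap length of reads
  ov <- pmin(rd$end, 400L) - pmax(rd$start, 0L)
  expect_equal(sum(v), sum(ov))

  # strand decomposition
  parts <- lapply(c("+", "-", "."), function(s) {
    sub <- rd[rd$strand == s, , drop = FALSE]
    if (nrow(sub)) track_values(pileup_coverage(ReadSet(reg, sub, "s1"),
                                                "ignore"))
    else numeric(400)
  })
  expect_equal(v, Reduce(`+`, parts))

  # permutation invariance: ReadSet canonicalizes order
  perm <- rd[sample.int(nrow(rd)), , drop = FALSE]
  expect_equal(track_values(pileup_coverage(ReadSet(reg, perm, "s1"),
                                            "ignore")), v)

  # unstranded reads are counted in both same-strand modes
  dot <- data.frame(start = 0L, end = 10L, strand = ".")
  for (std in c("+", "-")) {
    r <- GenomicInterval("chr1", 0, 20, std)
    expect_equal(sum(track_values(pileup_coverage(ReadSet(r, dot, "s")))), 10)
  }

  expect_error(pileup_coverage(ReadSet(GenomicInterval("chr1", 0, 10, "."),
                                       sample_id = "s"), "same"),
               "stranded")
})

test_that("region_count honours rules, boundaries and strand", {
  reg <- GenomicInterval("chr1", 0, 200, ".")
  expect_equal(region_count(ReadSet(reg, sample_id = "s"),
                            GenomicInterval("chr1", 0, 100)), 0L)

  rs <- ReadSet(reg, data.frame(start = 10L, end = 60L, strand = "+"), "s")
  expect_equal(region_count(rs, GenomicInterval("chr1", 0, 100)), 1L)
  # half-open: a read starting at 10 does not overlap [0, 10)
  expect_equal(region_count(rs, GenomicInterval("chr1", 0, 10)), 0L)
  # strand-matched unless the interval is unstranded
  expect_equal(region_count(rs, GenomicInterval("chr1", 0, 100, "-")), 0L)
  expect_equal(region_count(rs, GenomicInterval("chr1", 0, 100, "+")), 1L)

  expect_error(region_count(rs, GenomicInterval("chr2", 0, 100)),
               "chromosome mismatch")

  # rules agree with an exhaustive per-read check
  set.seed(303)
  rd <- random_reads(100, 500, read_len = 40L)
  big <- GenomicInterval("chr1", 0, 600, ".")
  rs2 <- ReadSet(big, rd, "s")
  sub <- GenomicInterval("chr1", 120, 300)
  expect_equal(region_count(rs2, sub, "any_overlap"),
               sum(rd$start < 300 & rd$end > 120))
  expect_equal(region_count(rs2, sub, "contained"),
               sum(rd$start >= 120 & rd$end <= 300))
})

test_that("slice_track restricts values and preserves partitions", {
  v <- rpois(100, 4)
  tr <- make_track(v)
  full <- slice_track(tr, tr@region)
  expect_equal(full@values, tr@values)

  sub <- slice_track(tr, GenomicInterval("chr1", 20, 30, "+"))
  expect_equal(as.numeric(sub@values), v[21:30])
  expect_equal(sub@kind, tr@kind)

  left <- slice_track(tr, GenomicInterval("chr1", 0, 40, "+"))
  right <- slice_track(tr, GenomicInterval("chr1", 40, 100, "+"))
  expect_equal(c(left@values, right@values), v)

  expect_error(slice_track(tr, GenomicInterval("chr1", 50, 150, "+")),
               "inside")
})
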