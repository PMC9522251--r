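# Enhancer calling and signal quantification.

test_that("interval_gap is edge-to-edge with 0 for overlap/book-ends", {
  a <- gintervals("chr1", 1000, 1200)
  expect_equal(interval_gap(a, gintervals("chr1", 1500, 1600)), 300)
  expect_equal(interval_gap(a, gintervals("chr1", 1100, 1300)), 0)
  expect_equal(interval_gap(a, gintervals("chr1", 1200, 1300)), 0)
  expect_equal(interval_gap(gintervals("chr1", 1500, 1600), a), 300)  # symmetric
  expect_error(interval_gap(a, gintervals("chr2", 1500, 1600)), "same chromosome")
})

test_that("call_enhancers applies the max-gap boundary exactly", {
  ac <- gintervals("chr1", 1000, 1200, name = "ac1")
  sel <- call_enhancers(ac, gintervals("chr1", 1500, 1600, name = "m1"))
  expect_equal(nrow(sel), 1)
  expect_equal(sel$gap_bp, 300)
  expect_equal(sel$partner_me1_id, "m1")
  expect_equal(nrow(call_enhancers(ac, gintervals("chr1", 1700, 1800))), 1) # gap 500
  expect_equal(nrow(call_enhancers(ac, gintervals("chr1", 1701, 1800))), 0) # gap 501
})

test_that("call_enhancers matches the brute-force oracle and is order-invariant", {
  set.seed(11)
  for (i in 1:10) {
    inst <- random_peak_instance(80, 60)
    got <- call_enhancers(inst$ac, inst$me1)
    want <- oracle_call_enhancers(inst$ac, inst$me1)
    expect_equal(got, want)
    # permutation invariance in input order
    got2 <- call_enhancers(inst$ac[sample.int(nrow(inst$ac)), ],
                           inst$me1[sample.int(nrow(inst$me1)), ])
    expect_equal(got2, got)
    expect_lte(nrow(got), nrow(inst$ac))
  }
})

test_that("raising max_gap never removes a selected enhancer", {
  set.seed(12)
  inst <- random_peak_instance(150, 100)
  prev <- character(0)
  for (mg in c(0, 100, 300, 500, 1000, 5000)) {
    cur <- call_enhancers(inst$ac, inst$me1, max_gap = mg)$enhancer_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("mean_peak_value samples the 201-point grid", {
  const <- signal_track(list(chr1 = data.frame(start = 0, end = 1e6, value = 3)))
  expect_equal(mean_peak_value(const, "chr1", 5000), 3)
  expect_equal(mean_peak_value(signal_track(list()), "chr1", 5000), 0)
  # value 10 on [center, center + 1e4): grid points >= center are 101 of 201
  half <- signal_track(list(chr1 = data.frame(start = 5000, end = 15000, value = 10)))
  expect_equal(mean_peak_value(half, "chr1", 5000), 10 * 101 / 201)
})

test_that("mean_peak_value is linear in the track", {
  set.seed(3)
  starts <- seq(0, 4000, by = 100)
  v1 <- rnorm(length(starts)); v2 <- rnorm(length(starts))
  t1 <- signal_track(list(chr1 = data.frame(start = starts, end = starts + 100, value = v1)))
  t2 <- signal_track(list(chr1 = data.frame(start = starts, end = starts + 100, value = v2)))
  tc <- signal_track(list(chr1 = data.frame(start = starts, end = starts + 100,
                                            value = 2 * v1 - 0.5 * v2)))
  centers <- c(500, 1500, 2500)
  expect_equal(mean_peak_value(tc, "chr1", centers),
               2 * mean_peak_value(t1, "chr1", centers) -
                 0.5 * mean_peak_value(t2, "chr1", centers),
               tolerance = 1e-12)
})

test_that("random_regions are deterministic, in bounds, and length-weighted", {
  gn <- genome(c(chr1 = 9e6, chr2 = 1e6))
  r1 <- random_regions(gn, 1e4, length = 500, seed = 99)
  r2 <- random_regions(gn, 1e4, length = 500, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$start >= 0))
  lens <- chrom_lengths(gn)[r1$chrom]
  expect_true(all(r1$end <= lens))
  # chromosome drawn proportionally to length: binomial 3 sigma around 9000
  n1 <- sum(r1$chrom == "chr1")
  expect_lt(abs(n1 - 9000), 3 * sqrt(1e4 * 0.9 * 0.1))
  expect_error(random_regions(gn, 10, length = 2e6, seed = 1), "at least")
  expect_error(random_regions(gn, 10, length = 2e7, seed = 1), "longest chromosome")
})

test_that("region_signal_test gives p = 1 on identical region sets", {
  tr <- signal_track(list(chr1 = data.frame(start = seq(0, 9000, 1000),
                                            end = seq(1000, 10000, 1000),
                                            value = 1:10)))
  regions <- gintervals("chr1", seq(0, 8000, 2000), seq(400, 8400, 2000))
  st <- region_signal_test(tr, regions, regions)
  expect_equal(st$p_value, 1)
  expect_equal(st$values_a, st$values_b)
})
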