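test_that("window statistics summarize depth correctly", {
  tr <- coverageTrack("chr", rep(150, 5000))
  st <- slidingWindowStats(tr)
  expect_true(all(st$min == 150 & st$mean == 150 & st$max == 150))
  expect_equal(st$start, seq(0, 4000, by = 100))
  expect_equal(st$end, st$start + 1000)

  # split window: half at 100, half at 200
  tr <- coverageTrack("chr", c(rep(100, 500), rep(200, 500)))
  st <- slidingWindowStats(tr, window = 1000, step = 100)
  expect_equal(nrow(st), 1L)
  expect_equal(st$mean, 150)
  expect_equal(st$min, 100)
  expect_equal(st$max, 200)

  # trailing partial window dropped
  expect_equal(nrow(slidingWindowStats(coverageTrack("c", rep(1, 1050)))), 1L)
  expect_error(slidingWindowStats(coverageTrack("c", rep(1, 500))),
               "exceeds contig length")
})

test_that("chunked window statistics agree with direct evaluation", {
  set.seed(8)
  d <- rpois(6000, 150)
  st <- slidingWindowStats(coverageTrack("c", d), window = 1000, step = 100)
  for (i in c(1, 17, 51)) {
    w <- d[(st$start[i] + 1):(st$end[i])]
    expect_equal(st$min[i], min(w))
    expect_equal(st$mean[i], mean(w))
    expect_equal(st$max[i], max(w))
  }
  # a step that does not divide the window takes the direct path
  st2 <- slidingWindowStats(coverageTrack("c", d), window = 1000, step = 300)
  w <- d[(st2$start[2] + 1):st2$end[2]]
  expect_equal(st2$mean[2], mean(w))
})

test_that("normalization puts the background at 1 and blocks at their copy ratio", {
  st <- slidingWindowStats(blockTrack(50000))
  expect_true(all(normalizeCoverage(st)$ratio == 1))

  st <- slidingWindowStats(blockTrack(
    50000, data.frame(start = 20000, end = 35000, copy = 2)))
  nr <- normalizeCoverage(st)
  inner <- nr$start >= 20000 & nr$end <= 35000
  outer <- nr$end <= 20000 | nr$start >= 35000
  expect_true(all(abs(nr$ratio[inner] - 2) < 1e-9))
  expect_true(all(abs(nr$ratio[outer] - 1) < 1e-9))

  expect_error(normalizeCoverage(slidingWindowStats(
    coverageTrack("c", rep(0, 5000)))), "all-zero")
})

test_that("duplication calling recovers a 21 kb block to within one step", {
  tr <- blockTrack(200000, data.frame(start = 50000, end = 71000, copy = 2))
  calls <- scanTrack(tr)
  expect_length(calls, 1L)
  expect_lte(abs(S4Vectors::mcols(calls)$start0 - 50000), 100)
  expect_lte(abs(GenomicRanges::end(calls) - 71000), 100)
  expect_equal(S4Vectors::mcols(calls)$meanRatio, 2, tolerance = 0.01)
  # a flat track yields no calls
  expect_length(scanTrack(blockTrack(200000)), 0L)
})

test_that("nearby runs merge and short runs are discarded", {
  # two 10 kb blocks separated by 1 kb (<= 2 kb merge gap): one call
  tr <- blockTrack(100000, data.frame(start = c(30000, 41000),
                                      end = c(40000, 51000), copy = 2))
  calls <- scanTrack(tr)
  expect_length(calls, 1L)
  expect_lte(abs(S4Vectors::mcols(calls)$start0 - 30000), 100)
  expect_lte(abs(GenomicRanges::end(calls) - 51000), 100)

  # separated by 3 kb: two calls
  tr <- blockTrack(100000, data.frame(start = c(30000, 43000),
                                      end = c(40000, 53000), copy = 2))
  expect_length(scanTrack(tr), 2L)

  # 3 kb block: below the 5 kb minimum length
  tr <- blockTrack(100000, data.frame(start = 30000, end = 33000, copy = 2))
  expect_length(scanTrack(tr), 0L)
})

test_that("reversing the depth array mirrors the call coordinates", {
  set.seed(21)
  sp <- syntheticSpec(200000, 150, dispersion = 0.05,
                      duplications = data.frame(start = 62000, end = 90000,
                                                copy = 2), seed = 21)
  d <- simulateCoverage(sp)$track@depth
  L <- length(d)
  fwd <- scanTrack(coverageTrack("c", d))
  rev <- scanTrack(coverageTrack("c", rev(d)))
  expect_length(fwd, 1L)
  expect_length(rev, 1L)
  expect_equal(S4Vectors::mcols(rev)$start0,
               L - GenomicRanges::end(fwd))
  expect_equal(GenomicRanges::end(rev),
               L - S4Vectors::mcols(fwd)$start0)
})

test_that("divergent sites are reported from allele counts inside calls", {
  tr <- blockTrack(200000, data.frame(start = 50000, end = 71000, copy = 2))
  calls <- scanTrack(tr)
  pu <- data.frame(contig = "chr", pos = 60000, ref = "G",
                   allele = c("G", "+T"), count = c(79, 76))
  sites <- callDivergentSites(pu, calls)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$fraction, 76 / 155, tolerance = 1e-12)
  expect_equal(sites$alt, "+T")
  expect_equal(sites$dupStart, S4Vectors::mcols(calls)$start0)

  # a fixed difference (fraction 1) is outside the band
  pu <- data.frame(contig = "chr", pos = 60000, ref = "G",
                   allele = "T", count = 155)
  expect_equal(nrow(callDivergentSites(pu, calls)), 0L)

  # depth below the threshold is ignored
  pu <- data.frame(contig = "chr", pos = 60000, ref = "G",
                   allele = c("G", "T"), count = c(5, 5))
  expect_equal(nrow(callDivergentSites(pu, calls)), 0L)

  # sites outside every call are ignored
  pu <- data.frame(contig = "chr", pos = 1000, ref = "G",
                   allele = c("G", "T"), count = c(80, 75))
  expect_equal(nrow(callDivergentSites(pu, calls)), 0L)

  # allele ties break lexicographically
  pu <- data.frame(contig = "chr", pos = 60000, ref = "G",
                   allele = c("G", "T", "A"), count = c(70, 55, 55))
  expect_equal(callDivergentSites(pu, calls)$alt, "A")
})
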