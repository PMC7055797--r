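test_that("reference generation is seed-deterministic and CDS are clean ORFs", {
  r1 <- makeReference(10000, seed = 5, cds = TRUE)
  r2 <- makeReference(10000, seed = 5, cds = TRUE)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  r3 <- makeReference(10000, seed = 6)
  expect_false(identical(as.character(r1$seq), as.character(r3$seq)))

  # the embedded CDS translates start-to-stop without internal stops
  cds <- r1$cds
  s <- GenomicRanges::start(cds); e <- GenomicRanges::end(cds)
  orf <- Biostrings::subseq(r1$seq[[1]], s, e)
  aa <- as.character(Biostrings::translate(orf))
  expect_match(aa, "^M")
  expect_match(aa, "\\*$")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))

  expect_error(makeReference(500), "at least 1000")
})

test_that("simulated coverage matches the specified mean and copy structure", {
  sp <- syntheticSpec(1e5, 150, seed = 11)
  cov <- simulateCoverage(sp)
  expect_equal(mean(cov$track@depth), 150, tolerance = 0.02)
  expect_length(cov$truth, 0L)

  sp <- syntheticSpec(1e5, 150,
                      duplications = data.frame(start = 50000, end = 71000,
                                                copy = 2), seed = 11)
  cov <- simulateCoverage(sp)
  inBlock <- mean(cov$track@depth[50001:71000])
  outBlock <- mean(cov$track@depth[1:50000])
  expect_equal(inBlock / outBlock, 2, tolerance = 0.05)
  expect_equal(GenomicRanges::start(cov$truth), 50001)
  expect_equal(GenomicRanges::end(cov$truth), 71000)

  # dispersion 0 is the Poisson limit: variance ~ mean
  sp0 <- syntheticSpec(1e5, 150, dispersion = 0, seed = 12)
  d0 <- simulateCoverage(sp0)$track@depth
  expect_equal(var(d0) / mean(d0), 1, tolerance = 0.05)
  # default dispersion is clearly overdispersed
  spd <- syntheticSpec(1e5, 150, dispersion = 0.05, seed = 12)
  dd <- simulateCoverage(spd)$track@depth
  expect_gt(var(dd) / mean(dd), 5)
})

test_that("pileup alternate counts are binomial at the true fraction", {
  fractions <- vapply(1:500, function(i) {
    sp <- syntheticSpec(5000, 200,
                        divergentSites = data.frame(pos = 2500, alt = "T",
                                                    fraction = 0.5),
                        dispersion = 0, seed = i)
    tr <- simulatePileup(sp)$truth
    tr$altCount / tr$depth
  }, numeric(1))
  expect_lt(abs(mean(fractions) - 0.5), 0.01)

  # counts at every site sum to the drawn depth
  sp <- syntheticSpec(5000, 200,
                      divergentSites = data.frame(pos = 2500, alt = "+T",
                                                  fraction = 0.49),
                      seed = 3)
  pu <- simulatePileup(sp, positions = c(100, 900))
  agg <- tapply(pu$pileup$count, pu$pileup$pos, sum)
  expect_equal(unname(agg[["2500"]]), pu$truth$depth)
  expect_true(all(pu$pileup$count >= 0))

  # degenerate fractions are outside the generator's contract
  expect_error(syntheticSpec(5000, 200,
                             divergentSites = data.frame(
                               pos = 1, alt = "T", fraction = 0)),
               "fractions")
})

test_that("the packaged worked-case fixture is reproducible and calibrated", {
  f1 <- fig4cFixture(seed = 1)
  f2 <- fig4cFixture(seed = 1)
  expect_identical(f1$track@depth, f2$track@depth)
  expect_identical(f1$pileup, f2$pileup)
  expect_identical(as.character(f1$reference), as.character(f2$reference))

  expect_equal(f1$truthSites$fraction, 0.49)
  expect_equal(f1$truthSites$alt, "+T")
  # 21 kb duplication at copy 2
  expect_equal(GenomicRanges::width(f1$truthDups), 21000)
  # the divergent site's expected depth is 2 x 77.5 = 155x by calibration;
  # the empirical mean over seeds must sit within 3 standard errors of it
  expect_equal(f1$spec@meanDepth * 2, 155)
  depths <- vapply(1:15, function(s) fig4cFixture(seed = s)$truthSites$depth,
                   numeric(1))
  sdSite <- sqrt(155 + 0.05 * 155^2)
  expect_lt(abs(mean(depths) - 155), 3 * sdSite / sqrt(15))
  # the site lies inside the duplication and inside the annotated CDS
  expect_gte(f1$truthSites$pos, 50000)
  expect_lt(f1$truthSites$pos, 71000)
  expect_gte(f1$truthSites$pos, GenomicRanges::start(f1$cds) - 1)
  expect_lt(f1$truthSites$pos, GenomicRanges::end(f1$cds))
})

test_that("a generated bundle round-trips through the package readers", {
  fx <- fig4cFixture(seed = 2)
  dir <- withr::local_tempdir()
  writeSyntheticBundle(fx, dir, prefix = "fx")

  track <- readCoverage(file.path(dir, "fx.bedgraph"))
  expect_identical(track@depth, fx$track@depth)
  expect_identical(track@contig, fx$track@contig)

  pu <- readPileup(file.path(dir, "fx.pileup.tsv"))
  expect_equal(pu$count, fx$pileup$count)
  expect_equal(pu$allele, fx$pileup$allele)

  cds <- readAnnotationGFF3(file.path(dir, "fx.gff3"))
  expect_equal(GenomicRanges::start(cds), GenomicRanges::start(fx$cds))
  expect_equal(GenomicRanges::end(cds), GenomicRanges::end(fx$cds))

  ref <- Biostrings::readDNAStringSet(file.path(dir, "fx.fasta"))
  expect_identical(as.character(ref[[1]]), as.character(fx$reference[[1]]))
})
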