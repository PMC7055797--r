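test_that("mutation probability is the capped product of generations and rate", {
  expect_equal(mutationProbability(6.64, 1e-4), 6.64e-4)
  expect_identical(mutationProbability(1e9, 0), 0)
  expect_identical(mutationProbability(1e6, 1e-5), 1)   # capped at 1
  expect_error(mutationProbability(-1, 1e-4), "non-negative")
  expect_error(mutationProbability(1, 2), "\\[0, 1\\]")
})

test_that("single-cell Monte Carlo seeding follows the forced draws", {
  g <- c(WT = 6.64, DUP = 0, D1 = 0, D2 = 0)
  n <- c(WT = 1e8, DUP = 0, D1 = 0, D2 = 0)

  # all rates zero: never seeds, whatever the draws
  res <- sampleMutationEvents(g, n, defaultRates() * 0, u = rep(1e-9, 5))
  expect_true(all(res$seeds == 0))

  # x >= p: no event
  res <- sampleMutationEvents(g, n, defaultRates(), u = rep(0.999, 5))
  expect_true(all(res$seeds == 0))

  # x < p on WT>DUP: exactly one DUP cell
  res <- sampleMutationEvents(g, n, defaultRates(), u = rep(1e-5, 5))
  expect_equal(unname(res$seeds["DUP"]), 1)
  expect_equal(sum(res$seeds), 1)   # no parent for the other arrows
  # arrows without a living parent are not evaluated
  expect_true(is.na(res$events$p[res$events$arrow == "DUP>D1"]))
})

test_that("continuous bottleneck divides counts and refreshes the medium", {
  gp <- growthParams()
  st <- populationState(c(WT = 1.01e10), resource = 1e-4, g = c(WT = 6.6))
  out <- applyBottleneck(st, passageProtocol(), gp)
  expect_equal(sum(strainCounts(out)), 1.01e8)
  expect_equal(resourceLeft(out), gp@r0)
  expect_true(all(generationsGrown(out) == 0))
  expect_identical(strainCounts(out)[["D2"]], 0)
})

test_that("stochastic bottleneck thins binomially", {
  gp <- growthParams()
  proto <- passageProtocol(bottleneckMode = "stochastic")
  st <- populationState(c(WT = 1e6), resource = 1e-4)
  set.seed(99)
  draws <- replicate(1000, strainCounts(
    applyBottleneck(st, proto, gp))[["WT"]])
  se <- sqrt(1e6 * 0.01 * 0.99 / 1000)
  expect_lt(abs(mean(draws) - 1e4), 3 * se)
  # zero counts stay zero
  expect_identical(strainCounts(applyBottleneck(
    populationState(c(DUP = 1e4), resource = 0), proto, gp))[["WT"]], 0)
})

test_that("with all transition rates zero the population stays wild type", {
  sc <- newScenario(rates = defaultRates() * 0,
                    protocol = passageProtocol(targetGenerations = 50))
  tr <- runSerialPassages(sc, seed = 3)
  r <- records(tr)
  expect_true(all(r$DUP == 0 & r$D1 == 0 & r$D2 == 0))
  expect_true(all(r$WT > 0))
  expect_true(all(diff(r$generations) > 0))
  expect_identical(nrow(tr@events), 0L)
})

test_that("identical scenario and seed give bit-identical trajectories", {
  sc <- scenarioPreset("C")
  sc@protocol@targetGenerations <- 60
  t1 <- runSerialPassages(sc, seed = 17)
  t2 <- runSerialPassages(sc, seed = 17)
  expect_identical(records(t1), records(t2))
  t3 <- runSerialPassages(sc, seed = 18)
  expect_false(identical(records(t1), records(t3)))
})

test_that("every post-first passage ends at the conserved capacity", {
  sc <- scenarioPreset("F")
  sc@protocol@targetGenerations <- 80
  gp <- sc@growth
  r <- records(runSerialPassages(sc, seed = 2))
  totals <- rowSums(r[strainTypes()])
  capacity <- gp@r0 / gp@e
  expected <- c(1e6 + capacity,
                totals[-length(totals)] / 100 + capacity)
  expect_equal(totals, expected, tolerance = 1e-4)
})

test_that("outcomes are classified from the records", {
  # fixation at a known passage
  rec <- makeRecords(rbind(c(1e10, 0, 0, 0),
                           c(1e8, 1e8, 1e8, 9.9e9),
                           c(1e6, 1e6, 1e6, 1e10)))
  cls <- classifyOutcome(rec)
  expect_equal(cls$outcome, "fixed_d2")
  expect_equal(cls$fixationGeneration, rec$generations[3])

  # constructed crossing exactly at a record
  rec <- makeRecords(rbind(c(1e10, 0, 0, 0), c(2e8, 0, 0, 9.9e9)))
  expect_equal(classifyOutcome(rec, threshold = 0.98)$fixationGeneration,
               rec$generations[2])

  # all-WT constant trajectory is a steady state
  rec <- makeRecords(matrix(rep(c(1e10, 0, 0, 0), 20), ncol = 4,
                            byrow = TRUE))
  expect_equal(classifyOutcome(rec)$outcome, "steady_state")

  # duplication classes rise then vanish: segregated
  rec <- makeRecords(rbind(c(1e10, 0, 0, 0), c(9e9, 1e9, 0, 0),
                           c(5e9, 5e9, 0, 0), c(1e10, 0, 0, 0)))
  expect_equal(classifyOutcome(rec)$outcome, "segregated")

  # still drifting: incomplete
  rec <- makeRecords(rbind(c(9e9, 1e9, 0, 0), c(7e9, 3e9, 0, 0),
                           c(5e9, 5e9, 0, 0)))
  expect_equal(classifyOutcome(rec)$outcome, "incomplete")
})

test_that("replicate averaging is exact for deterministic runs", {
  sc <- newScenario(rates = defaultRates() * 0, replicates = 3, seed = 10,
                    protocol = passageProtocol(targetGenerations = 30))
  avg <- averageReplicates(sc)
  single <- records(runSerialPassages(sc, seed = 11))
  expect_equal(records(avg)$WT, single$WT)
  expect_equal(sum(avg@outcomeFractions), 1)
  expect_equal(unname(avg@outcomeFractions["steady_state"]), 1)
})

test_that("single-cell mode seeds one whole cell that grows a full cycle", {
  rates <- defaultRates() * 0
  rates["WT>DUP"] <- 1   # p = min(1, g) = 1: seeds every passage
  sc <- newScenario(rates = rates, mutationMode = "single",
                    protocol = passageProtocol(targetGenerations = 25))
  tr <- runSerialPassages(sc, seed = 4)
  ev <- tr@events
  expect_true(all(ev$cells == 1))
  expect_true(all(ev$arrow == "WT>DUP"))
  r <- records(tr)
  expect_identical(r$DUP[1], 0)   # seeded after the first record
  # the single seeded cell expands ~2^g by the end of the next cycle
  gDup <- log2(sum(r[2, strainTypes()]) / (sum(r[1, strainTypes()]) / 100))
  expect_equal(r$DUP[2], 2^gDup, tolerance = 0.05)
})

test_that("stronger duplication advantage means more duplication by gen 200", {
  meanDupFrac <- function(panel) {
    sc <- scenarioPreset(panel, replicates = 15, seed = 100)
    sc@protocol@targetGenerations <- 200
    avg <- records(averageReplicates(sc))
    last <- avg[nrow(avg), ]
    last$DUP / sum(last[strainTypes()])
  }
  fracs <- vapply(c("A", "B", "C"), meanDupFrac, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})
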