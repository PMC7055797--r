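# Serial-transfer protocol: mutant appearance, bottleneck dilution,
# full runs, replicate averaging and outcome classification.

#' Mutant-appearance probability
#'
#' `p = min(1, g * mu)`: the probability that a lineage of the parent strain
#' generates a derived cell over `g` generations of growth at
#' per-generation rate `mu`. The cap at 1 keeps the product a probability.
#'
#' @param g Generations of parent growth (>= 0); vectorized.
#' @param mu Per-generation transition rate in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @examples
#' mutationProbability(6.64, 1e-4)
#' @export
mutationProbability <- function(g, mu) {
  if (any(g < 0)) stop("generations of growth must be non-negative")
  if (any(mu < 0) || any(mu > 1)) stop("rate must lie in [0, 1]")
  pmin(1, g * mu)
}

#' Single-cell Monte Carlo mutation events
#'
#' The literal one-draw-per-arrow procedure: for each transition arrow
#' i -> j whose parent strain has a positive count, one uniform variate `x`
#' is drawn and a single cell of strain j is seeded if
#' `x < mutationProbability(g_i, mu_ij)`. Arrows are evaluated in the fixed
#' order given by [transitionArrows()] so seeded runs are reproducible.
#' Used by `mutationMode = "single"`; see the methods vignette for why the
#' per-cell mode is the package default.
#'
#' @param g Named per-strain generations grown in the most recent completed
#'   cycle.
#' @param counts Named per-strain parent counts (end of that cycle).
#' @param rates Named transition-rate vector.
#' @param u Optional numeric vector of uniforms, one per arrow in
#'   [transitionArrows()] order (for deterministic tests); defaults to fresh
#'   `runif` draws.
#' @return `list(seeds = <named count of cells to seed per strain>,
#'   events = <data.frame arrow/p/x/seeded>)`.
#' @examples
#' g <- c(WT = 6.64, DUP = 0, D1 = 0, D2 = 0)
#' n <- c(WT = 1e8, DUP = 0, D1 = 0, D2 = 0)
#' sampleMutationEvents(g, n, defaultRates(), u = rep(1e-5, 5))
#' @export
sampleMutationEvents <- function(g, counts, rates, u = NULL) {
  arr <- .arrowEnds()
  nA <- nrow(arr)
  if (is.null(u)) u <- stats::runif(nA)
  stopifnot(length(u) == nA)
  seeds <- stats::setNames(numeric(4L), strainTypes())
  p <- x <- numeric(nA)
  fired <- logical(nA)
  for (i in seq_len(nA)) {
    from <- arr$from[i]
    if (counts[[from]] > 0) {
      p[i] <- mutationProbability(g[[from]], rates[[arr$arrow[i]]])
      x[i] <- u[i]
      if (x[i] < p[i]) {
        seeds[arr$to[i]] <- seeds[arr$to[i]] + 1
        fired[i] <- TRUE
      }
    } else {
      p[i] <- NA_real_
      x[i] <- NA_real_
    }
  }
  list(seeds = seeds,
       events = data.frame(arrow = arr$arrow, p = p, x = x,
                           seeded = fired, stringsAsFactors = FALSE))
}

# Per-cell conversion (default mode): the appearance probability p = g*mu is
# applied to every cell of the parent strain over the completed cycle, and
# the number of converted cells is drawn Poisson(n_parent * p) (the
# binomial's Poisson approximation; p << 1 at the defaults), capped at the
# parent count. Converted cells move from parent to derived strain.
.sampleCellConversions <- function(g, counts, rates) {
  arr <- .arrowEnds()
  delta <- stats::setNames(numeric(4L), strainTypes())
  moved <- numeric(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    from <- arr$from[i]
    nFrom <- counts[[from]]
    if (nFrom > 0) {
      lambda <- nFrom * mutationProbability(g[[from]], rates[[arr$arrow[i]]])
      if (lambda > 0) {
        m <- if (lambda < 1e7) stats::rpois(1L, lambda)
             else round(stats::rnorm(1L, lambda, sqrt(lambda)))
        m <- min(max(m, 0), nFrom)
        if (m > 0) {
          delta[from] <- delta[from] - m
          delta[arr$to[i]] <- delta[arr$to[i]] + m
          moved[i] <- m
        }
      }
    }
  }
  list(delta = delta,
       events = data.frame(arrow = arr$arrow, cells = moved,
                           stringsAsFactors = FALSE))
}

#' Dilute an end-of-cycle culture into fresh medium
#'
#' Continuous mode divides every strain count by the dilution factor
#' (fractional cells permitted, the deterministic-ODE treatment);
#' stochastic mode draws transferred counts by binomial thinning with
#' probability `1/dilutionFactor` per strain. The resource is reset to `r0`
#' and the per-strain cycle generations to 0.
#'
#' @param state End-of-cycle [populationState()].
#' @param protocol A [passageProtocol()]; its `bottleneckMode` selects the
#'   dilution treatment unless overridden via `mode`.
#' @param growth A [growthParams()] supplying the fresh-medium resource.
#' @param mode Optional override of the protocol's bottleneck mode.
#' @return The diluted `PopulationState` with fresh resource.
#' @examples
#' st <- populationState(c(WT = 1.01e10), resource = 1e-4)
#' strainCounts(applyBottleneck(st, passageProtocol(), growthParams()))
#' @export
applyBottleneck <- function(state, protocol, growth,
                            mode = protocol@bottleneckMode) {
  stopifnot(is(state, "PopulationState"), is(protocol, "PassageProtocol"),
            is(growth, "GrowthParams"))
  f <- protocol@dilutionFactor
  n <- state@n
  if (mode == "continuous") {
    n <- n / f
  } else {
    p <- 1 / f
    n <- vapply(n, function(ni) {
      if (ni <= 0) return(0)
      if (ni <= 1e9) stats::rbinom(1L, round(ni), p)
      else max(0, round(stats::rnorm(1L, ni * p, sqrt(ni * p * (1 - p)))))
    }, numeric(1L))
  }
  new("PopulationState", n = n, resource = growth@r0, time = 0,
      g = stats::setNames(numeric(4L), strainTypes()))
}

#' Run one serial-passage trajectory
#'
#' Starts from the protocol's initial wild-type population in fresh medium
#' and repeats: grow to resource exhaustion ([integrateCycle()]),
#' accumulate generations as log2 of the total-population fold-expansion,
#' apply the mutation step for the completed cycle, record the passage, and
#' dilute ([applyBottleneck()]). In the default `"percell"` mode converted
#' cells move between strains at the end of the cycle they arose in; in
#' `"single"` mode a seeded cell joins the culture after the bottleneck so
#' its lineage grows one full cycle before first facing dilution. The run
#' stops once cumulative generations reach the protocol target.
#'
#' @param scenario A validated [newScenario()].
#' @param seed Integer seed; identical scenario and seed give bit-identical
#'   trajectories.
#' @param fixationThreshold Population fraction of `D2` that counts as
#'   fixation of the rearranged gene order. Default 0.99.
#' @return A `Trajectory`; see [records()], [outcome()],
#'   [fixationGeneration()].
#' @examples
#' sc <- newScenario(rates = defaultRates() * 0,
#'                   protocol = passageProtocol(targetGenerations = 30))
#' runSerialPassages(sc, seed = 7)
#' @export
runSerialPassages <- function(scenario, seed = scenario@seed,
                              fixationThreshold = 0.99) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  set.seed(as.integer(seed))
  growth <- scenario@growth
  proto <- scenario@protocol
  fitness <- scenario@fitness
  rates <- scenario@rates
  mode <- scenario@mutationMode

  state <- populationState(c(WT = proto@initialPopulation),
                           resource = growth@r0)
  target <- proto@targetGenerations
  maxPassages <- ceiling(target / log2(proto@dilutionFactor)) + 10L

  recs <- matrix(NA_real_, nrow = maxPassages, ncol = 6L,
                 dimnames = list(NULL, c("passage", "generations",
                                         strainTypes())))
  eventList <- vector("list", maxPassages)
  cumGen <- 0
  passage <- 0L
  repeat {
    passage <- passage + 1L
    startTotal <- sum(state@n)
    state <- tryCatch(
      integrateCycle(state, fitness, growth),
      error = function(e)
        stop(sprintf("integration failed at passage %d: %s", passage,
                     conditionMessage(e)), call. = FALSE))
    cumGen <- cumGen + log2(sum(state@n) / startTotal)

    pendingSeeds <- NULL
    if (mode == "percell") {
      conv <- .sampleCellConversions(state@g, state@n, rates)
      n2 <- pmax(state@n + conv$delta, 0)
      state <- new("PopulationState", n = n2, resource = state@resource,
                   time = state@time, g = state@g)
      ev <- conv$events[conv$events$cells > 0, , drop = FALSE]
    } else {
      mut <- sampleMutationEvents(state@g, state@n, rates)
      pendingSeeds <- mut$seeds
      ev <- mut$events[!is.na(mut$events$seeded) & mut$events$seeded, ,
                       drop = FALSE]
      if (nrow(ev)) ev <- data.frame(arrow = ev$arrow, cells = 1)
      else ev <- data.frame(arrow = character(), cells = numeric())
    }
    if (nrow(ev)) eventList[[passage]] <- cbind(passage = passage, ev)

    recs[passage, ] <- c(passage, cumGen, state@n)
    if (cumGen >= target || passage >= maxPassages) break

    state <- applyBottleneck(state, proto, growth)
    if (!is.null(pendingSeeds) && any(pendingSeeds > 0)) {
      state <- new("PopulationState", n = state@n + pendingSeeds,
                   resource = state@resource, time = 0, g = state@g)
    }
  }

  rec <- as.data.frame(recs[seq_len(passage), , drop = FALSE])
  events <- do.call(rbind, eventList[!vapply(eventList, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(passage = integer(), arrow = character(),
                         cells = numeric())
  cls <- classifyOutcome(rec, threshold = fixationThreshold)
  out <- if (rec$generations[nrow(rec)] < target) "incomplete" else cls$outcome
  new("Trajectory", records = rec, outcome = out,
      fixationGeneration = cls$fixationGeneration,
      seed = as.numeric(seed), events = events)
}

#' Classify the outcome of a trajectory
#'
#' `fixed_d2` if the `D2` fraction of the population reaches `threshold` at
#' any record (the first crossing sets the fixation generation);
#' `segregated` if the duplication-carrying classes (`DUP + D1 + D2`) fall
#' to exactly 0 after having been positive; `steady_state` if over the last
#' 10% of records every strain fraction changes by less than 1e-3;
#' otherwise `incomplete`.
#'
#' @param x A `Trajectory` or its [records()] data.frame.
#' @param threshold Fixation fraction. Default 0.99.
#' @return `list(outcome = <label>, fixationGeneration = <generations at
#'   first crossing, or NA>)`.
#' @examples
#' rec <- data.frame(passage = 1:3, generations = c(7, 13, 20),
#'                   WT = c(1e8, 1e6, 1e4), DUP = 0, D1 = 0,
#'                   D2 = c(0, 1e8, 1e10))
#' classifyOutcome(rec)
#' @export
classifyOutcome <- function(x, threshold = 0.99) {
  rec <- if (is(x, "Trajectory")) x@records else x
  stopifnot(nrow(rec) >= 1L)
  counts <- as.matrix(rec[strainTypes()])
  totals <- rowSums(counts)
  frac <- counts / totals

  hit <- which(frac[, "D2"] >= threshold)
  if (length(hit))
    return(list(outcome = "fixed_d2",
                fixationGeneration = rec$generations[hit[1L]]))

  mutant <- rowSums(counts[, c("DUP", "D1", "D2"), drop = FALSE])
  if (any(mutant > 0) && mutant[length(mutant)] == 0)
    return(list(outcome = "segregated", fixationGeneration = NA_real_))

  tailN <- max(2L, ceiling(nrow(rec) * 0.1))
  if (nrow(rec) >= tailN) {
    tailFrac <- frac[seq(nrow(rec) - tailN + 1L, nrow(rec)), , drop = FALSE]
    drift <- apply(tailFrac, 2L, function(col) diff(range(col)))
    if (all(drift < 1e-3))
      return(list(outcome = "steady_state", fixationGeneration = NA_real_))
  }
  list(outcome = "incomplete", fixationGeneration = NA_real_)
}

#' Average independent replicate runs
#'
#' Runs `replicates(scenario)` independent trajectories with seeds
#' `scenario seed + i` (one independent stream each) and returns the
#' pointwise arithmetic mean of strain counts per passage together with the
#' fraction of replicates in each outcome class and the per-replicate
#' fixation generations. Runs are averaged over the passages all replicates
#' share (replicate lengths can differ by one passage in stochastic
#' bottleneck mode).
#'
#' @param scenario A [newScenario()].
#' @param fixationThreshold Passed to [runSerialPassages()].
#' @return A `ReplicateSummary`.
#' @examples
#' sc <- newScenario(replicates = 3, seed = 1,
#'                   protocol = passageProtocol(targetGenerations = 30))
#' averageReplicates(sc)
#' @export
averageReplicates <- function(scenario, fixationThreshold = 0.99) {
  stopifnot(is(scenario, "Scenario"))
  reps <- as.integer(scenario@replicates)
  runs <- lapply(seq_len(reps), function(i)
    runSerialPassages(scenario, seed = scenario@seed + i,
                      fixationThreshold = fixationThreshold))
  nP <- min(vapply(runs, function(tr) nrow(tr@records), integer(1L)))
  cols <- c("generations", strainTypes())
  acc <- matrix(0, nrow = nP, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (tr in runs)
    acc <- acc + as.matrix(tr@records[seq_len(nP), cols])
  avg <- cbind(passage = seq_len(nP), as.data.frame(acc / reps))

  outcomes <- vapply(runs, function(tr) tr@outcome, character(1L))
  lev <- c("fixed_d2", "steady_state", "segregated", "incomplete")
  fracs <- vapply(lev, function(l) mean(outcomes == l), numeric(1L))
  fix <- vapply(runs, function(tr) tr@fixationGeneration, numeric(1L))
  new("ReplicateSummary", records = avg, outcomeFractions = fracs,
      fixationGenerations = fix, replicates = as.numeric(reps),
      seed = scenario@seed)
}

#' Fitness-scenario presets
#'
#' Six fitness schemes spanning the modelled selective conditions. In
#' panels A-C the duplicated classes (`DUP`, `D1`, `D2`) share one fitness
#' relative to the wild type: equal (A), a 5% advantage (B), or a 25%
#' advantage (C). Panels D-F keep the 25% duplication advantage and add a
#' further advantage for the double-inactivated class -- deleting the
#' unnecessary duplicate genes -- of 2% (D), 5% (E) or 10% (F), composed
#' multiplicatively: `v_D2 = 1.25 * (1 + s)`. The single-inactivated class
#' is assigned the duplication fitness (its own value is a model
#' assumption). All presets use the default rates, growth parameters and
#' protocol.
#'
#' @param panel One of `"A"`..`"F"`.
#' @param replicates Replicate count for the preset. Default 100.
#' @param seed Base seed.
#' @param mutationMode Passed to [newScenario()].
#' @return A `Scenario`.
#' @examples
#' fitnessScheme(scenarioPreset("C"))
#' @export
scenarioPreset <- function(panel, replicates = 100, seed = 1,
                           mutationMode = c("percell", "single")) {
  panel <- toupper(as.character(panel))
  dupAdv <- switch(panel, A = 1.0, B = 1.05, C = 1.25,
                   D = 1.25, E = 1.25, F = 1.25,
                   stop("unknown panel label: ", panel))
  d2Extra <- switch(panel, D = 0.02, E = 0.05, F = 0.10, 0)
  fitness <- c(WT = 1, DUP = dupAdv, D1 = dupAdv,
               D2 = dupAdv * (1 + d2Extra))
  newScenario(fitness = fitness, rates = defaultRates(),
              growth = growthParams(), protocol = passageProtocol(),
              replicates = replicates, seed = seed,
              mutationMode = match.arg(mutationMode))
}
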