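#' @import methods
NULL

#' Strain labels of the four-state duplication model
#'
#' The model follows four cell types: wild-type (`WT`), cells carrying a
#' chromosomal duplication that spans two essential genes (`DUP`), and
#' duplication carriers with one (`D1`) or two different (`D2`) essential
#' genes inactivated across the two copies. `D2` is terminal: once a
#' different essential gene is lost from each copy the duplication can no
#' longer segregate, which fixes the rearranged gene order.
#'
#' @return Character vector of the four strain labels, in model order.
#' @examples
#' strainTypes()
#' @export
strainTypes <- function() c("WT", "DUP", "D1", "D2")

#' Transition arrows of the strain model
#'
#' The five permitted transitions: duplication formation (`WT>DUP`),
#' segregation back to wild type (`DUP>WT`), first essential-gene
#' inactivation (`DUP>D1`), segregation of a single-inactivated duplication
#' retaining the intact copy (`D1>WT`), and the second, reciprocal
#' inactivation (`D1>D2`). `D2` has no outgoing arrows.
#'
#' @return Character vector of arrow names, in the fixed evaluation order.
#' @examples
#' transitionArrows()
#' @export
transitionArrows <- function() c("WT>DUP", "DUP>WT", "DUP>D1", "D1>WT", "D1>D2")

.arrowEnds <- function() {
  a <- strsplit(transitionArrows(), ">", fixed = TRUE)
  data.frame(
    arrow = transitionArrows(),
    from = vapply(a, `[`, "", 1L),
    to = vapply(a, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Growth parameters

#' @rdname growthParams
#' @export
setClass("GrowthParams", representation(
  r0 = "numeric",
  k = "numeric",
  e = "numeric",
  exhaustionFraction = "numeric",
  maxTime = "numeric"
))

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (length(object@r0) != 1L || !is.finite(object@r0) || object@r0 <= 0)
    msg <- c(msg, "r0 must be a single positive number")
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "k must be a single positive number")
  if (length(object@e) != 1L || !is.finite(object@e) || object@e <= 0)
    msg <- c(msg, "e must be a single positive number")
  if (length(object@exhaustionFraction) != 1L ||
      object@exhaustionFraction <= 0 || object@exhaustionFraction >= 1)
    msg <- c(msg, "exhaustionFraction must lie strictly between 0 and 1")
  if (length(object@maxTime) != 1L || object@maxTime <= 0)
    msg <- c(msg, "maxTime must be positive")
  if (length(msg)) msg else TRUE
})

#' Batch-growth parameters
#'
#' Parameters of one resource-limited growth cycle. `r0` is the initial
#' amount of the limiting resource and `k` the half-saturation constant of
#' the Monod rate (same resource units). `e` is the conversion efficiency:
#' resource consumed per cell produced, so `r0 / e` is the batch carrying
#' capacity. The default `e = 1e-8` calibrates the capacity to 1e10 cells,
#' the end-of-cycle population size the model is built around. A cycle ends
#' when the remaining resource falls below `exhaustionFraction * r0`
#' (the Monod rate never reaches zero in finite time); `maxTime` guards the
#' integrator against non-convergence.
#'
#' @param r0 Initial resource (resource units). Default 100.
#' @param k Half-saturation constant (resource units). Default 1.
#' @param e Resource consumed per cell produced. Default 1e-8.
#' @param exhaustionFraction Stop threshold as a fraction of `r0`.
#' @param maxTime Integration horizon (arbitrary time units).
#' @return A `GrowthParams` object.
#' @examples
#' gp <- growthParams()
#' gp@r0 / gp@e   # batch carrying capacity: 1e10 cells
#' @export
growthParams <- function(r0 = 100, k = 1, e = 1e-8,
                         exhaustionFraction = 1e-6, maxTime = 1000) {
  new("GrowthParams", r0 = as.numeric(r0), k = as.numeric(k),
      e = as.numeric(e), exhaustionFraction = as.numeric(exhaustionFraction),
      maxTime = as.numeric(maxTime))
}

# ---------------------------------------------------------------------------
# Passage protocol

#' @rdname passageProtocol
#' @export
setClass("PassageProtocol", representation(
  dilutionFactor = "numeric",
  bottleneckSize = "numeric",
  initialPopulation = "numeric",
  targetGenerations = "numeric",
  bottleneckMode = "character"
))

setValidity("PassageProtocol", function(object) {
  msg <- character()
  if (object@dilutionFactor <= 1)
    msg <- c(msg, "dilutionFactor must exceed 1")
  if (object@bottleneckSize <= 0)
    msg <- c(msg, "bottleneckSize must be positive")
  if (object@initialPopulation <= 0)
    msg <- c(msg, "initialPopulation must be positive")
  if (object@targetGenerations <= 0)
    msg <- c(msg, "targetGenerations must be positive")
  if (!object@bottleneckMode %in% c("continuous", "stochastic"))
    msg <- c(msg, "bottleneckMode must be 'continuous' or 'stochastic'")
  if (length(msg)) msg else TRUE
})

#' Serial-transfer protocol
#'
#' Defaults follow the modelled regime: cultures grown to a total of 1e10
#' cells are diluted 100-fold into fresh medium (1e8 cells per bottleneck),
#' starting from 1e6 wild-type cells, until 1000 cumulative generations of
#' growth. In `"continuous"` mode the bottleneck divides every strain count
#' by `dilutionFactor` (fractional cells permitted, matching a deterministic
#' ODE treatment); `"stochastic"` mode draws transferred counts by binomial
#' thinning with probability `1/dilutionFactor`.
#'
#' @param dilutionFactor Fold-dilution at each transfer. Default 100.
#' @param bottleneckSize Nominal cells transferred per bottleneck (recorded
#'   in summaries; the dilution itself is governed by `dilutionFactor`).
#' @param initialPopulation Starting wild-type cells. Default 1e6.
#' @param targetGenerations Cumulative generations to simulate. Default 1000.
#' @param bottleneckMode `"continuous"` (default) or `"stochastic"`.
#' @return A `PassageProtocol` object.
#' @examples
#' passageProtocol()
#' @export
passageProtocol <- function(dilutionFactor = 100, bottleneckSize = 1e8,
                            initialPopulation = 1e6,
                            targetGenerations = 1000,
                            bottleneckMode = c("continuous", "stochastic")) {
  new("PassageProtocol",
      dilutionFactor = as.numeric(dilutionFactor),
      bottleneckSize = as.numeric(bottleneckSize),
      initialPopulation = as.numeric(initialPopulation),
      targetGenerations = as.numeric(targetGenerations),
      bottleneckMode = match.arg(bottleneckMode))
}

# ---------------------------------------------------------------------------
# Population state

#' @rdname populationState
#' @export
setClass("PopulationState", representation(
  n = "numeric",
  resource = "numeric",
  time = "numeric",
  g = "numeric"
))

setValidity("PopulationState", function(object) {
  msg <- character()
  st <- strainTypes()
  if (!identical(names(object@n), st))
    msg <- c(msg, "counts must be named WT, DUP, D1, D2 in order")
  if (any(!is.finite(object@n)) || any(object@n < 0))
    msg <- c(msg, "all strain counts must be finite and non-negative")
  if (object@resource < 0)
    msg <- c(msg, "resource must be non-negative")
  if (!identical(names(object@g), st) || any(object@g < 0))
    msg <- c(msg, "g must be named per strain and non-negative")
  if (length(msg)) msg else TRUE
})

#' Within-cycle population state
#'
#' Absolute cell counts per strain, the remaining limiting resource, elapsed
#' within-cycle time, and per-strain generations grown this cycle (log2
#' fold-expansion). Counts are absolute cells rather than per-mL densities:
#' the protocol is specified entirely in absolute sizes (1e6 start, 1e10
#' capacity, 1e8 bottleneck) and no culture volume enters the model.
#'
#' @param n Named numeric counts; missing strains default to 0. A single
#'   unnamed number is taken as the wild-type count.
#' @param resource Remaining resource (resource units).
#' @param time Elapsed within-cycle time.
#' @param g Named per-strain generations grown this cycle; defaults to 0.
#' @return A `PopulationState` object.
#' @examples
#' populationState(c(WT = 1e6), resource = 100)
#' @export
populationState <- function(n, resource, time = 0, g = NULL) {
  st <- strainTypes()
  full <- stats::setNames(numeric(4L), st)
  if (is.null(names(n))) {
    if (length(n) == 1L) names(n) <- "WT"
    else if (length(n) == 4L) names(n) <- st
    else stop("'n' must be named by strain type")
  }
  bad <- setdiff(names(n), st)
  if (length(bad)) stop("unknown strain type(s): ", paste(bad, collapse = ", "))
  full[names(n)] <- n
  gf <- stats::setNames(numeric(4L), st)
  if (!is.null(g)) gf[names(g)] <- g
  new("PopulationState", n = full, resource = as.numeric(resource),
      time = as.numeric(time), g = gf)
}

setMethod("show", "PopulationState", function(object) {
  cat("PopulationState:",
      paste(sprintf("%s=%.4g", names(object@n), object@n), collapse = " "),
      sprintf("| resource=%.4g time=%.4g\n",
              object@resource, object@time))
})

# ---------------------------------------------------------------------------
# Scenario

#' @rdname newScenario
#' @export
setClass("Scenario", representation(
  fitness = "numeric",
  rates = "numeric",
  growth = "GrowthParams",
  protocol = "PassageProtocol",
  replicates = "numeric",
  seed = "numeric",
  mutationMode = "character"
))

setValidity("Scenario", function(object) {
  msg <- character()
  v <- tryCatch({
    validateScheme(object@fitness, object@rates)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(v)) msg <- c(msg, v)
  if (length(object@replicates) != 1L || object@replicates < 1)
    msg <- c(msg, "replicates must be >= 1")
  if (!object@mutationMode %in% c("percell", "single"))
    msg <- c(msg, "mutationMode must be 'percell' or 'single'")
  if (length(msg)) msg else TRUE
})

#' Simulation scenario
#'
#' Bundles a fitness scheme, transition rates, growth parameters, passage
#' protocol, replicate plan and seed. `mutationMode` selects how the
#' mutant-appearance probability `p = g * mu` is applied each passage:
#' `"percell"` (default) applies it to every cell of the parent strain
#' (Poisson-approximated binomial conversion at the end of the cycle), while
#' `"single"` performs the literal one-draw-per-arrow Monte Carlo in which a
#' single cell of the derived strain is seeded when `x < p` (see the methods
#' vignette for why per-cell conversion is the default).
#'
#' @param fitness Named relative-fitness vector, see [defaultFitness()].
#' @param rates Named transition-rate vector, see [defaultRates()].
#' @param growth A [growthParams()] object.
#' @param protocol A [passageProtocol()] object.
#' @param replicates Number of independent replicate runs. Default 100.
#' @param seed Base seed; replicate i runs with `seed + i`.
#' @param mutationMode `"percell"` or `"single"`.
#' @return A validated `Scenario`.
#' @examples
#' sc <- newScenario(replicates = 5, seed = 42)
#' @export
newScenario <- function(fitness = defaultFitness(), rates = defaultRates(),
                        growth = growthParams(),
                        protocol = passageProtocol(),
                        replicates = 100, seed = 1,
                        mutationMode = c("percell", "single")) {
  new("Scenario", fitness = fitness, rates = rates, growth = growth,
      protocol = protocol, replicates = as.numeric(replicates),
      seed = as.numeric(seed), mutationMode = match.arg(mutationMode))
}

setMethod("show", "Scenario", function(object) {
  cat("Scenario (", object@mutationMode, " mutation mode)\n", sep = "")
  cat("  fitness:", paste(sprintf("%s=%.3g", names(object@fitness),
                                  object@fitness), collapse = " "), "\n")
  cat("  rates:  ", paste(sprintf("%s=%.1e", names(object@rates),
                                  object@rates), collapse = " "), "\n")
  cat(sprintf("  capacity %.3g cells, %g-fold bottleneck, %g generations, %d replicate(s), seed %d\n",
              object@growth@r0 / object@growth@e,
              object@protocol@dilutionFactor,
              object@protocol@targetGenerations,
              as.integer(object@replicates), as.integer(object@seed)))
})

# ---------------------------------------------------------------------------
# Trajectory

#' @rdname runSerialPassages
#' @export
setClass("Trajectory", representation(
  records = "data.frame",
  outcome = "character",
  fixationGeneration = "numeric",
  seed = "numeric",
  events = "data.frame"
))

setValidity("Trajectory", function(object) {
  msg <- character()
  need <- c("passage", "generations", strainTypes())
  if (!all(need %in% names(object@records)))
    msg <- c(msg, "records must have columns passage, generations, WT, DUP, D1, D2")
  else {
    if (is.unsorted(object@records$generations, strictly = TRUE))
      msg <- c(msg, "cumulative generations must be strictly increasing")
    if (any(as.matrix(object@records[strainTypes()]) < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (!object@outcome %in% c("fixed_d2", "steady_state", "segregated", "incomplete"))
    msg <- c(msg, "unknown outcome label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  r <- object@records
  cat(sprintf("Trajectory: %d passages, %.1f generations, outcome '%s'",
              nrow(r), r$generations[nrow(r)], object@outcome))
  if (!is.na(object@fixationGeneration))
    cat(sprintf(" (fixation at generation %.1f)", object@fixationGeneration))
  cat("\n")
  last <- r[nrow(r), strainTypes()]
  cat("  final counts:",
      paste(sprintf("%s=%.4g", strainTypes(), as.numeric(last)),
            collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# Replicate summary

#' @rdname averageReplicates
#' @export
setClass("ReplicateSummary", representation(
  records = "data.frame",
  outcomeFractions = "numeric",
  fixationGenerations = "numeric",
  replicates = "numeric",
  seed = "numeric"
))

setMethod("show", "ReplicateSummary", function(object) {
  cat(sprintf("ReplicateSummary over %d run(s), base seed %d\n",
              as.integer(object@replicates), as.integer(object@seed)))
  f <- object@outcomeFractions
  cat("  outcomes:", paste(sprintf("%s=%.2f", names(f), f), collapse = " "),
      "\n")
  fx <- object@fixationGenerations
  if (any(!is.na(fx)))
    cat(sprintf("  mean fixation generation (fixed runs): %.1f\n",
                mean(fx, na.rm = TRUE)))
})

# ---------------------------------------------------------------------------
# Coverage track

#' @rdname coverageTrack
#' @export
setClass("CoverageTrack", representation(
  contig = "character",
  depth = "numeric"
))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@contig) != 1L || !nzchar(object@contig))
    msg <- c(msg, "contig must be a single non-empty name")
  if (length(object@depth) < 1L)
    msg <- c(msg, "depth array must be non-empty")
  if (any(object@depth < 0) || any(!is.finite(object@depth)))
    msg <- c(msg, "depth must be finite and non-negative at every position")
  if (length(msg)) msg else TRUE
})

#' Per-base coverage track
#'
#' Aligned read depth at every position of one contig. Coordinates are
#' 0-based half-open throughout the scanner: `depth[i]` (R index `i`) is the
#' depth at genomic position `i - 1`.
#'
#' @param contig Contig name.
#' @param depth Non-negative per-base depth vector.
#' @return A `CoverageTrack` object.
#' @examples
#' coverageTrack("chr", rep(150, 2000))
#' @export
coverageTrack <- function(contig, depth) {
  new("CoverageTrack", contig = as.character(contig),
      depth = as.numeric(depth))
}

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack '%s': %d bp, mean depth %.1f\n",
              object@contig, length(object@depth), mean(object@depth)))
})

setMethod("length", "CoverageTrack", function(x) length(x@depth))

# ---------------------------------------------------------------------------
# Synthetic data specification

#' @rdname syntheticSpec
#' @export
setClass("SyntheticSpec", representation(
  contig = "character",
  contigLength = "numeric",
  meanDepth = "numeric",
  dispersion = "numeric",
  duplications = "data.frame",
  divergentSites = "data.frame",
  seed = "numeric"
))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  L <- object@contigLength
  if (L < 1L) msg <- c(msg, "contigLength must be positive")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  d <- object@duplications
  if (nrow(d)) {
    if (any(d$start < 0) || any(d$end > L) || any(d$end <= d$start))
      msg <- c(msg, "duplication intervals must lie within the contig")
    if (any(d$copy < 2)) msg <- c(msg, "duplication copy number must be >= 2")
    o <- order(d$start)
    if (nrow(d) > 1L && any(d$start[o][-1L] < d$end[o][-nrow(d)]))
      msg <- c(msg, "duplication intervals must not overlap")
  }
  s <- object@divergentSites
  if (nrow(s)) {
    if (any(s$fraction <= 0) || any(s$fraction >= 1))
      msg <- c(msg, "divergent-site fractions must lie in (0, 1)")
    if (any(s$pos < 0) || any(s$pos >= L))
      msg <- c(msg, "divergent-site positions must lie within the contig")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic sequencing-signal specification
#'
#' Describes the signal the generator emulates: per-base depth with
#' overdispersed (negative-binomial) noise around `meanDepth`, duplicated
#' intervals at `copy` times the baseline, and single divergent sites inside
#' duplications observed at an intermediate alternate-allele fraction.
#'
#' @param contigLength Contig length in bp.
#' @param meanDepth Genome-wide mean depth at copy number 1.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); `0` gives Poisson depth. Default 0.05.
#' @param duplications `data.frame(start, end, copy)`, 0-based half-open.
#' @param divergentSites `data.frame(pos, alt, fraction)`; `alt` is a base,
#'   or an insertion/deletion allele written `"+SEQ"`/`"-SEQ"`.
#' @param seed Generator seed.
#' @param contig Contig name.
#' @return A validated `SyntheticSpec`.
#' @examples
#' syntheticSpec(1e5, 150, duplications = data.frame(
#'   start = 20000, end = 40000, copy = 2))
#' @export
syntheticSpec <- function(contigLength, meanDepth, dispersion = 0.05,
                          duplications = NULL, divergentSites = NULL,
                          seed = 1, contig = "contig_1") {
  if (is.null(duplications))
    duplications <- data.frame(start = numeric(), end = numeric(),
                               copy = numeric())
  if (is.null(divergentSites))
    divergentSites <- data.frame(pos = numeric(), alt = character(),
                                 fraction = numeric())
  new("SyntheticSpec", contig = as.character(contig),
      contigLength = as.numeric(contigLength),
      meanDepth = as.numeric(meanDepth),
      dispersion = as.numeric(dispersion),
      duplications = duplications, divergentSites = divergentSites,
      seed = as.numeric(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec '%s': %g bp, mean depth %g, dispersion %g, %d duplication(s), %d divergent site(s), seed %d\n",
              object@contig, object@contigLength, object@meanDepth,
              object@dispersion, nrow(object@duplications),
              nrow(object@divergentSites), as.integer(object@seed)))
})
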