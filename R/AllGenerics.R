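# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' Per-passage records of a trajectory or replicate summary
#'
#' @param x A `Trajectory` or `ReplicateSummary`.
#' @return A data.frame with columns `passage`, `generations`, `WT`, `DUP`,
#'   `D1`, `D2` (mean counts for a `ReplicateSummary`).
#' @examples
#' sc <- newScenario(rates = defaultRates() * 0,
#'                   protocol = passageProtocol(targetGenerations = 20))
#' records(runSerialPassages(sc, seed = 1))
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "Trajectory", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "ReplicateSummary", function(x) x@records)

#' Outcome label of a trajectory
#'
#' @param x A `Trajectory`.
#' @return One of `"fixed_d2"`, `"steady_state"`, `"segregated"`,
#'   `"incomplete"`.
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname outcome
#' @export
setMethod("outcome", "Trajectory", function(x) x@outcome)

#' Generation at which the double-inactivated class first crossed the
#' fixation threshold
#'
#' @param x A `Trajectory`.
#' @return Cumulative generations at the first threshold crossing, or `NA`.
#' @export
setGeneric("fixationGeneration",
           function(x) standardGeneric("fixationGeneration"))

#' @rdname fixationGeneration
#' @export
setMethod("fixationGeneration", "Trajectory", function(x) x@fixationGeneration)

#' Fitness scheme of a scenario
#'
#' @param x A `Scenario`.
#' @return Named relative-fitness vector.
#' @export
setGeneric("fitnessScheme", function(x) standardGeneric("fitnessScheme"))

#' @rdname fitnessScheme
#' @export
setMethod("fitnessScheme", "Scenario", function(x) x@fitness)

#' Transition rates of a scenario
#'
#' @param x A `Scenario`.
#' @return Named per-generation rate vector.
#' @export
setGeneric("transitionRates", function(x) standardGeneric("transitionRates"))

#' @rdname transitionRates
#' @export
setMethod("transitionRates", "Scenario", function(x) x@rates)

#' Strain counts of a population state
#'
#' @param x A `PopulationState`.
#' @return Named numeric vector of absolute cell counts.
#' @export
setGeneric("strainCounts", function(x) standardGeneric("strainCounts"))

#' @rdname strainCounts
#' @export
setMethod("strainCounts", "PopulationState", function(x) x@n)

#' Remaining resource of a population state
#'
#' @param x A `PopulationState`.
#' @return Remaining limiting resource (resource units).
#' @export
setGeneric("resourceLeft", function(x) standardGeneric("resourceLeft"))

#' @rdname resourceLeft
#' @export
setMethod("resourceLeft", "PopulationState", function(x) x@resource)

#' Per-strain generations grown in the current cycle
#'
#' @param x A `PopulationState`.
#' @return Named numeric vector of log2 fold-expansions.
#' @export
setGeneric("generationsGrown", function(x) standardGeneric("generationsGrown"))

#' @rdname generationsGrown
#' @export
setMethod("generationsGrown", "PopulationState", function(x) x@g)
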