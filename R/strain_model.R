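# Parameterization of the four-strain model: default fitness and transition
# rates, and the validation shared by every Scenario.

#' Default transition rates
#'
#' Per-generation rates for the five arrows of the model. Spontaneous
#' duplication of chromosomal segments occurs at rates between roughly 1e-2
#' and 1e-5 per generation depending on the flanking repeats; gene-inactivating
#' mutations (frameshift, nonsense, deletion) occur at 1e-5 to 1e-6 per gene
#' per generation. The package defaults sit inside those experimentally
#' anchored ranges: duplication formation 1e-4, segregation 1e-2, each
#' essential-gene inactivation 1e-5. Segregation of a single-inactivated
#' duplication is halved (5e-3) because only the segregant retaining the
#' intact gene copy is viable. Arrows out of `D2` do not exist: reciprocal
#' inactivation stabilizes the duplication.
#'
#' @return Named numeric vector over [transitionArrows()].
#' @examples
#' defaultRates()
#' @export
defaultRates <- function() {
  c("WT>DUP" = 1e-4, "DUP>WT" = 1e-2, "DUP>D1" = 1e-5,
    "D1>WT" = 5e-3, "D1>D2" = 1e-5)
}

#' Default fitness scheme
#'
#' Relative fitness per strain with the wild type as reference (`WT = 1`).
#' All strains start neutral; scenario presets override the duplicated
#' classes.
#'
#' @return Named numeric vector over [strainTypes()].
#' @examples
#' defaultFitness()
#' @export
defaultFitness <- function() {
  stats::setNames(rep(1, 4L), strainTypes())
}

#' Validate a fitness scheme and transition-rate set
#'
#' Rejects non-positive fitness values, a wild-type fitness different from 1
#' (the reference convention), rates outside \[0, 1\], rates on undefined
#' arrows, and in particular any nonzero arrow out of the terminal `D2`
#' class. Error messages name the offending field.
#'
#' @param fitness Named fitness vector over [strainTypes()].
#' @param rates Named rate vector; names must be a subset of
#'   [transitionArrows()] (missing arrows are treated as rate 0).
#' @return Invisibly, `list(fitness, rates)` with `rates` completed to the
#'   full arrow set.
#' @examples
#' validateScheme(defaultFitness(), defaultRates())
#' @export
validateScheme <- function(fitness, rates) {
  st <- strainTypes()
  if (!all(st %in% names(fitness)))
    stop("fitness must provide a value for each of: ",
         paste(st, collapse = ", "))
  fitness <- fitness[st]
  bad <- names(fitness)[!is.finite(fitness) | fitness <= 0]
  if (length(bad))
    stop("fitness must be positive; offending strain(s): ",
         paste(bad, collapse = ", "))
  if (fitness[["WT"]] != 1)
    stop("fitness of WT must be 1 (wild type is the reference)")

  arrows <- transitionArrows()
  extra <- setdiff(names(rates), arrows)
  if (length(extra)) {
    fromD2 <- grepl("^D2>", extra)
    if (any(rates[extra] != 0))
      stop(if (any(fromD2 & rates[extra] != 0))
             "D2 is terminal; no outgoing transition is allowed: "
           else "rate given for an undefined transition arrow: ",
           paste(extra[rates[extra] != 0], collapse = ", "))
    rates <- rates[setdiff(names(rates), extra)]
  }
  full <- stats::setNames(numeric(length(arrows)), arrows)
  full[names(rates)] <- rates
  bad <- names(full)[!is.finite(full) | full < 0 | full > 1]
  if (length(bad))
    stop("transition rates must lie in [0, 1]; offending arrow(s): ",
         paste(bad, collapse = ", "))
  invisible(list(fitness = fitness, rates = full))
}
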