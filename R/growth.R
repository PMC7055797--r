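# One batch-growth cycle under Monod kinetics with a shared limiting
# resource. The coupled system is
#   dn_i/dt = n_i * psi_i(R),   psi_i(R) = v_i * R / (R + k)
#   dR/dt   = -e * sum_i n_i * psi_i(R)
# which conserves  sum(n) + R/e  along the solution.

#' Monod per-capita growth rate
#'
#' `psi(R) = v * R / (R + k)`: saturating in the limiting resource, with
#' maximum `v` (the strain's relative fitness) and half-maximum at `R = k`.
#'
#' @param r Resource concentration (>= 0); vectorized.
#' @param v Relative fitness (maximum rate), > 0.
#' @param k Half-saturation constant, > 0.
#' @return Per-capita growth rate(s) in `[0, v]`.
#' @examples
#' monodRate(1, 1, 1)    # half-maximum: 0.5
#' monodRate(99, 1, 1)   # 0.99
#' @export
monodRate <- function(r, v, k) {
  if (any(r < 0)) stop("resource concentration must be non-negative")
  if (any(v <= 0)) stop("fitness must be positive")
  if (any(k <= 0)) stop("half-saturation constant must be positive")
  v * r / (r + k)
}

#' Time derivatives of the batch-growth system
#'
#' @param state A [populationState()].
#' @param fitness Named fitness vector over [strainTypes()].
#' @param params A [growthParams()] object.
#' @return `list(dn = <named per-strain derivative>, dR = <resource
#'   derivative>)`.
#' @examples
#' st <- populationState(c(WT = 1e8), resource = 100)
#' strainDerivatives(st, defaultFitness(), growthParams())
#' @export
strainDerivatives <- function(state, fitness, params) {
  stopifnot(is(state, "PopulationState"), is(params, "GrowthParams"))
  v <- fitness[strainTypes()]
  psi <- monodRate(state@resource, v, params@k)
  dn <- state@n * psi
  list(dn = dn, dR = -sum(dn) * params@e)
}

#' Integrate one growth cycle to resource exhaustion
#'
#' Integrates the coupled resource/strain system with an adaptive
#' stiff-capable solver (`deSolve::lsodar`, relative tolerance 1e-8,
#' absolute tolerance 1e-3 cells) until the remaining resource crosses
#' `exhaustionFraction * r0`, located as a root so the cycle end is not
#' truncated to a step boundary. Strains entering at count 0 remain exactly
#' 0. On return, per-strain `g` holds the generations grown this cycle
#' (log2 of the fold-expansion) for strains with a positive starting count.
#' Failure to exhaust the resource before `maxTime` is an explicit error.
#'
#' @param state Entry [populationState()]; at least one strain count must be
#'   positive. An entry resource at or below the exhaustion threshold
#'   returns immediately with zero growth.
#' @param fitness Named fitness vector.
#' @param params A [growthParams()] object.
#' @param full If `TRUE`, also return the dense solution (matrix with
#'   columns `time`, `R`, strain counts) for diagnostics.
#' @return The end-of-cycle `PopulationState` (or, with `full = TRUE`,
#'   `list(state=, solution=)`).
#' @examples
#' st <- populationState(c(WT = 1e8), resource = 100)
#' out <- integrateCycle(st, defaultFitness(), growthParams())
#' sum(strainCounts(out))   # ~1.01e10: inoculum + r0/e
#' @export
integrateCycle <- function(state, fitness, params, full = FALSE) {
  stopifnot(is(state, "PopulationState"), is(params, "GrowthParams"))
  v <- unname(fitness[strainTypes()])
  n0 <- state@n
  if (all(n0 <= 0)) stop("at least one strain count must be positive")
  thresh <- params@exhaustionFraction * params@r0

  if (state@resource <= thresh) {
    out <- populationState(n0, resource = state@resource,
                           time = state@time)
    if (full) return(list(state = out, solution = NULL))
    return(out)
  }

  k <- params@k
  e <- params@e
  rhs <- function(t, y, p) {
    r <- if (y[1L] > 0) y[1L] else 0
    psi <- v * r / (r + k)
    dn <- y[-1L] * psi
    list(c(-sum(dn) * e, dn))
  }
  rootf <- function(t, y, p) y[1L] - thresh

  y0 <- c(state@resource, unname(n0))
  times <- if (full) seq(0, params@maxTime, length.out = 201L)
           else c(0, params@maxTime)
  sol <- deSolve::lsodar(y = y0, times = times, func = rhs, parms = NULL,
                         rtol = 1e-8,
                         atol = c(1e-10, rep(1e-3, length(n0))),
                         rootfunc = rootf)
  end <- sol[nrow(sol), -1L]
  if (end[1L] > thresh * (1 + 1e-6))
    stop(sprintf(
      "growth cycle did not reach resource exhaustion within maxTime = %g (resource still %.4g)",
      params@maxTime, end[1L]))

  nEnd <- pmax(end[-1L], 0)
  names(nEnd) <- strainTypes()
  # zero-entry strains stay exactly zero; guard against solver noise
  nEnd[n0 == 0] <- 0
  g <- ifelse(n0 > 0, log2(nEnd / n0), 0)
  g[!is.finite(g) | g < 0] <- 0
  names(g) <- strainTypes()
  res <- new("PopulationState", n = nEnd,
             resource = max(end[1L], 0),
             time = state@time + sol[nrow(sol), 1L], g = g)
  if (full) {
    colnames(sol) <- c("time", "R", strainTypes())
    return(list(state = res, solution = sol))
  }
  res
}
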