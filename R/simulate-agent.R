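#' @include AllClasses.R protocol.R
NULL

#' Create thermotaxis agent parameters
#'
#' Defaults encode what is known of murine behavioural thermoregulation: a
#' thermal preferendum around 22-30 degrees C (comfort optimum 26) and heat
#' stress above 34 degrees C. The preference gain scales how strongly the
#' comfort difference between the two plates biases plate choice; at the
#' default gain the agent's long-run occupancy of the more comfortable plate
#' at a (0, 5) degree session is about 90 percent.
#'
#' @param comfortOptimum preferred temperature, degrees C
#' @param comfortWidth comfort-curve spread below the optimum, degrees C
#' @param heatStressOnset heat-stress temperature, degrees C
#' @param preferenceGain dimensionless choice gain (0 = indifferent)
#' @param crossingRate plate-crossing attempt rate, events/s
#' @param immobilityProb probability a 10 s block is spent immobile
#' @param stepSd within-plate positional jitter, pixels/frame
#' @param approachGain fraction of distance to the target plate centre
#'   covered per frame
#' @param seed default seed for simulators
#' @return An [AgentParams-class] object.
#' @export
#' @examples
#' a <- AgentParams()
#' comfort(26, a) > comfort(5, a)
AgentParams <- function(comfortOptimum = 26, comfortWidth = 10,
                        heatStressOnset = 34, preferenceGain = 30,
                        crossingRate = 0.15, immobilityProb = 0.1,
                        stepSd = 2.5, approachGain = 0.25, seed = 1L) {
  new("AgentParams", comfortOptimum = comfortOptimum,
      comfortWidth = comfortWidth, heatStressOnset = heatStressOnset,
      preferenceGain = preferenceGain, crossingRate = crossingRate,
      immobilityProb = immobilityProb, stepSd = stepSd,
      approachGain = approachGain, seed = as.integer(seed))
}

setMethod("show", "AgentParams", function(object) {
  cat(sprintf(paste0(
    "AgentParams: optimum %g degC (width %g), heat stress > %g degC\n",
    "  gain %g, crossing rate %g /s, immobility %g /10 s block\n"),
    object@comfortOptimum, object@comfortWidth, object@heatStressOnset,
    object@preferenceGain, object@crossingRate, object@immobilityProb))
})

#' Thermal comfort of a temperature
#'
#' Unimodal comfort score in (0, 1\]: an asymmetric Gaussian bump, maximal at
#' the comfort optimum, with spread `comfortWidth` on the cold side and a
#' steeper spread of `0.75 * (heatStressOnset - comfortOptimum)` on the warm
#' side, so the score decays quickly once temperatures pass the heat-stress
#' onset. Strictly increasing below the optimum and strictly decreasing
#' above it.
#'
#' @param temp temperature(s), degrees C (vectorized)
#' @param params an [AgentParams-class]
#' @param optimumShift additive shift of the comfort optimum, degrees C
#'   (used by treatment effect profiles)
#' @return Numeric comfort score(s) in (0, 1\].
#' @export
#' @examples
#' a <- AgentParams()
#' comfort(c(0, 5, 26, 34, 45), a)
comfort <- function(temp, params = AgentParams(), optimumShift = 0) {
  stopifnot(all(is.finite(temp)))
  opt <- params@comfortOptimum + optimumShift
  sdHigh <- 0.75 * (params@heatStressOnset - params@comfortOptimum)
  s <- ifelse(temp <= opt, params@comfortWidth, sdHigh)
  exp(-0.5 * ((temp - opt) / s)^2)
}

# Effect profiles -------------------------------------------------------

.emptyGainScale <- function() {
  m <- matrix(1, nrow = 3, ncol = 9,
              dimnames = list(timepointLevels(), NULL))
  m
}

#' Construct an effect profile
#'
#' @param gainScale numeric matrix (3 timepoints x sessions) of multiplicative
#'   modifiers of the preference gain; 0 abolishes thermal bias, negative
#'   values invert it
#' @param optimumShift length-3 numeric, degrees C added to the comfort
#'   optimum per timepoint
#' @return An [EffectProfile-class].
#' @export
EffectProfile <- function(gainScale = .emptyGainScale(),
                          optimumShift = c(0, 0, 0)) {
  rownames(gainScale) <- timepointLevels()
  new("EffectProfile", gainScale = gainScale,
      optimumShift = as.numeric(optimumShift))
}

#' Built-in treatment effect profiles
#'
#' `identityProfile()` leaves the agent unchanged at all timepoints (the null
#' model for calibration studies). The two drug-like profiles act at the
#' post-drug timepoint, after a mild sharpening of thermal aversion (gain
#' x 1.2) at the pre-drug timepoint that stands in for oxaliplatin-induced
#' hypersensitivity:
#' * `duloxetineProfile()`: gain abolished at the (0,5) session, inverted at
#'   (5,10), untouched elsewhere - an analgesic selective for noxious cold.
#' * `pregabalinProfile()`: gain abolished at (0,5) and inverted across the
#'   (5,10) ... (25,30) sessions - a non-selective preference reversal
#'   toward the colder plate, with heat avoidance above 30 degrees intact.
#'
#' @param nSessions number of sessions the profile covers (standard: 9)
#' @return An [EffectProfile-class].
#' @export
#' @examples
#' identityProfile()@gainScale
identityProfile <- function(nSessions = 9L) {
  EffectProfile(matrix(1, 3, nSessions,
                       dimnames = list(timepointLevels(), NULL)))
}

#' @rdname identityProfile
#' @export
duloxetineProfile <- function() {
  g <- .emptyGainScale()
  g["pre_drug", ] <- 1.2
  g["post_drug", ] <- c(0, -1, 1, 1, 1, 1, 1, 1, 1) * 1.2
  EffectProfile(g)
}

#' @rdname identityProfile
#' @export
pregabalinProfile <- function() {
  g <- .emptyGainScale()
  g["pre_drug", ] <- 1.2
  g["post_drug", ] <- c(0, -1, -1, -1, -1, -1, 1, 1, 1) * 1.2
  EffectProfile(g)
}

# Effective agent parameters at a timepoint/session
.effectiveGain <- function(agent, effect, timepoint, sessionId) {
  tp <- .validTimepoint(timepoint)
  ncol_ <- ncol(effect@gainScale)
  j <- if (sessionId <= ncol_) sessionId else ncol_
  unname(agent@preferenceGain * effect@gainScale[tp, j])
}

.effectiveShift <- function(effect, timepoint) {
  effect@optimumShift[match(.validTimepoint(timepoint), timepointLevels())]
}
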