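#' @import methods
NULL

#' Ordered timepoint labels of the assay
#'
#' The assay measures each animal three times: before the neuropathy-inducing
#' oxaliplatin injection, after oxaliplatin but before the candidate analgesic
#' ("pre-drug"), and after the analgesic ("post-drug"). The temporal order is
#' fixed and all cohort tables use these factor levels.
#'
#' @return Character vector `c("before_oxa", "pre_drug", "post_drug")`.
#' @export
#' @examples
#' timepointLevels()
timepointLevels <- function() c("before_oxa", "pre_drug", "post_drug")

.validTimepoint <- function(x) {
  if (!is.character(x) || length(x) != 1L || !x %in% timepointLevels())
    stop("timepoint must be one of: ",
         paste(timepointLevels(), collapse = ", "), call. = FALSE)
  x
}

#' PlatePair: the temperature configuration of one session
#'
#' A single session of the two-plate assay exposes the animal to two adjacent
#' thermal zones. Temperatures are in degrees Celsius, within the device's
#' 0-45 range, and must differ so that a colder (starting) plate is defined.
#'
#' @slot tLeft temperature of the left plate, degrees Celsius
#' @slot tRight temperature of the right plate, degrees Celsius
#' @slot sessionId integer session identifier
#' @export
setClass("PlatePair",
  representation(tLeft = "numeric", tRight = "numeric", sessionId = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@tLeft) != 1L || length(object@tRight) != 1L)
      msg <- c(msg, "tLeft and tRight must be scalars")
    else {
      if (!is.finite(object@tLeft) || !is.finite(object@tRight))
        msg <- c(msg, "temperatures must be finite")
      else {
        if (object@tLeft < 0 || object@tLeft > 45 ||
            object@tRight < 0 || object@tRight > 45)
          msg <- c(msg, "temperatures must lie within [0, 45] degrees C")
        if (object@tLeft == object@tRight)
          msg <- c(msg, "plate temperatures must differ (equal-temperature session is ill-posed)")
      }
    }
    if (length(object@sessionId) != 1L || is.na(object@sessionId) ||
        object@sessionId < 1L)
      msg <- c(msg, "sessionId must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' SessionProtocol: an ordered schedule of sessions
#'
#' @slot sessions list of [PlatePair] objects, in testing order
#' @slot durationS session duration in seconds (300 for the standard protocol)
#' @slot habituation whether a habituation day (both plates at room
#'   temperature) precedes testing
#' @export
setClass("SessionProtocol",
  representation(sessions = "list", durationS = "numeric",
                 habituation = "logical"),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@sessions, is, logical(1), "PlatePair")))
      msg <- c(msg, "sessions must all be PlatePair objects")
    if (length(object@durationS) != 1L || object@durationS <= 0)
      msg <- c(msg, "durationS must be a positive scalar")
    ids <- vapply(object@sessions, function(p) p@sessionId, integer(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "session ids must be unique")
    if (length(msg)) msg else TRUE
  })

#' ArenaGeometry: pixel geometry of the two-plate arena
#'
#' Columns use a half-open midline convention: pixel column `c` belongs to
#' the left plate iff `c < midlineX`; the midline column itself belongs to
#' the right plate. Column indices are 1-based.
#'
#' @slot widthPx arena width in pixels
#' @slot heightPx arena height in pixels
#' @slot midlineX first pixel column of the right plate
#' @export
setClass("ArenaGeometry",
  representation(widthPx = "integer", heightPx = "integer",
                 midlineX = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@widthPx < 2L || object@heightPx < 1L)
      msg <- c(msg, "arena must be at least 2 x 1 pixels")
    if (object@midlineX <= 1L || object@midlineX > object@widthPx)
      msg <- c(msg, "midlineX must satisfy 1 < midlineX <= widthPx")
    if (length(msg)) msg else TRUE
  })

#' AgentParams: behavioural parameters of the thermotaxis agent
#'
#' The simulated animal attempts plate crossings as a Poisson process with
#' rate `crossingRate`; at each attempt it moves to the other plate with
#' probability `plogis(preferenceGain * (comfort(other) - comfort(current)))`.
#' The comfort curve is an asymmetric Gaussian bump centred on
#' `comfortOptimum`, with spread `comfortWidth` on the cold side and a
#' steeper decline calibrated to `heatStressOnset` on the warm side.
#'
#' @slot comfortOptimum preferred ambient temperature, degrees C
#' @slot comfortWidth spread of the comfort curve below the optimum, degrees C
#' @slot heatStressOnset temperature above which heat stress sets in, degrees C
#' @slot preferenceGain dimensionless gain (0 = no thermal bias)
#' @slot crossingRate plate-crossing attempt rate, events per second
#' @slot immobilityProb probability that any 10 s block is spent completely
#'   immobile
#' @slot stepSd within-plate positional jitter per frame, pixels
#' @slot approachGain per-frame fraction of the distance to the current
#'   target-plate centre covered by the agent
#' @slot seed default random seed used when none is supplied to simulators
#' @export
setClass("AgentParams",
  representation(comfortOptimum = "numeric", comfortWidth = "numeric",
                 heatStressOnset = "numeric", preferenceGain = "numeric",
                 crossingRate = "numeric", immobilityProb = "numeric",
                 stepSd = "numeric", approachGain = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@preferenceGain < 0)
      msg <- c(msg, "preferenceGain must be >= 0")
    if (object@immobilityProb < 0 || object@immobilityProb > 1)
      msg <- c(msg, "immobilityProb must lie in [0, 1]")
    if (object@crossingRate <= 0)
      msg <- c(msg, "crossingRate must be > 0")
    if (object@comfortWidth <= 0)
      msg <- c(msg, "comfortWidth must be > 0")
    if (object@heatStressOnset <= object@comfortOptimum)
      msg <- c(msg, "heatStressOnset must exceed comfortOptimum")
    if (object@approachGain <= 0 || object@approachGain > 1)
      msg <- c(msg, "approachGain must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' EffectProfile: per-timepoint modifiers of the agent
#'
#' Treatment effects act multiplicatively on the preference gain, per
#' timepoint and per session: `gainScale[timepoint, session]` rescales
#' `preferenceGain` (0 abolishes thermal bias, negative values invert it),
#' and `optimumShift[timepoint]` shifts the comfort optimum in degrees C.
#' The identity profile leaves the agent unchanged.
#'
#' @slot gainScale numeric matrix, rows = the three timepoints, columns =
#'   sessions
#' @slot optimumShift numeric vector of length 3, degrees C per timepoint
#' @export
setClass("EffectProfile",
  representation(gainScale = "matrix", optimumShift = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(rownames(object@gainScale), timepointLevels()))
      msg <- c(msg, "gainScale rows must be the three timepoints, in order")
    if (!is.numeric(object@gainScale))
      msg <- c(msg, "gainScale must be numeric")
    if (length(object@optimumShift) != 3L)
      msg <- c(msg, "optimumShift must have one entry per timepoint")
    if (length(msg)) msg else TRUE
  })

#' Trajectory: a simulated path across the two plates
#'
#' Positions are continuous pixel coordinates in the arena. `state` is the
#' behavioural plate choice of the agent (the Markov-chain side); `trueSide`
#' is derived from the x coordinate under the half-open midline rule and is
#' the reference the tracker is scored against.
#'
#' @slot x,y per-frame position, pixels
#' @slot time per-frame timestamps, seconds
#' @slot state per-frame behavioural side, "left"/"right"
#' @slot frameRate frames per second
#' @slot arena the [ArenaGeometry] the path lives in
#' @export
setClass("Trajectory",
  representation(x = "numeric", y = "numeric", time = "numeric",
                 state = "character", frameRate = "numeric",
                 arena = "ArenaGeometry"),
  validity = function(object) {
    n <- length(object@x)
    msg <- character()
    if (length(object@y) != n || length(object@time) != n ||
        length(object@state) != n)
      msg <- c(msg, "x, y, time and state must have equal length")
    if (n >= 2 && any(diff(object@time) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
    if (!all(object@state %in% c("left", "right")))
      msg <- c(msg, "state must be 'left' or 'right'")
    if (length(msg)) msg else TRUE
  })

#' RenderConfig: how a trajectory is rendered to grayscale video
#'
#' Intensities are on a 0-255 scale. The mouse is a dark disc on lighter
#' plate backgrounds, so frame differencing can detect it; validity enforces
#' the blob being darker than either plate.
#'
#' @slot arena [ArenaGeometry] (image size and midline)
#' @slot blobRadius mouse blob radius, pixels
#' @slot blobIntensity blob intensity (dark), 0-255
#' @slot bgLeft,bgRight plate background intensities, 0-255
#' @slot noiseSd per-pixel Gaussian sensor noise sd, intensity units
#' @slot driftAmplitude amplitude of a slow sinusoidal illumination drift over
#'   the recording, intensity units
#' @export
setClass("RenderConfig",
  representation(arena = "ArenaGeometry", blobRadius = "numeric",
                 blobIntensity = "numeric", bgLeft = "numeric",
                 bgRight = "numeric", noiseSd = "numeric",
                 driftAmplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@blobIntensity >= min(object@bgLeft, object@bgRight))
      msg <- c(msg, "blob must be darker than both plate backgrounds")
    if (object@noiseSd < 0 || object@driftAmplitude < 0)
      msg <- c(msg, "noiseSd and driftAmplitude must be >= 0")
    if (object@blobRadius < 1)
      msg <- c(msg, "blobRadius must be >= 1 pixel")
    if (length(msg)) msg else TRUE
  })

#' FrameSequence: timed grayscale frames of the arena
#'
#' Frames are stored as an `nx x ny x nFrames` numeric array on a 0-255
#' intensity scale, first dimension = pixel columns (x), matching the
#' orientation used by EBImage. Rendered sequences carry their ground truth
#' (per-frame blob centre and true side) in `truth`.
#'
#' @slot frames numeric array, `dim = c(nx, ny, nFrames)`
#' @slot frameRate frames per second
#' @slot timestamps per-frame times, seconds, strictly increasing
#' @slot truth data.frame with columns frame, x, y, side (may have 0 rows)
#' @export
setClass("FrameSequence",
  representation(frames = "array", frameRate = "numeric",
                 timestamps = "numeric", truth = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L)
      msg <- c(msg, "frames must be an nx x ny x nFrames array")
    else {
      if (d[3] < 2L)
        msg <- c(msg, "a frame sequence needs at least 2 frames")
      if (length(object@timestamps) != d[3])
        msg <- c(msg, "one timestamp per frame required")
      else if (any(diff(object@timestamps) <= 0))
        msg <- c(msg, "timestamps must be strictly increasing")
    }
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' TrackerConfig: parameters of the frame-differencing tracker
#'
#' The tracker resizes and median-filters each frame, takes the absolute
#' difference of consecutive frames, binarizes it at `binarizeThreshold`,
#' median-filters the mask, and counts white pixels on each side of
#' `midlineX`. `midlineX` is expressed in post-resize pixel columns; when
#' `NA` it defaults to the image centre (`floor(nx/2) + 1`). A native-
#' resolution midline `m` maps to `floor((m - 1) * resizeFactor) + 1`.
#'
#' @slot resizeFactor frame down-scaling factor in (0, 1]
#' @slot medianKernel odd median-filter window side, pixels (1 = off)
#' @slot binarizeThreshold intensity threshold on the absolute difference,
#'   0-255 scale; pixels strictly above it are motion
#' @slot minMotionPixels minimum white-pixel count for a side call
#' @slot midlineX post-resize midline column (half-open rule); NA = centre
#' @slot tiePolicy "hold" (tie left unresolved, filled by carry-forward) or
#'   "unknown"
#' @slot stride frame step between the two differenced frames (1 = every
#'   adjacent pair)
#' @export
setClass("TrackerConfig",
  representation(resizeFactor = "numeric", medianKernel = "integer",
                 binarizeThreshold = "numeric", minMotionPixels = "integer",
                 midlineX = "integer", tiePolicy = "character",
                 stride = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@resizeFactor <= 0 || object@resizeFactor > 1)
      msg <- c(msg, "resizeFactor must lie in (0, 1]")
    if (object@medianKernel < 1L || object@medianKernel %% 2L == 0L)
      msg <- c(msg, "medianKernel must be odd and >= 1")
    if (object@binarizeThreshold <= 0)
      msg <- c(msg, "binarizeThreshold must be > 0")
    if (object@minMotionPixels < 0L)
      msg <- c(msg, "minMotionPixels must be >= 0")
    if (!object@tiePolicy %in% c("hold", "unknown"))
      msg <- c(msg, "tiePolicy must be 'hold' or 'unknown'")
    if (object@stride < 1L)
      msg <- c(msg, "stride must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' MotionMask: binarized motion image with per-side pixel counts
#'
#' @slot mask binary matrix (values 0/1), `nx x ny`
#' @slot nLeft,nRight white-pixel counts on each side of the midline
#' @slot midlineX midline column used for the counts
#' @export
setClass("MotionMask",
  representation(mask = "matrix", nLeft = "integer", nRight = "integer",
                 midlineX = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask values must be strictly binary")
    else if (object@nLeft + object@nRight != sum(object@mask))
      msg <- c(msg, "nLeft + nRight must equal the total white-pixel count")
    if (length(msg)) msg else TRUE
  })

#' OccupancySeries: per-iteration side assignments of the tracker
#'
#' One record per differenced frame pair: time, per-side white-pixel counts,
#' the raw call (left/right/unknown) and the resolved call after the
#' carry-forward fallback (left/right only).
#'
#' @slot records data.frame with columns iteration, t, nLeft, nRight,
#'   rawSide, resolvedSide
#' @slot frameRate frames per second of the source video
#' @export
setClass("OccupancySeries",
  representation(records = "data.frame", frameRate = "numeric"),
  validity = function(object) {
    req <- c("iteration", "t", "nLeft", "nRight", "rawSide", "resolvedSide")
    msg <- character()
    if (!all(req %in% names(object@records)))
      msg <- c(msg, paste("records must have columns:",
                          paste(req, collapse = ", ")))
    else if (!all(object@records$resolvedSide %in% c("left", "right")))
      msg <- c(msg, "resolvedSide must contain only 'left'/'right'")
    if (length(msg)) msg else TRUE
  })

#' SessionResult: zone-occupancy summary of one tracked session
#'
#' @slot secondsLeft,secondsRight time credited to each plate, seconds
#' @slot pctLeft,pctRight percent time per plate (sums to 100 exactly)
#' @slot pctColder,pctWarmer the same, oriented by the session's [PlatePair]
#' @slot nUnresolved number of iterations with no raw side call (resolved by
#'   carry-forward)
#' @slot pair the session's [PlatePair]
#' @export
setClass("SessionResult",
  representation(secondsLeft = "numeric", secondsRight = "numeric",
                 pctLeft = "numeric", pctRight = "numeric",
                 pctColder = "numeric", pctWarmer = "numeric",
                 nUnresolved = "integer", pair = "PlatePair"),
  validity = function(object) {
    msg <- character()
    if (object@pctLeft + object@pctRight != 100)
      msg <- c(msg, "pctLeft + pctRight must equal 100 exactly")
    if (length(msg)) msg else TRUE
  })

#' SimulatedCohort: a synthetic cohort with its generating ground truth
#'
#' @slot table tidy cohort data.frame (subject, session, timepoint, t_low,
#'   t_high, pct_colder, pct_warmer)
#' @slot subjects per-subject realized agent parameters
#' @slot seed master seed the cohort was generated from
#' @export
setClass("SimulatedCohort",
  representation(table = "data.frame", subjects = "data.frame",
                 seed = "integer"))

#' PreferenceCall: plate preference at one session and timepoint
#'
#' @slot sessionId session identifier
#' @slot timepoint one of [timepointLevels()]
#' @slot direction "warmer", "colder" or "none"
#' @slot meanPctColder cohort mean percent time on the colder plate
#' @slot pAdj adjusted p-value of the plate-vs-plate comparison
#' @slot stars significance label (ns, *, **, ***, ****)
#' @export
setClass("PreferenceCall",
  representation(sessionId = "integer", timepoint = "character",
                 direction = "character", meanPctColder = "numeric",
                 pAdj = "numeric", stars = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@direction %in% c("warmer", "colder", "none"))
      msg <- c(msg, "direction must be 'warmer', 'colder' or 'none'")
    if (!object@timepoint %in% timepointLevels())
      msg <- c(msg, "invalid timepoint")
    if (length(msg)) msg else TRUE
  })

#' DrugEffectCall: the analgesia classification for one session
#'
#' Compares the pre-drug and post-drug [PreferenceCall]s of the same session:
#' a significant preference that disappears is "lost", one that flips plate
#' is "reversed", one that persists in the same direction is "maintained";
#' sessions with no pre-drug preference are "no_baseline" and excluded from
#' analgesia claims.
#'
#' @slot sessionId session identifier
#' @slot category "maintained", "lost", "reversed" or "no_baseline"
#' @slot pre,post the two [PreferenceCall]s
#' @slot crossPAdj Tukey-adjusted p of the same-plate pre- vs post-drug
#'   comparison (the hash family)
#' @slot hashes hash-mark label for `crossPAdj` (ns, #, ##, ###, ####)
#' @export
setClass("DrugEffectCall",
  representation(sessionId = "integer", category = "character",
                 pre = "PreferenceCall", post = "PreferenceCall",
                 crossPAdj = "numeric", hashes = "character"),
  validity = function(object) {
    ok <- c("maintained", "lost", "reversed", "no_baseline")
    if (!object@category %in% ok)
      return(paste("category must be one of:", paste(ok, collapse = ", ")))
    TRUE
  })
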