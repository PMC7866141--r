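#' @include simulate-agent.R
NULL

# Immobility blocks are 10 s long: a mouse that stops grooming/resting does
# so on a seconds scale, and 10 s blocks exercise the tracker's zero-motion
# fallback.
.IMMOBILITY_BLOCK_S <- 10

# Per-frame switch hazards of the two-state plate chain. Crossing attempts
# are Poisson with rate crossingRate; an attempt on side s succeeds with
# probability plogis(gain * (comfort(other) - comfort(s))).
.crossingHazards <- function(pair, agent, gain, shift, dt) {
  cl <- comfort(pair@tLeft, agent, shift)
  cr <- comfort(pair@tRight, agent, shift)
  pAtt <- 1 - exp(-agent@crossingRate * dt)
  list(left = pAtt * stats::plogis(gain * (cr - cl)),
       right = pAtt * stats::plogis(gain * (cl - cr)))
}

# Simulate the per-frame side sequence (behavioural state) of one session.
# Immobility blocks are drawn first, then the chain runs over active frames
# via exact geometric sojourns; frozen frames hold the current side. Assumes
# the RNG is already seeded by the caller.
.simulateSideSequence <- function(pair, agent, gain, shift, nFrames,
                                  frameRate) {
  dt <- 1 / frameRate
  h <- .crossingHazards(pair, agent, gain, shift, dt)
  start <- colderSide(pair)

  blockLen <- max(1L, as.integer(round(.IMMOBILITY_BLOCK_S * frameRate)))
  nBlocks <- ceiling(nFrames / blockLen)
  frozenBlock <- stats::runif(nBlocks) < agent@immobilityProb
  frozen <- rep(frozenBlock, each = blockLen)[seq_len(nFrames)]
  nActive <- sum(!frozen)

  states <- character(0)
  lens <- integer(0)
  cur <- start
  pos <- 0L
  while (pos < nActive) {
    hc <- if (cur == "left") h$left else h$right
    len <- if (hc <= 0) nActive - pos
           else max(1, ceiling(log(stats::runif(1)) / log1p(-hc)))
    len <- min(len, nActive - pos)
    states <- c(states, cur)
    lens <- c(lens, as.integer(len))
    pos <- pos + as.integer(len)
    cur <- if (cur == "left") "right" else "left"
  }
  activeSides <- rep(states, lens)

  side <- character(nFrames)
  side[!frozen] <- activeSides
  if (any(frozen)) {
    pos <- cummax(ifelse(!frozen, seq_len(nFrames), 0L))
    side <- ifelse(pos == 0L, start, side[pmax(pos, 1L)])
  }
  list(side = side, frozen = frozen)
}

#' Simulate a thermotaxis trajectory across the two plates
#'
#' A biased random walk: the agent starts on the colder plate (the assay's
#' starting plate), attempts plate crossings as a Poisson process, and at
#' each attempt moves toward the other plate with probability
#' `plogis(gain * dComfort)`, where the gain is the agent's preference gain
#' modified by the effect profile at the given timepoint. Between crossings
#' the position relaxes toward the current plate centre with Gaussian
#' jitter; immobility blocks freeze the position entirely. Fully
#' reproducible from `seed`.
#'
#' @param pair the session's [PlatePair]
#' @param agent an [AgentParams-class]
#' @param effect an [EffectProfile-class]
#' @param timepoint one of [timepointLevels()]
#' @param durationS session duration, seconds
#' @param frameRate frames per second
#' @param arena an [ArenaGeometry-class]
#' @param seed integer seed (default: the agent's)
#' @param margin pixels kept between the blob centre and the arena edge, so
#'   a rendered blob stays in bounds
#' @return A [Trajectory-class] object.
#' @export
#' @examples
#' tr <- simulateTrajectory(PlatePair(0, 5), AgentParams(),
#'                          durationS = 30, seed = 7)
#' table(trajectoryStates(tr))
simulateTrajectory <- function(pair, agent = AgentParams(),
                               effect = identityProfile(),
                               timepoint = "before_oxa",
                               durationS = 300, frameRate = 10,
                               arena = ArenaGeometry(),
                               seed = agent@seed, margin = 8) {
  stopifnot(is(pair, "PlatePair"), durationS > 0, frameRate > 0)
  n <- as.integer(round(durationS * frameRate))
  if (n < 2L) stop("durationS x frameRate must give at least 2 frames")
  gain <- .effectiveGain(agent, effect, timepoint, pair@sessionId)
  shift <- .effectiveShift(effect, timepoint)

  .withSeed(seed, {
    seq_ <- .simulateSideSequence(pair, agent, gain, shift, n, frameRate)
    side <- seq_$side
    frozen <- seq_$frozen

    w <- arena@widthPx; hgt <- arena@heightPx; mid <- arena@midlineX
    cx <- c(left = (1 + (mid - 1)) / 2, right = (mid + w) / 2)
    cy <- (1 + hgt) / 2
    xlim <- c(1 + margin, w - margin)
    ylim <- c(1 + margin, hgt - margin)

    ex <- stats::rnorm(n, 0, agent@stepSd)
    ey <- stats::rnorm(n, 0, agent@stepSd)
    x <- numeric(n); y <- numeric(n)
    x[1] <- cx[[colderSide(pair)]]
    y[1] <- cy
    g <- agent@approachGain
    for (i in 2:n) {
      if (frozen[i]) {
        x[i] <- x[i - 1]; y[i] <- y[i - 1]
      } else {
        x[i] <- min(max(x[i - 1] + g * (cx[[side[i]]] - x[i - 1]) + ex[i],
                        xlim[1]), xlim[2])
        y[i] <- min(max(y[i - 1] + g * (cy - y[i - 1]) + ey[i],
                        ylim[1]), ylim[2])
      }
    }
    new("Trajectory", x = x, y = y, time = (seq_len(n) - 1) / frameRate,
        state = side, frameRate = frameRate, arena = arena)
  })
}

#' Accessors for simulated trajectories
#'
#' `trajectoryStates` returns the behavioural plate choice per frame;
#' `trajectoryTruth` returns the per-frame ground truth used to score the
#' tracker: blob centre coordinates and the side implied by the x coordinate
#' under the half-open midline rule.
#'
#' @param traj a [Trajectory-class]
#' @return `trajectoryStates`: character vector; `trajectoryTruth`: a
#'   data.frame with columns frame, t, x, y, side.
#' @export
trajectoryStates <- function(traj) traj@state

#' @rdname trajectoryStates
#' @export
trajectoryTruth <- function(traj) {
  data.frame(frame = seq_along(traj@x), t = traj@time,
             x = traj@x, y = traj@y,
             side = ifelse(traj@x < traj@arena@midlineX, "left", "right"))
}

setMethod("show", "Trajectory", function(object) {
  fr <- table(factor(object@state, c("left", "right")))
  cat(sprintf(
    "Trajectory: %d frames @ %g fps (%.1f s); left %.1f%% / right %.1f%%\n",
    length(object@x), object@frameRate,
    length(object@x) / object@frameRate,
    100 * fr[["left"]] / length(object@x),
    100 * fr[["right"]] / length(object@x)))
})

setMethod("frameRate", "Trajectory", function(x) x@frameRate)
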