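#' @include track.R cohort.R
NULL

#' Construct a Trajectory from explicit coordinates
#'
#' For validation fixtures: builds a [Trajectory-class] from per-frame
#' pixel coordinates. The behavioural state is taken from the x coordinate
#' under the half-open midline rule, so `trajectoryStates()` and
#' `trajectoryTruth()` agree by construction.
#'
#' @param x,y per-frame blob-centre coordinates, pixels
#' @param frameRate frames per second
#' @param arena an [ArenaGeometry-class]
#' @return A [Trajectory-class].
#' @export
#' @examples
#' tr <- Trajectory(x = seq(20, 100, length.out = 50), y = rep(32, 50))
#' table(trajectoryStates(tr))
Trajectory <- function(x, y, frameRate = 10, arena = ArenaGeometry()) {
  new("Trajectory", x = as.numeric(x), y = as.numeric(y),
      time = (seq_along(x) - 1) / frameRate,
      state = ifelse(x < arena@midlineX, "left", "right"),
      frameRate = frameRate, arena = arena)
}

#' Benchmark the tracker against simulated ground truth
#'
#' The package's default synthetic suite: one video per standard session
#' (nine videos with the default thermotaxis agent) plus a tenth video of
#' an indifferent agent (preference gain 0) that wanders freely. Each video
#' is rendered at the default 128 x 64 px / 10 fps configuration, tracked,
#' and scored against the simulator's ground truth: per-iteration side
#' agreement and the error in percent time on the colder plate.
#'
#' @param seed master seed; every video derives its own stream from it
#' @param durationS session length in seconds (default 300)
#' @param agent an [AgentParams-class]
#' @param renderCfg a [RenderConfig-class]
#' @param trackerCfg a [TrackerConfig-class]
#' @param frameRate frames per second
#' @return data.frame with one row per video: session, agreement (fraction),
#'   pct_colder_tracked, pct_colder_true, abs_error (percentage points),
#'   pct_left, pct_right, n_iterations.
#' @export
#' @examples
#' b <- trackerBenchmark(seed = 1, durationS = 20)
#' mean(b$agreement)
trackerBenchmark <- function(seed = 1L, durationS = 300,
                             agent = AgentParams(),
                             renderCfg = RenderConfig(),
                             trackerCfg = TrackerConfig(),
                             frameRate = 10) {
  prot <- standardProtocol()
  specs <- c(lapply(sessions(prot), function(p) list(pair = p, a = agent)),
             list(list(pair = sessions(prot)[[5]],
                       a = AgentParams(preferenceGain = 0))))
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    tr <- simulateTrajectory(sp$pair, sp$a, durationS = durationS,
                             frameRate = frameRate,
                             arena = renderCfg@arena,
                             seed = .deriveSeed(seed, 41L, i))
    fs <- renderFrames(tr, renderCfg, seed = .deriveSeed(seed, 43L, i))
    out <- trackSession(fs, trackerCfg, sp$pair)
    rec <- records(out$occupancy)
    s <- trackerCfg@stride
    trueSide <- truth(fs)$side[rec$iteration + s]
    agree <- mean(rec$resolvedSide == trueSide)
    pctTrue <- 100 * mean(trueSide ==
                            colderSide(sp$pair))
    data.frame(video = i, session = sp$pair@sessionId,
               agreement = agree,
               pct_colder_tracked = pctColder(out$result),
               pct_colder_true = pctTrue,
               abs_error = abs(pctColder(out$result) - pctTrue),
               pct_left = pctLeft(out$result),
               pct_right = out$result@pctRight,
               n_iterations = nrow(rec))
  })
  do.call(rbind, rows)
}
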