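# Shared fixtures, all generated in code.

# Deterministic always-moving sweep: a Lissajous-like path covering both
# plates, moving at least 1 px between any two consecutive frames.
sweepTrajectory <- function(durationS = 30, frameRate = 10,
                            arena = ArenaGeometry(), margin = 8) {
  n <- round(durationS * frameRate)
  t <- seq_len(n)
  xm <- (1 + margin); xM <- arena@widthPx - margin
  ym <- (1 + margin); yM <- arena@heightPx - margin
  x <- (xm + xM) / 2 + (xM - xm) / 2 * sin(2 * pi * t / 97)
  y <- (ym + yM) / 2 + (yM - ym) / 2 * sin(2 * pi * t / 31)
  Trajectory(x = x, y = y, frameRate = frameRate, arena = arena)
}

# Orbit on the left plate for `moveS` seconds, then frozen in place.
freezeTrajectory <- function(durationS = 100, moveS = 10, frameRate = 10,
                             arena = ArenaGeometry()) {
  n <- round(durationS * frameRate)
  nm <- round(moveS * frameRate)
  t <- seq_len(n)
  cx <- arena@midlineX / 2
  cy <- arena@heightPx / 2
  x <- cx + 8 * sin(2 * pi * t / 23)
  y <- cy + 8 * cos(2 * pi * t / 23)
  x[(nm + 1):n] <- x[nm]
  y[(nm + 1):n] <- y[nm]
  Trajectory(x = x, y = y, frameRate = frameRate, arena = arena)
}

# 3 subjects x 3 timepoints hand fixture with small-integer percentages.
handCohort <- function() {
  data.frame(
    subject = rep(c("s1", "s2", "s3"), each = 3),
    session = 1L,
    timepoint = rep(timepointLevels(), 3),
    t_low = 0, t_high = 5,
    pct_colder = c(40, 50, 60, 45, 55, 70, 35, 45, 50))
}

# Cohort table with given per-timepoint means and tiny subject scatter.
syntheticCohort <- function(means, nSubjects = 6, sessionId = 1L,
                            noise = 2, seed = 99) {
  set.seed(seed)
  rows <- expand.grid(subject = sprintf("s%02d", seq_len(nSubjects)),
                      timepoint = timepointLevels(),
                      stringsAsFactors = FALSE)
  rows$session <- sessionId
  rows$t_low <- 0; rows$t_high <- 5
  rows$pct_colder <- pmin(100, pmax(0,
    means[match(rows$timepoint, timepointLevels())] +
      rnorm(nrow(rows), 0, noise)))
  rows
}

# Brute-force median filter oracle: replicate-edge padding, same contract
# as the package's compiled filter.
medianFilterOracle <- function(m, kernel) {
  h <- kernel %/% 2
  nx <- nrow(m); ny <- ncol(m)
  out <- m
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      ii <- pmin(pmax(i + (-h:h), 1), nx)
      jj <- pmin(pmax(j + (-h:h), 1), ny)
      out[i, j] <- stats::median(m[ii, jj])
    }
  }
  out
}

# A minimal PreferenceCall for classifier tests.
prefCall <- function(direction, sessionId = 1L, timepoint = "pre_drug",
                     p = if (direction == "none") 0.5 else 0.001) {
  mean_ <- switch(direction, colder = 80, warmer = 20, none = 50)
  new("PreferenceCall", sessionId = as.integer(sessionId),
      timepoint = timepoint, direction = direction,
      meanPctColder = mean_, pAdj = p, stars = stars(p))
}
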