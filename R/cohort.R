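#' @include simulate-trajectory.R
NULL

# Occupancy-only fast path: same seeded side sequence as simulateTrajectory
# (identical RNG prefix), without generating pixel coordinates.
.simulateOccupancy <- function(pair, agent, gain, shift, durationS,
                               frameRate, seed) {
  n <- as.integer(round(durationS * frameRate))
  .withSeed(seed, {
    side <- .simulateSideSequence(pair, agent, gain, shift, n, frameRate)$side
    mean(side == "left")
  })
}

#' Simulate a cohort across the full protocol
#'
#' Generates percent time per plate for each subject x session x timepoint
#' cell by running the thermotaxis agent (the same seeded side-choice chain
#' that drives [simulateTrajectory()]) for the session duration. Subjects
#' carry stable trait jitter - a log-normal multiplier on the preference
#' gain and a Gaussian shift of the comfort optimum - drawn once per animal
#' so the repeated-measures structure is real. All randomness derives
#' deterministically from `seed` via per-cell streams.
#'
#' @param nSubjects number of animals (the assay uses 8-10)
#' @param protocol a [SessionProtocol-class]
#' @param agent an [AgentParams-class]
#' @param effects an [EffectProfile-class] applied per timepoint
#' @param seed master integer seed
#' @param frameRate frames per second of the simulated sessions
#' @param gainJitterSd sd of the per-subject log-gain multiplier
#' @param optimumJitterSd sd (degrees C) of the per-subject optimum shift
#' @return A [SimulatedCohort-class]; its `table` has one row per cell with
#'   columns subject, session, timepoint, t_low, t_high, pct_colder,
#'   pct_warmer.
#' @export
#' @examples
#' sc <- simulateCohort(3, standardProtocol(durationS = 30), seed = 1)
#' head(cohortTable(sc))
simulateCohort <- function(nSubjects = 10L, protocol = standardProtocol(),
                           agent = AgentParams(),
                           effects = identityProfile(), seed = 1L,
                           frameRate = 10, gainJitterSd = 0.15,
                           optimumJitterSd = 1.5) {
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  subj <- data.frame(
    subject = sprintf("m%02d", seq_len(nSubjects)),
    gainMult = numeric(nSubjects), optimumShift = numeric(nSubjects))
  for (i in seq_len(nSubjects)) {
    .withSeed(.deriveSeed(seed, 11L, i), {
      subj$gainMult[i] <- exp(stats::rnorm(1, 0, gainJitterSd))
      subj$optimumShift[i] <- stats::rnorm(1, 0, optimumJitterSd)
    })
  }

  tps <- timepointLevels()
  rows <- vector("list", nSubjects * length(protocol@sessions) * 3L)
  k <- 0L
  for (i in seq_len(nSubjects)) {
    for (p in protocol@sessions) {
      cs <- colderSide(p)
      for (j in seq_along(tps)) {
        gain <- .effectiveGain(agent, effects, tps[j], p@sessionId) *
          subj$gainMult[i]
        shift <- .effectiveShift(effects, tps[j]) + subj$optimumShift[i]
        fracLeft <- .simulateOccupancy(
          p, agent, gain, shift, protocol@durationS, frameRate,
          .deriveSeed(seed, 13L, i, p@sessionId, j))
        pctColder <- 100 * if (cs == "left") fracLeft else 1 - fracLeft
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject = subj$subject[i], session = p@sessionId,
          timepoint = tps[j],
          t_low = min(p@tLeft, p@tRight), t_high = max(p@tLeft, p@tRight),
          pct_colder = pctColder, pct_warmer = 100 - pctColder,
          stringsAsFactors = FALSE)
      }
    }
  }
  new("SimulatedCohort", table = do.call(rbind, rows), subjects = subj,
      seed = as.integer(seed))
}

#' @describeIn SimulatedCohort the tidy cohort table
#' @param x object
#' @export
setMethod("cohortTable", "SimulatedCohort", function(x) x@table)

setMethod("show", "SimulatedCohort", function(object) {
  t <- object@table
  cat(sprintf(
    "SimulatedCohort: %d subjects x %d sessions x %d timepoints (seed %d)\n",
    length(unique(t$subject)), length(unique(t$session)),
    length(unique(t$timepoint)), object@seed))
})

#' Validate a tidy cohort table
#'
#' Checks the schema required by the statistics functions: columns subject,
#' session, timepoint, pct_colder; `pct_colder` within \[0, 100\];
#' timepoints among [timepointLevels()]; no duplicate
#' (subject, session, timepoint) keys; and (unless `allowIncomplete`) a
#' complete subject x session x timepoint grid. Violations are reported
#' with the offending row numbers.
#'
#' @param tab data.frame
#' @param allowIncomplete skip the complete-grid check
#' @return `tab`, invisibly, if valid; otherwise an error.
#' @export
validateCohortTable <- function(tab, allowIncomplete = FALSE) {
  req <- c("subject", "session", "timepoint", "pct_colder")
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    stop("cohort table is empty or not a data.frame")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("cohort table lacks required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$pct_colder) | tab$pct_colder < 0 |
                 tab$pct_colder > 100)
  if (length(bad))
    stop("pct_colder outside [0, 100] at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  badTp <- which(!tab$timepoint %in% timepointLevels())
  if (length(badTp))
    stop("unknown timepoint at row(s): ",
         paste(utils::head(badTp, 10), collapse = ", "))
  key <- paste(tab$subject, tab$session, tab$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (subject, session, timepoint) at row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  if (!allowIncomplete) {
    full <- expand.grid(subject = unique(tab$subject),
                        session = unique(tab$session),
                        timepoint = unique(tab$timepoint),
                        stringsAsFactors = FALSE)
    fkey <- paste(full$subject, full$session, full$timepoint, sep = "\r")
    missing_ <- setdiff(fkey, key)
    if (length(missing_))
      stop("incomplete cohort grid; missing cell(s): ",
           paste(utils::head(gsub("\r", "/", missing_), 10),
                 collapse = ", "))
  }
  invisible(tab)
}

#' Write / read a cohort table as tidy CSV
#'
#' @param tab cohort data.frame (or a [SimulatedCohort-class])
#' @param path CSV file path
#' @return `readCohortTable`: a validated data.frame.
#' @export
writeCohortTable <- function(tab, path) {
  if (is(tab, "SimulatedCohort")) tab <- cohortTable(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @param allowIncomplete passed to [validateCohortTable()]
#' @export
readCohortTable <- function(path, allowIncomplete = FALSE) {
  if (!file.exists(path)) stop("cannot read cohort table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohortTable(tab, allowIncomplete = allowIncomplete)
  tab
}
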