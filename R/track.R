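#' @include render.R
NULL

#' Create a tracker configuration
#'
#' The algorithm's steps are fixed (resize, grayscale, median filter,
#' absolute frame difference, binarize, median filter, per-side white-pixel
#' count); the parameters here are conventional defaults and all
#' configurable. The binarize threshold of 15 on the 0-255 scale is applied
#' to the absolute difference; `minMotionPixels` gates how much motion is
#' needed before a side is called, which is what detects the
#' stationary-mouse case.
#'
#' @param resizeFactor frame down-scaling in (0, 1]
#' @param medianKernel odd median window (1 disables filtering)
#' @param binarizeThreshold difference threshold, 0-255 scale (strict `>`)
#' @param minMotionPixels minimum total white pixels for a raw side call
#' @param midlineX post-resize midline column; `NA` = image centre. A native
#'   midline `m` maps to `floor((m - 1) * resizeFactor) + 1`.
#' @param tiePolicy what an exact left/right tie yields: "hold" or "unknown"
#'   (both leave the iteration to the carry-forward fallback)
#' @param stride step between the two differenced frames (1 = adjacent)
#' @return A [TrackerConfig-class].
#' @export
TrackerConfig <- function(resizeFactor = 0.5, medianKernel = 3L,
                          binarizeThreshold = 15, minMotionPixels = 5L,
                          midlineX = NA_integer_, tiePolicy = "hold",
                          stride = 1L) {
  new("TrackerConfig", resizeFactor = resizeFactor,
      medianKernel = as.integer(medianKernel),
      binarizeThreshold = binarizeThreshold,
      minMotionPixels = as.integer(minMotionPixels),
      midlineX = as.integer(midlineX), tiePolicy = tiePolicy,
      stride = as.integer(stride))
}

# Map a native-resolution midline column to post-resize coordinates.
.resizedMidline <- function(midlineX, resizeFactor) {
  as.integer(floor((midlineX - 1) * resizeFactor) + 1)
}

# midline actually used for counting, given a processed frame width
.effectiveMidline <- function(cfg, nx) {
  if (is.na(cfg@midlineX)) as.integer(floor(nx / 2) + 1L) else cfg@midlineX
}

.medianFilterArr <- function(arr, kernel) {
  d <- dim(arr)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- .medianFilter3d(as.numeric(arr), d[1], d[2], d[3], kernel)
  array(out, dim = dim(arr))
}

#' Preprocess frames: resize, grayscale, median filter
#'
#' Accepts a single frame (matrix), a frame array or a [FrameSequence].
#' Color input (`nx x ny x 3` per frame) is collapsed to luminance
#' `0.299 R + 0.587 G + 0.114 B` first; frames are then resized by
#' `resizeFactor` (bilinear) and median-filtered with `medianKernel`.
#' With `resizeFactor = 1` and `medianKernel = 1` the output equals the
#' grayscale input exactly. Deterministic.
#'
#' @param x frame(s): matrix, array or [FrameSequence-class]
#' @param cfg a [TrackerConfig-class]
#' @return Object of the same shape with processed frames.
#' @export
preprocessFrames <- function(x, cfg = TrackerConfig()) {
  if (is(x, "FrameSequence")) {
    arr <- preprocessFrames(x@frames, cfg)
    return(FrameSequence(arr, frameRate = x@frameRate,
                         timestamps = x@timestamps, truth = x@truth))
  }
  if (is.matrix(x)) {
    if (length(x) == 0L) stop("empty frame")
    return(preprocessFrames(array(x, dim = c(dim(x), 1L)), cfg)[, , 1])
  }
  d <- dim(x)
  if (is.null(d) || length(x) == 0L) stop("empty frame")
  if (length(d) == 4L && d[3] == 3L)  # color stack
    x <- 0.299 * x[, , 1, ] + 0.587 * x[, , 2, ] + 0.114 * x[, , 3, ]
  d <- dim(x)
  if (cfg@resizeFactor < 1) {
    w <- max(2L, as.integer(round(d[1] * cfg@resizeFactor)))
    h <- max(1L, as.integer(round(d[2] * cfg@resizeFactor)))
    x <- EBImage::imageData(
      EBImage::resize(EBImage::Image(x / 255), w = w, h = h)) * 255
    if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  }
  if (cfg@medianKernel > 1L) x <- .medianFilterArr(x, cfg@medianKernel)
  x
}

#' Motion mask of a preprocessed frame pair
#'
#' Absolute pixel-wise difference of the two frames, binarized (white where
#' the difference strictly exceeds `binarizeThreshold`), median-filtered to
#' remove speckle noise, then white pixels counted on each side of the
#' midline under the half-open rule.
#'
#' @param frameA,frameB preprocessed grayscale frames (matrices, same shape)
#' @param cfg a [TrackerConfig-class]
#' @return A [MotionMask-class].
#' @export
differenceMask <- function(frameA, frameB, cfg = TrackerConfig()) {
  if (!identical(dim(frameA), dim(frameB)))
    stop("frame shape mismatch: ", paste(dim(frameA), collapse = "x"),
         " vs ", paste(dim(frameB), collapse = "x"))
  m <- (abs(frameA - frameB) > cfg@binarizeThreshold) * 1
  if (cfg@medianKernel > 1L)
    m <- .medianFilterArr(m, cfg@medianKernel)
  mid <- .effectiveMidline(cfg, nrow(m))
  nL <- as.integer(sum(m[seq_len(mid - 1L), ]))
  nR <- as.integer(sum(m) - nL)
  new("MotionMask", mask = m, nLeft = nL, nRight = nR,
      midlineX = mid)
}

#' Classify one tracker iteration from its motion counts
#'
#' Returns "left" or "right" by white-pixel majority, provided the total
#' motion reaches `minMotionPixels`; otherwise "unknown" (the stationary-
#' mouse case). Exact ties are left "unknown" at this stage and resolved by
#' the carry-forward fallback in [trackSession()].
#'
#' @param mask a [MotionMask-class] (or anything with `nLeft`/`nRight`
#'   counts via `classifyCounts`)
#' @param cfg a [TrackerConfig-class]
#' @return "left", "right" or "unknown".
#' @export
classifyIteration <- function(mask, cfg = TrackerConfig()) {
  classifyCounts(mask@nLeft, mask@nRight, cfg)
}

#' @rdname classifyIteration
#' @param nLeft,nRight white-pixel counts (vectorized)
#' @export
classifyCounts <- function(nLeft, nRight, cfg = TrackerConfig()) {
  out <- rep("unknown", length(nLeft))
  enough <- (nLeft + nRight) >= cfg@minMotionPixels
  out[enough & nLeft > nRight] <- "left"
  out[enough & nRight > nLeft] <- "right"
  # ties: both policies leave the iteration unresolved here
  out
}

# Carry the last determined side forward; backfill leading unknowns from the
# first determined side. Errors if nothing was ever determined.
.resolveSides <- function(raw) {
  known <- raw != "unknown"
  if (!any(known)) stop("no motion detected in recording")
  idx <- cummax(ifelse(known, seq_along(raw), 0L))
  first <- which(known)[1]
  idx[idx == 0L] <- first
  raw[idx]
}

#' Track a full session
#'
#' Runs the frame-differencing pipeline over every consecutive frame pair
#' (at the configured stride): preprocess, difference, binarize, filter,
#' count, classify. "Unknown" iterations (insufficient motion or ties) are
#' resolved by carrying forward the last determined side - a stationary
#' animal cannot change plates - with leading unknowns backfilled from the
#' first determined side. Each iteration credits `stride / frameRate`
#' seconds to its resolved side.
#'
#' @param fs a [FrameSequence-class] (at least 2 frames)
#' @param cfg a [TrackerConfig-class]
#' @param pair the session's [PlatePair], used to orient percent time onto
#'   the colder/warmer plates
#' @return A list with elements `occupancy` ([OccupancySeries-class]) and
#'   `result` ([SessionResult-class]).
#' @export
#' @examples
#' tr <- simulateTrajectory(PlatePair(0, 5), durationS = 5, seed = 2)
#' fs <- renderFrames(tr, seed = 2)
#' out <- trackSession(fs, TrackerConfig(), PlatePair(0, 5))
#' pctColder(out$result)
trackSession <- function(fs, cfg = TrackerConfig(), pair) {
  stopifnot(is(fs, "FrameSequence"), is(cfg, "TrackerConfig"),
            is(pair, "PlatePair"))
  n <- nFrames(fs)
  if (n < 2L) stop("a frame sequence needs at least 2 frames")

  arr <- preprocessFrames(fs@frames, cfg)
  d <- dim(arr)
  mid <- .effectiveMidline(cfg, d[1])

  s <- cfg@stride
  iA <- seq(1L, n - s, by = 1L)
  iB <- iA + s
  diffArr <- abs(arr[, , iB, drop = FALSE] - arr[, , iA, drop = FALSE])
  maskArr <- (diffArr > cfg@binarizeThreshold) * 1
  if (cfg@medianKernel > 1L)
    maskArr <- .medianFilterArr(maskArr, cfg@medianKernel)

  nL <- as.integer(colSums(maskArr[seq_len(mid - 1L), , , drop = FALSE],
                           dims = 2))
  nTot <- as.integer(colSums(maskArr, dims = 2))
  nR <- nTot - nL

  raw <- classifyCounts(nL, nR, cfg)
  resolved <- .resolveSides(raw)

  nIter <- length(raw)
  dtIter <- s / fs@frameRate
  rec <- data.frame(iteration = seq_len(nIter),
                    t = fs@timestamps[iB],
                    nLeft = nL, nRight = nR,
                    rawSide = raw, resolvedSide = resolved,
                    stringsAsFactors = FALSE)
  occ <- new("OccupancySeries", records = rec, frameRate = fs@frameRate)

  nLeftIter <- sum(resolved == "left")
  pctL <- 100 * nLeftIter / nIter
  pctR <- 100 - pctL
  pctC <- if (colderSide(pair) == "left") pctL else pctR
  res <- new("SessionResult",
             secondsLeft = nLeftIter * dtIter,
             secondsRight = (nIter - nLeftIter) * dtIter,
             pctLeft = pctL, pctRight = pctR,
             pctColder = pctC, pctWarmer = 100 - pctC,
             nUnresolved = sum(raw == "unknown"), pair = pair)
  list(occupancy = occ, result = res)
}

#' @describeIn OccupancySeries per-iteration records
#' @param x object
#' @export
setMethod("records", "OccupancySeries", function(x) x@records)

setMethod("show", "OccupancySeries", function(object) {
  r <- object@records
  cat(sprintf(
    "OccupancySeries: %d iterations (%d unknown before fallback)\n",
    nrow(r), sum(r$rawSide == "unknown")))
})

#' @describeIn SessionResult percent time on the colder plate
#' @param x object
#' @export
setMethod("pctColder", "SessionResult", function(x) x@pctColder)

#' @describeIn SessionResult percent time on the left plate
#' @export
setMethod("pctLeft", "SessionResult", function(x) x@pctLeft)

setMethod("show", "SessionResult", function(object) {
  cat(sprintf(paste0(
    "SessionResult [session %d: left %g / right %g degC]\n",
    "  left %.1f%% (%.1f s) | right %.1f%% (%.1f s)\n",
    "  colder %.1f%% | warmer %.1f%% | %d unresolved iterations\n"),
    object@pair@sessionId, object@pair@tLeft, object@pair@tRight,
    object@pctLeft, object@secondsLeft, object@pctRight,
    object@secondsRight, object@pctColder, object@pctWarmer,
    object@nUnresolved))
})

#' Write tracker outputs as CSV/JSON
#'
#' @param out the list returned by [trackSession()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
writeTrackResult <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(records(out$occupancy),
                   file.path(dir, "occupancy.csv"), row.names = FALSE)
  r <- out$result
  jsonlite::write_json(list(
    session_id = r@pair@sessionId, t_left = r@pair@tLeft,
    t_right = r@pair@tRight,
    seconds_left = r@secondsLeft, seconds_right = r@secondsRight,
    pct_left = r@pctLeft, pct_right = r@pctRight,
    pct_colder = r@pctColder, pct_warmer = r@pctWarmer,
    n_unresolved = r@nUnresolved),
    file.path(dir, "session_result.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
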