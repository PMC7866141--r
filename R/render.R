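#' @include simulate-trajectory.R
NULL

#' Create a render configuration
#'
#' Defaults produce the package's reference synthetic video: a 128 x 64 px
#' arena (left and right plates of 64 columns each), a dark mouse-sized blob
#' (radius 5 px, intensity 40) on light plates (200 / 185), Gaussian sensor
#' noise of sd 5 and a slow illumination drift of amplitude 6 - all on the
#' 0-255 intensity scale. At 10 fps a 300 s session is 3000 frames, small
#' enough for seconds-scale tests.
#'
#' @param arena an [ArenaGeometry-class]
#' @param blobRadius blob radius, pixels
#' @param blobIntensity blob intensity, 0-255 (must be darker than plates)
#' @param bgLeft,bgRight plate background intensities, 0-255
#' @param noiseSd Gaussian noise sd, intensity units
#' @param driftAmplitude illumination drift amplitude, intensity units
#' @return A [RenderConfig-class].
#' @export
RenderConfig <- function(arena = ArenaGeometry(), blobRadius = 5,
                         blobIntensity = 40, bgLeft = 200, bgRight = 185,
                         noiseSd = 5, driftAmplitude = 6) {
  new("RenderConfig", arena = arena, blobRadius = blobRadius,
      blobIntensity = blobIntensity, bgLeft = bgLeft, bgRight = bgRight,
      noiseSd = noiseSd, driftAmplitude = driftAmplitude)
}

#' Construct a FrameSequence from an array
#'
#' @param frames numeric array `dim = c(nx, ny, nFrames)`, intensities 0-255
#' @param frameRate frames per second
#' @param timestamps per-frame times in seconds (default: regular grid)
#' @param truth optional ground-truth data.frame (frame, x, y, side)
#' @return A [FrameSequence-class].
#' @export
FrameSequence <- function(frames, frameRate,
                          timestamps = (seq_len(dim(frames)[3]) - 1) / frameRate,
                          truth = data.frame()) {
  new("FrameSequence", frames = frames, frameRate = frameRate,
      timestamps = timestamps, truth = truth)
}

#' @describeIn FrameSequence number of frames
#' @param x object
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])

#' @describeIn FrameSequence the frame array
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @describeIn FrameSequence frames per second
#' @export
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)

#' @describeIn FrameSequence ground-truth data.frame (0 rows if unknown)
#' @export
setMethod("truth", "FrameSequence", function(x) x@truth)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px @ %g fps%s\n",
              d[3], d[1], d[2], object@frameRate,
              if (nrow(object@truth)) ", with ground truth" else ""))
})

#' Render a trajectory to noisy grayscale video
#'
#' One frame per trajectory point: plate backgrounds, a dark disc at the
#' blob centre (rounded to the pixel grid), seeded Gaussian sensor noise and
#' an optional slow sinusoidal illumination drift (one period over the
#' recording). Intensities are clamped to \[0, 255\] and rounded to
#' integers. Ground truth (per-frame centre and true side) is carried on
#' the returned sequence.
#'
#' @param traj a [Trajectory-class]
#' @param cfg a [RenderConfig-class]; its arena must match the trajectory's
#' @param seed integer seed for the sensor noise
#' @return A [FrameSequence-class].
#' @export
#' @examples
#' tr <- simulateTrajectory(PlatePair(0, 5), durationS = 2, seed = 3)
#' fs <- renderFrames(tr, RenderConfig(), seed = 3)
#' nFrames(fs)
renderFrames <- function(traj, cfg = RenderConfig(), seed = 1L) {
  stopifnot(is(traj, "Trajectory"), is(cfg, "RenderConfig"))
  a <- cfg@arena
  nx <- a@widthPx; ny <- a@heightPx; n <- length(traj@x)
  r <- cfg@blobRadius
  xi <- round(traj@x); yi <- round(traj@y)
  if (any(xi - r < 1 | xi + r > nx | yi - r < 1 | yi + r > ny))
    stop("blob out of bounds: trajectory leaves the renderable arena")

  bg <- matrix(cfg@bgRight, nx, ny)
  bg[seq_len(a@midlineX - 1L), ] <- cfg@bgLeft

  # disc offsets once; per-frame linear indices
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]

  drift <- cfg@driftAmplitude * sin(2 * pi * traj@time / max(traj@time[n], 1))

  .withSeed(seed, {
    arr <- array(rep(bg, n), dim = c(nx, ny, n))
    frameOff <- (seq_len(n) - 1) * nx * ny
    for (i in seq_len(n)) {
      idx <- (xi[i] + off$di) + (yi[i] + off$dj - 1) * nx + frameOff[i]
      arr[idx] <- cfg@blobIntensity
    }
    if (cfg@driftAmplitude > 0)
      arr <- arr + rep(drift, each = nx * ny)
    if (cfg@noiseSd > 0)
      arr <- arr + stats::rnorm(length(arr), 0, cfg@noiseSd)
    arr <- round(pmin(pmax(arr, 0), 255))
    FrameSequence(arr, frameRate = traj@frameRate, timestamps = traj@time,
                  truth = trajectoryTruth(traj))
  })
}

# Frame I/O -------------------------------------------------------------

#' Write / read a frame sequence as a numbered PNG image sequence
#'
#' `writeFrameSequence` writes one PNG per frame (`frame_000001.png`, ...)
#' plus, when ground truth is present, `truth.csv` with columns
#' frame, t, x, y, side. `readFrameSequence` reads a directory (or an
#' explicit file vector) of PNG/TIFF frames in lexical order; color frames
#' are converted to luminance (0.299 R + 0.587 G + 0.114 B).
#'
#' @param fs a [FrameSequence-class]
#' @param dir output/input directory
#' @return `writeFrameSequence`: the directory, invisibly;
#'   `readFrameSequence`: a [FrameSequence-class].
#' @export
writeFrameSequence <- function(fs, dir) {
  stopifnot(is(fs, "FrameSequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nFrames(fs)
  files <- file.path(dir, sprintf("frame_%06d.png", seq_len(n)))
  for (i in seq_len(n))
    EBImage::writeImage(EBImage::Image(fs@frames[, , i] / 255), files[i],
                        type = "png")
  if (nrow(fs@truth))
    utils::write.csv(fs@truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  writeLines(as.character(fs@frameRate), file.path(dir, "frame_rate.txt"))
  invisible(dir)
}

#' @rdname writeFrameSequence
#' @param frameRate frames per second of the recording; if `NULL`, read from
#'   `frame_rate.txt` in the directory (error if absent)
#' @export
readFrameSequence <- function(dir, frameRate = NULL) {
  if (length(dir) == 1L && dir.exists(dir)) {
    files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE))
    if (is.null(frameRate)) {
      frf <- file.path(dir, "frame_rate.txt")
      if (!file.exists(frf))
        stop("frameRate not given and no frame_rate.txt in ", dir)
      frameRate <- as.numeric(readLines(frf)[1])
    }
  } else {
    files <- dir
    missing_ <- files[!file.exists(files)]
    if (length(missing_))
      stop("cannot read input file(s): ", paste(missing_, collapse = ", "))
    if (is.null(frameRate)) stop("frameRate must be supplied")
  }
  if (length(files) < 2L)
    stop("a frame sequence needs at least 2 frames (found ",
         length(files), ")")
  img <- EBImage::readImage(files)
  arr <- EBImage::imageData(img) * 255
  dimnames(arr) <- NULL
  if (length(dim(arr)) == 4L) {       # color: collapse to luminance
    arr <- 0.299 * arr[, , 1, ] + 0.587 * arr[, , 2, ] + 0.114 * arr[, , 3, ]
  }
  tr <- data.frame()
  if (length(dir) == 1L && dir.exists(dir[1])) {
    tf <- file.path(dir, "truth.csv")
    if (file.exists(tf))
      tr <- utils::read.csv(tf, stringsAsFactors = FALSE)
  }
  FrameSequence(arr, frameRate = frameRate, truth = tr)
}
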