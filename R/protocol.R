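#' @include AllClasses.R AllGenerics.R
NULL

# RNG helpers -----------------------------------------------------------

# Derive a reproducible child seed from a master seed and integer keys.
# Linear-congruential mixing kept below 2^31 so seeds stay valid R integers.
.deriveSeed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483629
  for (k in c(...)) s <- (s * 69069 + as.double(k) + 1) %% 2147483629
  as.integer(s)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Constructors ----------------------------------------------------------

#' Create a PlatePair
#'
#' @param tLeft,tRight plate temperatures in degrees Celsius, within
#'   \[0, 45\] and distinct
#' @param sessionId positive integer session identifier
#' @return A [PlatePair-class] object.
#' @export
#' @examples
#' PlatePair(0, 5, sessionId = 1)
PlatePair <- function(tLeft, tRight, sessionId = 1L) {
  new("PlatePair", tLeft = as.numeric(tLeft), tRight = as.numeric(tRight),
      sessionId = as.integer(sessionId))
}

#' Create a SessionProtocol
#'
#' @param sessions list of [PlatePair] objects
#' @param durationS session duration in seconds
#' @param habituation logical, habituation day included
#' @return A [SessionProtocol-class] object.
#' @export
SessionProtocol <- function(sessions, durationS = 300, habituation = TRUE) {
  new("SessionProtocol", sessions = sessions,
      durationS = as.numeric(durationS), habituation = habituation)
}

#' Create an ArenaGeometry
#'
#' @param widthPx,heightPx image dimensions in pixels
#' @param midlineX first pixel column belonging to the right plate
#'   (half-open rule: column `c` is left iff `c < midlineX`); defaults to
#'   the image centre
#' @return An [ArenaGeometry-class] object.
#' @export
ArenaGeometry <- function(widthPx = 128L, heightPx = 64L,
                          midlineX = floor(widthPx / 2) + 1L) {
  new("ArenaGeometry", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), midlineX = as.integer(midlineX))
}

#' The standard nine-session 0-45 degree protocol
#'
#' Builds the canonical schedule of nine 5-minute sessions whose plate pairs
#' tile 0-45 degrees C in contiguous 5-degree steps: (0,5), (5,10), ...,
#' (40,45). With `randomizeSides = TRUE` the colder temperature of each pair
#' is assigned to the left or right plate by a seeded coin flip, emulating
#' random cooling/heating of the physical plates; otherwise the colder
#' temperature is always on the left.
#'
#' @param randomizeSides randomize which plate carries the colder temperature
#' @param seed integer seed used when `randomizeSides = TRUE`
#' @param durationS session duration in seconds (default 300)
#' @return A [SessionProtocol-class] with exactly 9 sessions.
#' @export
#' @examples
#' p <- standardProtocol()
#' length(sessions(p))
#' colderSide(sessions(p)[[1]])
standardProtocol <- function(randomizeSides = FALSE, seed = 1L,
                             durationS = 300) {
  lows <- seq(0, 40, by = 5)
  swap <- if (randomizeSides) {
    .withSeed(.deriveSeed(seed, 97L), runif(length(lows)) < 0.5)
  } else rep(FALSE, length(lows))
  sess <- lapply(seq_along(lows), function(i) {
    lo <- lows[i]; hi <- lows[i] + 5
    if (swap[i]) PlatePair(hi, lo, i) else PlatePair(lo, hi, i)
  })
  SessionProtocol(sess, durationS = durationS, habituation = TRUE)
}

# Accessors -------------------------------------------------------------

#' @describeIn PlatePair-class left plate temperature
#' @param x object
#' @export
setMethod("tLeft", "PlatePair", function(x) x@tLeft)

#' @describeIn PlatePair-class right plate temperature
#' @export
setMethod("tRight", "PlatePair", function(x) x@tRight)

#' @describeIn PlatePair-class session identifier
#' @export
setMethod("sessionId", "PlatePair", function(x) x@sessionId)

#' @describeIn PlatePair-class side ("left"/"right") holding the lower
#'   temperature; this is the starting plate of the session
#' @export
setMethod("colderSide", "PlatePair", function(x) {
  if (x@tLeft < x@tRight) "left" else "right"
})

#' @describeIn PlatePair-class side holding the higher temperature
#' @export
setMethod("warmerSide", "PlatePair", function(x) {
  if (x@tLeft > x@tRight) "left" else "right"
})

#' @describeIn SessionProtocol-class list of the protocol's [PlatePair]s
#' @param x object
#' @export
setMethod("sessions", "SessionProtocol", function(x) x@sessions)

#' @describeIn SessionProtocol-class session duration, seconds
#' @export
setMethod("durationS", "SessionProtocol", function(x) x@durationS)

setMethod("show", "PlatePair", function(object) {
  cat(sprintf("PlatePair [session %d]: left %g degC | right %g degC (colder: %s)\n",
              object@sessionId, object@tLeft, object@tRight,
              colderSide(object)))
})

setMethod("show", "SessionProtocol", function(object) {
  cat(sprintf("SessionProtocol: %d sessions, %g s each%s\n",
              length(object@sessions), object@durationS,
              if (object@habituation) ", with habituation" else ""))
  for (p in object@sessions)
    cat(sprintf("  session %d: left %g / right %g degC\n",
                p@sessionId, p@tLeft, p@tRight))
})

# Serialization ---------------------------------------------------------

#' Write / read a protocol as a plain-text YAML config
#'
#' The config stores one record per session (`session_id`, `t_left`,
#' `t_right`) plus `duration_s` and `habituation`, so a schedule can be
#' shared between the simulator and the tracker CLI.
#'
#' @param protocol a [SessionProtocol-class]
#' @param path file path of the YAML config
#' @return `readProtocolConfig` returns a [SessionProtocol-class];
#'   `writeProtocolConfig` returns `path` invisibly.
#' @export
writeProtocolConfig <- function(protocol, path) {
  stopifnot(is(protocol, "SessionProtocol"))
  obj <- list(
    duration_s = protocol@durationS,
    habituation = protocol@habituation,
    sessions = lapply(protocol@sessions, function(p)
      list(session_id = p@sessionId, t_left = p@tLeft, t_right = p@tRight)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeProtocolConfig
#' @export
readProtocolConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  sess <- lapply(obj$sessions, function(s)
    PlatePair(s$t_left, s$t_right, s$session_id))
  SessionProtocol(sess, durationS = obj$duration_s,
                  habituation = isTRUE(obj$habituation))
}
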