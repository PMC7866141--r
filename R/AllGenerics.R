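#' @include AllClasses.R
NULL

#' @export
setGeneric("tLeft", function(x) standardGeneric("tLeft"))
#' @export
setGeneric("tRight", function(x) standardGeneric("tRight"))
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @export
setGeneric("colderSide", function(x) standardGeneric("colderSide"))
#' @export
setGeneric("warmerSide", function(x) standardGeneric("warmerSide"))
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @export
setGeneric("pctColder", function(x) standardGeneric("pctColder"))
#' @export
setGeneric("pctLeft", function(x) standardGeneric("pctLeft"))
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @export
setGeneric("pAdj", function(x) standardGeneric("pAdj"))
#' @export
setGeneric("category", function(x) standardGeneric("category"))
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
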