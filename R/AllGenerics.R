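#' @rdname EventSet-class
#' @param x,object an object.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname EventSet-class
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname EventSet-class
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))

#' @rdname EventSet-class
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' @rdname EventSet-class
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' Raster of one channel of one event
#'
#' @param x an [EventSet-class].
#' @param i event index (position, not object id).
#' @param marker marker role, e.g. `"bf"`, `"cd41"`.
#' @return integer matrix of pixel values.
#' @export
setGeneric("eventRaster", function(x, i, marker) standardGeneric("eventRaster"))

#' @rdname PanelConfig-class
#' @param x a `PanelConfig`.
#' @param marker marker role name.
#' @export
setGeneric("channelOf", function(x, marker) standardGeneric("channelOf"))
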