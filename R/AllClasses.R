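#' @import methods
#' @importFrom stats median mad rnorm rpois runif rlnorm sd var quantile setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib mkflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Panel configuration
#'
#' Maps marker roles to detection channels and records acquisition geometry.
#' All pipeline operations address channels by marker role (\code{"bf"},
#' \code{"cd41"}, \code{"cd45"}, \code{"ssc"}, \code{"dump"}, \code{"dna"},
#' \code{"viability"}), never by hard-coded channel id, so the same analysis
#' runs on any instrument layout.
#'
#' @slot channels named character vector, marker role -> channel id.
#' @slot pixelSize micrometres per pixel (0.5 for a 40x ImageStream field).
#' @slot bitDepth pixel dynamic range in bits; 12 gives the 0--4095 range in
#'   which the saturation threshold 4030 is meaningful.
#' @export
setClass("PanelConfig",
  representation(channels = "character", pixelSize = "numeric",
                 bitDepth = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@channels)) || any(names(object@channels) == ""))
      msg <- c(msg, "channels must be a named character vector (marker -> channel)")
    if (anyDuplicated(object@channels))
      msg <- c(msg, "channel ids must be unique")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (!(object@bitDepth %in% c(8L, 12L, 16L)))
      msg <- c(msg, "bitDepth must be one of 8, 12, 16")
    if (length(msg)) msg else TRUE
  })

#' Multichannel event-image set
#'
#' One acquired object per event: co-registered per-channel pixel rasters,
#' acquisition time, and an object id. Optionally carries per-event
#' ground-truth class labels (synthetic data only).
#'
#' @slot panel a [PanelConfig-class].
#' @slot objectId integer vector of unique object ids.
#' @slot time numeric vector, seconds since acquisition start.
#' @slot rasters list (one element per event) of named lists of integer
#'   matrices keyed by channel id; all rasters of an event share dimensions.
#' @slot labels character vector of ground-truth classes, or length-0.
#' @export
setClass("EventSet",
  representation(panel = "PanelConfig", objectId = "integer",
                 time = "numeric", rasters = "list", labels = "character"),
  validity = function(object) {
    n <- length(object@objectId)
    msg <- character()
    if (anyDuplicated(object@objectId)) msg <- c(msg, "object ids must be unique")
    if (length(object@time) != n) msg <- c(msg, "time length != event count")
    if (length(object@rasters) != n) msg <- c(msg, "rasters length != event count")
    if (any(object@time < 0)) msg <- c(msg, "times must be >= 0")
    if (!(length(object@labels) %in% c(0L, n)))
      msg <- c(msg, "labels must be absent or cover every event")
    if (n > 0L) {
      maxv <- 2L^object@panel@bitDepth - 1L
      ok <- vapply(object@rasters, function(ev) {
        d <- vapply(ev, dim, integer(2L))
        all(d[1L, ] == d[1L, 1L]) && all(d[2L, ] == d[2L, 1L]) &&
          all(vapply(ev, function(m) min(m) >= 0L && max(m) <= maxv, logical(1L)))
      }, logical(1L))
      if (!all(ok))
        msg <- c(msg, "each event's rasters must share dimensions and lie in [0, 2^bitDepth - 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Estimated spillover matrix
#'
#' Square matrix whose (i, j) entry is the fraction of fluorophore-i signal
#' detected in channel j; diagonal fixed at 1.
#'
#' @slot matrix numeric square matrix with marker dimnames.
#' @slot markers character vector declaring the channel order.
#' @export
setClass("SpilloverMatrix",
  representation(matrix = "matrix", markers = "character"),
  validity = function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (nrow(m) != length(object@markers))
      msg <- c(msg, "marker names must match matrix dimension")
    if (any(m < 0)) msg <- c(msg, "spillover entries must be >= 0")
    if (any(abs(diag(m) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    inv <- tryCatch(solve(m), error = function(e) NULL)
    if (is.null(inv) || !all(is.finite(inv)))
      msg <- c(msg, "matrix must be invertible")
    if (length(msg)) msg else TRUE
  })

#' Boolean object mask
#'
#' @slot bits logical matrix, same shape as the event rasters.
#' @slot channel marker role the mask was derived from.
#' @slot kind `"default"` (Otsu, hole-filled, largest component) or
#'   `"morphology"` (closed and eroded by 1 px; tight boundary for size
#'   features).
#' @slot valid `FALSE` when the foreground was empty or below the minimum
#'   pixel count; downstream features are then undefined.
#' @export
setClass("Mask",
  representation(bits = "matrix", channel = "character", kind = "character",
                 valid = "logical"))

#' Linear-discriminant singlet classifier
#'
#' Two-class LDA on standardized morphometric features with the decision
#' boundary anchored at score 0 (singlets score positive).
#'
#' @slot features feature column names used.
#' @slot center,scale per-feature standardization.
#' @slot weights discriminant weight vector.
#' @slot offset score offset placing the class-mean midpoint at 0.
#' @slot scoreScale pooled within-class SD of raw scores (scores are divided
#'   by it, making the 0 boundary scale-free).
#' @export
setClass("SingletClassifier",
  representation(features = "character", center = "numeric", scale = "numeric",
                 weights = "numeric", offset = "numeric", scoreScale = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@weights))) return("weights must be finite")
    if (object@scoreScale <= 0) return("scoreScale must be positive")
    TRUE
  })

#' Fitted CNN classifier
#'
#' @slot weights list of weight arrays (conv kernels, biases, dense layer).
#' @slot spec the model specification list used at fit time (see
#'   [cnnModelSpec()]).
#' @slot classes class labels; element 2 is the positive (index-1) class.
#' @slot history per-epoch training/validation accuracy curves.
#' @export
setClass("CnnModel",
  representation(weights = "list", spec = "list", classes = "character",
                 history = "data.frame"))

#' Two-class confusion matrix
#'
#' @slot tp,fp,tn,fn nonnegative integer counts.
#' @slot positive name of the positive class.
#' @slot negative name of the negative class.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", positive = "character", negative = "character"),
  validity = function(object) {
    if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
      return("counts must be nonnegative")
    TRUE
  })

#' Gating cascade report
#'
#' @slot gates data.frame with one row per applied gate: name, input count,
#'   surviving count, fraction surviving.
#' @slot pass logical matrix, events x gates, cumulative pass flags.
#' @slot objectId object ids in row order of `pass`.
#' @slot terminalIds object ids of the terminal population.
#' @slot terminalDiameters BF diameters (um) of the terminal population.
#' @export
setClass("GatingReport",
  representation(gates = "data.frame", pass = "matrix", objectId = "integer",
                 terminalIds = "integer", terminalDiameters = "numeric"),
  validity = function(object) {
    s <- object@gates$surviving
    if (length(s) > 1L && any(diff(s) > 0L))
      return("survivor counts must be non-increasing along the cascade")
    if (any(abs(object@gates$fraction * object@gates$input -
                object@gates$surviving) > 1e-9))
      return("fraction must equal surviving/input")
    TRUE
  })

#' Classification metrics report
#'
#' Per-class precision/recall/F1 (percent, half-up to 1 dp), support-weighted
#' averages, overall accuracy (2 dp), and the row-/column-normalized views of
#' the confusion matrix (recall and precision views respectively).
#'
#' @slot table per-class and weighted-average metric rows.
#' @slot accuracy overall accuracy in percent (2 dp).
#' @slot rowNorm,colNorm normalized confusion-matrix views (proportions).
#' @slot cm the underlying [ConfusionMatrix-class].
#' @export
setClass("MetricsReport",
  representation(table = "data.frame", accuracy = "numeric",
                 rowNorm = "matrix", colNorm = "matrix", cm = "ConfusionMatrix"))
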