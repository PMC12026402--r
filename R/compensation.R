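# Spillover estimation by zero-intercept least squares on single-stain
# controls, and its inverse applied to per-event channel intensities.
# Compensation acts on scalar intensities, not per-pixel rasters: the gates
# consume intensities, and the raw-max-pixel feature is by contract always
# taken from the uncompensated rasters.

#' Estimate a spillover matrix from single-stain controls
#'
#' Entry (i, j) is the slope of the zero-intercept least-squares regression
#' of channel-j total intensity on channel-i total intensity over the
#' control-i events; the diagonal is forced to 1 and negative slopes are
#' clamped at 0 (spillover is physically nonnegative and proportional).
#'
#' @param controls named list, marker -> [EventSet-class] of single-stained
#'   events (or marker -> feature data.frame from [computeFeatures()]).
#' @param minEvents minimum events per control.
#' @return a [SpilloverMatrix-class] over the control markers.
#' @export
estimateSpillover <- function(controls, minEvents = 30L) {
  mk <- names(controls)
  if (is.null(mk) || length(mk) < 1L) stop("controls must be a named list")
  feats <- lapply(controls, function(x)
    if (is(x, "EventSet")) computeFeatures(x) else x)
  m <- diag(length(mk))
  dimnames(m) <- list(mk, mk)
  for (i in seq_along(mk)) {
    ft <- feats[[i]]
    if (nrow(ft) < minEvents)
      stop("control '", mk[i], "' has ", nrow(ft), " events; need >= ",
           minEvents)
    x <- ft[[paste0("intensity_", mk[i])]]
    if (!is.finite(var(x)) || var(x) == 0 || all(x == 0))
      stop("control '", mk[i], "' has constant primary intensity; ",
           "singular design")
    for (j in seq_along(mk)) {
      if (i == j) next
      y <- ft[[paste0("intensity_", mk[j])]]
      m[i, j] <- max(sum(x * y) / sum(x * x), 0)
    }
  }
  new("SpilloverMatrix", matrix = m, markers = mk)
}

#' Apply (inverse) compensation to a feature table
#'
#' Right-multiplies the per-event intensity vectors by the inverse of the
#' spillover matrix. Only `intensity_<marker>` columns for the matrix's
#' markers are touched; `raw_max_pixel_*` columns are never modified (they
#' are raw, pre-compensation features by definition). Negative compensated
#' intensities are floored at 0.
#'
#' @param x a feature data.frame from [computeFeatures()], or an
#'   [EventSet-class] (features are computed first).
#' @param spill a [SpilloverMatrix-class].
#' @return the compensated feature data.frame.
#' @export
applyCompensation <- function(x, spill) {
  stopifnot(is(spill, "SpilloverMatrix"))
  if (is(x, "EventSet")) x <- computeFeatures(x)
  m <- spill@matrix
  inv <- tryCatch(solve(m), error = function(e)
    stop("spillover matrix is singular"))
  cols <- paste0("intensity_", spill@markers)
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  comp <- as.matrix(x[, cols, drop = FALSE]) %*% inv
  comp[comp < 0] <- 0
  x[, cols] <- comp
  x
}

#' Read/write a spillover matrix as CSV
#'
#' CSV with a header row and first column of marker names.
#' @param spill a [SpilloverMatrix-class].
#' @param path file path.
#' @export
writeSpillover <- function(spill, path) {
  df <- data.frame(marker = spill@markers, spill@matrix,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpillover
#' @export
readSpillover <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$marker
  new("SpilloverMatrix", matrix = m, markers = df$marker)
}

setMethod("show", "SpilloverMatrix", function(object) {
  cat("SpilloverMatrix over", length(object@markers), "channels:\n")
  print(round(object@matrix, 4))
})
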