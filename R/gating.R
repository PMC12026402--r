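# The hierarchical gating cascade: stable flow -> unsaturated ->
# viable -> nucleated -> lymphocyte exclusion -> CD41+/dump- -> singlet
# (LDA score >= 0) -> focus (gradient RMS) -> CNN CD41+ classification,
# with per-gate attrition reporting.
#
# Gate placement that a cytometrist would do by eye is made explicit here:
# every threshold is a number or "auto" in the gate config. "auto" uses an
# Otsu valley on log1p intensities with a unimodality guard (if the two
# sides of the cut are separated by less than a configurable log-gap the
# population is treated as single and the gate keeps everything).

#' Gating cascade configuration
#'
#' Defaults follow the published workflow: raw-max-pixel saturation cutoff
#' 4030 (strict "below"), focus gate at gradient RMS > 55, singlet gate at
#' LDA score >= 0; the intensity gates default to automatic placement.
#'
#' @param saturation_max_raw_pixel events with any used channel at or above
#'   this raw pixel value are removed.
#' @param saturation_channels marker roles checked for saturation;
#'   `NULL` = every channel in the panel.
#' @param focus_min_gradient_rms keep events strictly above this BF
#'   gradient RMS.
#' @param singlet_min_score keep events with LDA score >= this value.
#' @param viability_max,dna_min,cd41_min,dump_max,cd45_min,ssc_max numeric
#'   thresholds or `"auto"`.
#' @param stable_flow `"auto"` (largest contiguous run of time bins whose
#'   event counts sit within a robust tolerance of the median bin count) or
#'   an explicit `c(t0, t1)` window in seconds.
#' @param auto_min_log_gap unimodality guard for "auto" thresholds.
#' @return a list of class `mkflow_gate_config`.
#' @export
gateConfig <- function(saturation_max_raw_pixel = 4030,
                       saturation_channels = NULL,
                       focus_min_gradient_rms = 55,
                       singlet_min_score = 0,
                       viability_max = "auto", dna_min = "auto",
                       cd41_min = "auto", dump_max = "auto",
                       cd45_min = "auto", ssc_max = "auto",
                       stable_flow = "auto",
                       auto_min_log_gap = 1.5) {
  cfg <- as.list(environment())
  num <- cfg[c("saturation_max_raw_pixel", "focus_min_gradient_rms",
               "singlet_min_score", "auto_min_log_gap")]
  if (!all(vapply(num, function(v) is.numeric(v) && is.finite(v),
                  logical(1L))))
    stop("fixed thresholds must be finite numbers")
  class(cfg) <- "mkflow_gate_config"
  cfg
}

resolveThreshold <- function(value, intensities, cfg) {
  if (identical(value, "auto")) autoLogThreshold(intensities,
                                                cfg$auto_min_log_gap)
  else as.numeric(value)
}

#' Stable-flow gate
#'
#' Auto mode bins the event times and keeps the largest contiguous run of
#' bins whose counts lie within `max(3 * mad, median)` of the median bin
#' count; explicit mode keeps events inside the given time window.
#'
#' @param features feature table (needs `time_s` and `object_id`).
#' @param cfg a [gateConfig()].
#' @return surviving object ids.
#' @export
gateStableFlow <- function(features, cfg = gateConfig()) {
  t <- features$time_s
  if (!identical(cfg$stable_flow, "auto")) {
    w <- cfg$stable_flow
    return(features$object_id[t >= w[1L] & t <= w[2L]])
  }
  n <- length(t)
  nb <- max(8L, min(40L, floor(n / 15)))
  if (n < 2L || diff(range(t)) == 0) {
    warning("too few time bins; keeping all events")
    return(features$object_id)
  }
  br <- seq(min(t), max(t), length.out = nb + 1L)
  bin <- findInterval(t, br, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nb)
  med <- median(counts)
  # robust band around the median bin count; the Poisson floor keeps
  # ordinary counting noise from fragmenting a steady acquisition
  tol <- max(3 * mad(counts), 2 * sqrt(med) + 1)
  good <- abs(counts - med) <= tol
  # largest contiguous run of good bins
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  if (!length(gi)) {
    warning("no stable time span found; keeping all events")
    return(features$object_id)
  }
  best <- gi[which.max(r$lengths[gi])]
  keep <- bin >= starts[best] & bin <= ends[best]
  features$object_id[keep]
}

#' Saturation gate
#'
#' Keeps events whose raw max pixel is strictly below the cutoff in every
#' checked channel ("below 4030").
#'
#' @inheritParams gateStableFlow
#' @return surviving object ids.
#' @export
gateUnsaturated <- function(features, cfg = gateConfig()) {
  chans <- cfg$saturation_channels
  if (is.null(chans))
    chans <- sub("^raw_max_pixel_", "",
                 grep("^raw_max_pixel_", names(features), value = TRUE))
  cols <- paste0("raw_max_pixel_", chans)
  m <- as.matrix(features[, cols, drop = FALSE])
  keep <- apply(m < cfg$saturation_max_raw_pixel, 1L, all)
  features$object_id[keep]
}

#' Live and nucleated gate
#'
#' Viability intensity at or below its threshold AND DNA intensity above
#' its threshold (negative-to-low viability dye, DNA-dye positive).
#'
#' @inheritParams gateStableFlow
#' @return surviving object ids.
#' @export
gateLiveNucleated <- function(features, cfg = gateConfig()) {
  ids <- gateViable(features, cfg)
  f2 <- features[features$object_id %in% ids, , drop = FALSE]
  gateNucleated(f2, cfg)
}

gateViable <- function(features, cfg) {
  v <- features$intensity_viability
  tv <- resolveThreshold(cfg$viability_max, v, cfg)
  keep <- if (is.na(tv)) rep(TRUE, length(v)) else v <= tv
  features$object_id[keep]
}

gateNucleated <- function(features, cfg) {
  d <- features$intensity_dna
  td <- resolveThreshold(cfg$dna_min, d, cfg)
  keep <- if (is.na(td)) rep(TRUE, length(d)) else d > td
  features$object_id[keep]
}

#' Lymphocyte exclusion gate
#'
#' Removes events inside the CD45-high/SSC-low exclusion rectangle
#' (CD45 > t_cd45 AND SSC < t_ssc). If either auto threshold finds no
#' second population nothing is removed.
#'
#' @inheritParams gateStableFlow
#' @return surviving object ids.
#' @export
gateExcludeLymphocytes <- function(features, cfg = gateConfig()) {
  cd45 <- features$intensity_cd45
  ssc <- features$intensity_ssc
  t45 <- resolveThreshold(cfg$cd45_min, cd45, cfg)
  tss <- resolveThreshold(cfg$ssc_max, ssc, cfg)
  if (is.na(t45) || is.na(tss)) return(features$object_id)
  remove <- cd45 > t45 & ssc < tss
  features$object_id[!remove]
}

#' CD41-positive, dump-negative gate
#'
#' Keeps events positive for the MK lineage marker and negative for all
#' pooled dump-channel markers.
#'
#' @inheritParams gateStableFlow
#' @return surviving object ids.
#' @export
gateCD41Dump <- function(features, cfg = gateConfig()) {
  cd41 <- features$intensity_cd41
  dump <- features$intensity_dump
  t41 <- resolveThreshold(cfg$cd41_min, cd41, cfg)
  td <- resolveThreshold(cfg$dump_max, dump, cfg)
  keep41 <- if (is.na(t41)) rep(TRUE, length(cd41)) else cd41 > t41
  keepd <- if (is.na(td)) rep(TRUE, length(dump)) else dump <= td
  features$object_id[keep41 & keepd]
}

#' Focus gate
#'
#' Keeps events with BF gradient RMS strictly above the focus threshold.
#'
#' @inheritParams gateStableFlow
#' @return surviving object ids.
#' @export
gateFocus <- function(features, cfg = gateConfig()) {
  g <- features$gradient_rms_bf
  g[is.na(g)] <- -Inf
  features$object_id[g > cfg$focus_min_gradient_rms]
}

gateSinglet <- function(features, cfg, classifier) {
  if (is.null(classifier))
    stop("singlet stage enabled but no singlet classifier supplied")
  keep <- if (is.function(classifier)) classifier(features)
          else singletScore(classifier, features) >= cfg$singlet_min_score
  features$object_id[keep]
}

gateCnn <- function(features, cfg, cnn, events) {
  if (is.null(cnn))
    stop("CNN stage enabled but no CNN classifier supplied")
  if (is.function(cnn)) return(features$object_id[cnn(features)])
  idx <- match(features$object_id, objectIds(events))
  crops <- extractCrops(events[idx])
  pred <- predictCNN(cnn, crops$x)
  features$object_id[pred$label == "cd41_pos"]
}

#' Run the full gating cascade
#'
#' Applies the gates in the published order and reports per-gate attrition.
#' The viability/DNA step is reported as two sub-gates ("viable",
#' "nucleated"). The singlet and CNN stages accept either a fitted
#' classifier ([SingletClassifier-class] / [CnnModel-class]) or a function
#' of the surviving feature rows returning a logical keep vector (an oracle
#' stand-in in tests); the CNN stage runs only when a classifier is
#' supplied or explicitly requested.
#'
#' @param events an [EventSet-class] (needed for the CNN stage; may be
#'   `NULL` when `features` is given and the CNN stage is disabled or an
#'   oracle function).
#' @param features feature table; computed from `events` when `NULL`.
#' @param singlet singlet classifier, oracle function, or `NULL`.
#' @param cnn CNN classifier, oracle function, or `NULL` (stage skipped).
#' @param cfg a [gateConfig()].
#' @param gates character vector of gate names to apply, in order.
#' @return a [GatingReport-class].
#' @export
runCascade <- function(events = NULL, features = NULL, singlet = NULL,
                       cnn = NULL, cfg = gateConfig(),
                       gates = c("stable_flow", "unsaturated", "viable",
                                 "nucleated", "lymphocytes", "cd41_dump",
                                 "singlet", "focus",
                                 if (!is.null(cnn)) "cnn")) {
  if (is.null(features)) {
    if (is.null(events)) stop("either events or features must be supplied")
    features <- computeFeatures(events)
  }
  n0 <- nrow(features)
  ids <- features$object_id
  gateRows <- data.frame(gate = character(), input = integer(),
                         surviving = integer(), fraction = numeric())
  pass <- matrix(TRUE, n0, 0L, dimnames = list(NULL, NULL))
  cur <- ids
  for (g in gates) {
    fsub <- features[features$object_id %in% cur, , drop = FALSE]
    surv <- if (nrow(fsub) == 0L) integer() else switch(g,
      stable_flow = gateStableFlow(fsub, cfg),
      unsaturated = gateUnsaturated(fsub, cfg),
      viable = gateViable(fsub, cfg),
      nucleated = gateNucleated(fsub, cfg),
      live_nucleated = gateLiveNucleated(fsub, cfg),
      lymphocytes = gateExcludeLymphocytes(fsub, cfg),
      cd41_dump = gateCD41Dump(fsub, cfg),
      singlet = gateSinglet(fsub, cfg, singlet),
      focus = gateFocus(fsub, cfg),
      cnn = gateCnn(fsub, cfg, cnn, events),
      stop("unknown gate: ", g))
    inN <- length(cur); outN <- length(surv)
    gateRows <- rbind(gateRows, data.frame(
      gate = g, input = inN, surviving = outN,
      fraction = if (inN > 0L) outN / inN else 0))
    pass <- cbind(pass, ids %in% surv)
    colnames(pass)[ncol(pass)] <- g
    cur <- surv
  }
  dia <- if ("diameter_um_bf" %in% names(features))
    features$diameter_um_bf[features$object_id %in% cur]
  else numeric()
  new("GatingReport", gates = gateRows, pass = pass,
      objectId = as.integer(ids), terminalIds = as.integer(cur),
      terminalDiameters = as.numeric(dia[!is.na(dia)]))
}

setMethod("show", "GatingReport", function(object) {
  cat("GatingReport:", nrow(object@gates), "gates,",
      length(object@objectId), "events in,",
      length(object@terminalIds), "terminal\n")
  df <- object@gates
  df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
  print(df, row.names = FALSE)
})

#' Serialize a gating report to JSON
#'
#' @param report a [GatingReport-class].
#' @param path output path.
#' @param meta named list of provenance fields stored alongside the counts.
#' @export
writeGatingReport <- function(report, path, meta = list()) {
  obj <- c(meta, list(
    gates = report@gates,
    terminal_ids = report@terminalIds,
    terminal_diameters_um = report@terminalDiameters))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
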