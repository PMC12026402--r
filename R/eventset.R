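#' Construct an EventSet
#'
#' @param panel a [PanelConfig-class].
#' @param rasters list (one per event) of named lists of integer matrices
#'   keyed by channel id.
#' @param time numeric acquisition times in seconds.
#' @param objectId integer ids; defaults to `0:(n-1)`.
#' @param labels optional per-event ground-truth class labels.
#' @return an [EventSet-class].
#' @export
eventSet <- function(panel, rasters, time, objectId = NULL, labels = NULL) {
  n <- length(rasters)
  if (is.null(objectId)) objectId <- seq_len(n) - 1L
  new("EventSet", panel = panel, objectId = as.integer(objectId),
      time = as.numeric(time), rasters = rasters,
      labels = if (is.null(labels)) character() else as.character(labels))
}

#' @rdname EventSet-class
#' @export
setMethod("nEvents", "EventSet", function(x) length(x@objectId))

#' @rdname EventSet-class
#' @export
setMethod("objectIds", "EventSet", function(x) x@objectId)

#' @rdname EventSet-class
#' @export
setMethod("eventTimes", "EventSet", function(x) x@time)

#' @rdname EventSet-class
#' @export
setMethod("eventLabels", "EventSet", function(x) x@labels)

#' @rdname EventSet-class
#' @export
setMethod("panel", "EventSet", function(x) x@panel)

#' @rdname eventRaster
#' @export
setMethod("eventRaster", "EventSet", function(x, i, marker) {
  ch <- channelOf(x@panel, marker)
  r <- x@rasters[[i]][[ch]]
  if (is.null(r)) stop("event ", x@objectId[i], ": missing channel ", ch)
  r
})

#' Subset an EventSet by event position
#'
#' @param x an [EventSet-class].
#' @param i integer positions.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EventSet", function(x, i, j, ..., drop = FALSE) {
  new("EventSet", panel = x@panel, objectId = x@objectId[i],
      time = x@time[i], rasters = x@rasters[i],
      labels = if (length(x@labels)) x@labels[i] else character())
})

setMethod("show", "EventSet", function(object) {
  cat("EventSet:", nEvents(object), "events,",
      length(object@panel@channels), "channels")
  if (nEvents(object) > 0L) {
    d <- dim(object@rasters[[1L]][[1L]])
    cat(",", paste(d, collapse = "x"), "px")
  }
  if (length(object@labels))
    cat("; labeled (", paste(names(table(object@labels)), collapse = ", "),
        ")", sep = "")
  cat("\n")
})

# ---- gallery I/O -----------------------------------------------------------
# Interchange format: a directory with index.csv (object_id, time_s, channel,
# file, page), one 16-bit multipage TIFF holding all rasters, panel.json, and
# truth.csv when labels are present. Round-trips are pixel-exact.

#' Save an event gallery
#'
#' Writes `index.csv`, a 16-bit multipage `gallery.tif`, `panel.json` and
#' (when labels are present) `labels.csv` under `path`.
#' [loadEventSet()] inverts this bit-exactly.
#'
#' @param events an [EventSet-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
saveEventSet <- function(events, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L)
    stop("gallery path is not writable: ", path)
  chans <- unname(events@panel@channels)
  n <- nEvents(events)
  pages <- vector("list", n * length(chans))
  idx <- data.frame(object_id = integer(), time_s = numeric(),
                    channel = character(), file = character(),
                    page = integer())
  k <- 0L
  for (i in seq_len(n)) {
    for (ch in chans) {
      k <- k + 1L
      pages[[k]] <- events@rasters[[i]][[ch]] / 65535
      idx <- rbind(idx, data.frame(
        object_id = events@objectId[i], time_s = events@time[i],
        channel = ch, file = "gallery.tif", page = k))
    }
  }
  if (k > 0L)
    tiff::writeTIFF(pages[seq_len(k)], file.path(path, "gallery.tif"),
                    bits.per.sample = 16L)
  write.csv(idx, file.path(path, "index.csv"), row.names = FALSE)
  writePanelConfig(events@panel, file.path(path, "panel.json"))
  if (length(events@labels))
    write.csv(data.frame(object_id = events@objectId, class = events@labels),
              file.path(path, "labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Load an event gallery
#'
#' @param path gallery directory written by [saveEventSet()].
#' @param panel optional [PanelConfig-class]; defaults to the `panel.json`
#'   stored in the gallery.
#' @return an [EventSet-class] in index order.
#' @export
loadEventSet <- function(path, panel = NULL) {
  if (!dir.exists(path)) stop("gallery path does not exist: ", path)
  idxPath <- file.path(path, "index.csv")
  if (!file.exists(idxPath)) stop("missing index.csv in ", path)
  if (is.null(panel)) panel <- readPanelConfig(file.path(path, "panel.json"))
  idx <- read.csv(idxPath, stringsAsFactors = FALSE)
  tiffCache <- new.env(parent = emptyenv())
  getPage <- function(f, page, oid, ch) {
    if (!exists(f, envir = tiffCache)) {
      fp <- file.path(path, f)
      if (!file.exists(fp))
        stop("event ", oid, " channel ", ch, ": TIFF file not found: ", f)
      assign(f, tiff::readTIFF(fp, all = TRUE, as.is = TRUE), envir = tiffCache)
    }
    pgs <- get(f, envir = tiffCache)
    if (page < 1L || page > length(pgs))
      stop("event ", oid, " channel ", ch, ": TIFF page ", page,
           " not found in ", f)
    m <- pgs[[page]]
    storage.mode(m) <- "integer"
    m
  }
  oids <- unique(idx$object_id)
  rasters <- vector("list", length(oids))
  time <- numeric(length(oids))
  for (i in seq_along(oids)) {
    rows <- idx[idx$object_id == oids[i], , drop = FALSE]
    time[i] <- rows$time_s[1L]
    ev <- lapply(seq_len(nrow(rows)), function(r)
      getPage(rows$file[r], rows$page[r], oids[i], rows$channel[r]))
    names(ev) <- rows$channel
    d <- vapply(ev, dim, integer(2L))
    if (any(d[1L, ] != d[1L, 1L]) || any(d[2L, ] != d[2L, 1L]))
      stop("event ", oids[i], ": raster dimension mismatch across channels")
    rasters[[i]] <- ev
  }
  labels <- NULL
  labPath <- file.path(path, "labels.csv")
  if (file.exists(labPath)) {
    lab <- read.csv(labPath, stringsAsFactors = FALSE)
    labels <- lab$class[match(oids, lab$object_id)]
  }
  eventSet(panel, rasters, time, objectId = oids, labels = labels)
}

# ---- FCS export ------------------------------------------------------------

#' Export a feature table as FCS 3.1
#'
#' Writes a minimal, standards-conforming FCS 3.1 file (list mode, float32,
#' little-endian) with one parameter per numeric feature column, so gated
#' feature tables can be opened in conventional cytometry software.
#'
#' @param table a feature table ([computeFeatures()]) or any data.frame of
#'   numeric columns.
#' @param path output file.
#' @param columns columns to export; defaults to all numeric columns.
#' @return `path`, invisibly.
#' @export
exportFeaturesFCS <- function(table, path, columns = NULL) {
  if (nrow(table) == 0L) stop("cannot export an empty feature table")
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1L))]
  mat <- as.matrix(table[, columns, drop = FALSE])
  storage.mode(mat) <- "double"
  if (ncol(mat) == 0L) stop("no numeric columns to export")
  npar <- ncol(mat); ntot <- nrow(mat)
  dataBytes <- ntot * npar * 4L

  mkText <- function(beginData, endData) {
    kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", as.character(beginData),
            "$ENDDATA", as.character(endData),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0", "$TOT", as.character(ntot),
            "$PAR", as.character(npar))
    for (j in seq_len(npar)) {
      rng <- max(1, ceiling(max(mat[, j], na.rm = TRUE)))
      kw <- c(kw, sprintf("$P%dN", j), colnames(mat)[j],
              sprintf("$P%dB", j), "32", sprintf("$P%dE", j), "0,0",
              sprintf("$P%dR", j), as.character(rng))
    }
    paste0("/", paste(kw, collapse = "/"), "/")
  }
  # offsets depend on the TEXT length; iterate to a fixed point
  textBegin <- 58L
  beginData <- 0L; endData <- 0L
  for (pass in 1:4) {
    txt <- mkText(beginData, endData)
    newBegin <- textBegin + nchar(txt, type = "bytes")
    newEnd <- newBegin + dataBytes - 1L
    if (newBegin == beginData && newEnd == endData) break
    beginData <- newBegin; endData <- newEnd
  }
  txt <- mkText(beginData, endData)
  textEnd <- textBegin + nchar(txt, type = "bytes") - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    textBegin, textEnd, beginData, endData, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
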