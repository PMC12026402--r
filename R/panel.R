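#' Construct a panel configuration
#'
#' The default layout follows the MK imaging-flow-cytometry panel:
#' brightfield in Ch01, CD41 PE in Ch03, SSC/darkfield in Ch06, CD45 in
#' Ch08, the dump channel (CD3/CD19/CD15/CD64) in Ch10, DNA (DRAQ5) in
#' Ch11 and the viability dye in Ch12, acquired at 40x (0.5 um pixels).
#'
#' @param channels named character vector, marker role -> channel id.
#' @param pixelSize micrometres per pixel.
#' @param bitDepth pixel bit depth (8, 12 or 16). The default 12-bit range
#'   (0--4095) is the one in which the standard saturation cutoff of 4030
#'   raw counts is expressed; it remains configurable.
#' @return a [PanelConfig-class].
#' @export
#' @examples
#' p <- panelConfig()
#' channelOf(p, "cd41")
panelConfig <- function(channels = c(bf = "Ch01", cd41 = "Ch03", ssc = "Ch06",
                                     cd45 = "Ch08", dump = "Ch10",
                                     dna = "Ch11", viability = "Ch12"),
                        pixelSize = 0.5, bitDepth = 12L) {
  new("PanelConfig", channels = channels, pixelSize = as.numeric(pixelSize),
      bitDepth = as.integer(bitDepth))
}

#' @rdname PanelConfig-class
#' @export
setMethod("channelOf", "PanelConfig", function(x, marker) {
  if (!marker %in% names(x@channels))
    stop("unknown marker role: ", marker)
  unname(x@channels[[marker]])
})

#' @rdname PanelConfig-class
#' @export
markers <- function(x) names(x@channels)

#' Read/write panel configuration as YAML or JSON
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @param x a [PanelConfig-class] (for writing).
#' @return [readPanelConfig()] returns a [PanelConfig-class].
#' @export
readPanelConfig <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  panelConfig(channels = unlist(lst$channels),
              pixelSize = lst$pixel_size_um, bitDepth = lst$bit_depth)
}

#' @rdname readPanelConfig
#' @export
writePanelConfig <- function(x, path) {
  lst <- list(channels = as.list(x@channels),
              pixel_size_um = x@pixelSize, bit_depth = x@bitDepth)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig:", length(object@channels), "channels;",
      object@pixelSize, "um/px;", object@bitDepth, "bit\n")
  cat(" ", paste0(names(object@channels), "=", object@channels,
                  collapse = " "), "\n")
})
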