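# Crop extraction and truth-set handling for the CNN stage. Classification
# is based solely on the brightfield and CD41 images; crops are resampled
# to a fixed input size with aspect-preserving padding and per-channel
# min-max normalization, so the network judges the signal pattern while
# cell size is handled by morphometry.

#' Extract BF + CD41 crops from an event set
#'
#' Crops the bounding box of the brightfield default mask (whole frame when
#' the mask is invalid), pads it to a square, resizes bilinearly to
#' `size x size`, and min-max normalizes each channel per crop to \[0, 1\].
#'
#' @param events an [EventSet-class].
#' @param size output side length in px.
#' @param channels marker roles to stack (order preserved).
#' @param pad margin in px around the mask bounding box.
#' @return list with `x` (array `n x size x size x length(channels)`) and
#'   `object_id`.
#' @export
extractCrops <- function(events, size = 64L, channels = c("bf", "cd41"),
                         pad = 4L) {
  n <- nEvents(events)
  x <- array(0, dim = c(n, size, size, length(channels)))
  for (i in seq_len(n)) {
    mask <- computeMask(events, i, "bf", kind = "default")
    ref <- eventRaster(events, i, channels[1L])
    if (mask@valid) {
      idx <- which(mask@bits, arr.ind = TRUE)
      r0 <- max(1L, min(idx[, 1L]) - pad); r1 <- min(nrow(ref), max(idx[, 1L]) + pad)
      c0 <- max(1L, min(idx[, 2L]) - pad); c1 <- min(ncol(ref), max(idx[, 2L]) + pad)
    } else {
      r0 <- 1L; r1 <- nrow(ref); c0 <- 1L; c1 <- ncol(ref)
    }
    h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
    side <- max(h, w)
    for (k in seq_along(channels)) {
      m <- eventRaster(events, i, channels[k])[r0:r1, c0:c1, drop = FALSE]
      sq <- matrix(median(m), side, side)
      ro <- (side - h) %/% 2L; co <- (side - w) %/% 2L
      sq[ro + seq_len(h), co + seq_len(w)] <- m
      rs <- EBImage::resize(sq, w = size, h = size)
      rng <- range(rs)
      x[i, , , k] <- if (rng[2L] > rng[1L]) (rs - rng[1L]) / (rng[2L] - rng[1L])
                     else 0
    }
  }
  list(x = x, object_id = objectIds(events))
}

#' Build a labeled CNN truth set from a synthetic gallery
#'
#' Maps ground-truth classes to the two CNN classes: megakaryocytic events
#' (`mk`, `micro_mk`) become `cd41_pos`; platelet-decorated CD41-negative
#' events (`platelet_adherent`) become `cd41_neg`. Other classes are
#' dropped (the cascade removes them before the CNN stage).
#'
#' @param events a labeled [EventSet-class].
#' @param size,channels crop parameters, see [extractCrops()].
#' @return list of class `mkflow_truth_set`: `x`, `labels` (factor
#'   cd41_neg/cd41_pos), `object_id`.
#' @export
makeTruthSet <- function(events, size = 64L, channels = c("bf", "cd41")) {
  lab <- eventLabels(events)
  if (!length(lab)) stop("event set carries no ground-truth labels")
  cls <- ifelse(lab %in% c("mk", "micro_mk"), "cd41_pos",
         ifelse(lab == "platelet_adherent", "cd41_neg", NA_character_))
  keep <- which(!is.na(cls))
  crops <- extractCrops(events[keep], size = size, channels = channels)
  out <- list(x = crops$x,
              labels = factor(cls[keep], levels = c("cd41_neg", "cd41_pos")),
              object_id = crops$object_id)
  class(out) <- "mkflow_truth_set"
  out
}

#' Subset a truth set by index
#'
#' @param truth a truth set from [makeTruthSet()].
#' @param idx integer indices (e.g. a partition from [splitTruthSet()]).
#' @return the subsetted truth set.
#' @export
subsetTruthSet <- function(truth, idx) {
  out <- list(x = truth$x[idx, , , , drop = FALSE],
              labels = truth$labels[idx],
              object_id = truth$object_id[idx])
  class(out) <- "mkflow_truth_set"
  out
}

#' Stratified train/validation/test split
#'
#' Random partition stratified by class label with largest-remainder
#' rounding per class (an exact nominal split is not always achievable for
#' arbitrary counts; realized fractions are reported alongside the nominal
#' ratios). Reproducible under the seed.
#'
#' @param truth a truth set from [makeTruthSet()], or a factor/character
#'   label vector.
#' @param ratios nominal train/validation/test proportions, summing to 1.
#' @param seed RNG seed.
#' @return list with `train`, `validation`, `test` (integer index vectors),
#'   `counts`, and `realized_pct` (1 dp).
#' @export
splitTruthSet <- function(truth, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  labels <- if (inherits(truth, "mkflow_truth_set")) truth$labels
            else as.factor(truth)
  parts <- list(train = integer(), validation = integer(), test = integer())
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      alloc <- largestRemainder(length(idx), ratios)
      cuts <- cumsum(alloc)
      parts$train <- c(parts$train, idx[seq_len(alloc[1L])])
      if (alloc[2L] > 0L)
        parts$validation <- c(parts$validation, idx[(cuts[1L] + 1L):cuts[2L]])
      if (alloc[3L] > 0L)
        parts$test <- c(parts$test, idx[(cuts[2L] + 1L):cuts[3L]])
    }
  })
  parts <- lapply(parts, sort)
  counts <- vapply(parts, length, integer(1L))
  parts$counts <- counts
  parts$realized_pct <- realizedFractions(counts)
  parts
}

largestRemainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- exact - base
  extra <- n - sum(base)
  if (extra > 0L) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  as.integer(base)
}

#' Realized partition fractions
#'
#' Percentages (half-up, 1 dp) of each partition count over the total;
#' e.g. counts (610, 92, 92) of 794 give 76.8/11.6/11.6.
#'
#' @param counts integer partition sizes.
#' @return named numeric percentages.
#' @export
realizedFractions <- function(counts) {
  halfUp(100 * counts / sum(counts), 1)
}

#' Combine truth sets
#'
#' @param ... truth sets from [makeTruthSet()].
#' @return one truth set with concatenated crops and labels.
#' @export
combineTruthSets <- function(...) {
  parts <- list(...)
  x <- do.call(abind4, lapply(parts, `[[`, "x"))
  out <- list(x = x,
              labels = factor(unlist(lapply(parts, function(p)
                as.character(p$labels))), levels = c("cd41_neg", "cd41_pos")),
              object_id = unlist(lapply(parts, function(p) p$object_id)))
  class(out) <- "mkflow_truth_set"
  out
}

abind4 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1L)))
  out <- array(0, dim = c(n, d[2L], d[3L], d[4L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[at + seq_len(k), , , ] <- a
    at <- at + k
  }
  out
}

#' Build the standard synthetic CNN benchmark truth set
#'
#' Renders `nPos` megakaryocytic events (85% MK, 15% microMK) and `nNeg`
#' platelet-decorated CD41-negative events at default rendering difficulty,
#' all in focus and unsaturated, and returns the combined labeled crop set.
#' The default sizes mirror a truth-set tally of 794 = 412 + 382.
#'
#' @param nPos,nNeg class sizes.
#' @param seed RNG seed.
#' @param size crop side length.
#' @return a truth set (see [makeTruthSet()]).
#' @export
makeCnnBenchmarkTruthSet <- function(nPos = 412L, nNeg = 382L, seed = 1L,
                                     size = 64L) {
  clean <- function(mix, n, s)
    generateEventSet(syntheticConfig(n_events = n, class_mixture = mix,
                                     defocus_fraction = 0,
                                     saturated_fraction = 0,
                                     flow_instability = 0, seed = s))$events
  pos <- clean(c(mk = 0.85, micro_mk = 0.15), as.integer(nPos), seed)
  neg <- clean(c(platelet_adherent = 1), as.integer(nNeg), seed + 1L)
  ts <- combineTruthSets(makeTruthSet(pos, size = size),
                         makeTruthSet(neg, size = size))
  ts$object_id <- seq_along(ts$labels) - 1L
  ts
}
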