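# Parametric renderer of ground-truth-labeled synthetic IFC event galleries.
# The generator emulates every phenotype the gating cascade and the CNN must
# handle: megakaryocytes (MKs) and micromegakaryocytes with a spotted CD41
# membrane-perimeter signal, CD41- cells carrying 1-4 bright adherent
# platelet spots, lymphocytes (CD45-high/SSC-low, dump-positive), dead cells
# (viability-dye-positive), anucleate events, touching-disc doublets,
# out-of-focus events, pixel-saturated events and an unstable-flow burst.

#' Synthetic gallery configuration
#'
#' Defaults encode the study conditions the generator emulates: MK diameters
#' log-normal with median 22.5 um truncated to 10.5--51.5 um,
#' micromegakaryocytes uniform on 7--15 um, 1--4 adherent ~2 um platelet
#' spots on CD41-negative cells, 8--24 membrane spots on true CD41+ cells,
#' and a 120x120 px canvas at 0.5 um/px (the 40x, 60-um field of view).
#'
#' @param n_events number of events to generate.
#' @param class_mixture named proportions over
#'   `mk, micro_mk, platelet_adherent, lymphocyte, dead, anucleate, doublet`;
#'   must sum to 1.
#' @param mk_diameter_um list with `meanlog`, `sdlog`, `min`, `max`.
#' @param micro_mk_diameter_um uniform range in um.
#' @param platelet_spots integer range of adherent platelet spots.
#' @param platelet_spot_diameter_um spot FWHM in um.
#' @param membrane_spot_count integer range of membrane-perimeter spots.
#' @param defocus_fraction fraction of events rendered out of focus.
#' @param blur_sigma defocus Gaussian sigma in px.
#' @param saturated_fraction fraction of events with a pixel-saturated
#'   CD41 blob.
#' @param read_noise_sd Gaussian read-noise SD (counts); Poisson shot noise
#'   is always applied unless `poisson_noise = FALSE`.
#' @param poisson_noise logical.
#' @param flow_instability fraction of events forced into a short
#'   elevated-rate time window near the start of acquisition.
#' @param instability_window seconds, the unstable window.
#' @param duration_s acquisition duration.
#' @param canvas_px square canvas side.
#' @param seed integer RNG seed; generation is a pure function of
#'   (config, seed).
#' @return a validated list of class `mkflow_synth_config`.
#' @export
syntheticConfig <- function(n_events = 500L,
                            class_mixture = c(mk = 0.25, micro_mk = 0.05,
                                              platelet_adherent = 0.20,
                                              lymphocyte = 0.20, dead = 0.10,
                                              anucleate = 0.10, doublet = 0.10),
                            mk_diameter_um = list(meanlog = log(22.5),
                                                  sdlog = 0.32,
                                                  min = 10.5, max = 51.5),
                            micro_mk_diameter_um = c(7, 15),
                            platelet_spots = c(1L, 4L),
                            platelet_spot_diameter_um = 2,
                            membrane_spot_count = c(8L, 24L),
                            defocus_fraction = 0.08, blur_sigma = 3,
                            saturated_fraction = 0.05,
                            read_noise_sd = 25, poisson_noise = TRUE,
                            flow_instability = 0.05,
                            instability_window = c(2, 3),
                            duration_s = 100, canvas_px = 120L,
                            seed = 1L) {
  cfg <- as.list(environment())
  known <- c("mk", "micro_mk", "platelet_adherent", "lymphocyte", "dead",
             "anucleate", "doublet")
  if (!all(names(class_mixture) %in% known))
    stop("unknown class in mixture: ",
         paste(setdiff(names(class_mixture), known), collapse = ", "))
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("class mixture proportions must sum to 1")
  fr <- c(defocus_fraction, saturated_fraction, flow_instability)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (mk_diameter_um$min <= 0 || mk_diameter_um$min >= mk_diameter_um$max)
    stop("diameter bounds must be positive and ordered")
  class(cfg) <- "mkflow_synth_config"
  cfg
}

# per-class fluorescence amplitudes (counts/px); chosen so that summed,
# background-subtracted intensities separate the populations on a log scale
# the way the gating panel expects (CD45-high/SSC-low lymphocytes, bright
# viability signal on dead cells, dump-positive lymphocytes, CD41 spots only
# on MK-lineage or platelet-decorated events).
.classAmps <- list(
  mk                = c(cd45 = 40,  ssc = 900, dump = 10,  viability = 15),
  micro_mk          = c(cd45 = 40,  ssc = 900, dump = 10,  viability = 15),
  doublet           = c(cd45 = 40,  ssc = 900, dump = 10,  viability = 15),
  platelet_adherent = c(cd45 = 60,  ssc = 900, dump = 10,  viability = 15),
  lymphocyte        = c(cd45 = 3000, ssc = 100, dump = 1800, viability = 15),
  dead              = c(cd45 = 60,  ssc = 700, dump = 10,  viability = 2600),
  anucleate         = c(cd45 = 40,  ssc = 900, dump = 10,  viability = 15))

.synthClasses <- names(.classAmps)

drawDiameter <- function(class, cfg) {
  switch(class,
    mk = {
      repeat {
        d <- rlnorm(1L, cfg$mk_diameter_um$meanlog, cfg$mk_diameter_um$sdlog)
        if (d >= cfg$mk_diameter_um$min && d <= cfg$mk_diameter_um$max)
          return(d)
      }
    },
    micro_mk = runif(1L, cfg$micro_mk_diameter_um[1L],
                     cfg$micro_mk_diameter_um[2L]),
    lymphocyte = runif(1L, 7, 10),
    dead = runif(1L, 8, 18),
    anucleate = runif(1L, 8, 18),
    platelet_adherent = runif(1L, 10, 20),
    doublet = NA_real_)
}

addSpot <- function(img, cx, cy, sigma, amp) {
  n <- nrow(img); hw <- ceiling(4 * sigma)
  r0 <- max(1L, floor(cy - hw)); r1 <- min(n, ceiling(cy + hw))
  c0 <- max(1L, floor(cx - hw)); c1 <- min(ncol(img), ceiling(cx + hw))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  g <- outer((rr - cy)^2, (cc - cx)^2, "+")
  img[rr, cc] <- img[rr, cc] + amp * exp(-g / (2 * sigma^2))
  img
}

discIdx <- function(n, cx, cy, r) {
  outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+") <= r^2
}

# Render the noiseless per-channel scenes for one event of a given class.
renderScene <- function(class, diameterUm, cfg, panel,
                        diameter2Um = NA_real_) {
  n <- cfg$canvas_px
  px <- panel@pixelSize
  ctr <- n / 2 + runif(2L, -3, 3)
  mult <- exp(rnorm(1L, 0, 0.2))
  spotSigma <- cfg$platelet_spot_diameter_um / px / 2.355
  amps <- .classAmps[[class]]
  sc <- list()
  bf <- matrix(2600, n, n) + matrix(rnorm(n * n, 0, 20), n, n)

  discs <- if (class == "doublet") {
    r1 <- diameterUm / px / 2; r2 <- diameter2Um / px / 2
    th <- runif(1L, 0, 2 * pi); u <- c(cos(th), sin(th))
    list(list(cx = ctr[1L] - u[1L] * r1, cy = ctr[2L] - u[2L] * r1, r = r1),
         list(cx = ctr[1L] + u[1L] * r2, cy = ctr[2L] + u[2L] * r2, r = r2))
  } else {
    list(list(cx = ctr[1L], cy = ctr[2L], r = diameterUm / px / 2))
  }
  cell <- matrix(FALSE, n, n)
  for (d in discs) cell <- cell | discIdx(n, d$cx, d$cy, d$r)
  ncell <- sum(cell)
  # brightfield: dark textured interior on a light background; the texture
  # carries the sharpness signal the focus gate measures
  bf[cell] <- pmin(pmax(1600 + rnorm(ncell, 0, 600), 400), 3000)
  sc$bf <- bf

  flat <- function(amp) {
    m <- matrix(30, n, n)
    m[cell] <- m[cell] + pmin(amp * mult, 3400) + rnorm(ncell, 0, amp / 6)
    pmin(pmax(m, 0), 3400)
  }
  sc$cd45 <- flat(amps[["cd45"]])
  sc$ssc <- flat(amps[["ssc"]])
  sc$dump <- flat(amps[["dump"]])
  sc$viability <- flat(amps[["viability"]])

  dna <- matrix(20, n, n)
  if (class != "anucleate") {
    for (d in discs) {
      nuc <- discIdx(n, d$cx, d$cy, 0.55 * d$r)
      dna[nuc] <- pmin(pmax(1500 + rnorm(sum(nuc), 0, 200), 800), 2600)
    }
  }
  sc$dna <- dna

  cd41 <- matrix(30, n, n)
  if (class %in% c("mk", "micro_mk", "doublet")) {
    for (d in discs) {
      s <- sample(cfg$membrane_spot_count[1L]:cfg$membrane_spot_count[2L], 1L)
      ang <- runif(s, 0, 2 * pi)
      rr <- pmax(d$r - 2, 1)
      for (a in ang)
        cd41 <- addSpot(cd41, d$cx + rr * cos(a), d$cy + rr * sin(a),
                        spotSigma,
                        min(max(rnorm(1L, 1100, 150), 700), 1600) * mult)
    }
  } else if (class == "platelet_adherent") {
    d <- discs[[1L]]
    k <- sample(cfg$platelet_spots[1L]:cfg$platelet_spots[2L], 1L)
    for (j in seq_len(k)) {
      u <- 0.9 * d$r * sqrt(runif(1L)); a <- runif(1L, 0, 2 * pi)
      cd41 <- addSpot(cd41, d$cx + u * cos(a), d$cy + u * sin(a), spotSigma,
                      min(max(rnorm(1L, 2600, 200), 2000), 3200))
    }
  }
  sc$cd41 <- pmin(cd41, 3400)
  list(scenes = sc, discs = discs, cell = cell)
}

sceneToRaster <- function(scene, cfg) {
  x <- scene
  if (cfg$poisson_noise) {
    lam <- pmax(x, 0)
    x <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
  }
  if (cfg$read_noise_sd > 0)
    x <- x + matrix(rnorm(length(x), 0, cfg$read_noise_sd), nrow(x), ncol(x))
  m <- matrix(as.integer(pmin(pmax(round(x), 0), 4095)), nrow(x), ncol(x))
  m
}

#' Render a single synthetic event
#'
#' @param class one of the supported phenotype classes.
#' @param diameterUm cell diameter in um (for doublets, the first disc).
#' @param cfg a [syntheticConfig()].
#' @param panel a [PanelConfig-class].
#' @param defocus render out of focus (blur the noiseless scene with
#'   `cfg$blur_sigma`).
#' @param saturate add a pixel-saturating CD41 blob.
#' @param diameter2Um second-disc diameter for doublets.
#' @return named list of integer channel rasters keyed by channel id.
#' @export
renderEvent <- function(class, diameterUm, cfg = syntheticConfig(),
                        panel = panelConfig(), defocus = FALSE,
                        saturate = FALSE, diameter2Um = NA_real_) {
  if (!class %in% .synthClasses) stop("unknown event class: ", class)
  rs <- renderScene(class, diameterUm, cfg, panel, diameter2Um)
  sc <- rs$scenes
  if (saturate) {
    d <- rs$discs[[sample(length(rs$discs), 1L)]]
    u <- 0.6 * d$r * sqrt(runif(1L)); a <- runif(1L, 0, 2 * pi)
    sc$cd41 <- addSpot(sc$cd41, d$cx + u * cos(a), d$cy + u * sin(a),
                       2.5, 4400)
  }
  if (defocus)
    sc <- lapply(sc, EBImage::gblur, sigma = cfg$blur_sigma)
  out <- lapply(sc, sceneToRaster, cfg = cfg)
  names(out) <- unname(panel@channels[names(sc)])
  out[unname(panel@channels)]
}

#' Generate a labeled synthetic event gallery
#'
#' A pure function of (config, seed): identical configurations give
#' bit-identical output. Ground truth is drawn first (classes, diameters,
#' flags, times), then each event is rendered; the saturation flag is
#' recomputed from the final rasters so it is consistent with the pixel data
#' by construction.
#'
#' @param cfg a [syntheticConfig()].
#' @param panel a [PanelConfig-class].
#' @param render if `FALSE`, skip rendering and return ground truth only
#'   (events is `NULL`); used for fast distribution checks.
#' @return list with `events` (an [EventSet-class] labeled by class) and
#'   `truth` (data.frame: object_id, class, is_singlet, is_in_focus,
#'   is_saturated, is_viable, is_nucleated, is_unstable, true_diameter_um,
#'   time_s).
#' @export
generateEventSet <- function(cfg = syntheticConfig(), panel = panelConfig(),
                             render = TRUE) {
  stopifnot(inherits(cfg, "mkflow_synth_config"))
  withSeed(cfg$seed, {
    n <- cfg$n_events
    cls <- sample(names(cfg$class_mixture), n, replace = TRUE,
                  prob = cfg$class_mixture)
    d1 <- vapply(cls, drawDiameter, numeric(1L), cfg = cfg)
    d2 <- ifelse(cls == "doublet", runif(n, 12, 26), NA_real_)
    d1 <- ifelse(cls == "doublet", runif(n, 12, 26), d1)
    trueD <- ifelse(cls == "doublet", sqrt(d1^2 + d2^2), d1)
    defocus <- runif(n) < cfg$defocus_fraction
    saturate <- runif(n) < cfg$saturated_fraction
    unstable <- runif(n) < cfg$flow_instability
    time <- ifelse(unstable,
                   runif(n, cfg$instability_window[1L],
                         cfg$instability_window[2L]),
                   runif(n, 0, cfg$duration_s))
    truth <- data.frame(object_id = seq_len(n) - 1L, class = cls,
                        is_singlet = cls != "doublet",
                        is_in_focus = !defocus,
                        is_saturated = saturate,
                        is_viable = cls != "dead",
                        is_nucleated = cls != "anucleate",
                        is_unstable = unstable,
                        true_diameter_um = trueD, time_s = time,
                        row.names = NULL)
    events <- NULL
    if (render) {
      rasters <- vector("list", n)
      for (i in seq_len(n))
        rasters[[i]] <- renderEvent(cls[i], d1[i], cfg, panel,
                                    defocus = defocus[i],
                                    saturate = saturate[i],
                                    diameter2Um = d2[i])
      events <- eventSet(panel, rasters, time, objectId = truth$object_id,
                         labels = cls)
      truth$is_saturated <- vapply(rasters, function(ev)
        any(vapply(ev, max, integer(1L)) >= 4030L), logical(1L))
    }
    list(events = events, truth = truth)
  })
}

#' Defocus an event set
#'
#' Gaussian-blurs every raster of the selected events; `sigma = 0` is the
#' identity. Blurring strictly lowers the gradient-RMS sharpness of
#' non-constant images, which is what the focus gate keys on.
#'
#' @param events an [EventSet-class].
#' @param sigma blur bandwidth in px, `>= 0`.
#' @param which event positions to blur (default all).
#' @return a new [EventSet-class].
#' @export
applyDefocus <- function(events, sigma, which = seq_len(nEvents(events))) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(events)
  maxv <- 2L^events@panel@bitDepth - 1L
  rasters <- events@rasters
  for (i in which) {
    rasters[[i]] <- lapply(rasters[[i]], function(m) {
      rad <- min(2L * ceiling(3 * sigma) + 1L,
                 (min(dim(m)) - 1L) %/% 2L * 2L + 1L)
      b <- EBImage::gblur(m, sigma = sigma, radius = rad)
      matrix(as.integer(pmin(pmax(round(b), 0), maxv)), nrow(m), ncol(m))
    })
  }
  eventSet(events@panel, rasters, events@time, objectId = events@objectId,
           labels = if (length(events@labels)) events@labels else NULL)
}

#' Generate single-stain compensation control galleries
#'
#' One control event set per fluorescence marker: each event is a uniform
#' disc of integer amplitude in the marker's primary channel, with the
#' configured fraction spilled into every other channel. With
#' `noise = "none"` the spill is pixel-exact (amplitudes are multiples of
#' 100 and spillover entries are taken at 2 decimals), so regression
#' recovery of the matrix is exact; with `noise = "poisson"` shot noise is
#' applied.
#'
#' @param spill a [SpilloverMatrix-class] or square matrix with marker
#'   dimnames (the generating truth).
#' @param nEvents events per control.
#' @param noise `"none"` or `"poisson"`.
#' @param panel a [PanelConfig-class].
#' @param seed RNG seed.
#' @return named list marker -> [EventSet-class].
#' @export
generateCompensationControls <- function(spill, nEvents = 60L,
                                         noise = c("none", "poisson"),
                                         panel = panelConfig(), seed = 1L) {
  noise <- match.arg(noise)
  m <- if (is(spill, "SpilloverMatrix")) spill@matrix else spill
  mk <- rownames(m)
  stopifnot(!is.null(mk), all(mk %in% markers(panel)))
  withSeed(seed, {
    out <- list()
    n <- panel@bitDepth  # not canvas; canvas fixed below
    side <- 120L
    for (src in mk) {
      rasters <- vector("list", nEvents)
      for (i in seq_len(nEvents)) {
        r <- sample(14:30, 1L)
        amp <- 100L * sample(5:30, 1L)
        cell <- discIdx(side, side / 2, side / 2, r)
        bf <- matrix(2600L, side, side); bf[cell] <- 1500L
        ev <- list(bf = bf)
        for (dst in mk) {
          a <- amp * m[src, dst]
          ch <- matrix(0, side, side); ch[cell] <- a
          if (noise == "poisson")
            ch <- matrix(rpois(length(ch), ch), side, side)
          ev[[dst]] <- matrix(as.integer(pmin(ch, 4095)), side, side)
        }
        for (other in setdiff(markers(panel), c("bf", mk)))
          ev[[other]] <- matrix(0L, side, side)
        names(ev) <- unname(panel@channels[names(ev)])
        rasters[[i]] <- ev[unname(panel@channels)]
      }
      out[[src]] <- eventSet(panel, rasters, time = seq_len(nEvents))
    }
    out
  })
}
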