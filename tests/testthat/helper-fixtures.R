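# Shared fixtures and independent oracles. Everything is generated in code;
# expensive galleries are built lazily and cached for the whole run.

.fx <- new.env(parent = emptyenv())

fxCache <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# default-mixture gallery with features, used by gating/synthgen tests
fxGallery <- function() fxCache("gallery", function() {
  gen <- generateEventSet(syntheticConfig(n_events = 450L,
                                          flow_instability = 0.1, seed = 1L))
  list(gen = gen, features = computeFeatures(gen$events),
       truth = gen$truth)
})

# single-channel event set around a bare raster matrix
rasterEvent <- function(m, marker = "bf", bitDepth = 12L, pixelSize = 0.5) {
  p <- panelConfig(channels = setNames("Ch01", marker),
                   pixelSize = pixelSize, bitDepth = bitDepth)
  storage.mode(m) <- "integer"
  eventSet(p, list(setNames(list(m), "Ch01")), time = 0)
}

fullMask <- function(m) new("Mask", bits = matrix(TRUE, nrow(m), ncol(m)),
                            channel = "bf", kind = "default", valid = TRUE)

discMatrix <- function(side, r, cx = side / 2, cy = side / 2) {
  outer((seq_len(side) - cy)^2, (seq_len(side) - cx)^2, "+") <= r^2
}

# independent Sobel gradient-RMS oracle: explicit loops, replicated edges
oracleGradientRMS <- function(x, mask, bitDepth = 12L) {
  xn <- x / (2^bitDepth - 1) * 100
  n <- nrow(xn); k <- ncol(xn)
  at <- function(i, j) xn[min(max(i, 1L), n), min(max(j, 1L), k)]
  acc <- 0; cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(k)) {
    if (!mask[i, j]) next
    gx <- (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
          (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))
    gy <- (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
          (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1))
    acc <- acc + gx^2 + gy^2
    cnt <- cnt + 1L
  }
  sqrt(acc / cnt)
}

# minimal independent FCS reader (header offsets -> TEXT keywords -> float32
# data), deliberately separate from the writer's code path
oracleReadFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  stopifnot(substr(header, 1L, 6L) == "FCS3.1")
  off <- as.integer(trimws(substring(header, 10 + 8 * (0:3) + 1,
                                     10 + 8 * (1:4))))
  seek(con, off[1L])
  txt <- rawToChar(readBin(con, "raw", off[2L] - off[1L] + 1L))
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1L]]
  kw <- setNames(parts[seq(2L, length(parts), 2L)],
                 parts[seq(1L, length(parts), 2L)])
  tot <- as.integer(kw[["$TOT"]]); par <- as.integer(kw[["$PAR"]])
  seek(con, as.integer(kw[["$BEGINDATA"]]))
  vals <- readBin(con, "numeric", n = tot * par, size = 4L,
                  endian = "little")
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(par), function(j) kw[[sprintf("$P%dN", j)]],
                        character(1L))
  list(matrix = m, keywords = kw)
}

# the constructed 100-event cascade fixture: each block of events fails
# exactly one gate, so per-gate survivor counts are forced by construction
cascadeFixture <- function() {
  n <- 100L
  f <- data.frame(
    object_id = 1:100,
    time_s = seq(0, 100, length.out = n),
    raw_max_pixel_cd41 = 1000, raw_max_pixel_bf = 1000,
    intensity_viability = 10, intensity_dna = 1000,
    intensity_cd45 = 100, intensity_ssc = 1000,
    intensity_cd41 = 1000, intensity_dump = 10,
    gradient_rms_bf = 80, diameter_um_bf = 20)
  f$time_s[1:10] <- 150                    # unstable flow
  f$raw_max_pixel_cd41[11:20] <- 4030      # saturated (strict "below 4030")
  f$intensity_viability[21:30] <- 1e5      # dead
  f$intensity_dna[31:40] <- 0              # anucleate
  f$intensity_cd45[41:55] <- 10000         # 15 lymphocytes (CD45 hi, SSC lo)
  f$intensity_ssc[41:55] <- 10
  f$intensity_dump[56:65] <- 5000          # dump-positive
  doubletIds <- 66:75
  f$gradient_rms_bf[76:85] <- 10           # defocused
  plateletIds <- 86:95
  cfg <- gateConfig(stable_flow = c(0, 100), viability_max = 100,
                    dna_min = 50, cd45_min = 5000, ssc_max = 100,
                    cd41_min = 500, dump_max = 100)
  list(features = f, cfg = cfg,
       singletOracle = function(ft) !(ft$object_id %in% doubletIds),
       cnnOracle = function(ft) !(ft$object_id %in% plateletIds))
}

# trivially separable toy crop set: bright ring (positive) vs noise (negative)
toyTruthSet <- function(n = 60L, size = 32L, seed = 42L) {
  withSeed(seed, {
    x <- array(0, dim = c(n, size, size, 2L))
    lab <- rep(c("cd41_neg", "cd41_pos"), length.out = n)
    ring <- discMatrix(size, 11) & !discMatrix(size, 8)
    for (i in seq_len(n)) {
      bf <- matrix(runif(size^2, 0, 0.3), size, size)
      cd41 <- matrix(runif(size^2, 0, 0.2), size, size)
      if (lab[i] == "cd41_pos") cd41[ring] <- cd41[ring] + 0.8
      x[i, , , 1L] <- bf; x[i, , , 2L] <- pmin(cd41, 1)
    }
    out <- list(x = x, labels = factor(lab, c("cd41_neg", "cd41_pos")),
                object_id = seq_len(n) - 1L)
    class(out) <- "mkflow_truth_set"
    out
  })
}

toyCnnSpec <- function(...) {
  args <- list(input_size = 32L, filters = c(8L, 16L), max_epochs = 30L,
               min_epochs = 6L, patience = 4L, batch_size = 8L, lr = 0.003,
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cnnModelSpec, args)
}

fullMaskFrom <- function(bits) new("Mask", bits = bits, channel = "bf",
                                   kind = "default", valid = TRUE)

# cached 0.20-spillover Poisson controls (expensive: 2 x 500 rendered events)
fxPoissonSpill <- function() fxCache("poisson_spill", function() {
  m <- diag(2)
  dimnames(m) <- list(c("cd41", "dump"), c("cd41", "dump"))
  m["cd41", "dump"] <- 0.2
  estimateSpillover(generateCompensationControls(m, nEvents = 500L,
                                                 noise = "poisson",
                                                 seed = 1L))
})
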