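# Linear-discriminant singlet/doublet classifier. Area/aspect-ratio gating
# fails for the largest MKs (they overlap doublets in those features), so a
# two-class LDA over brightfield and CD41 morphometrics replaces it, with
# the decision boundary anchored at score 0 and singlets scoring positive.

.defaultSingletFeatures <- c(
  "area_um2_bf", "aspect_ratio_bf", "diameter_um_bf", "gradient_rms_bf",
  "intensity_bf",
  "area_um2_cd41", "aspect_ratio_cd41", "diameter_um_cd41",
  "gradient_rms_cd41", "intensity_cd41")

featureMatrix <- function(x, features) {
  ft <- if (is(x, "EventSet")) computeFeatures(x) else x
  missing <- setdiff(features, names(ft))
  if (length(missing))
    stop("missing features: ", paste(missing, collapse = ", "))
  m <- as.matrix(ft[, features, drop = FALSE])
  if (anyNA(m)) stop("NA feature values (invalid masks?) in classifier input")
  m
}

#' Fit the singlet/doublet linear discriminant
#'
#' Two-class LDA with pooled, ridge-regularized within-class covariance
#' (lambda = 1e-3 * trace / p) on standardized features. The score is
#' shifted so the standardized class-mean midpoint scores exactly 0, signed
#' so singlets score positive, and divided by the pooled within-class SD of
#' raw scores so the ">= 0" gate is scale-free. Rescaling any raw feature
#' by a positive constant leaves scores unchanged.
#'
#' @param singlets,doublets truth populations: [EventSet-class]s or feature
#'   data.frames ([computeFeatures()]); each needs >= 2 events.
#' @param features feature column names to use.
#' @return a [SingletClassifier-class].
#' @export
fitSingletClassifier <- function(singlets, doublets,
                                 features = .defaultSingletFeatures) {
  xs <- featureMatrix(singlets, features)
  xd <- featureMatrix(doublets, features)
  if (nrow(xs) < 2L || nrow(xd) < 2L)
    stop("each truth class needs at least 2 events")
  xall <- rbind(xs, xd)
  ctr <- colMeans(xall)
  scl <- apply(xall, 2L, sd)
  scl[scl == 0] <- 1
  zs <- sweep(sweep(xs, 2L, ctr), 2L, scl, "/")
  zd <- sweep(sweep(xd, 2L, ctr), 2L, scl, "/")
  mu1 <- colMeans(zs); mu0 <- colMeans(zd)
  n1 <- nrow(zs); n0 <- nrow(zd); p <- length(features)
  sp <- ((n1 - 1L) * stats::cov(zs) + (n0 - 1L) * stats::cov(zd)) /
        (n1 + n0 - 2L)
  lambda <- 1e-3 * sum(diag(sp)) / p
  spr <- sp + diag(lambda, p)
  w <- tryCatch(solve(spr, mu1 - mu0), error = function(e)
    stop("singular pooled covariance after regularization; ",
         "degenerate truth populations"))
  if (!all(is.finite(w)))
    stop("singular pooled covariance after regularization; ",
         "degenerate truth populations")
  offset <- sum(w * (mu1 + mu0)) / 2
  raw1 <- zs %*% w - offset
  raw0 <- zd %*% w - offset
  pooledVar <- ((n1 - 1L) * var(as.vector(raw1)) +
                (n0 - 1L) * var(as.vector(raw0))) / (n1 + n0 - 2L)
  scale0 <- sqrt(pooledVar)
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1
  new("SingletClassifier", features = features, center = ctr, scale = scl,
      weights = as.numeric(w), offset = offset, scoreScale = scale0)
}

#' Score events with the singlet classifier
#'
#' Affine function of the standardized features; the gate rule is
#' `score >= 0` keeps singlets. The event at the midpoint of the class
#' means scores exactly 0.
#'
#' @param classifier a [SingletClassifier-class].
#' @param x an [EventSet-class] or feature data.frame.
#' @return numeric score per event.
#' @export
singletScore <- function(classifier, x) {
  m <- featureMatrix(x, classifier@features)
  z <- sweep(sweep(m, 2L, classifier@center), 2L, classifier@scale, "/")
  as.numeric(z %*% classifier@weights - classifier@offset) /
    classifier@scoreScale
}

#' Serialize / restore a singlet classifier (JSON)
#'
#' @param classifier a [SingletClassifier-class].
#' @param path file path.
#' @export
writeSingletClassifier <- function(classifier, path) {
  jsonlite::write_json(list(
    features = classifier@features,
    center = classifier@center, scale = classifier@scale,
    weights = classifier@weights, offset = classifier@offset,
    score_scale = classifier@scoreScale), path, digits = NA)
  invisible(path)
}

#' @rdname writeSingletClassifier
#' @export
readSingletClassifier <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SingletClassifier", features = l$features,
      center = setNames(l$center, l$features),
      scale = setNames(l$scale, l$features),
      weights = l$weights, offset = l$offset, scoreScale = l$score_scale)
}

setMethod("show", "SingletClassifier", function(object) {
  cat("SingletClassifier:", length(object@features),
      "features; boundary at score 0 (singlets >= 0)\n")
})
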