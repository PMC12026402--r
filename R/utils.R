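#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (the convention used for the
#' percentage tables in cytometry reports), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
#' @examples
#' halfUp(96.735, 2)
#' halfUp(94.87179, 1)
halfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a total
#'
#' @param count,total nonnegative numbers, `total > 0`.
#' @param digits decimal places (half-up); `0` gives nearest integer.
#' @return percentage as a number.
#' @export
proportionPct <- function(count, total, digits = 0) {
  stopifnot(total > 0, count >= 0)
  halfUp(100 * count / total, digits)
}

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Otsu threshold on a numeric vector (wraps EBImage's histogram search).
# Returns the threshold on the scale of `v`.
otsuVector <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop("degenerate intensity distribution: an explicit threshold is required")
  lo <- min(v); hi <- max(v)
  vn <- (v - lo) / (hi - lo)
  th <- EBImage::otsu(matrix(vn, ncol = 1L), range = c(0, 1), levels = levels)
  lo + th * (hi - lo)
}

# Otsu valley on log1p(v) with a unimodality guard: if the two sides of the
# cut are separated by less than `minGap` on the log scale the distribution
# is treated as a single population and NA is returned (gate keeps all).
autoLogThreshold <- function(v, minGap = 1.5) {
  lv <- log1p(v)
  if (length(unique(lv)) < 2L)
    stop("degenerate intensity distribution: an explicit threshold is required")
  t0 <- otsuVector(lv)
  lowMean <- mean(lv[lv <= t0])
  highMean <- mean(lv[lv > t0])
  if (!is.finite(lowMean) || !is.finite(highMean) ||
      (highMean - lowMean) < minGap)
    return(NA_real_)
  expm1(t0)
}
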