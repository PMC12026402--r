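# Feature frames for LDA toys: two columns are enough, the fitter accepts
# any feature data.frame.
toyFrame <- function(x1, x2 = NULL) {
  if (is.null(x2)) data.frame(f1 = x1) else data.frame(f1 = x1, f2 = x2)
}

test_that("symmetric 1-D Gaussian classes put the boundary at 0", {
  withSeed(1L, {
    s <- toyFrame(rnorm(200, 1, 1))
    d <- toyFrame(rnorm(200, -1, 1))
  })
  cl <- fitSingletClassifier(s, d, features = "f1")
  # midpoint of the class means scores 0 by construction
  mid <- toyFrame((mean(s$f1) + mean(d$f1)) / 2)
  expect_equal(singletScore(cl, mid), 0, tolerance = 1e-9)
  expect_gt(singletScore(cl, toyFrame(mean(s$f1))), 0)
  expect_lt(singletScore(cl, toyFrame(mean(d$f1))), 0)
  # the raw feature value 0 is essentially the boundary
  expect_lt(abs(singletScore(cl, toyFrame(0))), 0.1)
})

test_that("scores are invariant to positive rescaling of raw features", {
  withSeed(2L, {
    s <- toyFrame(rnorm(50, 2), rnorm(50, 0, 2))
    d <- toyFrame(rnorm(50, -1), rnorm(50, 1, 2))
    q <- toyFrame(rnorm(20), rnorm(20))
  })
  cl1 <- fitSingletClassifier(s, d, features = c("f1", "f2"))
  sc1 <- singletScore(cl1, q)
  k <- 1000
  s2 <- s; d2 <- d; q2 <- q
  s2$f1 <- s2$f1 * k; d2$f1 <- d2$f1 * k; q2$f1 <- q2$f1 * k
  cl2 <- fitSingletClassifier(s2, d2, features = c("f1", "f2"))
  expect_equal(singletScore(cl2, q2), sc1, tolerance = 1e-9)
})

test_that("fitter agrees with explicit-matrix-algebra LDA on small inputs", {
  withSeed(3L, {
    s <- toyFrame(rnorm(8, 1.5), rnorm(8, 1))
    d <- toyFrame(rnorm(9, -0.5), rnorm(9, -1))
  })
  cl <- fitSingletClassifier(s, d, features = c("f1", "f2"))
  # brute-force Gaussian discriminant, written out by hand
  xall <- rbind(as.matrix(s), as.matrix(d))
  ctr <- colMeans(xall); scl <- apply(xall, 2, sd)
  zs <- sweep(sweep(as.matrix(s), 2, ctr), 2, scl, "/")
  zd <- sweep(sweep(as.matrix(d), 2, ctr), 2, scl, "/")
  mu1 <- colMeans(zs); mu0 <- colMeans(zd)
  sp <- (7 * cov(zs) + 8 * cov(zd)) / 15
  spr <- sp + diag(1e-3 * sum(diag(sp)) / 2, 2)
  # 2x2 inverse by the adjugate formula
  det2 <- spr[1, 1] * spr[2, 2] - spr[1, 2] * spr[2, 1]
  inv <- matrix(c(spr[2, 2], -spr[2, 1], -spr[1, 2], spr[1, 1]), 2) / det2
  w <- inv %*% (mu1 - mu0)
  raw <- function(z) as.numeric(z %*% w - sum(w * (mu1 + mu0)) / 2)
  pooledSd <- sqrt((7 * var(raw(zs)) + 8 * var(raw(zd))) / 15)
  expect_equal(singletScore(cl, rbind(s, d)),
               c(raw(zs), raw(zd)) / pooledSd, tolerance = 1e-9)
})

test_that("direction matches MASS::lda on a well-conditioned toy", {
  withSeed(4L, {
    s <- toyFrame(rnorm(60, 1), rnorm(60, 0.5))
    d <- toyFrame(rnorm(60, -1), rnorm(60, -0.5))
  })
  cl <- fitSingletClassifier(s, d, features = c("f1", "f2"))
  fit <- MASS::lda(cls ~ f1 + f2,
                   data = rbind(cbind(s, cls = "s"), cbind(d, cls = "d")))
  q <- toyFrame(rnorm(50), rnorm(50))
  ours <- singletScore(cl, q) >= 0
  theirs <- predict(fit, q)$class == "s"
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("degenerate truth populations are rejected", {
  one <- toyFrame(1)
  expect_error(fitSingletClassifier(one, toyFrame(c(0, 1)),
                                    features = "f1"), "at least 2")
  dupS <- toyFrame(rep(1, 5), rep(2, 5))
  dupD <- toyFrame(rep(-1, 5), rep(0, 5))
  expect_error(fitSingletClassifier(dupS, dupD,
                                    features = c("f1", "f2")),
               "degenerate|singular")
  withNA <- toyFrame(c(1, NA), c(0, 1))
  expect_error(fitSingletClassifier(withNA, toyFrame(c(0, 1), c(1, 0)),
                                    features = c("f1", "f2")), "NA")
})

test_that("synthetic truth populations (28 singlets, 52 doublets) separate", {
  mkSet <- function(mix, n, seed)
    generateEventSet(syntheticConfig(n_events = n, class_mixture = mix,
                                     defocus_fraction = 0,
                                     saturated_fraction = 0,
                                     flow_instability = 0,
                                     seed = seed))$events
  singlets <- mkSet(c(mk = 1), 28L, 31L)
  doublets <- mkSet(c(doublet = 1), 52L, 32L)
  cl <- fitSingletClassifier(singlets, doublets)
  trainScores <- c(singletScore(cl, singlets), singletScore(cl, doublets))
  trainTruth <- rep(c(TRUE, FALSE), c(28L, 52L))
  expect_gte(mean((trainScores >= 0) == trainTruth), 0.9)

  # fresh doublets: at least 85% score below the 0 boundary
  fresh <- mkSet(c(doublet = 1), 100L, 33L)
  expect_gte(mean(singletScore(cl, fresh) < 0), 0.85)
  # fresh singlets mostly kept
  freshS <- mkSet(c(mk = 1), 50L, 34L)
  expect_gte(mean(singletScore(cl, freshS) >= 0), 0.85)

  # JSON round trip preserves scores exactly
  path <- withr::local_tempfile(fileext = ".json")
  writeSingletClassifier(cl, path)
  back <- readSingletClassifier(path)
  expect_equal(singletScore(back, fresh), singletScore(cl, fresh),
               tolerance = 1e-12)
})
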