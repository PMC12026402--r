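test_that("stratified split honors exact divisibility and determinism", {
  labels <- rep(c("cd41_pos", "cd41_neg"), each = 50L)
  sp <- splitTruthSet(labels, c(0.8, 0.1, 0.1), seed = 1L)
  expect_equal(unname(sp$counts), c(80L, 10L, 10L))
  expect_equal(as.integer(table(labels[sp$train])), c(40L, 40L))
  expect_equal(as.integer(table(labels[sp$validation])), c(5L, 5L))
  expect_equal(as.integer(table(labels[sp$test])), c(5L, 5L))
  # disjoint and exhaustive
  all <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all), 1:100)
  sp2 <- splitTruthSet(labels, c(0.8, 0.1, 0.1), seed = 1L)
  expect_identical(sp[1:3], sp2[1:3])
  sp3 <- splitTruthSet(labels, c(0.8, 0.1, 0.1), seed = 2L)
  expect_false(identical(sp$train, sp3$train))
  expect_error(splitTruthSet(labels, c(0.8, 0.1, 0.2)), "sum to 1")
})

test_that("largest-remainder split reports honest realized fractions", {
  expect_equal(unname(realizedFractions(c(610L, 92L, 92L))),
               c(76.8, 11.6, 11.6))
  # 794 events split 80/10/10 with per-class largest remainder
  labels <- rep(c("cd41_pos", "cd41_neg"), c(412L, 382L))
  sp <- splitTruthSet(labels, seed = 1L)
  expect_equal(sum(sp$counts), 794L)
  expect_equal(unname(sp$counts), c(636L, 79L, 79L))
})

test_that("a trivially separable truth set reaches validation accuracy 1", {
  toy <- toyTruthSet(n = 60L)
  sp <- splitTruthSet(toy, c(0.6, 0.2, 0.2), seed = 1L)
  m <- trainCNN(subsetTruthSet(toy, sp$train),
                subsetTruthSet(toy, sp$validation), toyCnnSpec())
  expect_equal(tail(m@history$val_acc, 1L), 1)
  pred <- predictCNN(m, subsetTruthSet(toy, sp$test))
  te <- subsetTruthSet(toy, sp$test)
  expect_equal(mean(pred$label == as.character(te$labels)), 1)
})

test_that("training is deterministic given (data, spec, seed)", {
  toy <- toyTruthSet(n = 40L)
  sp <- splitTruthSet(toy, c(0.7, 0.15, 0.15), seed = 1L)
  tr <- subsetTruthSet(toy, sp$train); va <- subsetTruthSet(toy, sp$validation)
  m1 <- trainCNN(tr, va, toyCnnSpec(max_epochs = 5L))
  m2 <- trainCNN(tr, va, toyCnnSpec(max_epochs = 5L))
  expect_identical(cnnWeightChecksum(m1), cnnWeightChecksum(m2))
  expect_identical(m1@history, m2@history)
  m3 <- trainCNN(tr, va, toyCnnSpec(max_epochs = 5L, seed = 2L))
  expect_false(identical(cnnWeightChecksum(m1), cnnWeightChecksum(m3)))
})

test_that("probabilities are softmax-normalized and order-invariant", {
  toy <- toyTruthSet(n = 30L)
  sp <- splitTruthSet(toy, c(0.7, 0.15, 0.15), seed = 1L)
  m <- trainCNN(subsetTruthSet(toy, sp$train),
                subsetTruthSet(toy, sp$validation),
                toyCnnSpec(max_epochs = 4L))
  pred <- predictCNN(m, toy)
  expect_equal(pred$cd41_neg + pred$cd41_pos, rep(1, 30L), tolerance = 1e-6)
  perm <- sample(30L)
  predP <- predictCNN(m, subsetTruthSet(toy, perm))
  expect_equal(predP$label, pred$label[perm])
  expect_error(predictCNN(m, array(0, c(2, 16, 16, 2))), "input spec")
})

test_that("augmented training is robust to 90-degree test rotation", {
  toy <- toyTruthSet(n = 60L)
  sp <- splitTruthSet(toy, c(0.6, 0.2, 0.2), seed = 1L)
  m <- trainCNN(subsetTruthSet(toy, sp$train),
                subsetTruthSet(toy, sp$validation), toyCnnSpec())
  # evaluate on all 60 crops so one flipped crop cannot exceed the bound
  rot <- toy
  rot$x <- aperm(toy$x, c(1L, 3L, 2L, 4L))[, , dim(toy$x)[2L]:1L, ,
                                           drop = FALSE]
  accPlain <- mean(predictCNN(m, toy)$label == as.character(toy$labels))
  accRot <- mean(predictCNN(m, rot)$label == as.character(rot$labels))
  expect_lte(abs(accPlain - accRot), 0.03)
})

test_that("inverse-frequency class weighting barely moves accuracy", {
  toy <- toyTruthSet(n = 60L)
  sp <- splitTruthSet(toy, c(0.6, 0.2, 0.2), seed = 1L)
  tr <- subsetTruthSet(toy, sp$train); va <- subsetTruthSet(toy, sp$validation)
  te <- subsetTruthSet(toy, sp$test)
  m1 <- trainCNN(tr, va, toyCnnSpec())
  w <- as.numeric(length(tr$labels) / (2 * table(tr$labels)))
  m2 <- trainCNN(tr, va, toyCnnSpec(class_weights = w))
  a1 <- mean(predictCNN(m1, te)$label == as.character(te$labels))
  a2 <- mean(predictCNN(m2, te)$label == as.character(te$labels))
  expect_lte(abs(a1 - a2), 0.05)
})

test_that("spec and input validation catch misuse", {
  toy <- toyTruthSet(n = 20L)
  one <- subsetTruthSet(toy, which(toy$labels == "cd41_pos"))
  va <- subsetTruthSet(toy, 1:4)
  expect_error(trainCNN(one, va, toyCnnSpec()), "both classes")
  expect_error(cnnModelSpec(input_size = 30L), "divisible")
  expect_error(cnnModelSpec(class_weights = c(1, -1)), "positive")
  expect_error(trainCNN(toy, va, cnnModelSpec(input_size = 64L)),
               "do not match")
})

test_that("model JSON serialization preserves predictions", {
  toy <- toyTruthSet(n = 30L)
  sp <- splitTruthSet(toy, c(0.7, 0.15, 0.15), seed = 1L)
  m <- trainCNN(subsetTruthSet(toy, sp$train),
                subsetTruthSet(toy, sp$validation),
                toyCnnSpec(max_epochs = 4L))
  path <- withr::local_tempfile(fileext = ".json")
  writeCnnModel(m, path)
  back <- readCnnModel(path)
  expect_equal(predictCNN(back, toy)$cd41_pos, predictCNN(m, toy)$cd41_pos,
               tolerance = 1e-7)
})
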