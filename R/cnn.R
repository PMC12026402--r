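# R front end for the CNN CD41+/CD41- classifier.

#' CNN model specification
#'
#' The default architecture — three 3x3 conv blocks of 16/32/64 filters with
#' ReLU and 2x2 max pooling, global average pooling and a 2-way softmax —
#' is small enough (~23k parameters) for CPU training on a few hundred
#' crops in minutes. Training stops once the training and validation
#' accuracy curves have approached one another (gap < `gap_tol`) for
#' `patience` consecutive epochs, or validation accuracy has stopped
#' improving for `patience` epochs, whichever comes first; `min_epochs`
#' prevents a spurious stop while both curves are still near chance.
#'
#' @param input_size crop side length (must be divisible by
#'   `2^length(filters)`).
#' @param channels input channel count (BF + CD41 = 2).
#' @param filters conv filters per block.
#' @param max_epochs,min_epochs,patience,gap_tol stopping rule.
#' @param lr,momentum,batch_size Adam optimizer parameters
#'   (`momentum` is the first-moment decay, beta1).
#' @param augment dihedral (flip/90-degree-rotation) augmentation; flow-cell
#'   orientation is physically arbitrary, so on by default.
#' @param class_weights length-2 multiplicative loss weights
#'   (cd41_neg, cd41_pos).
#' @param seed RNG seed for init/shuffling/augmentation.
#' @return list of class `mkflow_cnn_spec`.
#' @export
cnnModelSpec <- function(input_size = 64L, channels = 2L,
                         filters = c(16L, 32L, 64L),
                         max_epochs = 30L, min_epochs = 10L, patience = 6L,
                         gap_tol = 0.02, lr = 0.001, momentum = 0.9,
                         batch_size = 32L, augment = TRUE,
                         class_weights = c(1, 1), seed = 1L) {
  spec <- as.list(environment())
  if (input_size %% 2L^length(filters) != 0L)
    stop("input_size must be divisible by 2^number of blocks")
  if (length(class_weights) != 2L || any(class_weights <= 0))
    stop("class_weights must be two positive numbers")
  class(spec) <- "mkflow_cnn_spec"
  spec
}

truthXY <- function(truth) {
  stopifnot(inherits(truth, "mkflow_truth_set"))
  list(x = truth$x, y = as.integer(truth$labels) - 1L)
}

#' Train the CD41+/CD41- CNN
#'
#' @param train,validation truth sets (see [makeTruthSet()] /
#'   [subsetTruthSet()]); both classes must be present in `train`.
#' @param spec a [cnnModelSpec()].
#' @return a [CnnModel-class] with per-epoch accuracy curves in `@history`.
#' @export
trainCNN <- function(train, validation, spec = cnnModelSpec()) {
  tr <- truthXY(train); va <- truthXY(validation)
  if (length(tr$y) == 0L || length(va$y) == 0L)
    stop("training and validation sets must be nonempty")
  if (length(unique(tr$y)) < 2L)
    stop("training set must contain both classes")
  d <- dim(tr$x)
  if (d[2L] != spec$input_size || d[4L] != spec$channels)
    stop("crop dimensions do not match the model spec")
  fit <- .cnn_train(as.numeric(tr$x), tr$y, as.numeric(va$x), va$y,
                    dims = as.integer(d[2:4]),
                    filters = as.integer(spec$filters),
                    maxEpochs = as.integer(spec$max_epochs),
                    minEpochs = as.integer(spec$min_epochs),
                    patience = as.integer(spec$patience),
                    gapTol = spec$gap_tol, lr = spec$lr,
                    momentum = spec$momentum,
                    batch = as.integer(spec$batch_size),
                    augment = isTRUE(spec$augment),
                    classWeights = as.numeric(spec$class_weights),
                    seed = as.integer(spec$seed))
  history <- data.frame(epoch = seq_along(fit$train_acc),
                        train_acc = fit$train_acc, val_acc = fit$val_acc)
  new("CnnModel",
      weights = fit[c("conv", "Wd", "bd", "in_size", "in_chan")],
      spec = unclass(spec), classes = levels(train$labels),
      history = history)
}

#' Classify crops with a fitted CNN
#'
#' @param model a [CnnModel-class].
#' @param x crop array `n x size x size x channels` (e.g.
#'   `extractCrops()$x`), or a truth set.
#' @return data.frame with `label` and the two class probabilities
#'   (softmax; each row sums to 1).
#' @export
predictCNN <- function(model, x) {
  if (inherits(x, "mkflow_truth_set")) x <- x$x
  d <- dim(x)
  if (length(d) != 4L || d[2L] != model@weights$in_size ||
      d[4L] != model@weights$in_chan)
    stop("crop array does not conform to the model input spec")
  probs <- .cnn_predict(model@weights, as.numeric(x), as.integer(d))
  colnames(probs) <- model@classes
  lab <- model@classes[max.col(probs, ties.method = "first")]
  out <- data.frame(label = lab, probs, check.names = FALSE)
  out
}

#' Serialize / restore a CNN model (JSON)
#'
#' @param model a [CnnModel-class].
#' @param path file path.
#' @export
writeCnnModel <- function(model, path) {
  jsonlite::write_json(list(weights = model@weights,
                            spec = model@spec,
                            classes = model@classes,
                            history = model@history),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeCnnModel
#' @export
readCnnModel <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- l$weights
  conv <- lapply(seq_len(nrow_or_len(w$conv)), function(i) {
    ci <- if (is.data.frame(w$conv)) list(W = w$conv$W[[i]], b = w$conv$b[[i]])
          else w$conv[[i]]
    list(W = as.matrix(ci$W), b = as.numeric(ci$b))
  })
  weights <- list(conv = conv, Wd = as.matrix(w$Wd),
                  bd = as.numeric(w$bd),
                  in_size = as.integer(w$in_size),
                  in_chan = as.integer(w$in_chan))
  new("CnnModel", weights = weights, spec = as.list(l$spec),
      classes = l$classes, history = as.data.frame(l$history))
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

setMethod("show", "CnnModel", function(object) {
  h <- object@history
  cat("CnnModel:", paste(object@spec$filters, collapse = "/"),
      "filters;", nrow(h), "epochs; final val acc",
      sprintf("%.3f", h$val_acc[nrow(h)]), "\n")
})

#' Checksum of the model weights
#'
#' Deterministic digest used to assert training reproducibility.
#' @param model a [CnnModel-class].
#' @return a numeric checksum.
#' @export
cnnWeightChecksum <- function(model) {
  v <- unlist(lapply(model@weights$conv, function(c) c(c$W, c$b)))
  v <- c(v, model@weights$Wd, model@weights$bd)
  sum(v * seq_along(v) %% 97)
}
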