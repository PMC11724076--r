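#' @useDynLib mrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# flatten the p x q x n array of a stack into a (p*q) x n matrix
flattenStack <- function(stack) {
  dm <- dim(stack@images)
  matrix(stack@images, nrow = dm[1] * dm[2], ncol = dm[3])
}

poolStacks <- function(stacks, labels) {
  X <- do.call(cbind, lapply(stacks, flattenStack))
  y <- rep.int(labels, length(stacks))
  list(X = X, y = y)
}

#' Train the classifier on pooled multi-representation image stacks
#'
#' All m stacks are pooled into one training set of n*m labelled images
#' (every representation of a sample carries the sample's label) and a
#' single network is trained on them. The epoch whose validation loss is
#' lowest is retained (checkpoint-best); with an empty validation set the
#' last-epoch weights are kept, with a warning.
#'
#' An optional learning-rate grid (`config@params$lrGrid`, e.g.
#' `c(1e-2, 1e-3, 1e-4)`) is screened for `config@params$screenEpochs`
#' epochs each; the rate with the best validation accuracy is then trained
#' in full. This is the desk-scale replacement for large hyperparameter
#' searches.
#'
#' @param stacks list of [ImageStack-class] (training partition).
#' @param labels integer class labels 1..c, one per sample.
#' @param config a [TrainConfig-class].
#' @param valStacks,valLabels validation stacks/labels (same maps).
#' @param classLevels class names; defaults to as.character(1..max(labels)).
#' @param normalizer the fitted training [Norm2Normalizer-class], stored in
#'   the model so raw samples can be classified later.
#' @param collision collision rule the stacks were rendered with.
#' @return an [MRepModel-class].
#' @export
trainModel <- function(stacks, labels, config = trainConfig(),
                       valStacks = list(), valLabels = integer(),
                       classLevels = NULL, normalizer = norm2Normalizer(),
                       collision = "mean") {
  stopifnot(length(stacks) >= 1L, is(config, "TrainConfig"))
  if (config@backbone %in% c("resnet50", "efficientnet_b6"))
    stop("backbone '", config@backbone, "' (pretrained large CNN) is not ",
         "bundled; plug it in via backbone = 'custom' with params$trainFun/",
         "params$predictFun, or use the built-in 'small_cnn'")
  if (is.null(classLevels)) classLevels <- as.character(seq_len(max(labels)))
  nc <- length(classLevels)
  missingClasses <- setdiff(seq_len(nc), unique(labels))
  if (length(missingClasses))
    stop("class(es) ", paste(missingClasses, collapse = ", "),
         " absent from the training set")
  n <- dim(stacks[[1]]@images)[3]
  if (length(labels) != n)
    stop("need one label per sample (", n, " samples, ", length(labels),
         " labels)")
  p <- stacks[[1]]@map@p; q <- stacks[[1]]@map@q
  tr <- poolStacks(stacks, labels)
  hasVal <- length(valStacks) > 0 && dim(valStacks[[1]]@images)[3] > 0
  va <- if (hasVal) poolStacks(valStacks, valLabels)
        else list(X = matrix(0, p * q, 0), y = integer())
  if (!hasVal)
    warning("empty validation set: keeping last-epoch weights ",
            "(no checkpoint-best)")

  if (config@backbone == "custom") {
    tf <- config@params$trainFun
    if (!is.function(tf)) stop("custom backbone requires params$trainFun")
    fit <- tf(tr$X, tr$y, va$X, va$y, p = p, q = q, nclass = nc,
              config = config)
    weights <- list(custom = fit, predictFun = config@params$predictFun)
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric(), valAccuracy = numeric())
    bestEpoch <- 1L
  } else {
    lr <- config@lr
    grid <- config@params$lrGrid
    if (!is.null(grid) && hasVal && length(grid) > 1L) {
      screen <- config@params$screenEpochs
      if (is.null(screen)) screen <- max(3L, config@epochs %/% 5L)
      accs <- vapply(grid, function(g) {
        f <- .cnn_train_cpp(tr$X, tr$y - 1L, va$X, va$y - 1L, p, q, nc,
                            as.integer(screen), config@batchSize, g,
                            config@weightDecay, config@momentum,
                            deriveSeed(config@seed, paste0("screen", g)))
        max(f$history[, 3], na.rm = TRUE)
      }, numeric(1))
      lr <- grid[which.max(accs)]
    }
    fit <- .cnn_train_cpp(tr$X, tr$y - 1L, va$X, va$y - 1L, p, q, nc,
                          config@epochs, config@batchSize, lr,
                          config@weightDecay, config@momentum, config@seed)
    weights <- fit$weights
    weights$lrUsed <- lr
    history <- data.frame(epoch = seq_len(nrow(fit$history)),
                          trainLoss = fit$history[, 1],
                          valLoss = fit$history[, 2],
                          valAccuracy = fit$history[, 3])
    bestEpoch <- as.integer(fit$bestEpoch)
  }
  methods::new("MRepModel", backbone = config@backbone, weights = weights,
               classLevels = classLevels, gridDim = c(p, q),
               maps = lapply(stacks, function(s) s@map),
               normalizer = normalizer, history = history,
               bestEpoch = bestEpoch, config = config,
               collision = collision)
}

#' Class probabilities for images
#'
#' Runs the trained network forward. Output rows are softmax probability
#' vectors: non-negative, summing to 1.
#'
#' @param model an [MRepModel-class].
#' @param image a single p x q matrix, a p x q x n array, or a (p*q) x n
#'   matrix of flattened images.
#' @return a numeric vector of length c (single image) or an n x c matrix.
#' @export
predictProbabilities <- function(model, image) {
  p <- model@gridDim[1]; q <- model@gridDim[2]
  single <- FALSE
  if (is.matrix(image) && all(dim(image) == c(p, q))) {
    X <- matrix(as.numeric(image), ncol = 1)
    single <- TRUE
  } else if (is.array(image) && length(dim(image)) == 3L) {
    if (!all(dim(image)[1:2] == c(p, q)))
      stop("image shape ", dim(image)[1], "x", dim(image)[2],
           " does not match the model grid ", p, "x", q)
    X <- matrix(image, nrow = p * q)
  } else if (is.matrix(image) && nrow(image) == p * q) {
    X <- image
  } else {
    stop("image shape does not match the model grid ", p, "x", q)
  }
  probs <- if (model@backbone == "custom") {
    pf <- model@weights$predictFun
    if (!is.function(pf)) stop("custom backbone requires params$predictFun")
    pf(model@weights$custom, X, p = p, q = q)
  } else {
    .cnn_predict_cpp(model@weights, X)
  }
  colnames(probs) <- model@classLevels
  if (single) probs[1, ] else probs
}
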