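#' Transform a test sample into its m representation images
#'
#' Maps a (normalized) sample through every frozen PixelMap carried by a
#' trained model -- no embedding is ever re-fitted at test time -- and
#' applies each representation's enhancement filter. This is the exact code
#' path used for training stacks, so re-transforming a training sample
#' reproduces its training images bit for bit.
#'
#' @param x numeric sample vector of length d, normalized into [0,1] with
#'   the training normalizer (see [applyNorm2()]).
#' @param model an [MRepModel-class].
#' @return list of m p x q image matrices.
#' @export
transformTestSample <- function(x, model) {
  d <- nrow(model@maps[[1]]@coords)
  if (length(x) != d)
    stop("sample has ", length(x), " values but the model was trained on ",
         d, " features")
  lapply(model@maps, function(map)
    applyRepFilter(renderSample(x, map, model@collision), map))
}

#' Soft-voting average of per-representation probabilities
#'
#' The unweighted arithmetic mean of the m probability rows; with m = 1 it
#' is the identity, recovering the single-representation behaviour.
#'
#' @param rows an m x c matrix or a list of length-c probability vectors,
#'   each summing to 1 (tolerance 1e-6).
#' @return length-c averaged probability vector.
#' @export
averageProbabilities <- function(rows) {
  if (is.list(rows)) {
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("ragged probability rows: lengths ", paste(lens, collapse = ", "))
    rows <- do.call(rbind, rows)
  }
  if (!is.matrix(rows) || nrow(rows) < 1L)
    stop("need at least one probability row")
  bad <- abs(rowSums(rows) - 1) > 1e-6
  if (any(bad))
    stop("probability row(s) ", paste(which(bad), collapse = ", "),
         " do not sum to 1")
  colMeans(rows)
}

#' Arg-max classification of an averaged probability vector
#'
#' Deterministic tie-break: the lowest class index wins.
#'
#' @param rho probability vector of length c.
#' @return integer class label in 1..c.
#' @export
classifyProbabilities <- function(rho) {
  if (!length(rho)) stop("empty probability vector")
  which.max(rho)
}

#' Classify a batch of samples by multi-representation soft voting
#'
#' Each raw sample is normalized with the model's training normalizer,
#' rendered under all m representations, scored by the network, and
#' assigned the class with the highest average probability. Rendering and
#' network forward passes are batched per representation.
#'
#' @param ds a [TabularDataset-class] of raw (or already-normalized) test
#'   samples; labels, when present, are used to score accuracy.
#' @param model an [MRepModel-class].
#' @return a [PredictionSet-class]; `accuracy(x)` is the percentage of
#'   correctly classified samples (NA without labels).
#' @export
predictBatch <- function(ds, model) {
  if (nSamples(ds) == 0L) stop("empty test set")
  if (nFeatures(ds) != nrow(model@maps[[1]]@coords))
    stop("feature count does not match the trained model")
  if (model@normalizer@fitted) ds <- applyNorm2(model@normalizer, ds)
  v <- featureValues(ds)
  n <- ncol(v)
  m <- length(model@maps)
  nc <- length(model@classLevels)
  p <- model@gridDim[1]; q <- model@gridDim[2]
  perRep <- array(NA_real_, dim = c(n, nc, m),
                  dimnames = list(colnames(v), model@classLevels, NULL))
  for (r in seq_len(m)) {
    map <- model@maps[[r]]
    X <- matrix(0, p * q, n)
    for (j in seq_len(n))
      X[, j] <- applyRepFilter(renderSample(v[, j], map, model@collision), map)
    perRep[, , r] <- predictProbabilities(model, X)
  }
  averaged <- apply(perRep, c(1, 2), mean)
  if (n == 1L) averaged <- matrix(averaged, 1, nc,
                                  dimnames = list(colnames(v),
                                                  model@classLevels))
  predicted <- apply(averaged, 1, which.max)
  truth <- sampleLabels(ds)
  acc <- if (length(truth)) 100 * mean(predicted == truth) else NA_real_
  methods::new("PredictionSet", sampleIds = colnames(v), perRep = perRep,
               averaged = averaged, predicted = as.integer(predicted),
               truth = as.integer(truth), accuracy = acc,
               classLevels = model@classLevels)
}

#' Write predictions as CSV
#'
#' One row per sample: sample id, the averaged per-class probabilities and
#' the predicted label. With `perRepresentation = TRUE` an extra file
#' `<stem>_per_representation.csv` dumps every representation's probability
#' row for diagnostics.
#'
#' @param predictions a [PredictionSet-class].
#' @param path output CSV path.
#' @param perRepresentation also dump per-representation rows.
#' @export
writePredictions <- function(predictions, path, perRepresentation = FALSE) {
  av <- predictions@averaged
  df <- data.frame(sample_id = predictions@sampleIds,
                   av,
                   predicted = predictions@classLevels[predictions@predicted],
                   check.names = FALSE)
  names(df)[2:(1 + ncol(av))] <- paste0("prob_", predictions@classLevels)
  write.csv(df, path, row.names = FALSE)
  if (perRepresentation) {
    m <- dim(predictions@perRep)[3]
    long <- do.call(rbind, lapply(seq_len(m), function(r) {
      data.frame(sample_id = predictions@sampleIds, representation = r,
                 predictions@perRep[, , r, drop = FALSE][, , 1],
                 check.names = FALSE)
    }))
    write.csv(long, sub("(\\.csv)?$", "_per_representation.csv", path),
              row.names = FALSE)
  }
  invisible(path)
}
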