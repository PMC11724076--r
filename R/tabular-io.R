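#' Read a delimited table into a TabularDataset
#'
#' The file is expected sample-per-row with a header naming the features and
#' a label column; orientation is normalised to the internal features x
#' samples layout. Missing feature values follow `missing`: `"error"`
#' (default) aborts naming the offending cell, `"median"` imputes the
#' per-feature median (computed over the non-missing entries of the file
#' being read) and records the affected cells in the dataset metadata.
#'
#' @param path file path.
#' @param labelColumn name of the label column (default "label").
#' @param delimiter field delimiter, "," or "\t".
#' @param missing missing-value policy, "error" or "median".
#' @return a [TabularDataset-class].
#' @export
readTabular <- function(path, labelColumn = "label", delimiter = ",",
                        missing = c("error", "median")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = delimiter, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!labelColumn %in% names(df))
    stop("label column '", labelColumn, "' not present in ", path)
  labels <- df[[labelColumn]]
  feat <- df[names(df) != labelColumn]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      suppressWarnings(num <- as.numeric(feat[[j]]))
      bad <- which(is.na(num) & !is.na(feat[[j]]) & feat[[j]] != "" &
                   tolower(feat[[j]]) != "na")
      if (length(bad))
        stop("non-numeric value in column '", names(feat)[j], "', row ",
             bad[1], ": '", feat[[j]][bad[1]], "'")
      feat[[j]] <- num
    }
  }
  values <- t(as.matrix(feat))           # features x samples
  imputed <- NULL
  if (anyNA(values)) {
    naIdx <- which(is.na(values), arr.ind = TRUE)
    if (missing == "error") {
      stop("missing value at feature '", rownames(values)[naIdx[1, 1]],
           "', sample row ", naIdx[1, 2],
           " (set missing = 'median' to impute)")
    }
    for (i in unique(naIdx[, 1])) {
      med <- median(values[i, ], na.rm = TRUE)
      values[i, is.na(values[i, ])] <- med
    }
    imputed <- naIdx
  }
  ids <- idSeq("s", ncol(values))
  tabularDataset(values, labels, featureNames = rownames(values),
                 sampleIds = ids,
                 metadata = list(source = path, imputedCells = imputed))
}

#' Write a TabularDataset as delimited text
#'
#' Samples as rows, header `f1..fd,label`, labels written as their integer
#' codes 1..c. Round-trips with [readTabular()].
#'
#' @param ds a [TabularDataset-class].
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
writeTabular <- function(ds, path, delimiter = ",") {
  df <- as.data.frame(t(featureValues(ds)), check.names = FALSE)
  df$label <- sampleLabels(ds)
  write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Splits samples into disjoint covering partitions. With `stratified =
#' TRUE` (default) the split is applied class-by-class, so per-class
#' proportions are within one sample of the targets; sizes follow
#' largest-remainder apportionment (7400 samples at 80:10:10 give
#' 5920/740/740).
#'
#' @param ds a [TabularDataset-class].
#' @param fractions partition fractions summing to 1 (default 80:10:10).
#' @param seed RNG seed; identical seeds give identical splits.
#' @param stratified stratify by class label.
#' @return a list with integer index vectors `train`, `validation`, `test`
#'   (or `part1..partk` for other partition counts), plus `seed` and
#'   `stratified`.
#' @export
splitDataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                         stratified = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  k <- length(fractions)
  n <- nSamples(ds)
  parts <- replicate(k, integer(0), simplify = FALSE)
  if (stratified) {
    labs <- sampleLabels(ds)
    for (cl in sort(unique(labs))) {
      idx <- which(labs == cl)
      if (length(idx) < k)
        stop("class ", cl, " has ", length(idx),
             " samples, fewer than the ", k, " split parts; cannot stratify")
      idx <- withSeed(deriveSeed(seed, paste0("split", cl)),
                      idx[sample.int(length(idx))])
      sizes <- apportion(length(idx), fractions)
      off <- cumsum(c(0L, sizes))
      for (p in seq_len(k))
        parts[[p]] <- c(parts[[p]], idx[(off[p] + 1L):off[p + 1L]][seq_len(sizes[p])])
    }
    parts <- lapply(parts, sort)
  } else {
    idx <- withSeed(deriveSeed(seed, "split"), sample.int(n))
    sizes <- apportion(n, fractions)
    off <- cumsum(c(0L, sizes))
    for (p in seq_len(k))
      parts[[p]] <- sort(idx[seq.int(off[p] + 1L, length.out = sizes[p])])
  }
  names(parts) <- if (k == 3L) c("train", "validation", "test")
                  else paste0("part", seq_len(k))
  c(parts, list(seed = as.integer(seed), stratified = stratified))
}

#' Subset a TabularDataset by sample indices
#'
#' @param ds a [TabularDataset-class].
#' @param idx sample (column) indices.
#' @return the subset as a [TabularDataset-class].
#' @export
subsetSamples <- function(ds, idx) {
  out <- ds[, idx]
  methods::validObject(out)
  out
}

#' Create an unfitted normalizer
#'
#' @param method "minmax" (default) or "l2minmax"; see
#'   [Norm2Normalizer-class].
#' @export
norm2Normalizer <- function(method = c("minmax", "l2minmax")) {
  methods::new("Norm2Normalizer", method = match.arg(method), fitted = FALSE)
}

#' Fit the norm-2 normalizer on a training partition
#'
#' Records per-feature statistics of the training data only; never fit on
#' validation or test samples. For `"l2minmax"` each feature is first
#' divided by its training L2 norm, then min-max statistics are taken on the
#' scaled values.
#'
#' @param train the training [TabularDataset-class].
#' @param method see [norm2Normalizer()].
#' @return a fitted [Norm2Normalizer-class].
#' @export
fitNorm2 <- function(train, method = c("minmax", "l2minmax")) {
  method <- match.arg(method)
  v <- featureValues(train)
  l2 <- rep(1, nrow(v))
  if (method == "l2minmax") {
    l2 <- sqrt(rowSums(v^2))
    l2[l2 == 0] <- 1
    v <- v / l2
  }
  methods::new("Norm2Normalizer", method = method,
               mins = apply(v, 1, min), maxs = apply(v, 1, max),
               l2norms = l2, featureNames = rownames(v), fitted = TRUE)
}

# rescale a raw feature matrix (features x samples) into [0,1]
norm2Matrix <- function(normalizer, values) {
  if (!normalizer@fitted) stop("normalizer has not been fitted; call fitNorm2() first")
  if (nrow(values) != length(normalizer@mins))
    stop("feature count does not match the fitted normalizer")
  v <- values / normalizer@l2norms
  rng <- normalizer@maxs - normalizer@mins
  const <- rng == 0
  rng[const] <- 1
  out <- (v - normalizer@mins) / rng
  out[const, ] <- 0                       # constant features map to 0
  out[out < 0] <- 0
  out[out > 1] <- 1                       # clip test-time values into [0,1]
  out
}

#' Apply a fitted normalizer to a dataset
#'
#' Values are rescaled into [0,1] with the training statistics; out-of-range
#' values are clipped and constant training features map to 0. The operation
#' is idempotent: a dataset already normalized by the same normalizer is
#' returned unchanged (the normalizer fingerprint is recorded in the dataset
#' metadata).
#'
#' @param normalizer a fitted [Norm2Normalizer-class].
#' @param ds a [TabularDataset-class].
#' @return the normalized [TabularDataset-class].
#' @export
applyNorm2 <- function(normalizer, ds) {
  if (!normalizer@fitted) stop("normalizer has not been fitted; call fitNorm2() first")
  fp <- digest::digest(list(normalizer@method, normalizer@mins,
                            normalizer@maxs, normalizer@l2norms))
  if (identical(S4Vectors::metadata(ds)$normalizedBy, fp)) return(ds)
  out <- norm2Matrix(normalizer, featureValues(ds))
  md <- S4Vectors::metadata(ds)
  md$normalizedBy <- fp
  tabularDataset(out, sampleLabels(ds), featureNames = rownames(out),
                 sampleIds = colnames(featureValues(ds)),
                 classLevels = classLevels(ds), metadata = md)
}
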