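#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats prcomp cov median rnorm sd as.dist predict
#' @importFrom utils read.csv write.csv write.table modifyList
NULL

#' TabularDataset: a labelled feature-by-sample matrix
#'
#' The central container consumed by every stage of the pipeline. It extends
#' \linkS4class{SummarizedExperiment} with the convention that rows are
#' features and columns are samples (the d x n orientation used throughout:
#' a sample is a column vector of d feature values). Class labels are stored
#' as integers 1..c in \code{colData(x)$label}; the mapping from original
#' label strings to integer codes is kept in \code{metadata(x)$classLevels}.
#'
#' @slot .. inherited from SummarizedExperiment; the single assay is named
#'   \code{"values"}.
#' @seealso [tabularDataset()], [featureValues()], [sampleLabels()]
#' @export
setClass("TabularDataset", contains = "SummarizedExperiment")

setValidity("TabularDataset", function(object) {
  v <- SummarizedExperiment::assay(object, "values")
  if (!is.numeric(v)) return("assay 'values' must be numeric")
  if (anyNA(v)) return("assay 'values' contains NA/NaN; apply an imputation policy at load time")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% colnames(cd)) return("colData must carry a 'label' column")
  lab <- cd$label
  if (length(lab) && (!is.numeric(lab) || any(lab != as.integer(lab))))
    return("labels must be integer codes 1..c")
  lev <- S4Vectors::metadata(object)$classLevels
  if (length(lab) && (any(lab < 1L) || any(lab > length(lev))))
    return("labels out of range of metadata classLevels")
  TRUE
})

#' Construct a TabularDataset
#'
#' @param values numeric matrix, features x samples (d x n).
#' @param labels vector of class labels, one per sample. Factors/characters
#'   are encoded to integers 1..c in stable sorted order of the observed
#'   levels; integer input is taken as already-encoded codes.
#' @param featureNames,sampleIds optional names; defaults `f1..fd` / `s1..sn`.
#' @param classLevels optional character vector naming the classes behind
#'   integer codes; inferred when `labels` is factor/character.
#' @param metadata extra metadata list entries.
#' @return a [TabularDataset-class] object.
#' @export
tabularDataset <- function(values, labels,
                           featureNames = NULL, sampleIds = NULL,
                           classLevels = NULL, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  d <- nrow(values); n <- ncol(values)
  if (length(labels) != n)
    stop("length(labels) [", length(labels), "] != number of samples [", n, "]")
  if (is.null(featureNames)) featureNames <- idSeq("f", d)
  if (is.null(sampleIds))    sampleIds    <- idSeq("s", n)
  if (is.factor(labels) || is.character(labels)) {
    lv  <- sort(unique(as.character(labels)))
    lab <- match(as.character(labels), lv)
    if (is.null(classLevels)) classLevels <- lv
  } else {
    lab <- as.integer(labels)
    if (is.null(classLevels))
      classLevels <- as.character(seq_len(max(lab, 0L)))
  }
  rownames(values) <- featureNames
  colnames(values) <- sampleIds
  metadata[["classLevels"]] <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(values = values),
    colData = S4Vectors::DataFrame(label = lab, row.names = sampleIds),
    metadata = c(list(classLevels = classLevels), metadata))
  methods::new("TabularDataset", se)
}

#' Min-max normalizer fitted on training data ("norm-2" in the DeepInsight
#' lineage)
#'
#' Two variants are supported: plain per-feature min-max to [0,1]
#' (`"minmax"`, the default) and per-feature division by the training L2
#' norm followed by min-max (`"l2minmax"`). Both bound values to [0,1],
#' the range the image encoder requires; out-of-range test-time values are
#' clipped. Fit strictly on the training partition.
#'
#' @slot method character, "minmax" or "l2minmax".
#' @slot mins,maxs per-feature statistics on the (possibly L2-scaled)
#'   training values.
#' @slot l2norms per-feature L2 norms (1s for method "minmax").
#' @slot featureNames the features the normalizer was fitted on.
#' @slot fitted logical.
#' @export
setClass("Norm2Normalizer",
  representation(method = "character", mins = "numeric", maxs = "numeric",
                 l2norms = "numeric", featureNames = "character",
                 fitted = "logical"),
  prototype(method = "minmax", fitted = FALSE))

setValidity("Norm2Normalizer", function(object) {
  if (!object@method %in% c("minmax", "l2minmax"))
    return("method must be 'minmax' or 'l2minmax'")
  if (object@fitted &&
      (length(object@mins) != length(object@maxs) ||
       length(object@mins) != length(object@featureNames)))
    return("fitted statistics have inconsistent lengths")
  TRUE
})

#' One tabular-to-image representation recipe
#'
#' A representation is a manifold technique applied to the transposed data
#' matrix (so features, not samples, receive 2-D coordinates), an optional
#' distance metric (t-SNE only), and an optional image enhancement filter.
#'
#' @slot technique "tsne", "umap", "pca" or "kpca".
#' @slot metric for t-SNE: "euclidean", "cosine", "hamming", "chebychev" or
#'   "mahalanobis"; must be "none" for other techniques.
#' @slot filter "none", "blur" or "gabor".
#' @slot params technique/filter settings (perplexity, n_neighbors, kernel
#'   sigma, blur sigma, Gabor bank, ...).
#' @slot seed integer seed controlling every stochastic step of the recipe.
#' @export
setClass("RepresentationSpec",
  representation(technique = "character", metric = "character",
                 filter = "character", params = "list", seed = "integer"))

setValidity("RepresentationSpec", function(object) {
  if (!object@technique %in% c("tsne", "umap", "pca", "kpca"))
    return("technique must be one of tsne/umap/pca/kpca")
  if (object@technique == "tsne") {
    if (!object@metric %in% c("euclidean", "cosine", "hamming", "chebychev",
                              "mahalanobis"))
      return("t-SNE metric must be euclidean/cosine/hamming/chebychev/mahalanobis")
  } else if (object@metric != "none") {
    return("metric may only be set when technique == 'tsne'")
  }
  if (!object@filter %in% c("none", "blur", "gabor")) {
    if (object@filter == "assignment")
      return("the assignment-distribution filter is not implemented")
    return("filter must be one of none/blur/gabor")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' @rdname RepresentationSpec-class
#' @param technique,metric,filter,params,seed see slots.
#' @export
representationSpec <- function(technique = c("tsne", "umap", "pca", "kpca"),
                               metric = NULL, filter = "none",
                               params = list(), seed = 1L) {
  technique <- match.arg(technique)
  if (is.null(metric)) metric <- if (technique == "tsne") "euclidean" else "none"
  methods::new("RepresentationSpec", technique = technique, metric = metric,
               filter = filter, params = params, seed = as.integer(seed))
}

#' Frozen per-feature pixel locations for one representation
#'
#' Computed once from training data and reused verbatim at test time. The
#' coordinate contract: `coords[i, ]` is the 0-based integer pair
#' `(a_i, b_i)` of feature i, with `0 <= a_i < p` rows and `0 <= b_i < q`
#' columns; cells are half-open `[k, k+1)` and the discretised rectangle is
#' anchored at cell (0, 0).
#'
#' @slot p,q grid rows / columns.
#' @slot coords d x 2 integer matrix of (row, col) pairs.
#' @slot rotationDeg rotation (degrees, counter-clockwise) that aligned the
#'   minimum-area bounding rectangle with the axes.
#' @slot spec the [RepresentationSpec-class] that produced the map.
#' @slot embedding the raw d x 2 embedding, retained for diagnostics.
#' @slot featureNames feature order the coordinates refer to.
#' @export
setClass("PixelMap",
  representation(p = "integer", q = "integer", coords = "matrix",
                 rotationDeg = "numeric", spec = "RepresentationSpec",
                 embedding = "matrix", featureNames = "character"))

setValidity("PixelMap", function(object) {
  if (object@p < 1L || object@q < 1L) return("grid dimensions must be >= 1")
  co <- object@coords
  if (ncol(co) != 2L) return("coords must have two columns (a, b)")
  if (nrow(co) != length(object@featureNames))
    return("coords must have one row per feature")
  if (nrow(co)) {
    if (any(co != floor(co))) return("coords must be integral")
    if (any(co[, 1] < 0) || any(co[, 1] >= object@p) ||
        any(co[, 2] < 0) || any(co[, 2] >= object@q))
      return("pixel coordinates out of grid bounds")
  }
  TRUE
})

#' A stack of images for one representation
#'
#' Holds the n images of one representation r: a p x q x n array with values
#' in [0,1], together with the PixelMap that produced them.
#'
#' @slot repIndex index r of the representation.
#' @slot images p x q x n numeric array.
#' @slot map the source [PixelMap-class].
#' @slot sampleIds sample identifiers (third-dimension order).
#' @export
setClass("ImageStack",
  representation(repIndex = "integer", images = "array", map = "PixelMap",
                 sampleIds = "character"))

setValidity("ImageStack", function(object) {
  dm <- dim(object@images)
  if (length(dm) != 3L) return("images must be a p x q x n array")
  if (dm[1] != object@map@p || dm[2] != object@map@q)
    return("image shape does not match the PixelMap grid")
  if (dm[3] != length(object@sampleIds))
    return("one image per sample required")
  rng <- range(object@images, 0)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("image values must lie in [0,1]")
  TRUE
})

#' Training hyperparameters for the convolutional classifier
#'
#' Defaults follow the method's printed optimizer settings: SGD with
#' learning rate 0.001, weight decay 0.0001 and momentum 0.9. An optional
#' learning-rate grid (validated on the validation set) replaces large-scale
#' Bayesian hyperparameter search at desk scale.
#'
#' @slot backbone "small_cnn" (built-in), "custom" (params$trainFun /
#'   params$predictFun), or the named pretrained nets "resnet50" /
#'   "efficientnet_b6" (not bundled; selecting them errors with guidance).
#' @slot lr,weightDecay,momentum SGD settings.
#' @slot epochs,batchSize training loop sizes.
#' @slot seed controls weight init and shuffling.
#' @slot pretrained flag, only meaningful for the named backbones.
#' @slot params backbone-specific extras (e.g. lrGrid, screenEpochs).
#' @export
setClass("TrainConfig",
  representation(backbone = "character", lr = "numeric",
                 weightDecay = "numeric", momentum = "numeric",
                 epochs = "integer", batchSize = "integer", seed = "integer",
                 pretrained = "logical", params = "list"))

setValidity("TrainConfig", function(object) {
  if (!object@backbone %in% c("small_cnn", "custom", "resnet50",
                              "efficientnet_b6"))
    return("unknown backbone")
  if (object@lr <= 0 || object@epochs < 1L || object@batchSize < 1L)
    return("lr, epochs and batchSize must be positive")
  if (object@pretrained && !object@backbone %in% c("resnet50", "efficientnet_b6"))
    return("pretrained weights exist only for the named large backbones")
  TRUE
})

#' @rdname TrainConfig-class
#' @param backbone,lr,weightDecay,momentum,epochs,batchSize,seed,pretrained,params
#'   see slots.
#' @export
trainConfig <- function(backbone = "small_cnn", lr = 0.001,
                        weightDecay = 1e-4, momentum = 0.9, epochs = 30L,
                        batchSize = 64L, seed = 1L, pretrained = FALSE,
                        params = list()) {
  methods::new("TrainConfig", backbone = backbone, lr = lr,
               weightDecay = weightDecay, momentum = momentum,
               epochs = as.integer(epochs), batchSize = as.integer(batchSize),
               seed = as.integer(seed), pretrained = pretrained,
               params = params)
}

#' A trained multi-representation model
#'
#' Bundles everything needed to classify a raw sample: the fitted
#' normalizer, the frozen PixelMaps of all m representations, the network
#' weights and the training history.
#'
#' @slot backbone backbone name.
#' @slot weights backbone weight list (opaque to R for the built-in CNN).
#' @slot classLevels class names behind integer codes 1..c.
#' @slot gridDim c(p, q).
#' @slot maps list of [PixelMap-class], one per representation.
#' @slot normalizer the training [Norm2Normalizer-class] (may be unfitted if
#'   inputs are pre-normalized).
#' @slot history data.frame epoch/trainLoss/valLoss/valAccuracy.
#' @slot bestEpoch epoch whose weights were retained (checkpoint-best).
#' @slot config the [TrainConfig-class] used.
#' @slot collision collision aggregation rule used at render time.
#' @export
setClass("MRepModel",
  representation(backbone = "character", weights = "list",
                 classLevels = "character", gridDim = "integer",
                 maps = "list", normalizer = "Norm2Normalizer",
                 history = "data.frame", bestEpoch = "integer",
                 config = "TrainConfig", collision = "character"))

setValidity("MRepModel", function(object) {
  if (length(object@maps) < 1L) return("representation list must be non-empty")
  if (length(object@classLevels) < 2L) return("need at least 2 classes")
  if (!object@collision %in% c("mean", "max")) return("collision must be mean/max")
  TRUE
})

#' Batch predictions with per-representation detail
#'
#' @slot sampleIds sample identifiers.
#' @slot perRep n x c x m array of per-representation probability rows.
#' @slot averaged n x c matrix of soft-voting averages.
#' @slot predicted integer predicted labels 1..c.
#' @slot truth integer true labels (length 0 when unknown).
#' @slot accuracy percentage of correct predictions (NA when truth absent).
#' @slot classLevels class names.
#' @export
setClass("PredictionSet",
  representation(sampleIds = "character", perRep = "array",
                 averaged = "matrix", predicted = "integer",
                 truth = "integer", accuracy = "numeric",
                 classLevels = "character"))

setValidity("PredictionSet", function(object) {
  n <- length(object@sampleIds)
  if (nrow(object@averaged) != n || length(object@predicted) != n)
    return("inconsistent prediction dimensions")
  if (n) {
    sums <- rowSums(object@averaged)
    if (any(abs(sums - 1) > 1e-6)) return("averaged rows must sum to 1")
    if (any(object@predicted < 1L) ||
        any(object@predicted > ncol(object@averaged)))
      return("predicted labels out of class range")
  }
  TRUE
})

#' Benchmark experiment report
#'
#' One row per method per seed plus a mean +/- sd summary, with the split
#' sizes and a configuration fingerprint for reproducibility.
#'
#' @slot results data.frame: method, seed, accuracy (percent).
#' @slot summary data.frame: method, mean, sd.
#' @slot splitSizes integer c(train, validation, test).
#' @slot seeds seeds used.
#' @slot fingerprint digest of the full configuration.
#' @export
setClass("ExperimentReport",
  representation(results = "data.frame", summary = "data.frame",
                 splitSizes = "integer", seeds = "integer",
                 fingerprint = "character"))

setValidity("ExperimentReport", function(object) {
  if (nrow(object@results) &&
      (any(object@results$accuracy < 0) || any(object@results$accuracy > 100)))
    return("accuracies must lie in [0, 100]")
  TRUE
})
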