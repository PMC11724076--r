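#' Accessors for pipeline objects
#'
#' Accessor generics follow the Bioconductor convention of never touching
#' slots directly.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @return `featureValues`: the d x n numeric matrix (features x samples).
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setMethod("featureValues", "TabularDataset", function(x, ...)
  SummarizedExperiment::assay(x, "values"))

#' @rdname accessors
#' @return `sampleLabels`: integer class codes 1..c, one per sample.
#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "TabularDataset", function(x, ...)
  as.integer(SummarizedExperiment::colData(x)$label))

#' @rdname accessors
#' @return `classLevels`: character names of the classes behind codes 1..c.
#' @export
setGeneric("classLevels", function(x, ...) standardGeneric("classLevels"))

#' @rdname accessors
#' @export
setMethod("classLevels", "TabularDataset", function(x, ...)
  S4Vectors::metadata(x)$classLevels)

#' @rdname accessors
#' @export
setMethod("classLevels", "MRepModel", function(x, ...) x@classLevels)

#' @rdname accessors
#' @return `nFeatures` / `nSamples`: dataset dimensions.
#' @export
setGeneric("nFeatures", function(x, ...) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setMethod("nFeatures", "TabularDataset", function(x, ...) nrow(x))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x, ...) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setMethod("nSamples", "TabularDataset", function(x, ...) ncol(x))

#' @rdname accessors
#' @return `pixelCoords`: the d x 2 integer (row, col) coordinate matrix of a
#'   PixelMap (0-based, see the class contract).
#' @export
setGeneric("pixelCoords", function(x, ...) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setMethod("pixelCoords", "PixelMap", function(x, ...) x@coords)

#' @rdname accessors
#' @return `gridDim`: c(p, q) grid shape.
#' @export
setGeneric("gridDim", function(x, ...) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setMethod("gridDim", "PixelMap", function(x, ...) c(x@p, x@q))

#' @rdname accessors
#' @export
setMethod("gridDim", "MRepModel", function(x, ...) x@gridDim)

#' @rdname accessors
#' @return `stackImages`: the p x q x n image array of an ImageStack.
#' @export
setGeneric("stackImages", function(x, ...) standardGeneric("stackImages"))

#' @rdname accessors
#' @export
setMethod("stackImages", "ImageStack", function(x, ...) x@images)

#' @rdname accessors
#' @return `representationMaps`: list of PixelMaps carried by a model.
#' @export
setGeneric("representationMaps", function(x, ...)
  standardGeneric("representationMaps"))

#' @rdname accessors
#' @export
setMethod("representationMaps", "MRepModel", function(x, ...) x@maps)

#' @rdname accessors
#' @return `trainingHistory`: per-epoch loss/accuracy data.frame.
#' @export
setGeneric("trainingHistory", function(x, ...)
  standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setMethod("trainingHistory", "MRepModel", function(x, ...) x@history)

#' @rdname accessors
#' @return `predictedLabels` / `averagedProbabilities` / `accuracy`:
#'   components of a PredictionSet.
#' @export
setGeneric("predictedLabels", function(x, ...)
  standardGeneric("predictedLabels"))

#' @rdname accessors
#' @export
setMethod("predictedLabels", "PredictionSet", function(x, ...) x@predicted)

#' @rdname accessors
#' @export
setGeneric("averagedProbabilities", function(x, ...)
  standardGeneric("averagedProbabilities"))

#' @rdname accessors
#' @export
setMethod("averagedProbabilities", "PredictionSet", function(x, ...)
  x@averaged)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setMethod("accuracy", "PredictionSet", function(x, ...) x@accuracy)

#' @rdname accessors
#' @return `reportResults` / `reportSummary`: the per-seed rows and the
#'   mean/sd summary of an ExperimentReport.
#' @export
setGeneric("reportResults", function(x, ...) standardGeneric("reportResults"))

#' @rdname accessors
#' @export
setMethod("reportResults", "ExperimentReport", function(x, ...) x@results)

#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x, ...) standardGeneric("reportSummary"))

#' @rdname accessors
#' @export
setMethod("reportSummary", "ExperimentReport", function(x, ...) x@summary)

setMethod("show", "TabularDataset", function(object) {
  cat("TabularDataset:", nrow(object), "features x", ncol(object), "samples,",
      length(S4Vectors::metadata(object)$classLevels), "classes\n")
  if (ncol(object)) {
    tab <- table(sampleLabels(object))
    cat("  class counts:", paste(tab, collapse = "/"), "\n")
  }
})

setMethod("show", "RepresentationSpec", function(object) {
  met <- if (object@metric != "none") paste0(" (", object@metric, ")") else ""
  fil <- if (object@filter != "none") paste0(" + ", object@filter) else ""
  cat("RepresentationSpec: ", object@technique, met, fil,
      ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "PixelMap", function(object) {
  cat("PixelMap: ", nrow(object@coords), " features on a ", object@p, "x",
      object@q, " grid (rotation ", round(object@rotationDeg, 2),
      " deg)\n  ", sep = "")
  show(object@spec)
})

setMethod("show", "ImageStack", function(object) {
  dm <- dim(object@images)
  cat("ImageStack r=", object@repIndex, ": ", dm[3], " images of ", dm[1],
      "x", dm[2], "\n", sep = "")
})

setMethod("show", "MRepModel", function(object) {
  cat("MRepModel: backbone ", object@backbone, ", ",
      length(object@maps), " representation(s), ",
      length(object@classLevels), " classes, grid ",
      object@gridDim[1], "x", object@gridDim[2], "\n", sep = "")
  if (nrow(object@history))
    cat("  best epoch ", object@bestEpoch, " (validation accuracy ",
        round(object@history$valAccuracy[object@bestEpoch], 2), "%)\n",
        sep = "")
})

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet:", length(object@sampleIds), "samples,",
      dim(object@perRep)[3], "representation(s)")
  if (!is.na(object@accuracy))
    cat(", accuracy ", round(object@accuracy, 2), "%", sep = "")
  cat("\n")
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport over seeds",
      paste(object@seeds, collapse = ", "), "\n")
  cat("  split sizes:", paste(object@splitSizes, collapse = "/"), "\n")
  print(object@summary, row.names = FALSE)
})
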