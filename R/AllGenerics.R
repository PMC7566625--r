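# Generics and accessors. Slot access goes through these everywhere.

#' @rdname RegisteredPair-class
#' @param object,x an object.
#' @export
setGeneric("heImage", function(object) standardGeneric("heImage"))
#' @rdname RegisteredPair-class
#' @export
setGeneric("ifImage", function(object) standardGeneric("ifImage"))
#' @rdname RegisteredPair-class
#' @export
setGeneric("nuclearImage", function(object) standardGeneric("nuclearImage"))
#' @rdname RegisteredPair-class
#' @export
setGeneric("markerMask", function(object) standardGeneric("markerMask"))
#' @rdname RegisteredPair-class
#' @export
setGeneric("plantedAffine", function(object) standardGeneric("plantedAffine"))
#' @rdname RegisteredPair-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setMethod("heImage", "RegisteredPair", function(object) object@he)
#' @export
setMethod("ifImage", "RegisteredPair", function(object) object@ifMarker)
#' @export
setMethod("nuclearImage", "RegisteredPair", function(object)
  if (length(object@nuclear)) object@nuclear else NULL)
#' @export
setMethod("markerMask", "RegisteredPair", function(object)
  object@groundTruth$markerMask)
#' @export
setMethod("plantedAffine", "RegisteredPair", function(object)
  object@groundTruth$affine)
#' @export
setMethod("sampleId", "RegisteredPair", function(object) object@sampleId)

setMethod("show", "RegisteredPair", function(object) {
  d <- dim(object@he)
  cat(sprintf("RegisteredPair: %d x %d H&E/IF pair, sample '%s'%s\n",
      d[1], d[2], object@sampleId,
      if (length(object@nuclear)) " (+nuclear channel)" else ""))
})

#' @rdname RegistrationModel-class
#' @param object an object.
#' @export
setGeneric("registrationAffine", function(object) standardGeneric("registrationAffine"))
#' @rdname RegistrationModel-class
#' @export
setGeneric("nMatchedFeatures", function(object) standardGeneric("nMatchedFeatures"))
#' @rdname RegistrationModel-class
#' @export
setGeneric("inlierFraction", function(object) standardGeneric("inlierFraction"))

#' @export
setMethod("registrationAffine", "RegistrationModel", function(object) object@affine)
#' @export
setMethod("nMatchedFeatures", "RegistrationModel", function(object) object@nMatchedFeatures)
#' @export
setMethod("inlierFraction", "RegistrationModel", function(object) object@inlierFraction)

setMethod("show", "RegistrationModel", function(object) {
  cat("RegistrationModel\n  affine:\n")
  print(round(object@affine, 5))
  cat(sprintf("  matches: %d, inlier fraction: %.3f\n",
      object@nMatchedFeatures, object@inlierFraction))
})

#' @rdname TileSet-class
#' @param object,x a TileSet.
#' @export
setGeneric("heTiles", function(object) standardGeneric("heTiles"))
#' @rdname TileSet-class
#' @export
setGeneric("ifTiles", function(object) standardGeneric("ifTiles"))
#' @rdname TileSet-class
#' @export
setGeneric("tileInfo", function(object) standardGeneric("tileInfo"))

#' @export
setMethod("heTiles", "TileSet", function(object) object@he)
#' @export
setMethod("ifTiles", "TileSet", function(object) object@ifch)
#' @export
setMethod("tileInfo", "TileSet", function(object) object@info)
#' @export
setMethod("length", "TileSet", function(x) length(x@he))

#' @export
#' @rdname TileSet-class
#' @param i index vector.
#' @param j,drop,... ignored.
setMethod("[", "TileSet", function(x, i, j, ..., drop = FALSE) {
  new("TileSet", he = x@he[i], ifch = x@ifch[i],
      info = x@info[i, , drop = FALSE], tileSize = x@tileSize)
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet: %d tiles of %d px from %d sample(s)\n",
      length(object@he), object@tileSize,
      length(unique(object@info$sample_id))))
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (most representative first)\n")
  for (i in seq_along(object@samples))
    cat(sprintf("  %d. %-8s weighted-KL score %.6g\n", i,
        object@samples[i], object@scores[i]))
})

#' @rdname SelectionResult-class
#' @param object a SelectionResult.
#' @export
setGeneric("selectedSamples", function(object) standardGeneric("selectedSamples"))
#' @rdname SelectionResult-class
#' @export
setGeneric("selectionScores", function(object) standardGeneric("selectionScores"))
#' @export
setMethod("selectedSamples", "SelectionResult", function(object) object@samples)
#' @export
setMethod("selectionScores", "SelectionResult", function(object)
  setNames(object@scores, object@samples))

#' @rdname TileFeatures-class
#' @param object a TileFeatures.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname TileFeatures-class
#' @export
setGeneric("sampleMembership", function(object) standardGeneric("sampleMembership"))

#' Tile feature accessors
#'
#' `featureMatrix()` returns the tiles x features matrix (tiles in rows);
#' `sampleMembership()` the per-tile sample id.
#' @export
setMethod("featureMatrix", "TileFeatures", function(object)
  t(SummarizedExperiment::assay(object, "features")))
#' @export
setMethod("sampleMembership", "TileFeatures", function(object)
  as.character(SummarizedExperiment::colData(object)$sample_id))

#' @rdname Translator-class
#' @param object a Translator.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname Translator-class
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @export
setMethod("modelConfig", "Translator", function(object) object@config)
#' @export
setMethod("trainingHistory", "Translator", function(object) object@history)

setMethod("show", "Translator", function(object) {
  cfg <- object@config
  cat(sprintf("Translator: mode '%s', %d px tiles, first layer %d filters, %d steps trained\n",
      cfg@mode, cfg@tileSize, cfg@firstLayerFilters, nrow(object@history)))
})

setMethod("show", "TranslatorConfig", function(object) {
  cat(sprintf(
    "TranslatorConfig: mode '%s', lambda %g, lr %g, epochs %d, batch %d, filters %d, tile %d\n",
    object@mode, object@baseLambda, object@learningRate, object@epochs,
    object@batchSize, object@firstLayerFilters, object@tileSize))
})

setMethod("show", "VaeModel", function(object) {
  cat(sprintf("VaeModel: %d-dim latent, input %d values (%s tiles)\n",
      object@latentDim, object@inputDim,
      paste(object@tileDim, collapse = " x ")))
})
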