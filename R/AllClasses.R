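# Central S4 classes. Images are plain numeric arrays in [0, 1] held in
# class slots; feature tables extend SummarizedExperiment (features in rows,
# tiles in columns, sample membership in colData).

#' PhantomSpec: parameters of a synthetic H&E/IF tissue phantom
#'
#' Describes one simulated field of H&E-stained tissue with a planted
#' single-marker IF channel. Nuclei are rendered as dark-violet disks on pink
#' stroma; marker regions (disks or polygons) carry the IF signal and also
#' receive a nucleus-density boost so the H&E-to-IF mapping is driven by
#' morphology rather than position.
#'
#' @slot height,width image size in pixels.
#' @slot nucleusDensity expected nuclei per pixel^2 outside marker regions.
#' @slot nucleusRadius mean nucleus radius in pixels.
#' @slot paletteId stain palette (1 = violet/pink, 2 = darker eosin-shifted).
#' @slot markerRegions list of shapes: `list(center = c(x, y), radius = r)`
#'   or `list(polygon = <n x 2 (x, y) matrix>)`.
#' @slot markerDensityBoost multiplicative nucleus-density factor inside
#'   marker regions.
#' @slot noiseSd additive Gaussian noise sd on the IF channel (intensity
#'   units in [0, 1]).
#' @slot backgroundLevel 8-bit intensity of non-tissue (glass) background.
#' @slot backgroundRegions list of shapes rendered as blank background.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
    nucleusDensity = "numeric", nucleusRadius = "numeric",
    paletteId = "integer", markerRegions = "list",
    markerDensityBoost = "numeric", noiseSd = "numeric",
    backgroundLevel = "numeric", backgroundRegions = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@height < 1L || object@width < 1L)
    msg <- c(msg, "height and width must be >= 1")
  if (object@height * object@width < 1)
    msg <- c(msg, "image area must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nucleusDensity < 0) msg <- c(msg, "nucleusDensity must be >= 0")
  if (object@markerDensityBoost < 0) msg <- c(msg, "markerDensityBoost must be >= 0")
  if (!(object@paletteId %in% c(1L, 2L))) msg <- c(msg, "paletteId must be 1 or 2")
  for (sh in object@markerRegions) {
    if (!is.null(sh$center)) {
      if (sh$center[1] - sh$radius < 0 || sh$center[2] - sh$radius < 0 ||
          sh$center[1] + sh$radius > object@width - 1 ||
          sh$center[2] + sh$radius > object@height - 1)
        msg <- c(msg, "marker region extends outside the image bounds")
    } else if (!is.null(sh$polygon)) {
      v <- matrix(as.numeric(sh$polygon), ncol = 2L)
      if (min(v) < 0 || max(v[, 1]) > object@width - 1 || max(v[, 2]) > object@height - 1)
        msg <- c(msg, "marker polygon extends outside the image bounds")
    } else msg <- c(msg, "marker region must have a center/radius or a polygon")
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: a multi-sample phantom cohort with planted cluster structure
#'
#' @slot samples data.frame with columns `sample_id`, `n_tiles`, `cluster_id`.
#' @slot clusters named list, one entry per cluster id, each a list of texture
#'   parameters (`nucleusDensity` range, `nucleusRadius`, `paletteId`,
#'   `markerDensityBoost`, `markerProb`, `markerRadius` range).
#' @slot tileSize side of the square tiles generated per sample.
#' @slot noiseSd IF additive noise sd.
#' @slot seed integer seed controlling the whole cohort.
#' @export
setClass("CohortSpec",
  representation(samples = "data.frame", clusters = "list",
    tileSize = "integer", noiseSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("sample_id", "n_tiles", "cluster_id")
  if (!all(need %in% names(s))) {
    msg <- c(msg, "samples must have columns sample_id, n_tiles, cluster_id")
  } else {
    if (nrow(s) < 1L) msg <- c(msg, "at least one sample is required")
    if (anyDuplicated(s$sample_id)) msg <- c(msg, "duplicate sample_id")
    if (any(s$n_tiles < 1)) msg <- c(msg, "n_tiles must be >= 1")
    if (!all(s$cluster_id %in% names(object@clusters)))
      msg <- c(msg, "every sample must reference a defined cluster")
  }
  if (object@tileSize < 16L) msg <- c(msg, "tileSize must be >= 16")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RegisteredPair: a spatially registered H&E / IF image pair
#'
#' Holds an RGB H&E image and a single-channel marker IF image in one
#' coordinate system, plus the DAPI-like nuclear counterstain channel that
#' anchors registration, provenance, and (for phantoms) the planted ground
#' truth (marker mask, misalignment affine, seed).
#'
#' @slot he H x W x 3 numeric array in [0, 1].
#' @slot ifMarker H x W numeric matrix in [0, 1].
#' @slot nuclear H x W numeric matrix (nuclear counterstain) or 0 x 0.
#' @slot sampleId character sample identifier.
#' @slot gridPos integer (row, col) tile-grid position, or NA.
#' @slot groundTruth list; for phantoms: `markerMask`, `affine` (planted
#'   misalignment, identity if none), `seed`, `nucleusCenters`.
#' @export
setClass("RegisteredPair",
  representation(he = "array", ifMarker = "matrix", nuclear = "matrix",
    sampleId = "character", gridPos = "integer", groundTruth = "list"))

setValidity("RegisteredPair", function(object) {
  msg <- character()
  if (length(dim(object@he)) != 3L || dim(object@he)[3] != 3L)
    msg <- c(msg, "he must be an H x W x 3 array")
  if (!all(dim(object@he)[1:2] == dim(object@ifMarker)))
    msg <- c(msg, "he and ifMarker dimensions must agree")
  if (length(object@nuclear) && !all(dim(object@nuclear) == dim(object@ifMarker)))
    msg <- c(msg, "nuclear channel dimensions must agree with ifMarker")
  if (length(msg)) msg else TRUE
})

#' RegistrationModel: a recovered affine registration
#'
#' @slot affine 2 x 3 affine mapping the IF (DAPI) frame onto the H&E frame.
#' @slot nMatchedFeatures number of descriptor matches used.
#' @slot inlierFraction fraction of matches consistent with the affine.
#' @slot meta diagnostics (keypoint counts, residuals).
#' @export
setClass("RegistrationModel",
  representation(affine = "matrix", nMatchedFeatures = "integer",
    inlierFraction = "numeric", meta = "list"))

setValidity("RegistrationModel", function(object) {
  msg <- character()
  if (!all(dim(object@affine) == c(2L, 3L))) msg <- c(msg, "affine must be 2 x 3")
  else if (inherits(try(affineInvert(object@affine), silent = TRUE), "try-error"))
    msg <- c(msg, "affine must be invertible")
  if (object@inlierFraction < 0 || object@inlierFraction > 1)
    msg <- c(msg, "inlierFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TileSet: paired H&E / IF tiles with grid provenance
#'
#' @slot he list of tileSize x tileSize x 3 arrays.
#' @slot ifch list of tileSize x tileSize matrices.
#' @slot info data.frame with columns `sample_id`, `row`, `col`,
#'   `background_fraction`, `if_source_mean` (mean IF intensity of the source
#'   image, used by the adaptive L1 weight).
#' @slot tileSize tile side in pixels.
#' @export
setClass("TileSet",
  representation(he = "list", ifch = "list", info = "data.frame",
    tileSize = "integer"))

setValidity("TileSet", function(object) {
  msg <- character()
  n <- length(object@he)
  if (length(object@ifch) != n || nrow(object@info) != n)
    msg <- c(msg, "he, ifch and info must have equal length")
  need <- c("sample_id", "row", "col", "background_fraction", "if_source_mean")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns", paste(need, collapse = ", ")))
  if (n > 0) {
    d <- dim(object@he[[1]])
    if (d[1] != object@tileSize || d[2] != object@tileSize)
      msg <- c(msg, "tiles must match tileSize")
  }
  if (length(msg)) msg else TRUE
})

#' TileFeatures: latent features of H&E tiles
#'
#' A \linkS4class{SummarizedExperiment} with one assay `"features"`
#' (latent features in rows, tiles in columns) and colData columns
#' `tile_id`, `sample_id`.
#' @export
setClass("TileFeatures", contains = "SummarizedExperiment")

setValidity("TileFeatures", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
    msg <- c(msg, "features must be finite (no missing values)")
  if (!all(c("tile_id", "sample_id") %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must have tile_id and sample_id")
  if (length(msg)) msg else TRUE
})

#' TileProbabilities: per-tile probability distributions over features
#'
#' Row-normalized tile features: each tile (column) is a strictly positive
#' distribution over the feature domain summing to one.
#' @export
setClass("TileProbabilities", contains = "TileFeatures")

setValidity("TileProbabilities", function(object) {
  p <- SummarizedExperiment::assay(object, "features")
  msg <- character()
  if (any(p <= 0)) msg <- c(msg, "all probabilities must be > 0")
  if (any(abs(colSums(p) - 1) > 1e-9))
    msg <- c(msg, "each tile distribution must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: greedy representative-sample sequence
#'
#' @slot samples ordered sample ids, most representative first.
#' @slot scores per-step weighted-KL score of the selected union.
#' @slot subsetSizes named tile counts per sample.
#' @slot total total number of tiles.
#' @slot candidates list of per-step data.frames of all candidate scores.
#' @export
setClass("SelectionResult",
  representation(samples = "character", scores = "numeric",
    subsetSizes = "integer", total = "integer", candidates = "list"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@samples) != length(object@scores))
    msg <- c(msg, "samples and scores lengths differ")
  if (anyDuplicated(object@samples)) msg <- c(msg, "selected sequence has repeats")
  if (any(object@scores < -1e-12)) msg <- c(msg, "scores must be >= 0")
  if (length(msg)) msg else TRUE
})

#' VaeModel: variational autoencoder for tile features
#'
#' Fully-connected encoder/decoder; the encoder emits a (mean, log-variance)
#' pair per latent dimension, the latent mean is the tile feature vector.
#'
#' @slot params named list of weight matrices/bias vectors.
#' @slot latentDim latent dimensionality (default 16).
#' @slot inputDim flattened tile length (h * w * channels).
#' @slot tileDim integer (h, w, c) expected tile shape.
#' @slot config training configuration actually used (architecture, epochs,
#'   batch size, learning rate, seed, loss trace).
#' @export
setClass("VaeModel",
  representation(params = "list", latentDim = "integer", inputDim = "integer",
    tileDim = "integer", config = "list"))

setValidity("VaeModel", function(object) {
  if (object@latentDim < 1L) return("latentDim must be >= 1")
  TRUE
})

#' TranslatorConfig: training configuration for the H&E-to-IF translator
#'
#' Defaults follow the adversarial training recipe (Adam, learning rate
#' 0.002, 500 epochs, batch 64, first layer 128 filters, base L1 weight 100);
#' the `"desk"` profile scales the same architecture down (64 px tiles,
#' 32 first-layer filters, batch 16) for CPU-sized runs.
#'
#' @slot mode `"adversarial"` (generator + patch discriminator) or
#'   `"l1_only"` (generator trained on the weighted L1 loss alone).
#' @slot baseLambda base L1 weight, adapted per batch by stain prevalence.
#' @slot learningRate Adam learning rate.
#' @slot epochs training epochs (full profile).
#' @slot maxSteps optimizer-step cap; NA_integer_ = no cap.
#' @slot batchSize tiles per batch.
#' @slot firstLayerFilters filters in the first generator/discriminator layer.
#' @slot tileSize expected tile side in pixels.
#' @slot seed integer training seed.
#' @slot augment logical; apply paired augmentation to each batch.
#' @export
setClass("TranslatorConfig",
  representation(mode = "character", baseLambda = "numeric",
    learningRate = "numeric", epochs = "integer", maxSteps = "integer",
    batchSize = "integer", firstLayerFilters = "integer",
    tileSize = "integer", seed = "integer", augment = "logical"))

setValidity("TranslatorConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("adversarial", "l1_only"))
    msg <- c(msg, "mode must be 'adversarial' or 'l1_only'")
  if (object@baseLambda < 0) msg <- c(msg, "baseLambda must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@tileSize < 16L || bitwAnd(object@tileSize, object@tileSize - 1L) != 0L)
    msg <- c(msg, "tileSize must be a power of two >= 16")
  if (length(msg)) msg else TRUE
})

#' Translator: a trained H&E-to-IF generator (plus optional discriminator)
#'
#' @slot generator named list of generator weights.
#' @slot discriminator named list of discriminator weights (empty in
#'   `l1_only` mode).
#' @slot config the \linkS4class{TranslatorConfig} used.
#' @slot history data.frame of per-step loss components.
#' @export
setClass("Translator",
  representation(generator = "list", discriminator = "list",
    config = "TranslatorConfig", history = "data.frame"))

setValidity("Translator", function(object) {
  if (object@config@mode == "l1_only" && length(object@discriminator) > 0)
    return("l1_only mode must not allocate a discriminator")
  TRUE
})

#' SsimParams: structural-similarity settings
#'
#' Standard stabilizers c1 = (0.01 L)^2, c2 = (0.03 L)^2 with data range
#' L = 1; uniform 11 x 11 sliding window (stride 1); both images are
#' Gaussian-prefiltered with `prefilterSigma` (0 disables).
#'
#' @slot windowSize odd window side, >= 3.
#' @slot c1,c2 positive stabilizing constants.
#' @slot prefilterSigma Gaussian prefilter sd in pixels.
#' @slot gaussianWeighted use Gaussian-weighted instead of uniform windows.
#' @export
setClass("SsimParams",
  representation(windowSize = "integer", c1 = "numeric", c2 = "numeric",
    prefilterSigma = "numeric", gaussianWeighted = "logical"))

setValidity("SsimParams", function(object) {
  msg <- character()
  if (object@windowSize < 3L || object@windowSize %% 2L == 0L)
    msg <- c(msg, "windowSize must be odd and >= 3")
  if (object@c1 <= 0 || object@c2 <= 0) msg <- c(msg, "c1 and c2 must be > 0")
  if (object@prefilterSigma < 0) msg <- c(msg, "prefilterSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ExperimentConfig: end-to-end experiment description
#'
#' @slot cohort a \linkS4class{CohortSpec}.
#' @slot compositions named list of training-set compositions (character
#'   vectors of sample ids); evaluation is on the samples held out of each.
#' @slot translator a \linkS4class{TranslatorConfig} template.
#' @slot ssim a \linkS4class{SsimParams}.
#' @slot seed global seed fanned out to per-stage seeds.
#' @export
setClass("ExperimentConfig",
  representation(cohort = "CohortSpec", compositions = "list",
    translator = "TranslatorConfig", ssim = "SsimParams", seed = "integer"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  ids <- object@cohort@samples$sample_id
  for (nm in names(object@compositions)) {
    comp <- object@compositions[[nm]]
    if (length(comp) < 1L) msg <- c(msg, sprintf("composition '%s' is empty", nm))
    if (!all(comp %in% ids))
      msg <- c(msg, sprintf("composition '%s' references unknown samples", nm))
    if (all(ids %in% comp))
      msg <- c(msg, sprintf("composition '%s' covers all samples; nothing is held out", nm))
  }
  if (is.null(names(object@compositions)) && length(object@compositions))
    msg <- c(msg, "compositions must be named")
  if (length(msg)) msg else TRUE
})
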