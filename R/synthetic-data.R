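# Synthetic paired H&E / IF tissue phantoms. Every downstream stage of the
# package is testable on these: the IF channel is a deterministic function of
# the H&E morphology (marker regions carry both the IF signal and a nucleus
# density boost), cohorts plant cluster structure through per-cluster texture
# parameters, and misalignments are planted through known affines.

#' Construct a PhantomSpec
#'
#' @param height,width image size in pixels.
#' @param nucleusDensity expected nuclei per pixel^2 outside marker regions.
#' @param nucleusRadius mean nucleus radius in pixels (jittered +/- 20% per
#'   nucleus).
#' @param paletteId stain palette: 1 = violet nuclei on pink stroma,
#'   2 = darker, eosin-shifted variant.
#' @param markerRegions list of shapes carrying IF signal, each
#'   `list(center = c(x, y), radius = r)` or `list(polygon = <n x 2 matrix>)`.
#' @param markerDensityBoost nucleus-density multiplier inside marker regions
#'   (keeps the H&E-to-IF mapping morphology-driven).
#' @param noiseSd additive Gaussian noise sd on the IF channel.
#' @param backgroundLevel 8-bit intensity of glass background regions.
#' @param backgroundRegions list of shapes rendered as blank background.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(height = 256L, width = 256L, nucleusDensity = 0.002,
                        nucleusRadius = 3, paletteId = 1L,
                        markerRegions = list(), markerDensityBoost = 3,
                        noiseSd = 0.02, backgroundLevel = 245,
                        backgroundRegions = list()) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nucleusDensity = nucleusDensity, nucleusRadius = nucleusRadius,
      paletteId = as.integer(paletteId), markerRegions = markerRegions,
      markerDensityBoost = markerDensityBoost, noiseSd = noiseSd,
      backgroundLevel = backgroundLevel, backgroundRegions = backgroundRegions)
}

stainPalette <- function(paletteId) {
  if (paletteId == 1L)
    list(stroma = c(0.91, 0.73, 0.81), nucleus = c(0.36, 0.22, 0.54))
  else
    list(stroma = c(0.86, 0.60, 0.68), nucleus = c(0.24, 0.14, 0.44))
}

rasterShapes <- function(h, w, shapes) {
  m <- matrix(FALSE, h, w)
  for (sh in shapes) {
    m <- m | if (!is.null(sh$center)) rasterDisk(h, w, sh$center, sh$radius)
             else rasterPolygon(h, w, sh$polygon)
  }
  m
}

## Render disks of given centers/radii/intensities into an h x w canvas
## (max-composited), by bounding box.
renderDisks <- function(h, w, centers, radii, intensity) {
  img <- matrix(0, h, w)
  if (!length(radii)) return(img)
  for (i in seq_along(radii)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii[i]
    x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
    y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    blk <- img[ys + 1L, xs + 1L, drop = FALSE]
    hit <- d2 <= r^2
    blk[hit] <- pmax(blk[hit], intensity[i])
    img[ys + 1L, xs + 1L] <- blk
  }
  img
}

#' Generate one registered H&E / IF phantom pair
#'
#' Nuclei are placed by a Poisson process whose intensity is
#' `nucleusDensity` outside marker regions and `nucleusDensity *
#' markerDensityBoost` inside, then rendered as dark disks on textured pink
#' stroma (H&E) and as a clean nuclear counterstain channel (DAPI analog).
#' The IF channel is the marker-region indicator smoothed with a Gaussian
#' (sigma 2 px) and masked to the region support — continuous boundaries
#' like real staining, but with foreground support exactly equal to the
#' rasterized region — plus additive Gaussian noise.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a \linkS4class{RegisteredPair} whose `groundTruth` records the
#'   marker mask, nucleus centers and count, seed, and an identity affine.
#' @export
generatePhantomPair <- function(spec, seed) {
  validObject(spec)
  h <- spec@height; w <- spec@width
  withSeed(seed, {
    pal <- stainPalette(spec@paletteId)
    marker <- rasterShapes(h, w, spec@markerRegions)
    bgmask <- rasterShapes(h, w, spec@backgroundRegions)

    ## Poisson nuclei: uniform proposals, thinned by the density boost map
    dens <- matrix(spec@nucleusDensity, h, w)
    dens[marker] <- spec@nucleusDensity * spec@markerDensityBoost
    dens[bgmask] <- 0
    nExp <- sum(dens)
    n <- rpois(1L, nExp)
    centers <- matrix(numeric(0), 0L, 2L)
    if (n > 0 && nExp > 0) {
      ## rejection-sample against the (piecewise-constant) density
      dmax <- max(dens)
      kept <- 0L; centers <- matrix(0, n, 2L)
      while (kept < n) {
        m <- (n - kept) * 2L + 8L
        px <- runif(m, 0, w); py <- runif(m, 0, h)
        u <- runif(m)
        dv <- dens[cbind(pmin(h, floor(py) + 1L), pmin(w, floor(px) + 1L))]
        ok <- u < dv / dmax
        take <- min(sum(ok), n - kept)
        if (take > 0) {
          idx <- which(ok)[seq_len(take)]
          centers[kept + seq_len(take), ] <- cbind(px[idx], py[idx])
          kept <- kept + take
        }
      }
    }
    radii <- spec@nucleusRadius * runif(nrow(centers), 0.8, 1.2)
    shade <- runif(nrow(centers), 0.85, 1)
    nuc <- renderDisks(h, w, centers, radii, shade)

    ## H&E: textured stroma, nuclei blended in hematoxylin color
    tex <- blurGaussian(matrix(rnorm(h * w, 0, 1), h, w), 3)
    tex <- 0.04 * tex / max(1e-8, sd(tex))
    he <- array(0, c(h, w, 3L))
    a <- nuc  # blend weight
    for (ch in 1:3) {
      stroma <- clip01(pal$stroma[ch] + tex)
      he[, , ch] <- stroma * (1 - a) + pal$nucleus[ch] * a
    }

    ## IF marker channel: smoothed indicator masked to its own support
    ifm <- blurGaussian(marker * 1, 2) * marker
    if (spec@noiseSd > 0)
      ifm <- ifm + matrix(rnorm(h * w, 0, spec@noiseSd), h, w)

    if (any(bgmask)) {
      bgv <- spec@backgroundLevel / 255
      for (ch in 1:3) { m <- he[, , ch]; m[bgmask] <- bgv; he[, , ch] <- m }
      nuc[bgmask] <- 0
      ifm[bgmask] <- 0
    }
    new("RegisteredPair", he = clip01(he), ifMarker = clip01(ifm),
        nuclear = nuc, sampleId = NA_character_,
        gridPos = c(NA_integer_, NA_integer_),
        groundTruth = list(markerMask = marker,
                           affine = affineMatrix2x3(),
                           seed = as.integer(seed),
                           nucleusCenters = centers,
                           nucleusCount = nrow(centers)))
  })
}

#' Construct a CohortSpec
#'
#' @param samples data.frame with columns `sample_id`, `n_tiles`,
#'   `cluster_id`.
#' @param clusters named list of per-cluster texture parameters; each entry a
#'   list with `nucleusDensity` (length-2 range), `nucleusRadius`,
#'   `paletteId`, `markerDensityBoost`, `markerProb` (probability a tile
#'   carries marker regions) and `markerRadius` (length-2 range).
#' @param tileSize tile side in pixels.
#' @param noiseSd IF noise sd.
#' @param seed integer cohort seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(samples, clusters, tileSize = 256L, noiseSd = 0.02,
                       seed = 1L) {
  samples$sample_id <- as.character(samples$sample_id)
  samples$cluster_id <- as.character(samples$cluster_id)
  new("CohortSpec", samples = samples, clusters = clusters,
      tileSize = as.integer(tileSize), noiseSd = noiseSd,
      seed = as.integer(seed))
}

clusterDefaults <- function(cl) {
  defaults <- list(nucleusDensity = c(0.0015, 0.0025), nucleusRadius = 3,
                   paletteId = 1L, markerDensityBoost = 3,
                   markerProb = 0.6, markerRadius = c(8, 16))
  defaults[names(cl)] <- cl
  defaults
}

#' Generate a phantom cohort with planted cluster structure
#'
#' Tiles within a cluster share texture statistics (nucleus density drawn
#' from the cluster range, radius, palette); clusters differ by the planted
#' texture offsets. Fully seeded: a fixed `CohortSpec` always produces an
#' identical cohort.
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @return named list: `sample_id -> list of` \linkS4class{RegisteredPair}.
#' @export
generateCohort <- function(cohort) {
  validObject(cohort)
  s <- cohort@samples
  ts <- cohort@tileSize
  out <- vector("list", nrow(s))
  names(out) <- s$sample_id
  for (i in seq_len(nrow(s))) {
    sid <- s$sample_id[i]
    cl <- clusterDefaults(cohort@clusters[[s$cluster_id[i]]])
    sSeed <- stageSeed(cohort@seed, sid)
    tiles <- vector("list", s$n_tiles[i])
    for (t in seq_len(s$n_tiles[i])) {
      tSeed <- stageSeed(sSeed, paste0("tile", t))
      spec <- withSeed(tSeed, {
        dens <- runif(1, cl$nucleusDensity[1], cl$nucleusDensity[2])
        regions <- list()
        if (runif(1) < cl$markerProb) {
          nreg <- sample(1:2, 1)
          for (k in seq_len(nreg)) {
            r <- runif(1, cl$markerRadius[1], min(cl$markerRadius[2], ts / 2 - 2))
            cx <- runif(1, r, ts - 1 - r); cy <- runif(1, r, ts - 1 - r)
            regions[[k]] <- list(center = c(cx, cy), radius = r)
          }
        }
        phantomSpec(height = ts, width = ts, nucleusDensity = dens,
                    nucleusRadius = cl$nucleusRadius,
                    paletteId = cl$paletteId, markerRegions = regions,
                    markerDensityBoost = cl$markerDensityBoost,
                    noiseSd = cohort@noiseSd)
      })
      pair <- generatePhantomPair(spec, stageSeed(tSeed, "render"))
      pair@sampleId <- sid
      pair@gridPos <- c(NA_integer_, NA_integer_)
      tiles[[t]] <- pair
    }
    out[[i]] <- tiles
  }
  out
}

#' Plant a known misalignment into a registered pair
#'
#' Resamples the IF (and nuclear) channel through the given affine with
#' bilinear interpolation, zero-filled outside; the H&E image is unchanged
#' and the planted transform is recorded in `groundTruth$affine`. Used as a
#' fixture for the registration stage, whose job is to recover the inverse.
#'
#' @param pair a \linkS4class{RegisteredPair}.
#' @param affine invertible 2 x 3 matrix (content-forward: a feature at p
#'   moves to `affine %*% c(p, 1)`).
#' @return the perturbed \linkS4class{RegisteredPair}.
#' @export
perturbAlignment <- function(pair, affine) {
  checkAffine(affine)
  pair@ifMarker <- warpAffine(pair@ifMarker, affine)
  if (length(pair@nuclear))
    pair@nuclear <- warpAffine(pair@nuclear, affine)
  pair@groundTruth$affine <- affine
  pair
}

#' Generate a synthetic tile-feature table
#'
#' Rows are drawn i.i.d. Gaussian around their sample's mean vector —
#' a fixture with a known representativeness ordering for the selection
#' algorithm.
#'
#' @param nPerSample named integer vector (or list) of tile counts per
#'   sample; names become sample ids (default `S1, S2, ...`).
#' @param featureMeans matrix with one row per sample (m columns, m = number
#'   of latent features, default 16).
#' @param noiseSd per-feature Gaussian sd around the sample mean.
#' @param seed integer seed.
#' @return a \linkS4class{TileFeatures}.
#' @export
generateFeatureTable <- function(nPerSample, featureMeans, noiseSd = 0.5,
                                 seed = 1L) {
  n <- unlist(nPerSample)
  if (any(n < 1)) stop("all n_per_sample must be >= 1")
  featureMeans <- as.matrix(featureMeans)
  if (nrow(featureMeans) != length(n))
    stop("featureMeans must have one row per sample")
  ids <- names(n)
  if (is.null(ids)) ids <- paste0("S", seq_along(n))
  m <- ncol(featureMeans)
  withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_along(n), function(i) {
      matrix(rnorm(n[i] * m, mean = rep(featureMeans[i, ], each = n[i]),
                   sd = noiseSd), n[i], m)
    }))
    tileFeatures(rows, rep(ids, n))
  })
}

#' Assemble a TileFeatures object
#'
#' @param features tiles x m numeric matrix.
#' @param sampleIds character vector, one per tile.
#' @param tileIds optional tile identifiers.
#' @return a \linkS4class{TileFeatures}.
#' @export
tileFeatures <- function(features, sampleIds, tileIds = NULL) {
  features <- as.matrix(features)
  if (length(sampleIds) != nrow(features))
    stop("sampleIds must have one entry per feature row")
  if (is.null(tileIds)) tileIds <- sprintf("tile%05d", seq_len(nrow(features)))
  m <- ncol(features)
  a <- t(features)
  rownames(a) <- paste0("L", seq_len(m))
  colnames(a) <- tileIds
  new("TileFeatures", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a),
    colData = S4Vectors::DataFrame(tile_id = tileIds,
                                   sample_id = as.character(sampleIds),
                                   row.names = tileIds)))
}

#' Write a phantom pair to disk (TIFFs + JSON ground-truth sidecar)
#'
#' H&E is written as 8-bit RGB TIFF, the IF and nuclear channels as 32-bit
#' float TIFFs, the marker mask as 8-bit TIFF, and a JSON sidecar records
#' the planted affine and seed.
#'
#' @param pair a \linkS4class{RegisteredPair}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the sidecar path.
#' @export
writePhantomPair <- function(pair, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hePath <- file.path(dir, paste0(prefix, "_he.tif"))
  ifPath <- file.path(dir, paste0(prefix, "_if.tif"))
  maskPath <- file.path(dir, paste0(prefix, "_mask.tif"))
  tiff::writeTIFF(heImage(pair), hePath, bits.per.sample = 8L)
  tiff::writeTIFF(ifImage(pair), ifPath, bits.per.sample = 32L)
  gt <- pair@groundTruth
  if (!is.null(gt$markerMask))
    tiff::writeTIFF(gt$markerMask * 1, maskPath, bits.per.sample = 8L)
  nucPath <- NULL
  if (length(pair@nuclear)) {
    nucPath <- file.path(dir, paste0(prefix, "_nuclear.tif"))
    tiff::writeTIFF(pair@nuclear, nucPath, bits.per.sample = 32L)
  }
  side <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(
    he = basename(hePath), if_marker = basename(ifPath),
    nuclear = if (is.null(nucPath)) NA else basename(nucPath),
    marker_mask = if (is.null(gt$markerMask)) NA else basename(maskPath),
    affine = gt$affine, seed = gt$seed, sample_id = pair@sampleId
  ), side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(side)
}
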