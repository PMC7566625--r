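# Preprocessing pipeline for paired H&E / IF slide images: downscaling,
# nuclei-mask affine registration, disk median filtering, intensity
# normalization, and background-filtered tiling.

#' Downscale a slide image by integer block averaging
#'
#' Each output pixel is the mean of a `factor` x `factor` input block
#' (anti-aliased local averaging); trailing rows/columns that do not fill a
#' block are dropped, so the output is `floor(H/factor) x floor(W/factor)`.
#'
#' @param img matrix or H x W x 3 array.
#' @param factor integer >= 1.
#' @return the downscaled image.
#' @export
downscaleImage <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be an integer >= 1")
  if (factor == 1L) return(img)
  if (length(dim(img)) == 3L) {
    h2 <- dim(img)[1] %/% factor; w2 <- dim(img)[2] %/% factor
    out <- array(0, c(h2, w2, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- downscaleImage(img[, , ch], factor)
    return(out)
  }
  h2 <- nrow(img) %/% factor; w2 <- ncol(img) %/% factor
  if (h2 < 1L || w2 < 1L) stop("image smaller than the downscale factor")
  x <- img[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
  ## average factor x factor blocks via two reshapes
  x <- matrix(colMeans(matrix(x, nrow = factor)), nrow = h2)  # rows pooled
  t(matrix(colMeans(matrix(t(x), nrow = factor)), nrow = w2))
}

#' Binary nuclei mask by Otsu thresholding
#'
#' H&E path: RGB is converted to grayscale (ITU-R 601 weights 0.299, 0.587,
#' 0.114), Otsu-thresholded on 256 intensity bins, and complemented so that
#' the dark (hematoxylin) nuclei are `TRUE`. DAPI path: the single channel is
#' Otsu-thresholded directly (bright nuclei are `TRUE`).
#'
#' @param img H x W x 3 array (`modality = "he"`) or matrix
#'   (`modality = "dapi"`), values in [0, 1].
#' @param modality `"he"` or `"dapi"`.
#' @return logical matrix, `TRUE` at nuclei.
#' @export
nucleiMask <- function(img, modality = c("he", "dapi")) {
  modality <- match.arg(modality)
  if (modality == "he") {
    if (!isRgb(img)) stop("'he' modality expects an H x W x 3 array")
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    g <- asImageMatrix(img, "dapi image")
  }
  if (max(g) - min(g) < 1e-12)
    stop("degenerate input: constant image has no Otsu threshold")
  thr <- EBImage::otsu(g, range = range(g), levels = 256L)
  if (modality == "he") g <= thr else g > thr
}

## Keypoints on a binary nuclei mask: connected-component centroids with
## strength = component area.
maskKeypoints <- function(mask, maxFeatures = 10000L, minArea = 3L) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n < 1L) return(matrix(numeric(0), 0L, 3L))
  idx <- which(lab > 0)
  lv <- lab[idx]
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  area <- tabulate(lv, nbins = n)
  cx <- tapply(cc - 1L, lv, mean)   # x = 0-based column
  cy <- tapply(rr - 1L, lv, mean)   # y = 0-based row
  kp <- cbind(x = as.numeric(cx), y = as.numeric(cy), strength = area)
  kp <- kp[area >= minArea, , drop = FALSE]
  if (nrow(kp) > maxFeatures)
    kp <- kp[order(kp[, 3], decreasing = TRUE)[seq_len(maxFeatures)], , drop = FALSE]
  kp
}

## Rotation- and scale-invariant local descriptor: sorted distances to the
## k nearest keypoints, normalized by their mean, concatenated with the
## relative strengths of those neighbors (in distance order).
keypointDescriptors <- function(kp, k = 8L) {
  n <- nrow(kp)
  k <- min(k, n - 1L)
  if (k < 2L) return(matrix(numeric(0), n, 0L))
  d2 <- outer(kp[, 1], kp[, 1], `-`)^2 + outer(kp[, 2], kp[, 2], `-`)^2
  desc <- matrix(0, n, 2L * k)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])[2:(k + 1L)]
    di <- sqrt(d2[i, ord])
    m <- mean(di)
    desc[i, ] <- c(di / m, kp[ord, 3] / max(1, kp[i, 3]))
  }
  desc
}

estimateAffineLS <- function(src, dst) {
  X <- cbind(src, 1)
  B <- qr.solve(X, dst)          # 3 x 2
  t(B)                           # 2 x 3
}

#' Register an IF image onto an H&E image via nuclei masks
#'
#' Computes nuclei masks for both modalities, detects keypoints (connected
#' nuclei components, strongest `min(maxFeatures, detected)` by area),
#' describes each by a rotation/scale-invariant neighborhood signature,
#' matches descriptors (mutual nearest neighbor), and robustly estimates the
#' affine mapping the IF (DAPI) frame onto the H&E frame by RANSAC (3-px
#' inlier threshold, 2000 iterations) followed by a least-squares refit on
#' the inliers. Applying the recovered affine to the IF image (e.g. with
#' [warpAffine()]) registers it to the H&E frame.
#'
#' @param he H x W x 3 H&E image.
#' @param ifImg matrix: the nuclear (DAPI) channel of the IF scan.
#' @param maxFeatures keep at most this many strongest keypoints per mask.
#' @param inlierThreshold RANSAC inlier radius in pixels.
#' @param iterations RANSAC iterations.
#' @return a \linkS4class{RegistrationModel}.
#' @export
registerPair <- function(he, ifImg, maxFeatures = 10000L,
                         inlierThreshold = 3, iterations = 2000L) {
  mHe <- tryCatch(nucleiMask(he, "he"),
                  error = function(e) stop("registration failed: H&E mask: ",
                                           conditionMessage(e)))
  mIf <- tryCatch(nucleiMask(asImageMatrix(ifImg, "ifImg"), "dapi"),
                  error = function(e) stop("registration failed: IF mask: ",
                                           conditionMessage(e)))
  kpHe <- maskKeypoints(mHe, maxFeatures)
  kpIf <- maskKeypoints(mIf, maxFeatures)
  if (nrow(kpHe) < 3L || nrow(kpIf) < 3L)
    stop(sprintf("registration failed: too few keypoints (H&E %d, IF %d)",
                 nrow(kpHe), nrow(kpIf)))
  dHe <- keypointDescriptors(kpHe)
  dIf <- keypointDescriptors(kpIf)
  ## mutual nearest-neighbor descriptor matching
  cross <- outer(rowSums(dIf^2), rowSums(dHe^2), `+`) - 2 * dIf %*% t(dHe)
  bestHe <- max.col(-cross)                        # for each IF kp
  bestIf <- max.col(-t(cross))                     # for each H&E kp
  mutual <- which(bestIf[bestHe] == seq_len(nrow(dIf)))
  if (length(mutual) < 3L)
    stop(sprintf("registration failed: only %d descriptor matches", length(mutual)))
  src <- kpIf[mutual, 1:2, drop = FALSE]
  dst <- kpHe[bestHe[mutual], 1:2, drop = FALSE]
  nm <- nrow(src)
  ## RANSAC
  rs <- withSeed(20201015L, matrix(sample.int(nm, 3L * iterations, replace = TRUE),
                                   ncol = 3L))
  bestInl <- integer(0)
  for (it in seq_len(iterations)) {
    tri <- rs[it, ]
    if (length(unique(tri)) < 3L) next
    M <- tryCatch(estimateAffineLS(src[tri, ], dst[tri, ]),
                  error = function(e) NULL)
    if (is.null(M)) next
    pred <- affineApplyPoints(M, src)
    res <- sqrt(rowSums((pred - dst)^2))
    inl <- which(res < inlierThreshold)
    if (length(inl) > length(bestInl)) bestInl <- inl
  }
  if (length(bestInl) < 3L)
    stop(sprintf("registration failed: %d inliers (need >= 3); %d matches, %d/%d keypoints",
                 length(bestInl), nm, nrow(kpHe), nrow(kpIf)))
  M <- estimateAffineLS(src[bestInl, , drop = FALSE], dst[bestInl, , drop = FALSE])
  ## one re-scoring pass after refit
  res <- sqrt(rowSums((affineApplyPoints(M, src) - dst)^2))
  inl <- which(res < inlierThreshold)
  if (length(inl) >= 3L)
    M <- estimateAffineLS(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  new("RegistrationModel", affine = M, nMatchedFeatures = as.integer(nm),
      inlierFraction = length(inl) / nm,
      meta = list(nKeypointsHe = nrow(kpHe), nKeypointsIf = nrow(kpIf),
                  meanResidual = mean(res[inl])))
}

#' Median filter an IF image with a disk structuring element
#'
#' Each pixel is replaced by the median over a disk neighborhood of the given
#' radius; edges are handled by reflect padding.
#'
#' @param ifImg numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return filtered matrix, same size.
#' @export
medianFilterIF <- function(ifImg, radius = 5L) {
  ifImg <- asImageMatrix(ifImg, "ifImg")
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("'radius' must be >= 1")
  disk_median_filter(ifImg, radius)
}

#' Normalize IF intensities to fixed mean and spread
#'
#' Affine intensity map to pre-clip mean 0.25 and standard deviation 0.125,
#' followed by clipping to [0, 1].
#'
#' @param ifImg numeric matrix with positive standard deviation.
#' @param targetMean,targetSd target pre-clip statistics.
#' @param clip clip the result to [0, 1] (set `FALSE` to inspect the
#'   pre-clip image).
#' @return normalized matrix (in [0, 1] when `clip = TRUE`).
#' @export
normalizeIF <- function(ifImg, targetMean = 0.25, targetSd = 0.125,
                        clip = TRUE) {
  ifImg <- asImageMatrix(ifImg, "ifImg")
  s <- sd(ifImg)
  if (!is.finite(s) || s <= 0)
    stop("degenerate input: zero-variance image cannot be normalized")
  out <- (ifImg - mean(ifImg)) / s * targetSd + targetMean
  if (clip) clip01(out) else out
}

#' Default H&E normalization target statistics
#'
#' Per-channel means and standard deviations of a reference phantom field
#' (violet-on-pink palette).
#' @return list with `mean` and `sd`, each length-3 (R, G, B).
#' @export
heTargetStats <- function() {
  list(mean = c(0.82, 0.66, 0.74), sd = c(0.12, 0.14, 0.12))
}

#' Normalize H&E color statistics to a fixed reference
#'
#' Per-channel affine map taking each RGB channel to the target mean and
#' standard deviation (Reinhard-style channel-statistics matching), then
#' clipped to [0, 1]. Deterministic given `targetStats`; an image already at
#' the target statistics is returned unchanged. The normalization method is
#' pluggable through `targetStats`.
#'
#' @param he H x W x 3 array in [0, 1].
#' @param targetStats list with `mean` and `sd` (length-3 each).
#' @return normalized H x W x 3 array.
#' @export
normalizeHE <- function(he, targetStats = heTargetStats()) {
  if (!isRgb(he)) stop("'he' must be an H x W x 3 array")
  out <- he
  for (ch in 1:3) {
    x <- he[, , ch]
    s <- max(sd(x), 1e-8)
    out[, , ch] <- clip01((x - mean(x)) / s * targetStats$sd[ch] +
                          targetStats$mean[ch])
  }
  out
}

#' Tile a registered H&E / IF pair with background filtering
#'
#' Decomposes the pair into non-overlapping `tileSize` x `tileSize` tiles on
#' a row-major, 0-based grid of half-open windows; partial edge tiles are
#' dropped. A pixel is background iff all three 8-bit H&E channel values are
#' strictly greater than `bgIntensityThreshold`; H&E tiles whose background
#' fraction is strictly greater than `bgFractionThreshold` are removed
#' together with their IF mates (a tile at exactly the threshold is
#' retained). The background test uses the H&E tile only.
#'
#' @param he H x W x 3 array in [0, 1].
#' @param ifImg H x W matrix in [0, 1].
#' @param tileSize tile side in pixels.
#' @param bgIntensityThreshold 8-bit background intensity threshold.
#' @param bgFractionThreshold maximum retained background fraction.
#' @param sampleId sample identifier recorded per tile.
#' @return a \linkS4class{TileSet} of retained tiles, with an attribute
#'   `"removed"` (data.frame of removed grid positions and their background
#'   fractions).
#' @export
tilePair <- function(he, ifImg, tileSize = 256L, bgIntensityThreshold = 180,
                     bgFractionThreshold = 0.5, sampleId = "sample") {
  if (!isRgb(he)) stop("'he' must be an H x W x 3 array")
  ifImg <- asImageMatrix(ifImg, "ifImg")
  if (!all(dim(he)[1:2] == dim(ifImg)))
    stop("he and ifImg must have the same dimensions")
  tileSize <- as.integer(tileSize)
  h <- dim(he)[1]; w <- dim(he)[2]
  nr <- h %/% tileSize; nc <- w %/% tileSize
  ifSourceMean <- mean(ifImg)
  heL <- list(); ifL <- list()
  info <- data.frame(sample_id = character(), row = integer(), col = integer(),
                     background_fraction = numeric(), if_source_mean = numeric())
  removed <- info
  if (nr < 1L || nc < 1L) {
    message("image smaller than tileSize; returning an empty tile set")
  } else {
    bg8 <- (he[, , 1] * 255 > bgIntensityThreshold) &
           (he[, , 2] * 255 > bgIntensityThreshold) &
           (he[, , 3] * 255 > bgIntensityThreshold)
    for (r in 0:(nr - 1L)) for (cc in 0:(nc - 1L)) {
      ys <- (r * tileSize + 1L):((r + 1L) * tileSize)
      xs <- (cc * tileSize + 1L):((cc + 1L) * tileSize)
      bf <- mean(bg8[ys, xs])
      rec <- data.frame(sample_id = sampleId, row = r, col = cc,
                        background_fraction = bf,
                        if_source_mean = ifSourceMean)
      if (bf > bgFractionThreshold) {
        removed <- rbind(removed, rec)
      } else {
        heL[[length(heL) + 1L]] <- he[ys, xs, , drop = FALSE]
        ifL[[length(ifL) + 1L]] <- ifImg[ys, xs, drop = FALSE]
        info <- rbind(info, rec)
      }
    }
  }
  ts <- new("TileSet", he = heL, ifch = ifL, info = info, tileSize = tileSize)
  attr(ts, "removed") <- removed
  ts
}

#' Combine tile sets
#'
#' @param ... \linkS4class{TileSet} objects with equal tile sizes.
#' @return a single \linkS4class{TileSet}.
#' @export
concatTileSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "TileSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ts <- unique(vapply(sets, function(s) s@tileSize, integer(1)))
  if (length(ts) != 1L) stop("tile sizes differ")
  new("TileSet",
      he = do.call(c, lapply(sets, heTiles)),
      ifch = do.call(c, lapply(sets, ifTiles)),
      info = do.call(rbind, lapply(sets, tileInfo)),
      tileSize = ts)
}

#' Write / read a tile manifest
#'
#' Tiles are written as TIFF files (H&E 8-bit RGB, IF 32-bit float) with a
#' CSV manifest (`sample_id, row, col, he_path, if_path,
#' background_fraction, if_source_mean`).
#'
#' @param tiles a \linkS4class{TileSet}.
#' @param dir output directory.
#' @return path of the written manifest CSV.
#' @export
writeTileManifest <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- tileInfo(tiles)
  hePaths <- character(length(tiles)); ifPaths <- character(length(tiles))
  for (i in seq_len(length(tiles))) {
    base <- sprintf("%s_r%03d_c%03d", info$sample_id[i], info$row[i], info$col[i])
    hePaths[i] <- file.path(dir, paste0(base, "_he.tif"))
    ifPaths[i] <- file.path(dir, paste0(base, "_if.tif"))
    tiff::writeTIFF(heTiles(tiles)[[i]], hePaths[i], bits.per.sample = 8L)
    tiff::writeTIFF(ifTiles(tiles)[[i]], ifPaths[i], bits.per.sample = 32L)
  }
  man <- cbind(info[, c("sample_id", "row", "col")],
               he_path = basename(hePaths), if_path = basename(ifPaths),
               info[, c("background_fraction", "if_source_mean")])
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  path
}

#' @rdname writeTileManifest
#' @param path manifest CSV path.
#' @export
readTileManifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  dir <- dirname(path)
  heL <- lapply(file.path(dir, man$he_path), tiff::readTIFF)
  ifL <- lapply(file.path(dir, man$if_path), function(p) {
    x <- tiff::readTIFF(p)
    asImageMatrix(if (length(dim(x)) == 3L) x[, , 1] else x)
  })
  new("TileSet", he = heL, ifch = ifL,
      info = man[, c("sample_id", "row", "col", "background_fraction",
                     "if_source_mean")],
      tileSize = as.integer(nrow(heL[[1]])))
}
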