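# H&E-to-IF translator: conditional adversarial training with an adaptive
# stain-prevalence L1 weight, an L1-only ablation mode, paired augmentation,
# tile inference, ensembling and stitching. The network engine (U-net
# generator, patch discriminator, Adam) lives in src/.

#' Construct a translator training configuration
#'
#' The `"full"` profile is the reference training recipe (256-px tiles,
#' first layer 128 filters, batch 64, learning rate 0.002, 500 epochs, base
#' L1 weight 100). The `"desk"` profile keeps the same architecture family
#' at CPU scale: 64-px tiles, 32 first-layer filters, batch 16, and a
#' 500-step cap.
#'
#' @param mode `"adversarial"` or `"l1_only"` (generator trained on the
#'   weighted L1 loss alone; no discriminator is allocated).
#' @param profile `"full"` or `"desk"`.
#' @param baseLambda base L1 weight (adapted per batch by stain prevalence).
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param maxSteps cap on optimizer steps (`NA` = uncapped).
#' @param batchSize tiles per batch.
#' @param firstLayerFilters filters in the first generator/discriminator
#'   layer.
#' @param tileSize tile side in pixels (power of two).
#' @param seed integer training seed.
#' @param augment apply paired augmentation to each training batch.
#' @return a \linkS4class{TranslatorConfig}.
#' @export
translatorConfig <- function(mode = c("adversarial", "l1_only"),
                             profile = c("full", "desk"),
                             baseLambda = 100, learningRate = 0.002,
                             epochs = NULL, maxSteps = NULL, batchSize = NULL,
                             firstLayerFilters = NULL, tileSize = NULL,
                             seed = 1L, augment = FALSE) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (profile == "full") {
    if (is.null(epochs)) epochs <- 500L
    if (is.null(maxSteps)) maxSteps <- NA_integer_
    if (is.null(batchSize)) batchSize <- 64L
    if (is.null(firstLayerFilters)) firstLayerFilters <- 128L
    if (is.null(tileSize)) tileSize <- 256L
  } else {
    if (is.null(epochs)) epochs <- 50L
    if (is.null(maxSteps)) maxSteps <- 500L
    if (is.null(batchSize)) batchSize <- 16L
    if (is.null(firstLayerFilters)) firstLayerFilters <- 32L
    if (is.null(tileSize)) tileSize <- 64L
  }
  new("TranslatorConfig", mode = mode, baseLambda = baseLambda,
      learningRate = learningRate, epochs = as.integer(epochs),
      maxSteps = as.integer(maxSteps), batchSize = as.integer(batchSize),
      firstLayerFilters = as.integer(firstLayerFilters),
      tileSize = as.integer(tileSize), seed = as.integer(seed),
      augment = augment)
}

#' Adaptive L1 weight from IF stain prevalence
#'
#' The base weight is scaled by the fraction of batch pixels whose IF
#' intensity strictly exceeds the mean intensity of their source slide:
#' `lambda = baseLambda * p`. A batch with half its pixels above the mean
#' gives `lambda = 50` at the default base of 100. Batches mixing source
#' slides use each tile's own source mean.
#'
#' @param ifBatch list of IF tile matrices (or one matrix / 3D array).
#' @param wsiMeanIntensity mean IF intensity of the source slide(s);
#'   a scalar or one value per tile.
#' @param baseLambda base L1 weight.
#' @return the adapted weight in `[0, baseLambda]`.
#' @export
adaptiveLambda <- function(ifBatch, wsiMeanIntensity, baseLambda = 100) {
  if (is.matrix(ifBatch)) ifBatch <- list(ifBatch)
  if (is.array(ifBatch) && length(dim(ifBatch)) == 3L)
    ifBatch <- lapply(seq_len(dim(ifBatch)[3]), function(i) ifBatch[, , i])
  if (!length(ifBatch)) stop("empty batch")
  if (any(!is.finite(wsiMeanIntensity))) stop("wsiMeanIntensity must be finite")
  means <- rep_len(wsiMeanIntensity, length(ifBatch))
  above <- 0; total <- 0
  for (i in seq_along(ifBatch)) {
    above <- above + sum(ifBatch[[i]] > means[i])
    total <- total + length(ifBatch[[i]])
  }
  baseLambda * above / total
}

#' Conditional-GAN objective components
#'
#' Evaluates the documented minimax objective
#' `L_cGAN(G, D) = E[log D(x, y)] + E[log(1 - D(x, G(x)))]` together with
#' `L_L1 = E[|y - G(x)|]`, the generator total (non-saturating adversarial
#' term `-E[log D(x, G(x))]` plus `lambda * L_L1`), and the discriminator
#' total (binary cross-entropy on real vs fake).
#'
#' @param dReal discriminator outputs on real pairs, in [0, 1].
#' @param dFake discriminator outputs on generated pairs, in [0, 1].
#' @param y real IF tile(s).
#' @param gx generated IF tile(s), same shape as `y`.
#' @param lambda L1 weight.
#' @return list with `l_cgan`, `l_l1`, `total_g`, `total_d`.
#' @export
cganObjective <- function(dReal, dFake, y, gx, lambda) {
  dReal <- as.numeric(dReal); dFake <- as.numeric(dFake)
  if (any(dReal < 0 | dReal > 1) || any(dFake < 0 | dFake > 1))
    stop("discriminator outputs must be probabilities in [0, 1]")
  if (length(y) != length(gx)) stop("y and gx must have equal shape")
  lCgan <- mean(log(dReal)) + mean(log(1 - dFake))
  lL1 <- mean(abs(as.numeric(y) - as.numeric(gx)))
  list(l_cgan = lCgan, l_l1 = lL1,
       total_g = -mean(log(dFake)) + lambda * lL1,
       total_d = -(mean(log(dReal)) + mean(log(1 - dFake))))
}

applyHueSatJitter <- function(he, dh, ds) {
  d <- dim(he)
  m <- rbind(as.vector(he[, , 1]), as.vector(he[, , 2]), as.vector(he[, , 3]))
  hsvm <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hsvm[1, ] <- (hsvm[1, ] + dh) %% 1
  hsvm[2, ] <- pmin(1, pmax(0, hsvm[2, ] * ds))
  rgbm <- grDevices::col2rgb(grDevices::hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ])) / 255
  array(c(rgbm[1, ], rgbm[2, ], rgbm[3, ]), d)
}

poissonNoise <- function(img, scale = 255) {
  matrix(rpois(length(img), pmax(img, 0) * scale) / scale,
         nrow(img), ncol(img))
}

#' Paired augmentation of an H&E / IF tile batch
#'
#' Geometric operations (flips, rotation, small affine jitter) are composed
#' into a single affine per pair and applied with identical parameters to
#' both members; photometric operations (Gaussian blur, Gaussian noise,
#' Poisson noise) are applied per image; hue/saturation jitter is applied to
#' the H&E member only. Fully seeded.
#'
#' @param heBatch list of H x W x 3 arrays.
#' @param ifBatch list of H x W matrices (same length).
#' @param seed integer seed.
#' @param maxRotation maximum absolute rotation in degrees.
#' @param maxShift maximum absolute translation in pixels.
#' @param scaleRange affine scale jitter range.
#' @return list with `he`, `ifch` (augmented batches) and `affines` (the
#'   geometric transform applied to each pair).
#' @export
augmentPairBatch <- function(heBatch, ifBatch, seed, maxRotation = 10,
                             maxShift = 3, scaleRange = c(0.98, 1.02)) {
  if (length(heBatch) != length(ifBatch))
    stop("heBatch and ifBatch must have equal length")
  withSeed(seed, {
    n <- length(heBatch)
    affines <- vector("list", n)
    for (i in seq_len(n)) {
      he <- heBatch[[i]]; ifm <- ifBatch[[i]]
      ctr <- c((ncol(ifm) - 1) / 2, (nrow(ifm) - 1) / 2)
      M <- affineMatrix2x3(rotation = runif(1, -maxRotation, maxRotation),
                           scale = runif(1, scaleRange[1], scaleRange[2]),
                           translation = runif(2, -maxShift, maxShift),
                           center = ctr)
      if (runif(1) < 0.5) {  # horizontal flip about the center
        Fh <- affineMatrix2x3(center = ctr); Fh[1, 1] <- -1
        Fh[1, 3] <- 2 * ctr[1]
        M <- cbind(M[, 1:2] %*% Fh[, 1:2], M[, 1:2] %*% Fh[, 3] + M[, 3])
      }
      if (runif(1) < 0.5) {  # vertical flip
        Fv <- affineMatrix2x3(center = ctr); Fv[2, 2] <- -1
        Fv[2, 3] <- 2 * ctr[2]
        M <- cbind(M[, 1:2] %*% Fv[, 1:2], M[, 1:2] %*% Fv[, 3] + M[, 3])
      }
      he <- warpAffine(he, M)
      ifm <- warpAffine(ifm, M)
      ## photometric, per image
      bs <- runif(1, 0, 0.8)
      if (bs > 0.05) he <- blurGaussian(he, bs)
      bs <- runif(1, 0, 0.8)
      if (bs > 0.05) ifm <- blurGaussian(ifm, bs)
      he <- clip01(he + array(rnorm(length(he), 0, runif(1, 0, 0.02)), dim(he)))
      ifm <- clip01(ifm + matrix(rnorm(length(ifm), 0, runif(1, 0, 0.02)),
                                 nrow(ifm)))
      if (runif(1) < 0.5) ifm <- clip01(poissonNoise(ifm))
      he <- clip01(applyHueSatJitter(he, runif(1, -0.02, 0.02),
                                     runif(1, 0.9, 1.1)))
      heBatch[[i]] <- he; ifBatch[[i]] <- ifm
      affines[[i]] <- M
    }
    list(he = heBatch, ifch = ifBatch, affines = affines)
  })
}

batchToArray <- function(tiles, channels) {
  n <- length(tiles)
  d <- dim(tiles[[1]])
  if (channels == 3L) {
    arr <- array(0, c(d[1], d[2], 3L, n))
    for (i in seq_len(n)) arr[, , , i] <- tiles[[i]]
  } else {
    arr <- array(0, c(d[1], d[2], 1L, n))
    for (i in seq_len(n)) arr[, , 1L, i] <- tiles[[i]]
  }
  arr
}

ganFromTranslator <- function(model) {
  cfg <- model@config
  ptr <- gan_create(cfg@tileSize, cfg@firstLayerFilters,
                    cfg@mode == "adversarial", cfg@seed)
  w <- list(generator = model@generator)
  if (cfg@mode == "adversarial") w$discriminator <- model@discriminator
  gan_set_weights(ptr, w)
  ptr
}

#' Train an H&E-to-IF translator
#'
#' Adversarial mode alternates discriminator and generator Adam updates on
#' each batch; `l1_only` mode updates the generator on the weighted L1 loss
#' alone (its total loss is exactly `lambda * L_L1`). The L1 weight is
#' recomputed for every batch from IF stain prevalence
#' ([adaptiveLambda()]), using each tile's source-slide mean intensity from
#' the tile metadata. Training is seeded and reproducible.
#'
#' @param tiles a \linkS4class{TileSet} of paired training tiles.
#' @param config a \linkS4class{TranslatorConfig}; `config@tileSize` must
#'   match the tiles.
#' @return a \linkS4class{Translator} with the full per-step loss history.
#' @export
trainTranslator <- function(tiles, config = translatorConfig()) {
  validObject(config)
  n <- length(tiles)
  if (n < 1L) stop("empty training set")
  if (tiles@tileSize != config@tileSize)
    stop(sprintf("tiles are %d px but config expects %d px",
                 tiles@tileSize, config@tileSize))
  heL <- heTiles(tiles); ifL <- ifTiles(tiles)
  srcMeans <- tileInfo(tiles)$if_source_mean
  if (all(is.na(srcMeans))) srcMeans <- rep(mean(unlist(lapply(ifL, mean))), n)
  withSeed(config@seed, {
    ptr <- gan_create(config@tileSize, config@firstLayerFilters,
                      config@mode == "adversarial",
                      stageSeed(config@seed, "init"))
    maxSteps <- if (is.na(config@maxSteps)) Inf else config@maxSteps
    hist <- list()
    step <- 0L
    done <- FALSE
    for (ep in seq_len(config@epochs)) {
      if (done) break
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, n)]
        heB <- heL[idx]; ifB <- ifL[idx]
        if (config@augment) {
          aug <- augmentPairBatch(heB, ifB,
                                  seed = stageSeed(config@seed,
                                                   paste0("aug", step)))
          heB <- aug$he; ifB <- aug$ifch
        }
        lambda <- adaptiveLambda(ifB, srcMeans[idx], config@baseLambda)
        d <- dim(heB[[1]])
        res <- gan_train_step(ptr, batchToArray(heB, 3L),
                              batchToArray(ifB, 1L),
                              c(d[1], d[2], 3L, length(idx)),
                              lambda, config@learningRate)
        step <- step + 1L
        hist[[step]] <- data.frame(step = step, epoch = ep,
          d_loss = res$d_loss, g_adv = res$g_adv, l1 = res$l1,
          lambda = lambda, lambda_l1 = res$lambda_l1,
          d_acc_real = res$d_acc_real, d_acc_fake = res$d_acc_fake)
        if (step >= maxSteps) { done <- TRUE; break }
      }
    }
    w <- gan_get_weights(ptr)
    new("Translator", generator = w$generator,
        discriminator = if (config@mode == "adversarial") w$discriminator
                        else list(),
        config = config, history = do.call(rbind, hist))
  })
}

#' Translate H&E tiles into virtual IF tiles
#'
#' Deterministic inference: two calls on the same tile return identical
#' output; values are in [0, 1] (sigmoid output head).
#'
#' @param model a trained \linkS4class{Translator}.
#' @param heTile one H x W x 3 tile or a list of them; H and W must equal
#'   the configured tile size.
#' @return a matrix (single tile) or list of matrices.
#' @export
translateTile <- function(model, heTile) {
  single <- !is.list(heTile)
  tilesL <- if (single) list(heTile) else heTile
  ts <- model@config@tileSize
  for (t in tilesL)
    if (length(dim(t)) != 3L || !all(dim(t) == c(ts, ts, 3L)))
      stop(sprintf("input tiles must be %d x %d x 3", ts, ts))
  ptr <- ganFromTranslator(model)
  d <- c(ts, ts, 3L, length(tilesL))
  out <- gan_forward(ptr, batchToArray(tilesL, 3L), d)
  res <- lapply(seq_len(length(tilesL)), function(i) out[, , i])
  if (single) res[[1]] else res
}

#' Ensemble translation by output averaging
#'
#' Pixel-wise arithmetic mean of the member models' virtual IF outputs.
#'
#' @param models non-empty list of \linkS4class{Translator} objects.
#' @param heTile one H x W x 3 tile or a list of them.
#' @return a matrix or list of matrices.
#' @export
ensembleTranslate <- function(models, heTile) {
  if (!length(models)) stop("empty model list")
  outs <- lapply(models, translateTile, heTile = heTile)
  if (!is.list(outs[[1]]))
    return(Reduce(`+`, outs) / length(outs))
  lapply(seq_along(outs[[1]]), function(i)
    Reduce(`+`, lapply(outs, `[[`, i)) / length(outs))
}

#' Stitch tiles back into a whole image
#'
#' Tile (r, c) occupies the half-open window `[r s, (r+1) s) x [c s, (c+1) s)`
#' of the output (0-based, row-major). The grid must be complete and free of
#' duplicates.
#'
#' @param tiles list of matrices (or H x W x 3 arrays).
#' @param positions n x 2 matrix (or data.frame) of 0-based (row, col) grid
#'   positions.
#' @param gridShape (rows, cols); inferred from positions if omitted.
#' @return the stitched image.
#' @export
stitchTiles <- function(tiles, positions, gridShape = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(tiles))
    stop("one grid position per tile is required")
  if (is.null(gridShape)) gridShape <- c(max(positions[, 1]) + 1L,
                                         max(positions[, 2]) + 1L)
  keys <- paste(positions[, 1], positions[, 2])
  dup <- unique(keys[duplicated(keys)])
  if (length(dup))
    stop("duplicate grid cell(s): ", paste0("(", dup, ")", collapse = ", "))
  want <- as.vector(outer(0:(gridShape[1] - 1L), 0:(gridShape[2] - 1L),
                          paste))
  miss <- setdiff(want, keys)
  if (length(miss))
    stop("missing grid cell(s): ", paste0("(", miss, ")", collapse = ", "))
  s <- nrow(asImageMatrix(if (is.matrix(tiles[[1]])) tiles[[1]]
                          else tiles[[1]][, , 1]))
  rgb <- length(dim(tiles[[1]])) == 3L
  out <- if (rgb) array(0, c(gridShape[1] * s, gridShape[2] * s, 3L))
         else matrix(0, gridShape[1] * s, gridShape[2] * s)
  for (i in seq_along(tiles)) {
    ys <- (positions[i, 1] * s + 1L):((positions[i, 1] + 1L) * s)
    xs <- (positions[i, 2] * s + 1L):((positions[i, 2] + 1L) * s)
    if (rgb) out[ys, xs, ] <- tiles[[i]] else out[ys, xs] <- tiles[[i]]
  }
  out
}

#' Save / load a translator checkpoint
#'
#' Plain-text checkpoint: config and loss history as JSON, weights as one
#' CSV of flattened layer parameters.
#'
#' @param model a \linkS4class{Translator}.
#' @param dir checkpoint directory.
#' @return invisibly `dir` (save); a \linkS4class{Translator} (load).
#' @export
saveTranslator <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model@config
  jsonlite::write_json(list(
    mode = cfg@mode, baseLambda = cfg@baseLambda,
    learningRate = cfg@learningRate, epochs = cfg@epochs,
    maxSteps = cfg@maxSteps, batchSize = cfg@batchSize,
    firstLayerFilters = cfg@firstLayerFilters, tileSize = cfg@tileSize,
    seed = cfg@seed, augment = cfg@augment
  ), file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
     na = "null")
  write.csv(model@history, file.path(dir, "history.csv"), row.names = FALSE)
  serializeWeights <- function(wl, path) {
    rows <- lapply(seq_along(wl), function(i) {
      data.frame(layer = i,
                 meta = paste(wl[[i]]$meta, collapse = ";"),
                 nW = length(wl[[i]]$W), nb = length(wl[[i]]$b),
                 values = paste(format(c(as.numeric(wl[[i]]$W),
                                         as.numeric(wl[[i]]$b)),
                                       digits = 17, trim = TRUE,
                                       scientific = TRUE),
                                collapse = ";"))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  serializeWeights(model@generator, file.path(dir, "generator.csv"))
  if (length(model@discriminator))
    serializeWeights(model@discriminator, file.path(dir, "discriminator.csv"))
  invisible(dir)
}

#' @rdname saveTranslator
#' @param dir checkpoint directory.
#' @export
loadTranslator <- function(dir) {
  cj <- jsonlite::read_json(file.path(dir, "config.json"),
                            simplifyVector = TRUE)
  cfg <- new("TranslatorConfig", mode = cj$mode, baseLambda = cj$baseLambda,
             learningRate = cj$learningRate, epochs = as.integer(cj$epochs),
             maxSteps = if (is.null(cj$maxSteps) || is.na(cj$maxSteps))
               NA_integer_ else as.integer(cj$maxSteps),
             batchSize = as.integer(cj$batchSize),
             firstLayerFilters = as.integer(cj$firstLayerFilters),
             tileSize = as.integer(cj$tileSize), seed = as.integer(cj$seed),
             augment = cj$augment)
  readWeights <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      meta <- as.integer(strsplit(df$meta[i], ";")[[1]])
      vals <- as.numeric(strsplit(df$values[i], ";")[[1]])
      k <- meta[3]; cin <- meta[1]; cout <- meta[2]
      ncolW <- if (k == 0) 1L else k * k * cin   # k = 0 marks a norm layer
      W <- matrix(vals[seq_len(df$nW[i])], nrow = cout, ncol = ncolW)
      b <- vals[df$nW[i] + seq_len(df$nb[i])]
      list(W = W, b = b, meta = meta)
    })
  }
  gen <- readWeights(file.path(dir, "generator.csv"))
  dis <- if (file.exists(file.path(dir, "discriminator.csv")))
    readWeights(file.path(dir, "discriminator.csv")) else list()
  hist <- read.csv(file.path(dir, "history.csv"), stringsAsFactors = FALSE)
  new("Translator", generator = gen, discriminator = dis, config = cfg,
      history = hist)
}
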