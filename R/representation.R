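# Variational autoencoder tile features. The encoder emits a (mean,
# log-variance) pair per latent dimension under a standard-normal prior;
# the posterior mean is the tile's feature vector. Architecture: fully
# connected encoder/decoder with one ReLU hidden layer each and a sigmoid
# output, trained by Adam on the Gaussian (fixed unit variance,
# mean-squared-error form) reconstruction term plus the closed-form KL
# term. The architecture is recorded in the model config.

#' VAE training configuration
#'
#' @param epochs training epochs.
#' @param batchSize tiles per batch.
#' @param learningRate Adam learning rate.
#' @param hidden hidden-layer width of encoder and decoder.
#' @param seed integer training seed.
#' @return a named list.
#' @export
vaeConfig <- function(epochs = 30L, batchSize = 16L, learningRate = 1e-3,
                      hidden = 128L, seed = 1L) {
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, hidden = as.integer(hidden),
       seed = as.integer(seed), architecture = "mlp-1hidden-relu-sigmoid")
}

#' VAE loss: reconstruction plus KL divergence to the prior
#'
#' `total = -E[log p(x|z)] + KL(q(z|x) || N(0, I))` with a Gaussian
#' fixed-unit-variance likelihood, so the reconstruction term is
#' `0.5 * sum((x - xhat)^2) + 0.5 * D * log(2 pi)` (D = number of pixels)
#' and the KL term has the diagonal-Gaussian closed form
#' `0.5 * sum(mu^2 + exp(logVar) - 1 - logVar)`, which is always >= 0 and
#' zero iff the posterior equals the prior.
#'
#' @param x original tile (any numeric array).
#' @param reconstruction decoded tile, same length.
#' @param mu latent posterior mean vector.
#' @param logVar latent posterior log-variance vector.
#' @return list with `total`, `recon`, `kl`.
#' @export
vaeLoss <- function(x, reconstruction, mu, logVar) {
  x <- as.numeric(x); reconstruction <- as.numeric(reconstruction)
  if (length(x) != length(reconstruction))
    stop("x and reconstruction must have equal length")
  if (length(mu) != length(logVar))
    stop("mu and logVar must have equal length")
  if (any(!is.finite(c(x, reconstruction, mu, logVar))))
    stop("non-finite inputs")
  recon <- 0.5 * sum((x - reconstruction)^2) + 0.5 * length(x) * log(2 * pi)
  kl <- 0.5 * sum(mu^2 + exp(logVar) - 1 - logVar)
  list(total = recon + kl, recon = recon, kl = kl)
}

tilesAsMatrix <- function(tiles) {
  if (is(tiles, "TileSet")) tiles <- heTiles(tiles)
  if (!is.list(tiles) || length(tiles) < 1L)
    stop("'tiles' must be a non-empty list of arrays (or a TileSet)")
  d <- dim(tiles[[1]])
  if (is.null(d)) d <- c(length(tiles[[1]]), 1L, 1L)
  if (length(d) == 2L) d <- c(d, 1L)
  X <- t(vapply(tiles, function(t) as.numeric(t), numeric(prod(d))))
  list(X = X, dim = as.integer(d))
}

vaeInit <- function(D, hidden, latentDim) {
  g <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = g(D, hidden), b1 = numeric(hidden),
       W2m = g(hidden, latentDim) * 0.1, b2m = numeric(latentDim),
       W2v = g(hidden, latentDim) * 0.1, b2v = numeric(latentDim),
       W3 = g(latentDim, hidden), b3 = numeric(hidden),
       W4 = g(hidden, D) * 0.1, b4 = numeric(D))
}

vaeEncodeMat <- function(params, X) {
  H1 <- pmax(sweep(X %*% params$W1, 2L, params$b1, `+`), 0)
  list(H1 = H1,
       MU = sweep(H1 %*% params$W2m, 2L, params$b2m, `+`),
       LV = sweep(H1 %*% params$W2v, 2L, params$b2v, `+`))
}

vaeDecodeMat <- function(params, Z) {
  H2 <- pmax(sweep(Z %*% params$W3, 2L, params$b3, `+`), 0)
  A4 <- sweep(H2 %*% params$W4, 2L, params$b4, `+`)
  list(H2 = H2, Y = 1 / (1 + exp(-A4)))
}

#' Train a variational autoencoder on H&E tiles
#'
#' @param tiles list of H x W x C arrays (or a \linkS4class{TileSet}); all
#'   tiles must share one shape.
#' @param latentDim latent dimensionality (default 16).
#' @param config a [vaeConfig()] list.
#' @return a \linkS4class{VaeModel}; `config$lossTrace` records the mean
#'   per-epoch training loss.
#' @export
trainVae <- function(tiles, latentDim = 16L, config = vaeConfig()) {
  tm <- tilesAsMatrix(tiles)
  X <- tm$X
  n <- nrow(X); D <- ncol(X)
  latentDim <- as.integer(latentDim)
  if (latentDim < 1L) stop("latentDim must be >= 1")
  lr <- config$learningRate
  withSeed(config$seed, {
    p <- vaeInit(D, config$hidden, latentDim)
    mAdam <- lapply(p, function(w) w * 0)
    vAdam <- mAdam
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tAdam <- 0
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0
      for (start in seq(1L, n, by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        nbt <- nrow(Xb)
        enc <- vaeEncodeMat(p, Xb)
        E <- matrix(rnorm(nbt * latentDim), nbt, latentDim)
        SD <- exp(enc$LV / 2)
        Z <- enc$MU + SD * E
        dec <- vaeDecodeMat(p, Z)
        ## loss (per-batch mean of per-tile totals, constants dropped)
        recon <- 0.5 * sum((dec$Y - Xb)^2) / nbt
        kl <- 0.5 * sum(enc$MU^2 + exp(enc$LV) - 1 - enc$LV) / nbt
        epLoss <- epLoss + recon + kl; nb <- nb + 1
        ## backprop
        dY <- (dec$Y - Xb) / nbt
        dA4 <- dY * dec$Y * (1 - dec$Y)
        g <- list()
        g$W4 <- t(dec$H2) %*% dA4; g$b4 <- colSums(dA4)
        dH2 <- dA4 %*% t(p$W4); dA3 <- dH2 * (dec$H2 > 0)
        g$W3 <- t(Z) %*% dA3; g$b3 <- colSums(dA3)
        dZ <- dA3 %*% t(p$W3)
        dMU <- dZ + enc$MU / nbt
        dLV <- dZ * E * SD / 2 + 0.5 * (exp(enc$LV) - 1) / nbt
        g$W2m <- t(enc$H1) %*% dMU; g$b2m <- colSums(dMU)
        g$W2v <- t(enc$H1) %*% dLV; g$b2v <- colSums(dLV)
        dH1 <- dMU %*% t(p$W2m) + dLV %*% t(p$W2v)
        dA1 <- dH1 * (enc$H1 > 0)
        g$W1 <- t(Xb) %*% dA1; g$b1 <- colSums(dA1)
        ## Adam
        tAdam <- tAdam + 1
        for (nm in names(g)) {
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g[[nm]]
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- mAdam[[nm]] / (1 - b1^tAdam)
          vhat <- vAdam[[nm]] / (1 - b2^tAdam)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      trace[ep] <- epLoss / nb
    }
    cfg <- config
    cfg$lossTrace <- trace
    new("VaeModel", params = p, latentDim = latentDim, inputDim = as.integer(D),
        tileDim = tm$dim, config = cfg)
  })
}

#' Encode tiles into the latent feature table
#'
#' Deterministic: the posterior mean (no sampling) is used as the feature
#' vector, one row per tile.
#'
#' @param model a trained \linkS4class{VaeModel}.
#' @param tiles list of tiles (or a \linkS4class{TileSet}).
#' @param sampleIds character vector, one per tile; taken from the TileSet
#'   when omitted.
#' @return a \linkS4class{TileFeatures}.
#' @export
encodeTiles <- function(model, tiles, sampleIds = NULL) {
  if (is(tiles, "TileSet") && is.null(sampleIds))
    sampleIds <- tileInfo(tiles)$sample_id
  tm <- tilesAsMatrix(tiles)
  if (ncol(tm$X) != model@inputDim)
    stop("tile shape does not match the model's input dimension")
  if (is.null(sampleIds)) sampleIds <- rep("sample", nrow(tm$X))
  if (length(sampleIds) != nrow(tm$X))
    stop("sampleIds must have one entry per tile")
  enc <- vaeEncodeMat(model@params, tm$X)
  tileFeatures(enc$MU, sampleIds)
}

#' Reconstruct tiles through the autoencoder (diagnostic)
#'
#' Deterministic decode of the posterior mean.
#'
#' @param model a \linkS4class{VaeModel}.
#' @param tiles list of tiles (or a \linkS4class{TileSet}).
#' @return list of reconstructed arrays in the original tile shape.
#' @export
vaeReconstruct <- function(model, tiles) {
  tm <- tilesAsMatrix(tiles)
  enc <- vaeEncodeMat(model@params, tm$X)
  dec <- vaeDecodeMat(model@params, enc$MU)
  lapply(seq_len(nrow(dec$Y)), function(i) array(dec$Y[i, ], tm$dim))
}

#' Write / read a tile feature table as CSV
#'
#' Columns: `tile_id, sample_id, L1..Lm`.
#'
#' @param features a \linkS4class{TileFeatures}.
#' @param path CSV path.
#' @return invisibly `path` (write) or a \linkS4class{TileFeatures} (read).
#' @export
writeFeatureTable <- function(features, path) {
  df <- data.frame(tile_id = colData(features)$tile_id,
                   sample_id = colData(features)$sample_id,
                   featureMatrix(features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tileFeatures(as.matrix(df[, grep("^L\\d+$", names(df)), drop = FALSE]),
               df$sample_id, df$tile_id)
}
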