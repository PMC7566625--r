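# Shared fixtures, built in code at test time.

# A small phantom spec with one marker disk.
diskSpec <- function(side = 96L, radius = 20, noiseSd = 0,
                     density = 0.004) {
  phantomSpec(height = side, width = side, nucleusDensity = density,
              markerRegions = list(list(center = c(side / 2, side / 2),
                                        radius = radius)),
              noiseSd = noiseSd)
}

# Two-cluster cohort specification used across selection / workflow tests.
twoClusterCohort <- function(nTiles = 8L, tileSize = 64L, seed = 21L,
                             noiseSd = 0.01) {
  samples <- data.frame(
    sample_id = c("A1", "B1", "C1", "D1"),
    n_tiles = nTiles,
    cluster_id = c("dense", "dense", "sparse", "sparse"))
  clusters <- list(
    dense = list(nucleusDensity = c(0.005, 0.008), nucleusRadius = 2.5,
                 paletteId = 1L, markerProb = 0.7, markerRadius = c(8, 14)),
    sparse = list(nucleusDensity = c(0.001, 0.002), nucleusRadius = 4,
                  paletteId = 2L, markerProb = 0.7, markerRadius = c(8, 14)))
  cohortSpec(samples, clusters, tileSize = tileSize, noiseSd = noiseSd,
             seed = seed)
}

# Brute-force SSIM oracle: slides the window explicitly and evaluates the
# standard formula per position (sample (n-1) normalization), no prefilter.
ssimOracle <- function(x, y, win = 11L, c1 = 0.01^2, c2 = 0.03^2) {
  vals <- c()
  for (r in seq_len(nrow(x) - win + 1L)) {
    for (cc in seq_len(ncol(x) - win + 1L)) {
      wx <- x[r:(r + win - 1L), cc:(cc + win - 1L)]
      wy <- y[r:(r + win - 1L), cc:(cc + win - 1L)]
      mx <- mean(wx); my <- mean(wy)
      vx <- var(as.vector(wx)); vy <- var(as.vector(wy))
      vxy <- cov(as.vector(wx), as.vector(wy))
      vals <- c(vals, ((2 * mx * my + c1) * (2 * vxy + c2)) /
                      ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# Independent greedy-step oracle: exhaustively scores every remaining
# sample at every step using direct probability arithmetic.
selectionOracle <- function(p, membership, k) {
  ids <- sort(unique(membership))
  pX <- colMeans(p)
  chosen <- character(0)
  for (step in seq_len(k)) {
    best <- NULL; bestScore <- Inf
    for (sid in setdiff(ids, chosen)) {
      rows <- membership %in% c(chosen, sid)
      pS <- colMeans(p[rows, , drop = FALSE])
      kl <- sum(ifelse(pS > 0, pS * log(pS / pX), 0))
      sc <- (nrow(p) / sum(rows)) * kl
      if (sc < bestScore - 1e-15 ||
          (abs(sc - bestScore) <= 1e-15 && sid < best)) {
        best <- sid; bestScore <- sc
      }
    }
    chosen <- c(chosen, best)
  }
  chosen
}
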