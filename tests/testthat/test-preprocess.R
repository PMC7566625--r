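# Preprocessing: downscaling, Otsu nuclei masks, registration, disk median
# filter, intensity normalization, background-filtered tiling.

test_that("downscaling averages blocks and floors the output size", {
  img <- array(runif(512 * 512 * 3), c(512L, 512L, 3L))
  out <- downscaleImage(img, 2L)
  expect_equal(dim(out), c(256L, 256L, 3L))
  flat <- matrix(0.7, 100, 100)
  expect_true(all(downscaleImage(flat, 2L) == 0.7))
  checker <- matrix(c(0, 1, 1, 0), 2L, 2L)
  expect_equal(downscaleImage(checker, 2L), matrix(0.5, 1L, 1L))
  # odd size: trailing row/col dropped
  expect_equal(dim(downscaleImage(matrix(0, 5, 7), 2L)), c(2L, 3L))
  expect_error(downscaleImage(flat, 0L), "factor")
})

test_that("Otsu nuclei masks split bimodal intensities at the planted modes", {
  set.seed(11)
  g <- matrix(sample(c(0.2, 0.8), 64 * 64, replace = TRUE), 64L)
  he <- array(rep(g, 3), c(64L, 64L, 3L))  # gray encoded as RGB
  mask <- nucleiMask(he, "he")
  # exhaustive Otsu oracle over 256 candidate thresholds
  lv <- seq(min(g), max(g), length.out = 256L)
  bcv <- vapply(lv[-256], function(t) {
    w0 <- mean(g <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(g[g > t]) - mean(g[g <= t]))^2
  }, numeric(1))
  thr <- lv[which.max(bcv)]
  expect_gte(thr, 0.2); expect_lt(thr, 0.8)
  # complemented: dark pixels are nuclei, split exactly at the modes
  expect_identical(mask, g <= thr)
  expect_identical(mask, g == 0.2)

  # DAPI path: bright disks on black become distinct components
  dapi <- matrix(0, 96L, 96L)
  for (cx in seq(10, 90, by = 26)) for (cy in seq(10, 90, by = 26))
    dapi[vistain:::rasterDisk(96L, 96L, c(cx, cy), 4)] <- 1
  m <- nucleiMask(dapi, "dapi")
  expect_equal(max(EBImage::bwlabel(m * 1)), 16L)

  expect_error(nucleiMask(matrix(0, 32L, 32L), "dapi"), "degenerate")
})

test_that("disk median filter matches a brute-force neighborhood oracle", {
  flat <- matrix(0.4, 20L, 20L)
  expect_equal(medianFilterIF(flat, 3L), flat)

  spike <- matrix(0.1, 21L, 21L); spike[11, 11] <- 1
  expect_equal(medianFilterIF(spike, 5L), matrix(0.1, 21L, 21L))

  set.seed(4)
  img <- matrix(runif(32 * 32), 32L)
  r <- 3L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  reflect <- function(i, n) {           # mirror without repeating the edge
    i <- abs(i - 1) %% (2L * (n - 1L))
    ifelse(i >= n, 2L * (n - 1L) - i, i) + 1L
  }
  oracle <- matrix(0, 32L, 32L)
  for (rr in 1:32) for (cc in 1:32) {
    vals <- img[cbind(reflect(rr + offs$dy, 32L), reflect(cc + offs$dx, 32L))]
    oracle[rr, cc] <- median(vals)
  }
  expect_equal(medianFilterIF(img, r), oracle, tolerance = 1e-12)
  expect_error(medianFilterIF(img, 0L), "radius")
})

test_that("IF normalization hits the target moments then clips", {
  set.seed(7)
  img <- matrix(rnorm(256 * 256, 0.5, 0.1), 256L)
  pre <- normalizeIF(img, clip = FALSE)
  expect_equal(mean(pre), 0.25, tolerance = 1e-9)
  expect_equal(sd(pre), 0.125, tolerance = 1e-9)
  expect_identical(normalizeIF(img), vistain:::clip01(pre))
  # idempotent on inputs whose normalized range stays inside (0,1)
  flatIn <- matrix(runif(64 * 64), 64L)          # z-scores within +/- 1.8
  out <- normalizeIF(flatIn)
  expect_gt(min(out), 0); expect_lt(max(out), 1)
  expect_equal(normalizeIF(out), out, tolerance = 1e-12)

  wild <- matrix(rnorm(1e4, 0, 50), 100L)
  expect_true(all(normalizeIF(wild) >= 0 & normalizeIF(wild) <= 1))
  expect_error(normalizeIF(matrix(1, 10L, 10L)), "zero-variance")
})

test_that("H&E normalization maps channel statistics to the reference", {
  tgt <- list(mean = c(0.5, 0.45, 0.55), sd = c(0.08, 0.09, 0.08))
  set.seed(8)
  base <- array(runif(64 * 64 * 3), c(64L, 64L, 3L))
  ref <- base
  for (ch in 1:3)
    ref[, , ch] <- (base[, , ch] - mean(base[, , ch])) / sd(base[, , ch]) *
      tgt$sd[ch] + tgt$mean[ch]       # in range: no clipping at these stats
  # already at target -> fixed point
  expect_equal(normalizeHE(ref, tgt), ref, tolerance = 1e-6)
  # global color casts converge to the same channel means
  castA <- vistain:::clip01(ref * 0.9 + 0.05)
  castB <- vistain:::clip01(ref * 1.05)
  nA <- normalizeHE(castA, tgt); nB <- normalizeHE(castB, tgt)
  for (ch in 1:3)
    expect_lt(abs(mean(nA[, , ch]) - mean(nB[, , ch])), 0.01)
  # grayscale encoded as RGB passes through without error
  g <- array(rep(matrix(runif(32 * 32), 32L), 3), c(32L, 32L, 3L))
  out <- normalizeHE(g)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("tiling follows the strict background rule and conserves tiles", {
  tissue <- array(0.5, c(512L, 512L, 3L))
  ts <- tilePair(tissue, matrix(0.1, 512L, 512L), tileSize = 256L)
  expect_equal(length(ts), 4L)
  expect_equal(nrow(attr(ts, "removed")), 0L)

  edged <- array(0.5, c(600L, 600L, 3L))
  expect_equal(length(tilePair(edged, matrix(0, 600L, 600L),
                               tileSize = 256L)), 4L)

  # left tile 60% pure white -> removed; right tile kept at grid (0,1)
  he <- array(0.5, c(256L, 512L, 3L))
  he[1:154, 1:256, ] <- 1                      # 154/256 = 60.2% of the tile
  ts <- tilePair(he, matrix(0, 256L, 512L), tileSize = 256L)
  expect_equal(length(ts), 1L)
  expect_equal(tileInfo(ts)$row, 0)
  expect_equal(tileInfo(ts)$col, 1)

  # exactly 50% background is retained (strictly "more than 50%" removed)
  he50 <- array(0.5, c(256L, 256L, 3L))
  he50[1:128, , ] <- 1
  ts50 <- tilePair(he50, matrix(0, 256L, 256L), tileSize = 256L)
  expect_equal(length(ts50), 1L)
  expect_equal(tileInfo(ts50)$background_fraction, 0.5)

  # a background pixel needs ALL three 8-bit channels above the threshold
  heCh <- array(1, c(256L, 256L, 3L))
  heCh[, , 2] <- 0.5                            # green below threshold
  expect_equal(length(tilePair(heCh, matrix(0, 256L, 256L),
                               tileSize = 256L)), 1L)

  # conservation: retained + removed = floor(H/s) * floor(W/s)
  set.seed(9)
  big <- array(runif(300 * 520 * 3, 0.6, 1), c(300L, 520L, 3L))
  ts <- tilePair(big, matrix(0, 300L, 520L), tileSize = 100L)
  expect_equal(length(ts) + nrow(attr(ts, "removed")), 3L * 5L)

  expect_message(empty <- tilePair(array(0.5, c(100L, 100L, 3L)),
                                   matrix(0, 100L, 100L), tileSize = 256L),
                 "smaller")
  expect_equal(length(empty), 0L)
})

test_that("registration recovers planted misalignments on phantoms", {
  spec <- phantomSpec(height = 320L, width = 320L, nucleusDensity = 0.0025,
                      noiseSd = 0)
  p <- generatePhantomPair(spec, 13L)
  corners <- rbind(c(0, 0), c(319, 0), c(0, 319), c(319, 319))

  # self-registration of an unperturbed pair is within half a pixel
  reg0 <- registerPair(heImage(p), nuclearImage(p))
  d0 <- affineApplyPoints(registrationAffine(reg0), corners) - corners
  expect_lt(max(sqrt(rowSums(d0^2))), 0.5)

  # planted translation + rotation recovered within a pixel at the corners
  M <- affineMatrix2x3(rotation = 2, translation = c(10, -5),
                       center = c(159.5, 159.5))
  pp <- perturbAlignment(p, M)
  reg <- registerPair(heImage(pp), nuclearImage(pp))
  truth <- affineInvert(M)
  err <- sqrt(rowSums((affineApplyPoints(registrationAffine(reg), corners) -
                       affineApplyPoints(truth, corners))^2))
  expect_lt(max(err), 1)
  expect_gte(nMatchedFeatures(reg), 3L)
  expect_true(inlierFraction(reg) > 0 && inlierFraction(reg) <= 1)

  expect_error(registerPair(heImage(p), matrix(0, 320L, 320L)),
               "registration failed")
})

test_that("tile manifests round-trip and validate", {
  dir <- withr::local_tempdir()
  he <- array(runif(128 * 128 * 3, 0, 0.6), c(128L, 128L, 3L))
  ts <- tilePair(he, matrix(runif(128 * 128), 128L), tileSize = 64L,
                 sampleId = "S1")
  man <- writeTileManifest(ts, dir)
  expect_equal(nrow(validateManifest(man)), 0L)

  back <- readTileManifest(man)
  expect_equal(length(back), length(ts))
  expect_equal(tileInfo(back)$row, tileInfo(ts)$row)
  expect_lt(max(abs(heTiles(back)[[1]] - heTiles(ts)[[1]])), 1 / 254)

  # a missing tile file is reported by path
  df <- read.csv(man)
  file.remove(file.path(dir, df$he_path[1]))
  iss <- validateManifest(man)
  expect_true(any(iss$issue == "missing_file" & iss$detail == df$he_path[1]))

  # a duplicated grid cell is reported with sample and position
  df2 <- rbind(df, df[2, ])
  man2 <- file.path(dir, "dup.csv")
  write.csv(df2, man2, row.names = FALSE)
  iss2 <- validateManifest(man2)
  expect_true(any(iss2$issue == "duplicate_grid_cell" &
                  grepl("S1", iss2$detail)))
})
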