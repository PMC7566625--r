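# Translator: adaptive L1 weight, cGAN objective arithmetic, paired
# augmentation, seeded training, inference, ensembling, stitching.

test_that("the adaptive L1 weight is the exceedance fraction times base", {
  half <- matrix(c(rep(0.9, 8), rep(0.1, 8)), 4L)
  expect_equal(adaptiveLambda(list(half), 0.5), 50)
  expect_equal(adaptiveLambda(list(matrix(0.1, 4L, 4L)), 0.5), 0)
  expect_equal(adaptiveLambda(list(matrix(0.9, 4L, 4L)), 0.5), 100)
  expect_error(adaptiveLambda(list(), 0.5), "empty")
  expect_error(adaptiveLambda(list(half), NaN), "finite")
  # strictly-above rule: pixels at exactly the mean do not count
  expect_equal(adaptiveLambda(list(matrix(0.5, 4L, 4L)), 0.5), 0)
  # mixed-source batches use each tile's own mean
  expect_equal(adaptiveLambda(list(matrix(0.9, 2L, 2L), matrix(0.9, 2L, 2L)),
                              c(0.95, 0.5)), 50)
  # linear in the fraction and bounded by [0, base]
  set.seed(1)
  for (i in 1:20) {
    b <- matrix(runif(64), 8L)
    lam <- adaptiveLambda(list(b), 0.5, baseLambda = 80)
    expect_equal(lam, 80 * mean(b > 0.5))
    expect_gte(lam, 0); expect_lte(lam, 80)
  }
})

test_that("cGAN objective components follow the printed forms", {
  y <- matrix(runif(16), 4L)
  perfect <- cganObjective(dReal = 1, dFake = 0, y = y, gx = y, lambda = 100)
  expect_equal(perfect$l_cgan, 0)      # log 1 + log(1 - 0)
  expect_equal(perfect$l_l1, 0)
  half <- cganObjective(0.5, 0.5, y, y, 100)
  expect_equal(half$l_cgan, 2 * log(0.5))
  expect_equal(half$total_d, -2 * log(0.5))
  gx <- y + 0.1
  expect_equal(cganObjective(0.5, 0.5, y, gx, 10)$l_l1, 0.1, tolerance = 1e-12)
  expect_equal(cganObjective(0.5, 0.5, y, gx, 10)$total_g,
               -log(0.5) + 10 * 0.1, tolerance = 1e-12)
  expect_error(cganObjective(1.2, 0.5, y, y, 1), "probabilities")
})

test_that("augmentation keeps pairs geometrically locked", {
  set.seed(2)
  pairs <- lapply(1:4, function(i) generatePhantomPair(diskSpec(side = 48L,
                                                                radius = 12),
                                                       i))
  heB <- lapply(pairs, heImage); ifB <- lapply(pairs, ifImage)
  a1 <- augmentPairBatch(heB, ifB, seed = 99L)
  a2 <- augmentPairBatch(heB, ifB, seed = 99L)
  expect_identical(a1, a2)                      # seeded repeatability
  expect_length(a1$he, 4L)                      # batch size preserved
  expect_false(identical(a1$he[[1]], heB[[1]]))

  # the IF foreground must still coincide with the transformed disk
  for (i in 1:4) {
    mask <- markerMask(pairs[[i]]) * 1
    warped <- warpAffine(mask, a1$affines[[i]]) > 0.5
    augFg <- a1$ifch[[i]] > 0.25
    iou <- sum(warped & augFg) / sum(warped | augFg)
    expect_gt(iou, 0.95)
  }
})

# shared tiny training fixture: 32-px tiles, small first layer
tiles32t <- local({
  samples <- data.frame(sample_id = "S", n_tiles = 40, cluster_id = "c")
  clusters <- list(c = list(nucleusDensity = c(0.004, 0.008),
                            markerProb = 0.7, markerRadius = c(5, 10)))
  asTileSet(generateCohort(cohortSpec(samples, clusters, tileSize = 32L,
                                      noiseSd = 0.01, seed = 5L)))
})
cfg32 <- function(...) translatorConfig(profile = "desk", tileSize = 32L,
                                        firstLayerFilters = 16L,
                                        batchSize = 8L, ...)

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- cfg32(mode = "l1_only", maxSteps = 10L, seed = 42L)
  a <- trainTranslator(tiles32t, cfg)
  b <- trainTranslator(tiles32t, cfg)
  expect_identical(a@generator, b@generator)
  expect_identical(a@history, b@history)
  expect_equal(nrow(a@history), 10L)            # history length = steps taken
  expect_length(a@discriminator, 0L)            # no D in l1_only mode
  expect_error(trainTranslator(tiles32t[integer(0)], cfg), "empty")
})

test_that("l1_only training converges to a constant target", {
  # constant IF c: the L1 optimum is the constant itself
  cval <- 0.6
  heL <- heTiles(tiles32t)[1:24]
  ts <- new("TileSet", he = heL,
            ifch = replicate(24, matrix(cval, 32L, 32L), simplify = FALSE),
            info = data.frame(sample_id = "S", row = 0:23, col = 0L,
                              background_fraction = 0,
                              if_source_mean = cval / 2),
            tileSize = 32L)
  m <- trainTranslator(ts, cfg32(mode = "l1_only", maxSteps = 120L,
                                 learningRate = 0.005, seed = 7L))
  out <- translateTile(m, heL[[1]])
  expect_lt(mean(abs(out - cval)), 0.02)
  # loss trajectory: last quarter beats the first quarter
  h <- m@history
  expect_lt(mean(tail(h$l1, 30)), mean(head(h$l1, 30)))
})

test_that("inference is deterministic, bounded and shape-checked", {
  m <- trainTranslator(tiles32t, cfg32(mode = "l1_only", maxSteps = 15L,
                                       seed = 3L))
  he <- heTiles(tiles32t)[[1]]
  o1 <- translateTile(m, he); o2 <- translateTile(m, he)
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(32L, 32L))
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_error(translateTile(m, array(0, c(16L, 16L, 3L))), "must be")
  # list input gives a list output in order (batched GEMMs may round
  # differently from the single-tile path, hence the tolerance)
  outs <- translateTile(m, heTiles(tiles32t)[1:3])
  expect_equal(outs[[1]], o1, tolerance = 1e-12)
})

test_that("adversarial training keeps the duel alive at desk scale", {
  cfg <- cfg32(mode = "adversarial", maxSteps = 30L, seed = 11L)
  m <- trainTranslator(tiles32t, cfg)
  expect_gt(length(m@discriminator), 0L)
  h <- m@history
  expect_true(all(is.finite(h$d_loss)))
  # after warm-up the discriminator is neither collapsed nor trivially
  # perfect
  acc <- (h$d_acc_real + h$d_acc_fake) / 2
  late <- tail(acc, 15)
  expect_true(all(late > 0.05 & late < 0.999))
  # weighted L1 component trends down over the run
  expect_lt(mean(tail(h$lambda_l1, 10)), mean(head(h$lambda_l1, 10)))
})

test_that("checkpoints round-trip through the plain-text format", {
  dir <- withr::local_tempdir()
  m <- trainTranslator(tiles32t, cfg32(mode = "l1_only", maxSteps = 8L,
                                       seed = 13L))
  saveTranslator(m, dir)
  back <- loadTranslator(dir)
  he <- heTiles(tiles32t)[[2]]
  expect_equal(translateTile(back, he), translateTile(m, he),
               tolerance = 1e-12)
  expect_equal(back@history$l1, m@history$l1, tolerance = 1e-12)
})

test_that("ensembles average member outputs pixel-wise", {
  m1 <- trainTranslator(tiles32t, cfg32(mode = "l1_only", maxSteps = 8L,
                                        seed = 1L))
  m2 <- trainTranslator(tiles32t, cfg32(mode = "l1_only", maxSteps = 8L,
                                        seed = 2L))
  he <- heTiles(tiles32t)[[1]]
  o1 <- translateTile(m1, he); o2 <- translateTile(m2, he)
  ens <- ensembleTranslate(list(m1, m2), he)
  expect_equal(ens, (o1 + o2) / 2, tolerance = 1e-12)
  # single-model ensemble is the model itself; order does not matter
  expect_equal(ensembleTranslate(list(m1), he), o1)
  expect_equal(ensembleTranslate(list(m2, m1), he), ens, tolerance = 1e-12)
  # bounded by the pointwise member envelope
  expect_true(all(ens >= pmin(o1, o2) - 1e-12 & ens <= pmax(o1, o2) + 1e-12))
  expect_error(ensembleTranslate(list(), he), "empty")
})

test_that("stitching inverts tiling and validates the grid", {
  set.seed(14)
  img <- matrix(runif(64 * 96), 64L)
  tiles <- list(); pos <- NULL
  for (r in 0:1) for (cc in 0:2) {
    tiles <- c(tiles, list(img[(r * 32 + 1):((r + 1) * 32),
                               (cc * 32 + 1):((cc + 1) * 32)]))
    pos <- rbind(pos, c(r, cc))
  }
  expect_equal(stitchTiles(tiles, pos), img)
  expect_error(stitchTiles(tiles[-2], pos[-2, ]), "missing grid cell.*0 1")
  expect_error(stitchTiles(tiles[c(1, 1, 2:6)], rbind(pos[1, ], pos)),
               "duplicate grid cell")
})
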