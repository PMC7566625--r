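# Phantom generator: planted signal, determinism, cohort structure,
# misalignment fixtures, feature-table fixtures.

test_that("phantom pair plants the marker signal exactly where specified", {
  side <- 128L
  spec <- phantomSpec(height = side, width = side, nucleusDensity = 0.003,
                      markerRegions = list(list(center = c(60, 70),
                                                radius = 40)),
                      noiseSd = 0)
  p <- generatePhantomPair(spec, 3L)
  # foreground support equals the rasterized disk exactly (noise-free)
  x <- rep(0:(side - 1), each = side); y <- rep(0:(side - 1), times = side)
  diskCount <- sum((x - 60)^2 + (y - 70)^2 <= 40^2)
  expect_equal(sum(ifImage(p) > 0), diskCount)
  expect_equal(sum(markerMask(p)), diskCount)
  # no marker regions, no noise -> an exactly blank IF channel
  blank <- generatePhantomPair(phantomSpec(height = 64L, width = 64L,
                                           noiseSd = 0), 5L)
  expect_true(all(ifImage(blank) == 0))
  # with noise, values stay near zero (no planted signal)
  noisy <- generatePhantomPair(phantomSpec(height = 64L, width = 64L,
                                           noiseSd = 0.02), 5L)
  expect_lt(quantile(ifImage(noisy), 0.99), 3 * 0.02)
})

test_that("phantom generation is bit-deterministic under a fixed seed", {
  spec <- diskSpec()
  a <- generatePhantomPair(spec, 17L)
  b <- generatePhantomPair(spec, 17L)
  expect_identical(heImage(a), heImage(b))
  expect_identical(ifImage(a), ifImage(b))
  expect_identical(nuclearImage(a), nuclearImage(b))
  c <- generatePhantomPair(spec, 18L)
  expect_false(identical(heImage(a), heImage(c)))
})

test_that("degenerate phantom specifications are rejected", {
  expect_error(phantomSpec(height = 0L, width = 64L), "height")
  expect_error(phantomSpec(noiseSd = -1), "noiseSd")
  expect_error(
    phantomSpec(height = 64L, width = 64L,
                markerRegions = list(list(center = c(60, 60), radius = 20))),
    "bounds")
})

test_that("cohorts conserve tile counts and separate planted clusters", {
  one <- cohortSpec(data.frame(sample_id = "S", n_tiles = 5,
                               cluster_id = "c"),
                    list(c = list()), tileSize = 64L, seed = 2L)
  coh <- generateCohort(one)
  expect_length(coh, 1L)
  expect_length(coh$S, 5L)
  expect_true(all(vapply(coh$S, sampleId, character(1)) == "S"))

  co <- twoClusterCohort(nTiles = 6L, seed = 30L)
  coh <- generateCohort(co)
  expect_equal(sum(lengths(coh)), 4L * 6L)
  counts <- vapply(coh, function(tiles)
    mean(vapply(tiles, function(p) p@groundTruth$nucleusCount, numeric(1))),
    numeric(1))
  # disjoint density ranges: every dense-cluster sample outcounts every
  # sparse-cluster sample
  expect_gt(min(counts[c("A1", "B1")]), max(counts[c("C1", "D1")]))

  coh2 <- generateCohort(co)
  expect_identical(lapply(coh, function(t) lapply(t, ifImage)),
                   lapply(coh2, function(t) lapply(t, ifImage)))

  expect_error(cohortSpec(data.frame(sample_id = c("S", "S"), n_tiles = 1,
                                     cluster_id = "c"), list(c = list())),
               "duplicate")
  expect_error(cohortSpec(data.frame(sample_id = "S", n_tiles = 1,
                                     cluster_id = "missing"),
                          list(c = list())), "cluster")
})

test_that("perturbAlignment warps the IF channel by exactly the given affine", {
  p <- generatePhantomPair(diskSpec(side = 80L), 4L)
  ident <- perturbAlignment(p, affineMatrix2x3())
  expect_equal(ifImage(ident), ifImage(p))

  M <- affineMatrix2x3(translation = c(10, -5))
  shifted <- perturbAlignment(p, M)
  orig <- ifImage(p); new <- ifImage(shifted)
  # content moved +10 in x (cols), -5 in y (rows)
  expect_equal(new[1:70, 11:80], orig[6:75, 1:70])
  expect_identical(plantedAffine(shifted), M)
  expect_identical(heImage(shifted), heImage(p))

  # round trip: affine then its inverse on a smooth IF surface (bilinear
  # interpolation error scales with curvature), compared away from borders
  ps <- p
  ps@ifMarker <- blurGaussian(ifImage(p), 2.5)
  M2 <- affineMatrix2x3(rotation = 3, scale = 1.01, translation = c(4, -2),
                        center = c(39.5, 39.5))
  rt <- perturbAlignment(perturbAlignment(ps, M2), affineInvert(M2))
  inner <- 15:65
  expect_lt(max(abs(ifImage(rt)[inner, inner] - ifImage(ps)[inner, inner])),
            0.02)

  bad <- matrix(c(1, 2, 2, 4, 0, 0), 2L, 3L)  # singular
  expect_error(perturbAlignment(p, bad), "invertible")
})

test_that("synthetic feature tables honor their sampling model", {
  mu <- rbind(S1 = rep(1, 16), S2 = rep(-1, 16))
  exact <- generateFeatureTable(c(S1 = 3, S2 = 2), mu, noiseSd = 0, seed = 1L)
  fm <- featureMatrix(exact)
  expect_equal(dim(fm), c(5L, 16L))
  expect_true(all(fm[1:3, ] == 1) && all(fm[4:5, ] == -1))
  expect_equal(sampleMembership(exact), c(rep("S1", 3), rep("S2", 2)))

  single <- generateFeatureTable(c(A = 1), matrix(0, 1, 16), seed = 2L)
  expect_equal(nrow(featureMatrix(single)), 1L)

  expect_error(generateFeatureTable(c(A = 2), matrix(0, 2, 16)), "row per")

  # identical sample means: at n = 10,000 the two samples' weighted-KL
  # scores from the pooled distribution converge toward zero together
  big <- generateFeatureTable(c(P = 10000, Q = 10000),
                              rbind(rep(0, 16), rep(0, 16)),
                              noiseSd = 1, seed = 3L)
  pt <- normalizeRows(big)
  s1 <- representativenessScore(pt, "P")
  s2 <- representativenessScore(pt, "Q")
  expect_lt(abs(s1 - s2), 1e-3)
  expect_lt(max(s1, s2), 1e-3)
})

test_that("phantom pairs round-trip through TIFF + JSON sidecars", {
  dir <- withr::local_tempdir()
  p <- generatePhantomPair(diskSpec(side = 64L), 9L)
  side <- writePhantomPair(p, dir, "ph")
  expect_true(file.exists(side))
  he <- tiff::readTIFF(file.path(dir, "ph_he.tif"))
  ifm <- tiff::readTIFF(file.path(dir, "ph_if.tif"))
  expect_equal(dim(he), c(64L, 64L, 3L))
  expect_equal(max(abs(he - heImage(p))), 0, tolerance = 1 / 255)
  expect_equal(max(abs(ifm - ifImage(p))), 0, tolerance = 1e-6)
  truth <- jsonlite::read_json(side, simplifyVector = TRUE)
  expect_equal(truth$seed, 9L)
})
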