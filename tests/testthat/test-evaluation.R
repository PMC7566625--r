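# SSIM / Pearson metrics and the paired nonparametric comparison battery.

test_that("windowed SSIM matches the brute-force sliding oracle", {
  set.seed(3)
  noPre <- ssimParams(prefilterSigma = 0)
  for (i in 1:5) {
    x <- matrix(runif(32 * 32), 32L)
    y <- vistain:::clip01(x + matrix(rnorm(32 * 32, 0, 0.2), 32L))
    expect_equal(ssim(x, y, noPre), ssimOracle(x, y), tolerance = 1e-10)
  }
  x <- matrix(runif(24 * 24), 24L)
  expect_equal(ssim(x, x, noPre), 1)
  expect_equal(ssim(x, x, ssimParams()), 1)   # prefilter preserves identity
})

test_that("SSIM is symmetric, bounded and gains from the noise prefilter", {
  set.seed(4)
  x <- matrix(runif(40 * 40), 40L)
  y <- matrix(runif(40 * 40), 40L)
  p0 <- ssimParams(prefilterSigma = 0)
  expect_equal(ssim(x, y, p0), ssim(y, x, p0), tolerance = 1e-12)
  expect_lte(ssim(x, y, p0), 1)

  # a noisy copy of a clean IF phantom scores higher with the sigma-3
  # prefilter than without: the prefilter discounts technical noise
  clean <- ifImage(generatePhantomPair(diskSpec(side = 64L), 6L))
  noisy <- vistain:::clip01(clean + matrix(rnorm(64 * 64, 0, 0.1), 64L))
  expect_gt(ssim(clean, noisy, ssimParams()),
            ssim(clean, noisy, p0))

  expect_error(ssim(x, y[1:20, 1:20]), "equal dimensions")
  expect_error(ssim(x[1:8, 1:8], y[1:8, 1:8]), "window")
})

test_that("Pearson correlation follows the direct formula", {
  set.seed(5)
  x <- matrix(runif(30 * 30), 30L)
  expect_equal(pearsonCor(x, 2 * x + 1), 1)
  expect_equal(pearsonCor(x, -x), -1)
  y <- matrix(runif(30 * 30), 30L)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonCor(x, y), direct, tolerance = 1e-12)
  expect_error(pearsonCor(x, matrix(0.5, 30L, 30L)), "constant")
})

test_that("comparison routing follows the group count", {
  set.seed(6)
  n <- 60
  base <- runif(n, 0.4, 0.8)
  mk <- function(models, shift = NULL) {
    do.call(rbind, lapply(seq_along(models), function(i)
      scoreTable(sprintf("t%03d", 1:n), "S1", models[i],
                 vistain:::clip01(base + rnorm(n, 0, 0.02) +
                                  if (is.null(shift)) 0 else shift[i]))))
  }
  two <- compareModels(mk(c("m1", "m2")))
  expect_equal(two$S1$test, "wilcoxon_signed_rank")
  three <- compareModels(mk(c("m1", "m2", "m3")))
  expect_equal(three$S1$test, "friedman")
  expect_error(compareModels(mk("m1")), "at least 2")
  # unpaired scores are refused, naming the subset
  broken <- mk(c("m1", "m2"))[-1, ]
  expect_error(compareModels(broken), "S1")
})

test_that("identical score columns give a null Friedman result", {
  s <- runif(40, 0.3, 0.9)
  tbl <- do.call(rbind, lapply(c("a", "b", "c"), function(m)
    scoreTable(sprintf("t%02d", 1:40), "S1", m, s)))
  rep <- suppressWarnings(compareModels(tbl))$S1
  expect_equal(unname(rep$statistic), 0)
  expect_null(rep$flagged_pairs)
})

test_that("a planted shift is detected with the right Nemenyi pair pattern", {
  set.seed(7)
  n <- 100
  base <- runif(n, 0.3, 0.6)
  tbl <- rbind(
    scoreTable(sprintf("t%03d", 1:n), "S1", "m1", base + rnorm(n, 0, 0.05)),
    scoreTable(sprintf("t%03d", 1:n), "S1", "m2", base + rnorm(n, 0, 0.05)),
    scoreTable(sprintf("t%03d", 1:n), "S1", "m3",
               vistain:::clip01(base + 0.2 + rnorm(n, 0, 0.05))))
  rep <- compareModels(tbl)$S1
  expect_lt(rep$p_value, 0.05)
  fp <- rep$flagged_pairs
  expect_equal(nrow(fp), 2L)
  # exactly the two pairs involving the shifted model m3
  expect_true(all(apply(fp[, 1:2], 1L, function(r) "m3" %in% r)))
  expect_false(any(fp$model_a == "m1" & fp$model_b == "m2"))
  # Shapiro-Wilk is reported for every model
  expect_length(rep$shapiro_p, 3L)
})

test_that("Nemenyi p-values are symmetric and calibrated against ranks", {
  set.seed(8)
  mat <- matrix(rnorm(50 * 3), 50L, dimnames = list(NULL, c("a", "b", "c")))
  p <- nemenyiFriedman(mat)
  expect_equal(p, t(p))
  expect_true(all(diag(p) == 1))
  expect_true(all(p >= 0 & p <= 1))
  # exchangeable columns should rarely flag; a huge shift always flags
  mat[, 3] <- mat[, 3] + 100
  expect_lt(nemenyiFriedman(mat)["a", "c"], 1e-6)
})

test_that("comparison reports serialize to JSON", {
  dir <- withr::local_tempdir()
  set.seed(9)
  n <- 30
  tbl <- do.call(rbind, lapply(c("a", "b", "c"), function(m)
    scoreTable(sprintf("t%02d", 1:n), "S1", m, runif(n))))
  rep <- compareModels(tbl)
  path <- writeComparisonReport(rep, file.path(dir, "rep.json"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$S1$test, "friedman")
})
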