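# Representative-sample selection: row normalization, subset distributions,
# KL divergence, size-weighted scores, and the greedy sequence against an
# exhaustive oracle.

test_that("softmax row normalization maps features onto the simplex", {
  ft <- tileFeatures(rbind(rep(2.5, 16), rnorm(16)), c("A", "A"))
  pt <- normalizeRows(ft)
  p <- featureMatrix(pt)
  expect_equal(p[1, ], rep(1 / 16, 16), ignore_attr = TRUE)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(p > 0))

  two <- tileFeatures(matrix(c(log(1), log(3)), 1L), "A")
  expect_equal(featureMatrix(normalizeRows(two))[1, ], c(0.25, 0.75),
               ignore_attr = TRUE)

  # order within a row is preserved
  r <- rnorm(16)
  pr <- featureMatrix(normalizeRows(tileFeatures(rbind(r), "A")))[1, ]
  expect_equal(order(pr), order(r))

  expect_error(normalizeRows(tileFeatures(rbind(c(1, Inf)), "A")), "finite")

  # alternative shift normalization is also a valid simplex map
  ps <- featureMatrix(normalizeRows(ft, method = "shift"))
  expect_equal(rowSums(ps), c(1, 1), ignore_attr = TRUE)
  expect_true(all(ps > 0))
})

test_that("subset distributions are arithmetic means of member rows", {
  set.seed(5)
  ft <- tileFeatures(matrix(rnorm(80 * 8), 80L), rep(c("A", "B"), each = 40))
  pt <- normalizeRows(ft)
  p <- featureMatrix(pt)
  expect_equal(subsetDistribution(pt, 7), p[7, ], ignore_attr = TRUE)
  idx <- sample(80, 50)
  expect_equal(subsetDistribution(pt, idx), colMeans(p[idx, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(subsetDistribution(pt, "A")), 1, tolerance = 1e-12)
  expect_error(subsetDistribution(pt, character(0)), "empty")
})

test_that("KL divergence has the textbook values and properties", {
  expect_equal(klDivergence(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_error(klDivergence(c(0.5, 0.5), c(1, 0)), "zero mass")
  expect_error(klDivergence(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  set.seed(6)
  for (i in 1:200) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8) + 1e-3; q <- q / sum(q)
    expect_gte(klDivergence(p, q), 0)
  }
})

test_that("representativeness scores weight KL by inverse subset size", {
  set.seed(7)
  ft <- tileFeatures(matrix(rnorm(200 * 6), 200L),
                     rep(c("A", "B"), each = 100))
  pt <- normalizeRows(ft)
  expect_equal(representativenessScore(pt, seq_len(200)), 0, tolerance = 1e-12)

  # duplicated rows: same subset distribution at sizes 10 vs 100
  base <- matrix(rnorm(6), 1L)
  dup <- tileFeatures(base[rep(1, 210), ] + 0,
                      c(rep("S10", 10), rep("S100", 100), rep("REST", 100)))
  dup <- tileFeatures(rbind(matrix(rnorm(100 * 6), 100L),
                            base[rep(1, 110), ]),
                      c(rep("REST", 100), rep("S10", 10), rep("S100", 100)))
  pdup <- normalizeRows(dup)
  s10 <- representativenessScore(pdup, "S10")
  s100 <- representativenessScore(pdup, "S100")
  # identical KL, so the scores differ exactly by the size ratio
  expect_equal(s10 / s100, 10, tolerance = 1e-9)
  expect_lt(s100, s10)  # the larger subset scores better
})

test_that("greedy selection matches exhaustive per-step enumeration", {
  set.seed(8)
  for (rep in 1:10) {
    nSamp <- sample(3:5, 1)
    n <- sample(20:60, 1)
    membership <- sample(paste0("S", seq_len(nSamp)), n, replace = TRUE)
    while (length(unique(membership)) < nSamp)
      membership <- sample(paste0("S", seq_len(nSamp)), n, replace = TRUE)
    ft <- tileFeatures(matrix(rnorm(n * 8), n), membership)
    pt <- normalizeRows(ft)
    k <- nSamp
    res <- selectRepresentativeSequence(pt, k)
    expect_identical(selectedSamples(res),
                     selectionOracle(featureMatrix(pt), membership, k))
    # selecting everything drives the score to zero
    expect_equal(res@scores[k], 0, tolerance = 1e-12)
    expect_gte(min(res@scores), 0)
  }
})

test_that("a duplicate of the full dataset is picked first", {
  set.seed(9)
  x <- matrix(rnorm(60 * 8), 60L)
  membership <- rep(c("A", "B", "C"), each = 20)
  # add a 'sample' that replicates the entire dataset
  ft <- tileFeatures(rbind(x, x), c(membership, rep("ALL", 60)))
  pt <- normalizeRows(ft)
  expect_equal(selectedSamples(selectRepresentativeSequence(pt, 1))[1], "ALL")
})

test_that("selection is invariant to consistent feature permutations", {
  set.seed(10)
  x <- matrix(rnorm(50 * 8), 50L)
  membership <- sample(c("A", "B", "C", "D"), 50, replace = TRUE)
  perm <- sample(8)
  a <- selectRepresentativeSequence(normalizeRows(tileFeatures(x, membership)), 4)
  b <- selectRepresentativeSequence(
    normalizeRows(tileFeatures(x[, perm], membership)), 4)
  expect_identical(selectedSamples(a), selectedSamples(b))
  expect_equal(a@scores, b@scores, tolerance = 1e-12)
})

test_that("selection reports serialize the sequence and candidate scores", {
  dir <- withr::local_tempdir()
  ft <- generateFeatureTable(c(A = 20, B = 30),
                             rbind(rnorm(16), rnorm(16)), seed = 4L)
  res <- selectRepresentativeSequence(normalizeRows(ft), 2)
  path <- writeSelectionReport(res, file.path(dir, "sel.json"))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$samples, selectedSamples(res))
  expect_true(file.exists(file.path(dir, "sel_candidates.csv")))
})
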