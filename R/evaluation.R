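# Virtual-vs-real IF agreement: Gaussian-prefiltered windowed SSIM and
# Pearson correlation, plus the paired nonparametric model-comparison
# battery (Shapiro-Wilk report, Friedman + Nemenyi post-hoc for >= 3
# models, Wilcoxon signed-rank for 2).

#' Construct SSIM parameters
#'
#' @param windowSize odd sliding-window side (default 11).
#' @param dataRange image data range L; stabilizers are c1 = (0.01 L)^2 and
#'   c2 = (0.03 L)^2.
#' @param prefilterSigma Gaussian prefilter sd applied to both images before
#'   windowing (0 disables).
#' @param gaussianWeighted use Gaussian-weighted windows instead of uniform.
#' @return an \linkS4class{SsimParams}.
#' @export
ssimParams <- function(windowSize = 11L, dataRange = 1, prefilterSigma = 3,
                       gaussianWeighted = FALSE) {
  new("SsimParams", windowSize = as.integer(windowSize),
      c1 = (0.01 * dataRange)^2, c2 = (0.03 * dataRange)^2,
      prefilterSigma = prefilterSigma, gaussianWeighted = gaussianWeighted)
}

## Weighted moving average with "valid" output via separable correlation.
movingMeanValid <- function(m, wvec) {
  win <- length(wvec)
  hh <- nrow(m) - win + 1L; ww <- ncol(m) - win + 1L
  acc <- matrix(0, hh, ncol(m))
  for (j in seq_len(win))
    acc <- acc + wvec[j] * m[j:(j + hh - 1L), , drop = FALSE]
  out <- matrix(0, hh, ww)
  for (j in seq_len(win))
    out <- out + wvec[j] * acc[, j:(j + ww - 1L), drop = FALSE]
  out
}

#' Mean structural similarity between two images
#'
#' Both images are Gaussian-prefiltered (`prefilterSigma`), then SSIM is
#' evaluated on every `windowSize` x `windowSize` window (stride 1) using
#' the standard form
#' \deqn{\frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'            {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with sample (n-1) variance/covariance normalization, and the mean over
#' windows is returned.
#'
#' @param x,y numeric matrices of equal size, at least the window size.
#' @param params an \linkS4class{SsimParams}.
#' @return mean SSIM in [-1, 1].
#' @export
ssim <- function(x, y, params = ssimParams()) {
  x <- asImageMatrix(x, "x"); y <- asImageMatrix(y, "y")
  if (!all(dim(x) == dim(y))) stop("images must have equal dimensions")
  win <- params@windowSize
  if (nrow(x) < win || ncol(x) < win)
    stop("images must be at least the window size")
  if (params@prefilterSigma > 0) {
    x <- blurGaussian(x, params@prefilterSigma)
    y <- blurGaussian(y, params@prefilterSigma)
  }
  wvec <- if (params@gaussianWeighted) {
    g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * 1.5^2))
    g / sum(g)
  } else rep(1 / win, win)
  n <- win * win
  covNorm <- n / (n - 1)                    # sample covariance
  mx <- movingMeanValid(x, wvec)
  my <- movingMeanValid(y, wvec)
  mxx <- movingMeanValid(x * x, wvec)
  myy <- movingMeanValid(y * y, wvec)
  mxy <- movingMeanValid(x * y, wvec)
  vx <- covNorm * (mxx - mx^2)
  vy <- covNorm * (myy - my^2)
  vxy <- covNorm * (mxy - mx * my)
  s <- ((2 * mx * my + params@c1) * (2 * vxy + params@c2)) /
       ((mx^2 + my^2 + params@c1) * (vx + vy + params@c2))
  mean(s)
}

#' Pearson correlation between two images
#'
#' @param x,y numeric matrices of equal size; both must be non-constant.
#' @return Pearson r over the flattened pixels.
#' @export
pearsonCor <- function(x, y) {
  x <- asImageMatrix(x, "x"); y <- asImageMatrix(y, "y")
  if (!all(dim(x) == dim(y))) stop("images must have equal dimensions")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant image")
  cor(as.vector(x), as.vector(y))
}

#' Assemble a per-tile model score table
#'
#' @param tile_id,sample_subset_id,model_id vectors of equal length.
#' @param ssim,pearson_r numeric score vectors.
#' @return validated data.frame with those columns.
#' @export
scoreTable <- function(tile_id, sample_subset_id, model_id, ssim,
                       pearson_r = NA_real_) {
  df <- data.frame(tile_id = as.character(tile_id),
                   sample_subset_id = as.character(sample_subset_id),
                   model_id = as.character(model_id),
                   ssim = as.numeric(ssim),
                   pearson_r = as.numeric(pearson_r))
  bad <- !is.na(df$ssim) & (df$ssim < -1 | df$ssim > 1)
  if (any(bad)) stop("ssim values must lie in [-1, 1]")
  df
}

#' Nemenyi post-hoc test after a Friedman test
#'
#' All-pairs comparison on the within-block ranks: the statistic for models
#' i, j is `|Rbar_i - Rbar_j| / sqrt(k (k + 1) / (6 n))`, referred to the
#' studentized range distribution (`ptukey(sqrt(2) q, k, Inf)`).
#'
#' @param mat n x k matrix: n paired observations (tiles), k models.
#' @return k x k matrix of two-sided p-values.
#' @export
nemenyiFriedman <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L || n < 2L) stop("need at least 2 models and 2 blocks")
  R <- t(apply(mat, 1L, rank))
  rbar <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(rbar, rbar, `-`)) / se
  p <- ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  dimnames(p) <- list(colnames(mat), colnames(mat))
  p
}

#' Paired model-comparison battery on a score table
#'
#' For every sample subset the paired per-tile scores are checked for
#' completeness, Shapiro-Wilk normality is reported per model (on at most
#' 5000 scores), and then: two models are compared by the Wilcoxon
#' signed-rank test; three or more by the Friedman test, followed (when the
#' Friedman null is rejected at `alpha`) by the Nemenyi post-hoc test. The
#' Shapiro-Wilk result is reported but does not gate the nonparametric
#' route.
#'
#' @param scores data.frame as built by [scoreTable()].
#' @param metric score column to compare (`"ssim"` or `"pearson_r"`).
#' @param alpha significance level.
#' @return named list, one entry per sample subset, each with the test used,
#'   statistic, p-value, per-model Shapiro p-values, the post-hoc p-value
#'   matrix (3+ models, when run) and `flagged_pairs` significant at alpha.
#' @export
compareModels <- function(scores, metric = "ssim", alpha = 0.05) {
  stopifnot(metric %in% names(scores))
  models <- sort(unique(scores$model_id))
  if (length(models) < 2L) stop("need at least 2 models to compare")
  out <- list()
  for (sub in sort(unique(scores$sample_subset_id))) {
    s <- scores[scores$sample_subset_id == sub, ]
    tiles <- sort(unique(s$tile_id))
    mat <- matrix(NA_real_, length(tiles), length(models),
                  dimnames = list(tiles, models))
    idx <- cbind(match(s$tile_id, tiles), match(s$model_id, models))
    mat[idx] <- s[[metric]]
    if (any(is.na(mat)))
      stop(sprintf("subset '%s': unpaired or missing scores", sub))
    shap <- vapply(models, function(m) {
      v <- mat[, m]
      v <- v[seq_len(min(length(v), 5000L))]
      if (length(v) < 3L || sd(v) == 0) NA_real_ else shapiro.test(v)$p.value
    }, numeric(1))
    k <- length(models)
    if (k == 2L) {
      wt <- wilcox.test(mat[, 1], mat[, 2], paired = TRUE, exact = FALSE)
      rep <- list(subset = sub, n = nrow(mat), models = models,
                  shapiro_p = shap, test = "wilcoxon_signed_rank",
                  statistic = unname(wt$statistic), p_value = wt$p.value,
                  posthoc = NULL,
                  flagged_pairs = if (!is.na(wt$p.value) && wt$p.value < alpha)
                    data.frame(model_a = models[1], model_b = models[2],
                               p_value = wt$p.value) else NULL)
    } else {
      ft <- friedman.test(mat)
      if (is.nan(ft$statistic)) {
        # complete within-block ties (e.g. identical columns): trivially null
        ft$statistic <- 0
        ft$p.value <- 1
      }
      posthoc <- NULL; flagged <- NULL
      if (!is.na(ft$p.value) && ft$p.value < alpha) {
        posthoc <- nemenyiFriedman(mat)
        pr <- which(upper.tri(posthoc) & posthoc < alpha, arr.ind = TRUE)
        if (nrow(pr))
          flagged <- data.frame(model_a = models[pr[, 1]],
                                model_b = models[pr[, 2]],
                                p_value = posthoc[pr])
      }
      rep <- list(subset = sub, n = nrow(mat), models = models,
                  shapiro_p = shap, test = "friedman",
                  statistic = unname(ft$statistic), p_value = ft$p.value,
                  posthoc = posthoc, flagged_pairs = flagged)
    }
    out[[sub]] <- rep
  }
  out
}

#' Write a model-comparison report as JSON
#'
#' @param report result of [compareModels()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeComparisonReport <- function(report, path) {
  ser <- lapply(report, function(r) {
    r$posthoc <- if (!is.null(r$posthoc)) as.data.frame(r$posthoc) else NULL
    r
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
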