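# Shared numerical helpers: seeded evaluation, affine geometry, separable
# Gaussian filtering, rasterization. Image convention throughout the package:
# numeric arrays indexed [row, col(, channel)] with values in [0, 1]; points
# are (x, y) = (0-based column, 0-based row) at pixel centers; affines are
# 2 x 3 matrices acting on column vectors (x, y, 1)'.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage sub-seed: fan a global seed out by stage name so
## each pipeline stage is individually reproducible. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

isRgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
isGray <- function(img) is.matrix(img)

#' Affine helpers
#'
#' `affineMatrix2x3()` builds a 2 x 3 affine from rotation (degrees, about the
#' image center if `center` given), scale and translation; `affineInvert()`
#' inverts; `affineApplyPoints()` maps an n x 2 matrix of (x, y) points.
#'
#' @param rotation rotation in degrees (counter-clockwise in (x, y)).
#' @param scale isotropic scale factor.
#' @param translation numeric length-2 (dx, dy) in pixels.
#' @param center optional (x, y) center of rotation/scaling.
#' @return a 2 x 3 numeric matrix.
#' @export
affineMatrix2x3 <- function(rotation = 0, scale = 1, translation = c(0, 0),
                            center = NULL) {
  th <- rotation * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t <- as.numeric(translation)
  if (!is.null(center)) {
    c0 <- as.numeric(center)
    t <- t + c0 - A %*% c0
  }
  cbind(A, t)
}

#' @rdname affineMatrix2x3
#' @param M a 2 x 3 affine matrix.
#' @export
affineInvert <- function(M) {
  A <- M[, 1:2, drop = FALSE]
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine matrix is not invertible")
  Ai <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2L, 2L) / d
  cbind(Ai, -Ai %*% M[, 3])
}

#' @rdname affineMatrix2x3
#' @param pts an n x 2 matrix of (x, y) points.
#' @export
affineApplyPoints <- function(M, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  t(M[, 1:2] %*% t(pts) + M[, 3])
}

checkAffine <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(2L, 3L)) || !all(is.finite(M)))
    stop("affine must be a finite 2 x 3 matrix")
  affineInvert(M)  # errors if singular
  invisible(M)
}

#' Warp an image through an affine transform
#'
#' Content-forward semantics: a feature at point p in the input appears at
#' M p in the output. Sampling is bilinear through the inverse map; samples
#' falling outside the input are filled with `fill`.
#'
#' @param img matrix or H x W x C array.
#' @param M 2 x 3 affine matrix in (x, y, 1) pixel coordinates (0-based).
#' @param dims output (height, width); defaults to input size.
#' @param fill fill value for out-of-bounds samples.
#' @return warped image of size `dims`.
#' @export
warpAffine <- function(img, M, dims = NULL, fill = 0) {
  checkAffine(M)
  if (length(dim(img)) == 3L) {
    out <- array(fill, c(if (is.null(dims)) dim(img)[1:2] else dims, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- warpAffine(img[, , ch], M, dims = dims, fill = fill)
    return(out)
  }
  h <- nrow(img); w <- ncol(img)
  if (is.null(dims)) dims <- c(h, w)
  Mi <- affineInvert(M)
  x <- rep(seq_len(dims[2]) - 1, each = dims[1])   # column-major grid
  y <- rep(seq_len(dims[1]) - 1, times = dims[2])
  sx <- Mi[1, 1] * x + Mi[1, 2] * y + Mi[1, 3]
  sy <- Mi[2, 1] * x + Mi[2, 2] * y + Mi[2, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  val <- function(yy, xx) {
    ok <- xx >= 0 & xx <= (w - 1) & yy >= 0 & yy <= (h - 1)
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v[!ok] <- fill
    v
  }
  v <- (1 - fx) * (1 - fy) * val(y0, x0) +
       fx * (1 - fy)       * val(y0, x0 + 1) +
       (1 - fx) * fy       * val(y0 + 1, x0) +
       fx * fy             * val(y0 + 1, x0 + 1)
  matrix(v, dims[1], dims[2])
}

## Separable Gaussian blur with reflect padding. Kernel truncated at
## ceiling(3.5 sigma) and renormalized.
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

reflectIndex <- function(i, n) {
  # reflect (without repeating the edge sample twice beyond bounds): 0 -> 2,
  # n+1 -> n-1 for 1-based indices
  i <- abs(i - 1)
  p <- 2L * (n - 1L)
  i <- i %% p
  i[i >= n] <- p - i[i >= n]
  i + 1L
}

convolve1dReflect <- function(mat, k, margin) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(mat)
  n <- if (margin == 1L) nrow(mat) else ncol(mat)
  out <- matrix(0, nrow(mat), ncol(mat))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- reflectIndex(seq_len(n) + off, n)
    if (margin == 1L) out <- out + k[j] * mat[idx, , drop = FALSE]
    else out <- out + k[j] * mat[, idx, drop = FALSE]
  }
  out
}

#' Gaussian blur with reflect boundary handling
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' about 3.5 sigma. `sigma = 0` returns the input unchanged.
#'
#' @param img matrix or H x W x C array.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred image, same dimensions.
#' @export
blurGaussian <- function(img, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(img)
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- blurGaussian(img[, , ch], sigma)
    return(out)
  }
  k <- gaussianKernel1d(sigma)
  convolve1dReflect(convolve1dReflect(img, k, 1L), k, 2L)
}

## Rasterize a disk (pixel centers strictly within or on the radius).
rasterDisk <- function(h, w, center, radius) {
  x <- rep(seq_len(w) - 1, each = h)
  y <- rep(seq_len(h) - 1, times = w)
  matrix((x - center[1])^2 + (y - center[2])^2 <= radius^2, h, w)
}

## Rasterize a polygon given an n x 2 (x, y) vertex matrix (even-odd rule).
rasterPolygon <- function(h, w, vertices) {
  v <- matrix(as.numeric(vertices), ncol = 2L)
  x <- rep(seq_len(w) - 1, each = h)
  y <- rep(seq_len(h) - 1, times = w)
  n <- nrow(v)
  inside <- logical(length(x))
  jj <- c(n, seq_len(n - 1L))
  for (i in seq_len(n)) {
    j <- jj[i]
    crosses <- ((v[i, 2] > y) != (v[j, 2] > y))
    if (any(crosses)) {
      xi <- v[i, 1] + (y - v[i, 2]) / (v[j, 2] - v[i, 2]) * (v[j, 1] - v[i, 1])
      inside <- xor(inside, crosses & (x < xi))
    }
  }
  matrix(inside, h, w)
}

asImageMatrix <- function(img, what = "image") {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 2L) return(matrix(img, dim(img)[1]))
  stop(sprintf("'%s' must be a single-channel matrix", what))
}
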