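# Information-theoretic representative-sample selection. Tile feature rows
# are mapped to probability distributions over the feature domain; a
# candidate subset S of tiles is scored by (|X|/|S|) * KL(P(A|S) || P(A|X)),
# and samples are chosen greedily so each step's selected union minimizes
# that score.

#' Row-normalize tile features into probability distributions
#'
#' Maps each tile's signed feature vector onto the probability simplex.
#' `"softmax"` (default) exponentiates and normalizes — strictly positive,
#' order-preserving within a row. `"shift"` subtracts the row minimum, adds a
#' small positive offset, and renormalizes.
#'
#' @param features a \linkS4class{TileFeatures}.
#' @param method `"softmax"` or `"shift"`.
#' @return a \linkS4class{TileProbabilities}.
#' @export
normalizeRows <- function(features, method = c("softmax", "shift")) {
  method <- match.arg(method)
  x <- featureMatrix(features)            # tiles x m
  if (any(!is.finite(x))) stop("features must be finite")
  p <- switch(method,
    softmax = {
      e <- exp(x - apply(x, 1L, max))
      e / rowSums(e)
    },
    shift = {
      rng <- apply(x, 1L, function(r) diff(range(r)))
      off <- x - apply(x, 1L, min) + pmax(rng, 1) * 1e-6
      off / rowSums(off)
    })
  a <- t(p)
  dimnames(a) <- dimnames(SummarizedExperiment::assay(features, "features"))
  new("TileProbabilities", SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a),
    colData = SummarizedExperiment::colData(features)))
}

resolveSubset <- function(table, subset) {
  if (is.character(subset)) {
    idx <- which(sampleMembership(table) %in% subset)
  } else idx <- as.integer(subset)
  if (length(idx) < 1L) stop("subset is empty")
  idx
}

#' Mean feature distribution of a tile subset
#'
#' `P(A | S) = 1/|S| * sum_{x in S} P(A | x)`: the arithmetic mean of the
#' member tiles' rows.
#'
#' @param table a \linkS4class{TileProbabilities}.
#' @param subset sample id(s) (character) or tile row indices.
#' @return numeric distribution over the feature domain (sums to 1).
#' @export
subsetDistribution <- function(table, subset) {
  idx <- resolveSubset(table, subset)
  p <- SummarizedExperiment::assay(table, "features")
  rowMeans(p[, idx, drop = FALSE])
}

#' Kullback-Leibler divergence between two distributions (nats)
#'
#' `sum_f p(f) log(p(f) / q(f))` with natural logarithm; terms with
#' `p(f) = 0` contribute zero.
#'
#' @param p,q numeric distributions of equal length; `q` must be positive
#'   wherever `p` is.
#' @return nonnegative divergence in nats.
#' @export
klDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(q <= 0 & p > 0)) stop("q has zero mass where p is positive")
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Size-weighted representativeness score of a tile subset
#'
#' `(|X| / |S|) * KL(P(A|S) || P(A|X))` — smaller is more representative;
#' the weight prioritizes subsets that contribute many tiles.
#'
#' @param table a \linkS4class{TileProbabilities}.
#' @param subset sample id(s) or tile row indices (non-empty, within X).
#' @param base optional base-set indices (defaults to all tiles).
#' @return nonnegative score.
#' @export
representativenessScore <- function(table, subset, base = NULL) {
  idx <- resolveSubset(table, subset)
  nAll <- if (is.null(base)) ncol(table) else length(resolveSubset(table, base))
  pS <- subsetDistribution(table, idx)
  pX <- if (is.null(base)) subsetDistribution(table, seq_len(ncol(table)))
        else subsetDistribution(table, base)
  (nAll / length(idx)) * klDivergence(pS, pX)
}

#' Greedy representative-sample sequence
#'
#' Step j scores each remaining sample merged with the already-selected
#' union and picks the minimizer of the size-weighted KL score; ties are
#' broken by the lexicographically smaller sample id. Step 1 is therefore an
#' exhaustive search over single samples.
#'
#' @param table a \linkS4class{TileProbabilities}.
#' @param k number of samples to select (1 <= k <= number of samples).
#' @return a \linkS4class{SelectionResult}.
#' @export
selectRepresentativeSequence <- function(table, k) {
  membership <- sampleMembership(table)
  ids <- sort(unique(membership))
  if (k < 1L || k > length(ids))
    stop(sprintf("k must be in [1, %d]", length(ids)))
  chosen <- character(0)
  scores <- numeric(0)
  cand <- list()
  for (step in seq_len(k)) {
    remaining <- setdiff(ids, chosen)
    sc <- vapply(remaining, function(sid)
      representativenessScore(table, c(chosen, sid)), numeric(1))
    ord <- order(sc, remaining)            # ties -> smaller sample id
    cand[[step]] <- data.frame(step = step, sample_id = remaining,
                               score = sc, row.names = NULL)
    chosen <- c(chosen, remaining[ord[1]])
    scores <- c(scores, unname(sc[ord[1]]))
  }
  sizes <- vapply(ids, function(sid) sum(membership == sid), integer(1))
  new("SelectionResult", samples = chosen, scores = scores,
      subsetSizes = setNames(as.integer(sizes), ids),
      total = length(membership), candidates = cand)
}

#' Write a selection report
#'
#' JSON report with the ordered sample sequence, per-step scores and subset
#' sizes, plus a CSV of all candidate scores per step.
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param path output JSON path (`.csv` sibling written alongside).
#' @return invisibly, `path`.
#' @export
writeSelectionReport <- function(result, path) {
  jsonlite::write_json(list(
    samples = result@samples, scores = result@scores,
    subset_sizes = as.list(result@subsetSizes), total_tiles = result@total
  ), path, auto_unbox = TRUE, digits = NA)
  write.csv(do.call(rbind, result@candidates),
            sub("\\.json$", "_candidates.csv", path), row.names = FALSE)
  invisible(path)
}
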