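# End-to-end orchestration: cohort simulation, tile assembly, translator
# training per training-set composition, held-out inference, evaluation and
# model comparison, with per-stage seed fan-out and a run directory holding
# the resolved configuration and all artifacts.

#' Assemble registered pairs into a TileSet
#'
#' Accepts a list of \linkS4class{RegisteredPair} tiles or a whole cohort
#' (named list of such lists). The per-sample mean IF intensity (the
#' source-slide mean that drives the adaptive L1 weight) is computed over
#' each sample's tiles.
#'
#' @param pairs list of pairs, or named list of lists (a cohort).
#' @return a \linkS4class{TileSet}.
#' @export
asTileSet <- function(pairs) {
  if (length(pairs) && is(pairs[[1]], "RegisteredPair")) pairs <- list(pairs)
  heL <- list(); ifL <- list(); info <- NULL
  for (grp in pairs) {
    sid <- sampleId(grp[[1]])
    srcMean <- mean(vapply(grp, function(p) mean(ifImage(p)), numeric(1)))
    for (i in seq_along(grp)) {
      p <- grp[[i]]
      heL[[length(heL) + 1L]] <- heImage(p)
      ifL[[length(ifL) + 1L]] <- ifImage(p)
      gp <- p@gridPos
      info <- rbind(info, data.frame(
        sample_id = if (is.na(sampleId(p))) "sample" else sampleId(p),
        row = if (is.na(gp[1])) i - 1L else gp[1],
        col = if (is.na(gp[2])) 0L else gp[2],
        background_fraction = 0, if_source_mean = srcMean))
    }
  }
  if (!length(heL)) stop("no pairs supplied")
  new("TileSet", he = heL, ifch = ifL, info = info,
      tileSize = as.integer(nrow(ifL[[1]])))
}

#' Construct an experiment configuration
#'
#' @param cohort a \linkS4class{CohortSpec}.
#' @param compositions named list of training-set compositions (character
#'   vectors of sample ids). Evaluation covers exactly the samples held out
#'   of each composition; a composition covering every sample is rejected.
#' @param translator a \linkS4class{TranslatorConfig} template (its seed is
#'   re-derived per composition from the global seed).
#' @param ssimSettings an \linkS4class{SsimParams}.
#' @param seed global seed, fanned out deterministically to the stages.
#' @return an \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(cohort, compositions,
                             translator = translatorConfig(mode = "l1_only",
                                                           profile = "desk"),
                             ssimSettings = ssimParams(), seed = 1L) {
  new("ExperimentConfig", cohort = cohort, compositions = compositions,
      translator = translator, ssim = ssimSettings, seed = as.integer(seed))
}

#' Run a full virtual-staining experiment
#'
#' Simulates the cohort, optionally learns VAE features and the
#' representative-sample sequence, then for every training-set composition
#' trains a translator on exactly those samples' tiles, translates the tiles
#' of every held-out sample, scores them (SSIM and Pearson r against the
#' real IF), and finally compares the compositions on the held-out subsets
#' shared by all of them. All artifacts (resolved configuration, per-step
#' training histories, score table, comparison report) are written under
#' `outDir`; re-running with the same configuration and seed reproduces the
#' score table.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @param outDir run directory (created).
#' @param featurize also train the VAE and record the selected
#'   representative sequence in the report.
#' @return list with `scores` (the score table), `comparison` (per-subset
#'   test report, `NULL` with one composition), `selection` (a
#'   \linkS4class{SelectionResult} or `NULL`), and `runDir`.
#' @export
runExperiment <- function(config, outDir, featurize = FALSE) {
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeExperimentConfig(config, file.path(outDir, "config.yaml"))
  cohort <- generateCohort(config@cohort)
  ids <- names(cohort)
  tilesBySample <- lapply(ids, function(sid) asTileSet(cohort[sid]))
  names(tilesBySample) <- ids

  selection <- NULL
  if (featurize) {
    allTiles <- concatTileSets(tilesBySample)
    vae <- trainVae(allTiles, latentDim = 16L,
                    config = vaeConfig(epochs = 20L,
                                       seed = stageSeed(config@seed, "vae")))
    feats <- encodeTiles(vae, allTiles)
    selection <- selectRepresentativeSequence(normalizeRows(feats),
                                              k = min(2L, length(ids)))
    writeSelectionReport(selection, file.path(outDir, "selection.json"))
  }

  scores <- NULL
  for (nm in names(config@compositions)) {
    comp <- config@compositions[[nm]]
    heldout <- setdiff(ids, comp)
    trainTiles <- concatTileSets(tilesBySample[comp])
    ## audit: no held-out tile may enter training
    stopifnot(!any(tileInfo(trainTiles)$sample_id %in% heldout))
    cfg <- config@translator
    cfg@seed <- stageSeed(config@seed, paste0("train_", nm))
    model <- trainTranslator(trainTiles, cfg)
    write.csv(trainingHistory(model),
              file.path(outDir, sprintf("history_%s.csv", nm)),
              row.names = FALSE)
    for (sid in heldout) {
      ts <- tilesBySample[[sid]]
      pred <- translateTile(model, heTiles(ts))
      truth <- ifTiles(ts)
      sv <- vapply(seq_along(pred), function(i)
        ssim(pred[[i]], truth[[i]], config@ssim), numeric(1))
      pv <- vapply(seq_along(pred), function(i) {
        if (sd(pred[[i]]) == 0 || sd(truth[[i]]) == 0) NA_real_
        else pearsonCor(pred[[i]], truth[[i]])
      }, numeric(1))
      scores <- rbind(scores, scoreTable(
        tile_id = sprintf("%s_t%04d", sid, seq_along(pred)),
        sample_subset_id = sid, model_id = nm, ssim = sv, pearson_r = pv))
    }
  }
  write.csv(scores, file.path(outDir, "scores.csv"), row.names = FALSE)

  comparison <- NULL
  if (length(config@compositions) >= 2L) {
    ## paired comparison only on subsets scored under every model
    bySubset <- table(scores$sample_subset_id, scores$model_id) > 0
    shared <- rownames(bySubset)[rowSums(bySubset) == ncol(bySubset)]
    if (length(shared)) {
      comparison <- compareModels(
        scores[scores$sample_subset_id %in% shared, ], metric = "ssim")
      writeComparisonReport(comparison, file.path(outDir, "comparison.json"))
    }
  }
  list(scores = scores, comparison = comparison, selection = selection,
       runDir = outDir)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @param path YAML path.
#' @return invisibly `path` (write); an \linkS4class{ExperimentConfig}
#'   (read).
#' @export
writeExperimentConfig <- function(config, path) {
  co <- config@cohort; tr <- config@translator; sp <- config@ssim
  yaml::write_yaml(list(
    seed = config@seed,
    cohort = list(samples = co@samples, clusters = co@clusters,
                  tileSize = co@tileSize, noiseSd = co@noiseSd,
                  seed = co@seed),
    compositions = config@compositions,
    translator = list(mode = tr@mode, baseLambda = tr@baseLambda,
                      learningRate = tr@learningRate, epochs = tr@epochs,
                      maxSteps = if (is.na(tr@maxSteps)) "none" else tr@maxSteps,
                      batchSize = tr@batchSize,
                      firstLayerFilters = tr@firstLayerFilters,
                      tileSize = tr@tileSize, augment = tr@augment),
    ssim = list(windowSize = sp@windowSize, prefilterSigma = sp@prefilterSigma)
  ), path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  co <- cohortSpec(as.data.frame(y$cohort$samples), y$cohort$clusters,
                   tileSize = y$cohort$tileSize, noiseSd = y$cohort$noiseSd,
                   seed = y$cohort$seed)
  tr <- translatorConfig(mode = y$translator$mode,
    baseLambda = y$translator$baseLambda,
    learningRate = y$translator$learningRate,
    epochs = y$translator$epochs,
    maxSteps = if (identical(y$translator$maxSteps, "none")) NA_integer_
               else y$translator$maxSteps,
    batchSize = y$translator$batchSize,
    firstLayerFilters = y$translator$firstLayerFilters,
    tileSize = y$translator$tileSize, augment = y$translator$augment)
  experimentConfig(co, y$compositions, tr,
                   ssimParams(windowSize = y$ssim$windowSize,
                              prefilterSigma = y$ssim$prefilterSigma),
                   seed = y$seed)
}

#' Validate a tile manifest
#'
#' Checks that every referenced image exists, that all tiles share the
#' manifest's tile size, and that each sample's grid positions are unique
#' and complete over their bounding grid. Returns a machine-readable issue
#' list (empty when the manifest is well formed) rather than raising on
#' content problems; only an unreadable manifest is an error.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `issue`, `detail`.
#' @export
validateManifest <- function(path) {
  if (!file.exists(path)) stop("unreadable manifest: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  dir <- dirname(path)
  issues <- data.frame(issue = character(), detail = character())
  add <- function(issue, detail)
    rbind(issues, data.frame(issue = issue, detail = detail))
  sizes <- integer(0)
  for (i in seq_len(nrow(man))) {
    for (col in c("he_path", "if_path")) {
      f <- file.path(dir, man[[col]][i])
      if (!file.exists(f)) {
        issues <- add("missing_file", man[[col]][i])
      } else if (col == "he_path") {
        img <- tiff::readTIFF(f)
        sizes <- c(sizes, nrow(img))
      }
    }
  }
  if (length(unique(sizes)) > 1L)
    issues <- add("tile_size_mismatch",
                  paste(sort(unique(sizes)), collapse = " vs "))
  for (sid in unique(man$sample_id)) {
    sub <- man[man$sample_id == sid, ]
    keys <- paste(sub$row, sub$col)
    for (d in unique(keys[duplicated(keys)]))
      issues <- add("duplicate_grid_cell", sprintf("%s (%s)", sid, d))
    if (!anyDuplicated(keys) && nrow(sub) > 1L &&
        all(c("row", "col") %in% names(sub))) {
      want <- as.vector(outer(0:max(sub$row), 0:max(sub$col), paste))
      for (d in setdiff(want, keys))
        issues <- add("missing_grid_cell", sprintf("%s (%s)", sid, d))
    }
  }
  issues
}
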