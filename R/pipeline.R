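#' Configuration for the end-to-end protocol
#'
#' Bundles the synthetic-generator, training and partition settings with the
#' experiment arm sizes: 20 models on raw curves, 20 on MSC-corrected curves
#' and 20 on the special (part A / part B) partition — the 60-model study —
#' plus a dedicated 40-model raw arm from which the per-sample stability
#' statistics and the part split are computed.
#'
#' @param synthetic a [syntheticConfig()].
#' @param train a [trainConfig()].
#' @param partition a [partitionScheme()].
#' @param arms named counts for the `raw`, `msc` and `special` arms.
#' @param stabilityModels models in the stability arm (default 40).
#' @param sMax line budget for the separability search.
#' @param masterSeed integer; all randomness derives from it.
#' @return Classed list of settings.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           train = trainConfig(),
                           partition = partitionScheme(),
                           arms = c(raw = 20L, msc = 20L, special = 20L),
                           stabilityModels = 40L,
                           sMax = 5L, masterSeed = 1L) {
  stopifnot(all(arms >= 0), stabilityModels >= 0,
            all(c("raw", "msc", "special") %in% names(arms)))
  structure(list(synthetic = synthetic, train = train, partition = partition,
                 arms = arms, stabilityModels = as.integer(stabilityModels),
                 sMax = as.integer(sMax), masterSeed = as.integer(masterSeed)),
            class = "PipelineConfig")
}

#' Run the full reproducible protocol
#'
#' Executes, deterministically from `config$masterSeed`: synthetic dataset
#' generation; the raw and MSC parallel-model arms; the 40-model stability
#' arm with per-sample statistics and the part A (always correct) / part B
#' split; the special-partition arm (train on A, test on B); and PCA plus
#' pairwise linear separability for the raw and globally-MSC-corrected
#' curves.  Optionally writes all artifacts to `outDir`.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional directory for the CSV/JSON artifacts
#'   (`table1.csv`, `stability.csv`, `summary.json`, `pca_raw.csv`,
#'   `pca_msc.csv`, `separability.json`, `config.lock.json`).
#' @return A list (class `"thzReport"`) with elements `dataset`, `table1`,
#'   `stability`, `parts`, `meanAccuracy`, `pca` and `separability`.
#' @export
reproduceProtocol <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$masterSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  synCfg <- config$synthetic
  synCfg$seed <- seeds[1]
  profiles <- makeClassProfiles(synCfg)
  dataset <- sampleExtinctionDataset(profiles, synCfg)

  rawRecs <- runParallelModels(dataset, config$arms[["raw"]],
                               config$partition, config$train,
                               "none", masterSeed = seeds[2])
  mscRecs <- runParallelModels(dataset, config$arms[["msc"]],
                               config$partition, config$train,
                               "msc", masterSeed = seeds[3])
  stabRecs <- runParallelModels(dataset, config$stabilityModels,
                                config$partition, config$train,
                                "none", masterSeed = seeds[4])
  stability <- perSampleStability(stabRecs, dataset = dataset)
  parts <- splitParts(stability)
  specRecs <- specialPartitionExperiment(dataset, parts$partA, parts$partB,
                                         config$arms[["special"]],
                                         config$train, masterSeed = seeds[5])

  table1 <- rbind(recordsTable(rawRecs, arm = "raw"),
                  recordsTable(mscRecs, arm = "msc"),
                  recordsTable(specRecs, arm = "special"))
  table1$model <- seq_len(nrow(table1))
  meanAcc <- summarizeMeanAccuracy(random = stabRecs, special = specRecs)

  analyse <- function(x) {
    pca <- pcaFit(x, q = 2L)
    scores <- pcaScores2D(pca, x)
    list(pca = pca, scores = scores,
         separability = multiclassSeparability(scores, sMax = config$sMax))
  }
  raw <- analyse(dataset)
  mscAll <- corrected(mscCorrect(dataset))
  msc <- analyse(mscAll)

  report <- structure(list(
    dataset = dataset, profiles = profiles,
    records = list(raw = rawRecs, msc = mscRecs,
                   stability = stabRecs, special = specRecs),
    table1 = table1, stability = stability, parts = parts,
    meanAccuracy = meanAcc,
    pca = list(raw = raw$pca, msc = msc$pca),
    scores = list(raw = raw$scores, msc = msc$scores),
    separability = list(raw = raw$separability, msc = msc$separability),
    masterSeed = config$masterSeed
  ), class = "thzReport")

  if (!is.null(outDir)) writeReportArtifacts(report, config, outDir)
  report
}

#' @export
print.thzReport <- function(x, ...) {
  cat("thzsep protocol report (master seed ", x$masterSeed, ")\n", sep = "")
  cat("  models: ", nrow(x$table1), " (",
      paste(table(x$table1$arm)[unique(x$table1$arm)],
            unique(x$table1$arm), collapse = " + "), ")\n", sep = "")
  cat("  part A:", length(x$parts$partA), " part B:", length(x$parts$partB), "\n")
  idx <- function(rs) vapply(rs, separabilityIndex, numeric(1))
  cat("  separability index raw:", paste(format(idx(x$separability$raw)),
                                         collapse = " "), "\n")
  cat("  separability index msc:", paste(format(idx(x$separability$msc)),
                                         collapse = " "), "\n")
  invisible(x)
}

.sepToList <- function(rs) {
  lapply(rs, function(r) list(
    classPair = r@classPair, s = r@s, exact = r@exact, index = r@index,
    witnessLines = lapply(r@witnessLines, function(L)
      list(normal = as.numeric(L$normal), offset = as.numeric(L$offset)))))
}

#' Write the protocol artifacts
#'
#' @param report a `thzReport` from [reproduceProtocol()].
#' @param config the [pipelineConfig()] that produced it.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeReportArtifacts <- function(report, config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, c("table1.csv", "stability.csv", "summary.json",
                               "pca_raw.csv", "pca_msc.csv",
                               "separability.json", "config.lock.json"))
  write.csv(report$table1, paths[1], row.names = FALSE)
  write.csv(report$stability, paths[2], row.names = FALSE)
  summaryDoc <- list(
    meanAccuracy = report$meanAccuracy,
    partSizes = lapply(report$parts, length),
    explainedVariance = lapply(report$pca, explainedVariance),
    masterSeed = report$masterSeed)
  jsonlite::write_json(summaryDoc, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write.csv(report$scores$raw, paths[4], row.names = FALSE)
  write.csv(report$scores$msc, paths[5], row.names = FALSE)
  jsonlite::write_json(list(raw = .sepToList(report$separability$raw),
                            msc = .sepToList(report$separability$msc)),
                       paths[6], auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$synthetic$grid <- list(fMin = min(cfg$synthetic$grid),
                             fMax = max(cfg$synthetic$grid),
                             nPoints = length(cfg$synthetic$grid))
  jsonlite::write_json(lapply(cfg, unclass), paths[7],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Estimate ANN suitability without training a network
#'
#' A rapid screen for whether a small feedforward network is worth tuning on
#' a labelled spectral dataset: compares between-group to within-group
#' differences by computing, for every class pair and for both the raw and
#' the MSC-corrected curves, the generalized Rayleigh quotient along the
#' Fisher direction of the 2-D principal-component scores and the
#' linear-separability index.  The verdict per pair operationalizes the
#' qualitative guidance as: `promising` when the post-MSC index equals 1,
#' `marginal` when it is at least 1/2, `poor` otherwise (including when no
#' arrangement within the line budget separates the classes).
#'
#' @param dataset a labelled [ThzSpectra-class] with at least two classes.
#' @param sMax line budget for the separability search (default 3).
#' @param ... passed to [minSeparatingLines()].
#' @return `data.frame` with one row per class pair: Rayleigh quotients and
#'   indices for raw and MSC curves, and the verdict.
#' @export
estimateSuitability <- function(dataset, sMax = 3L, ...) {
  stopifnot(is(dataset, "ThzSpectra"))
  labels <- classLabels(dataset)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")

  analyse <- function(x) {
    scores <- pcaScores2D(pcaFit(x, q = 2L), x)
    pairs <- utils::combn(classes, 2)
    res <- lapply(seq_len(ncol(pairs)), function(k) {
      g <- pairs[, k]
      keep <- scores$label %in% g
      pts <- cbind(scores$pc1, scores$pc2)[keep, , drop = FALSE]
      lab <- scores$label[keep]
      S <- scatterMatrices(pts, lab)
      J <- tryCatch(rayleighQuotient(fisherDirection(S), S),
                    error = function(e) NA_real_)
      sep <- minSeparatingLines(pts, lab, sMax = sMax, ...)
      list(pair = g, J = J, index = separabilityIndex(sep), s = sep@s)
    })
    res
  }
  raw <- analyse(dataset)
  msc <- analyse(corrected(mscCorrect(dataset)))
  out <- do.call(rbind, lapply(seq_along(raw), function(k) {
    idx <- msc[[k]]$index
    verdict <- if (!is.na(idx) && idx == 1) "promising"
               else if (!is.na(idx) && idx >= 0.5) "marginal"
               else "poor"
    data.frame(class_a = raw[[k]]$pair[1], class_b = raw[[k]]$pair[2],
               J_raw = raw[[k]]$J, index_raw = raw[[k]]$index,
               J_msc = msc[[k]]$J, index_msc = idx,
               verdict = verdict)
  }))
  out
}
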