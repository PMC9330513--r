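#' Random train/test partition scheme
#'
#' @param trainFraction fraction of samples used for training (default 0.66).
#' @param stratified draw the training fraction within each class instead of
#'   overall (default `FALSE`, matching a plain random draw).
#' @param seed integer seed.
#' @return Classed list of settings.
#' @export
partitionScheme <- function(trainFraction = 0.66, stratified = FALSE, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  structure(list(trainFraction = trainFraction, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "PartitionScheme")
}

#' Draw one random train/test split
#'
#' The training set holds `round(trainFraction * n)` indices drawn uniformly
#' without replacement (per class when `stratified`); deterministic per seed.
#'
#' @param n number of samples (`>= 2`).
#' @param scheme a [partitionScheme()].
#' @param labels class labels, required when `scheme$stratified`.
#' @return `list(train, test)` of integer index vectors.
#' @examples
#' sp <- randomPartition(270, partitionScheme(seed = 4))
#' lengths(sp)   # 178 / 92
#' @export
randomPartition <- function(n, scheme, labels = NULL) {
  stopifnot(n >= 2)
  set.seed(scheme$seed)
  if (scheme$stratified) {
    if (is.null(labels) || length(labels) != n)
      stop("stratified partition needs one label per sample")
    train <- unlist(lapply(unique(labels), function(g) {
      idx <- which(labels == g)
      sample(idx, round(scheme$trainFraction * length(idx)))
    }), use.names = FALSE)
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, round(scheme$trainFraction * n)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

.deriveSeeds <- function(masterSeed, k) {
  set.seed(masterSeed)
  matrix(sample.int(.Machine$integer.max - 1L, 2L * k), ncol = 2,
         dimnames = list(NULL, c("partition", "init")))
}

.fitOneModel <- function(X, labels, trainIdx, testIdx, config, pretreatment,
                         sampleIds, modelIndex, partitionTag) {
  if (pretreatment == "msc") {
    ref <- colMeans(X[trainIdx, , drop = FALSE])
    Xtr <- corrected(mscCorrect(X[trainIdx, , drop = FALSE], reference = ref))
    Xte <- corrected(mscCorrect(X[testIdx, , drop = FALSE], reference = ref))
    Xtr <- kappaMatrix(Xtr); Xte <- kappaMatrix(Xte)
  } else {
    Xtr <- X[trainIdx, , drop = FALSE]
    Xte <- X[testIdx, , drop = FALSE]
  }
  model <- annTrain(Xtr, as.numeric(labels[trainIdx]), config)
  predTr <- annPredict(model, Xtr)
  predTe <- annPredict(model, Xte)
  predictions <- integer(length(labels))
  predictions[trainIdx] <- predTr
  predictions[testIdx] <- predTe
  names(predictions) <- sampleIds
  accTr <- annAccuracy(model, Xtr, labels[trainIdx])
  accTe <- annAccuracy(model, Xte, labels[testIdx])
  list(modelIndex = modelIndex,
       trainIds = sampleIds[trainIdx], testIds = sampleIds[testIdx],
       predictions = predictions,
       trainAcc = accTr$perClass, testAcc = accTe$perClass,
       trainOverall = accTr$overall, testOverall = accTe$overall,
       pretreatment = pretreatment, partition = partitionTag,
       stopReason = model@stopReason)
}

#' Run parallel ANN models on random partitions
#'
#' Builds `nModels` networks of identical structure, each on a fresh random
#' 66/34 partition and a fresh random initialization (both derived
#' deterministically from `masterSeed`), optionally with MSC fitted on the
#' training split and applied to both splits.
#'
#' @param dataset a labelled [ThzSpectra-class].
#' @param nModels number of parallel models.
#' @param scheme a [partitionScheme()] (its `seed` is overridden per model).
#' @param config a [trainConfig()] (its `seed` is overridden per model).
#' @param pretreatment `"none"` or `"msc"`.
#' @param masterSeed integer controlling all per-model seeds.
#' @return List of run records (class `"thzRunRecords"`); see
#'   [recordsTable()] for the flat accuracy table.
#' @export
runParallelModels <- function(dataset, nModels, scheme = partitionScheme(),
                              config = trainConfig(),
                              pretreatment = c("none", "msc"),
                              masterSeed = 1L) {
  pretreatment <- match.arg(pretreatment)
  stopifnot(is(dataset, "ThzSpectra"), nModels >= 0)
  if (nModels == 0) return(structure(list(), class = "thzRunRecords"))
  X <- kappaMatrix(dataset)
  labels <- as.integer(classLabels(dataset))
  ids <- colnames(dataset)
  seeds <- .deriveSeeds(masterSeed, nModels)
  records <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    sch <- scheme; sch$seed <- seeds[m, "partition"]
    part <- randomPartition(nrow(X), sch, labels)
    cfg <- config; cfg$seed <- seeds[m, "init"]
    records[[m]] <- tryCatch(
      .fitOneModel(X, labels, part$train, part$test, cfg, pretreatment,
                   ids, m, "random"),
      error = function(e) list(modelIndex = m, failed = TRUE,
                               message = conditionMessage(e),
                               pretreatment = pretreatment,
                               partition = "random"))
  }
  structure(records, class = "thzRunRecords")
}

#' Per-sample prediction-stability statistics
#'
#' For every sample, counts how often it fell in a training set, how often it
#' was tested, and how often it was predicted correctly *when tested*; the
#' correct rate is `times_correct / times_tested` (`NA` when never tested).
#' Rows are sorted ascending by correct rate (never-tested samples last), the
#' convention used for stability plots.
#'
#' @param records output of [runParallelModels()].
#' @param labels named integer labels (taken from the records' prediction
#'   names if a `dataset` is given instead).
#' @param dataset optional [ThzSpectra-class] supplying the labels.
#' @return `data.frame(sample_id, label, times_trained, times_tested,
#'   times_correct, correct_rate)`.
#' @export
perSampleStability <- function(records, dataset = NULL, labels = NULL) {
  records <- Filter(function(r) is.null(r$failed), records)
  if (!length(records)) stop("no successful run records")
  if (!is.null(dataset)) labels <- classLabels(dataset)
  ids <- names(records[[1]]$predictions)
  trained <- tested <- correct <- stats::setNames(integer(length(ids)), ids)
  for (r in records) {
    trained[r$trainIds] <- trained[r$trainIds] + 1L
    tested[r$testIds] <- tested[r$testIds] + 1L
    lab <- labels[r$testIds]
    ok <- r$predictions[r$testIds] == lab
    correct[r$testIds] <- correct[r$testIds] + as.integer(ok)
  }
  rate <- ifelse(tested > 0, correct / tested, NA_real_)
  out <- data.frame(sample_id = ids,
                    label = as.integer(labels[ids]),
                    times_trained = as.integer(trained),
                    times_tested = as.integer(tested),
                    times_correct = as.integer(correct),
                    correct_rate = rate,
                    row.names = NULL)
  out[order(out$correct_rate, na.last = TRUE), , drop = FALSE]
}

#' Split samples into stable (part A) and unstable (part B) sets
#'
#' Part A holds the samples predicted correctly every time they were tested
#' (defined correct rate exactly 1); part B holds all others, including
#' samples never tested, whose stability is unproven.
#'
#' @param stability output of [perSampleStability()].
#' @return `list(partA, partB)` of sample id vectors.
#' @export
splitParts <- function(stability) {
  defined <- !is.na(stability$correct_rate)
  inA <- defined & stability$correct_rate == 1
  list(partA = stability$sample_id[inA],
       partB = stability$sample_id[!inA])
}

#' Special-partition experiment: train on part A, test on part B
#'
#' Every model uses the same fixed partition (all of part A for training, all
#' of part B for testing); only the random initialization differs between
#' models.
#'
#' @param dataset a labelled [ThzSpectra-class].
#' @param partA,partB sample id vectors from [splitParts()]; both non-empty.
#' @param nModels number of models.
#' @param config a [trainConfig()] (seed overridden per model).
#' @param masterSeed integer controlling the per-model init seeds.
#' @return List of run records (class `"thzRunRecords"`).
#' @export
specialPartitionExperiment <- function(dataset, partA, partB, nModels,
                                       config = trainConfig(), masterSeed = 1L) {
  stopifnot(is(dataset, "ThzSpectra"))
  if (!length(partA) || !length(partB))
    stop("both part A and part B must be non-empty")
  X <- kappaMatrix(dataset)
  labels <- as.integer(classLabels(dataset))
  ids <- colnames(dataset)
  trainIdx <- match(partA, ids)
  testIdx <- match(partB, ids)
  if (anyNA(trainIdx) || anyNA(testIdx)) stop("unknown sample ids in parts")
  seeds <- .deriveSeeds(masterSeed, max(nModels, 1L))
  records <- vector("list", nModels)
  for (m in seq_len(nModels)) {
    cfg <- config; cfg$seed <- seeds[m, "init"]
    records[[m]] <- tryCatch(
      .fitOneModel(X, labels, trainIdx, testIdx, cfg, "none", ids, m, "special"),
      error = function(e) list(modelIndex = m, failed = TRUE,
                               message = conditionMessage(e),
                               pretreatment = "none", partition = "special"))
  }
  structure(records, class = "thzRunRecords")
}

#' Flatten run records into an accuracy table
#'
#' One row per model with per-class training and test accuracies, the
#' partition tag and the pretreatment tag — the layout of the study's
#' 60-model summary table.
#'
#' @param records a `thzRunRecords` list (or a concatenation of several).
#' @param arm optional arm label recycled over rows.
#' @return `data.frame` with columns `model`, `arm`, `partition`,
#'   `pretreatment`, `train_acc_class1..3`, `test_acc_class1..3`.
#' @export
recordsTable <- function(records, arm = NA_character_) {
  rows <- lapply(records, function(r) {
    if (!is.null(r$failed))
      return(data.frame(model = r$modelIndex, arm = arm,
                        partition = r$partition, pretreatment = r$pretreatment,
                        train_acc_class1 = NA_real_, train_acc_class2 = NA_real_,
                        train_acc_class3 = NA_real_, test_acc_class1 = NA_real_,
                        test_acc_class2 = NA_real_, test_acc_class3 = NA_real_))
    data.frame(model = r$modelIndex, arm = arm,
               partition = r$partition, pretreatment = r$pretreatment,
               train_acc_class1 = r$trainAcc[["class1"]],
               train_acc_class2 = r$trainAcc[["class2"]],
               train_acc_class3 = r$trainAcc[["class3"]],
               test_acc_class1 = r$testAcc[["class1"]],
               test_acc_class2 = r$testAcc[["class2"]],
               test_acc_class3 = r$testAcc[["class3"]])
  })
  do.call(rbind, rows)
}

#' Mean per-class test accuracy per experiment arm
#'
#' Arithmetic mean over models of the per-class test-set accuracies, one row
#' per arm.
#'
#' @param ... named `thzRunRecords` lists, one per arm (e.g.
#'   `random = ..., special = ...`).
#' @return `data.frame(arm, class1, class2, class3)`; classes absent from a
#'   model's test set are skipped in that model's contribution.
#' @export
summarizeMeanAccuracy <- function(...) {
  arms <- list(...)
  if (is.null(names(arms)) || any(names(arms) == ""))
    stop("arms must be named")
  rows <- lapply(names(arms), function(nm) {
    recs <- Filter(function(r) is.null(r$failed), arms[[nm]])
    if (!length(recs)) stop("arm '", nm, "' has no successful records")
    acc <- do.call(rbind, lapply(recs, function(r) r$testAcc))
    data.frame(arm = nm,
               class1 = mean(acc[, "class1"], na.rm = TRUE),
               class2 = mean(acc[, "class2"], na.rm = TRUE),
               class3 = mean(acc[, "class3"], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
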