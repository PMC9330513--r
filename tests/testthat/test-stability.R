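test_that("random partitions have the documented sizes and are seeded", {
  sp <- randomPartition(270, partitionScheme(seed = 1))
  expect_length(sp$train, 178)   # round(0.66 * 270)
  expect_length(sp$test, 92)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:270)

  expect_length(randomPartition(3, partitionScheme(seed = 2))$train, 2)

  sp2 <- randomPartition(270, partitionScheme(seed = 1))
  expect_identical(sp, sp2)

  lab <- rep(1:3, each = 30)
  st <- randomPartition(90, partitionScheme(stratified = TRUE, seed = 5), lab)
  expect_equal(unname(table(lab[st$train])), array(rep(20L, 3)),
               ignore_attr = TRUE)
})

# a small shared protocol run: weak models (few epochs) on a small dataset so
# predictions are genuinely unstable
protoRun <- local({
  done <- NULL
  function() {
    if (!is.null(done)) return(done)
    ds <- tinyDataset(nPerClass = 10, seed = 6)
    cfg <- trainConfig(maxEpochs = 150, seed = 1)
    recs <- runParallelModels(ds, 6, partitionScheme(), cfg,
                              "none", masterSeed = 77)
    done <<- list(ds = ds, cfg = cfg, recs = recs)
    done
  }
})

test_that("parallel models produce complete, reproducible records", {
  pr <- protoRun()
  expect_length(pr$recs, 6)
  tab <- recordsTable(pr$recs, arm = "raw")
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 10)  # model, arm, partition, pretreatment, 6 accuracies
  accs <- as.matrix(tab[, 5:10])
  expect_true(all(accs >= 0 & accs <= 1, na.rm = TRUE))

  recs2 <- runParallelModels(pr$ds, 6, partitionScheme(), pr$cfg,
                             "none", masterSeed = 77)
  expect_identical(recordsTable(recs2), recordsTable(pr$recs))

  expect_length(runParallelModels(pr$ds, 0, masterSeed = 1), 0)
})

test_that("per-sample stability counts conserve and sort ascending", {
  pr <- protoRun()
  st <- perSampleStability(pr$recs, dataset = pr$ds)
  expect_equal(nrow(st), 30)
  expect_true(all(st$times_trained + st$times_tested == 6))
  defined <- !is.na(st$correct_rate)
  expect_true(all(st$correct_rate[defined] >= 0 & st$correct_rate[defined] <= 1))
  expect_false(is.unsorted(st$correct_rate, na.rm = TRUE))
  expect_true(all(st$correct_rate[defined] ==
                    st$times_correct[defined] / st$times_tested[defined]))
})

test_that("hand-counted stability on two toy records", {
  ids <- c("a", "b", "c")
  mkrec <- function(trainIds, testIds, preds) {
    list(modelIndex = 1, trainIds = trainIds, testIds = testIds,
         predictions = stats::setNames(preds, ids),
         trainAcc = c(class1 = 1, class2 = 1, class3 = NA),
         testAcc = c(class1 = 1, class2 = 1, class3 = NA),
         pretreatment = "none", partition = "random")
  }
  labels <- stats::setNames(c(1L, 2L, 1L), ids)
  recs <- structure(list(
    mkrec(c("b"), c("a", "c"), c(1L, 2L, 2L)),   # a right, c wrong
    mkrec(c("b", "c"), c("a"), c(2L, 2L, 1L))    # a wrong
  ), class = "thzRunRecords")
  st <- perSampleStability(recs, labels = labels)
  expect_equal(st$correct_rate[st$sample_id == "a"], 0.5)
  expect_equal(st$correct_rate[st$sample_id == "c"], 0)
  expect_true(is.na(st$correct_rate[st$sample_id == "b"]))
  expect_equal(st$times_trained[st$sample_id == "b"], 2L)

  parts <- splitParts(st)
  expect_false("a" %in% parts$partA)
  expect_true("b" %in% parts$partB)   # never tested -> unproven -> part B
  expect_false("c" %in% parts$partA)
})

test_that("part split sends exactly the always-correct samples to part A", {
  pr <- protoRun()
  st <- perSampleStability(pr$recs, dataset = pr$ds)
  parts <- splitParts(st)
  expect_setequal(c(parts$partA, parts$partB), colnames(pr$ds))
  expect_length(intersect(parts$partA, parts$partB), 0)
  inA <- st$sample_id %in% parts$partA
  expect_true(all(st$correct_rate[inA] == 1))
  expect_true(all(is.na(st$correct_rate[!inA]) | st$correct_rate[!inA] < 1))
})

test_that("special partition fixes the split and only varies initialization", {
  pr <- protoRun()
  st <- perSampleStability(pr$recs, dataset = pr$ds)
  parts <- splitParts(st)
  expect_gt(length(parts$partA), 0)
  expect_gt(length(parts$partB), 0)
  sp <- specialPartitionExperiment(pr$ds, parts$partA, parts$partB, 3,
                                   pr$cfg, masterSeed = 5)
  expect_length(sp, 3)
  for (r in sp) {
    expect_setequal(r$trainIds, parts$partA)
    expect_setequal(r$testIds, parts$partB)
    expect_equal(r$partition, "special")
  }
  sp2 <- specialPartitionExperiment(pr$ds, parts$partA, parts$partB, 3,
                                    pr$cfg, masterSeed = 5)
  expect_identical(recordsTable(sp), recordsTable(sp2))

  expect_error(specialPartitionExperiment(pr$ds, character(0),
                                          parts$partB, 2), "non-empty")
})

test_that("mean accuracy summarizes arms arithmetically", {
  mk <- function(a1, a2, a3) list(
    modelIndex = 1, trainIds = "x", testIds = "y",
    predictions = c(x = 1L, y = 1L),
    trainAcc = c(class1 = 1, class2 = 1, class3 = 1),
    testAcc = c(class1 = a1, class2 = a2, class3 = a3),
    pretreatment = "none", partition = "random")
  armA <- structure(list(mk(0.8, 1, 0.5), mk(0.6, 1, 0.7)),
                    class = "thzRunRecords")
  armB <- structure(list(mk(0.4, 0.9, 0.2)), class = "thzRunRecords")
  out <- summarizeMeanAccuracy(random = armA, special = armB)
  expect_equal(out$class1, c(0.7, 0.4))
  expect_equal(out$class3, c(0.6, 0.2))
  expect_error(summarizeMeanAccuracy(armA), "named")
})

test_that("random partitions outperform the special partition on the hardest class", {
  # full protocol in miniature on raw (uncorrected) curves: part B collects
  # the unstably-predicted samples, so testing exclusively on part B is the
  # harder task
  ds <- tinyDataset(nPerClass = 15, seed = 12)
  cfg <- trainConfig(maxEpochs = 1600, seed = 1)
  stab <- runParallelModels(ds, 8, partitionScheme(), cfg, "none",
                            masterSeed = 31)
  st <- perSampleStability(stab, dataset = ds)
  parts <- splitParts(st)
  expect_gt(length(parts$partA), 0)
  expect_gt(length(parts$partB), 0)
  spec <- specialPartitionExperiment(ds, parts$partA, parts$partB, 4, cfg,
                                     masterSeed = 32)
  mean_ <- summarizeMeanAccuracy(random = stab, special = spec)
  hardest <- which.min(as.numeric(mean_[2, c("class1", "class2", "class3")]))
  expect_gt(mean_[1, hardest + 1], mean_[2, hardest + 1])
})
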