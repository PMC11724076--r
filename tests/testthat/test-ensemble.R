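test_that("soft-voting arithmetic matches its oracles", {
  expect_equal(averageProbabilities(rbind(c(0.2, 0.8), c(0.6, 0.4))),
               c(0.4, 0.6))
  expect_equal(averageProbabilities(rbind(c(0.3, 0.7))), c(0.3, 0.7))  # m = 1
  u <- matrix(1 / 3, 4, 3)
  expect_equal(averageProbabilities(u), rep(1 / 3, 3))    # uniform fixed point
  expect_error(averageProbabilities(list(c(0.5, 0.5), c(0.2, 0.3, 0.5))),
               "ragged")
  expect_error(averageProbabilities(rbind(c(0.9, 0.9))), "sum to 1")

  expect_equal(classifyProbabilities(c(0.4, 0.6)), 2L)
  expect_equal(classifyProbabilities(c(0.5, 0.5)), 1L)    # lowest-index tie
  expect_error(classifyProbabilities(numeric()), "empty")

  set.seed(21)
  for (i in 1:50) {
    rho <- runif(sample(2:6, 1)); rho <- rho / sum(rho)
    scan <- 1L                                   # linear-scan oracle
    for (k in seq_along(rho)) if (rho[k] > rho[scan]) scan <- k
    expect_identical(classifyProbabilities(rho), scan)
  }

  # averaging oracle on random stacks of rows
  for (i in 1:20) {
    m <- sample(1:5, 1); c_ <- sample(2:4, 1)
    rows <- t(vapply(seq_len(m), function(...) {
      r <- runif(c_); r / sum(r)
    }, numeric(c_)))
    expect_equal(averageProbabilities(rows), colSums(rows) / m)
  }
})

test_that("test samples are transformed with frozen maps, never re-fitted", {
  ds <- blobsFixture(60, d = 8, seed = 2)
  pr <- preparedSplit(ds, seed = 2)
  specs <- list(representationSpec("tsne", seed = 1L),
                representationSpec("pca", filter = "blur", seed = 2L),
                representationSpec("umap", seed = 3L))
  maps <- lapply(specs, function(s) computePixelMap(pr$train, s, 9, 9))
  st <- buildStacks(pr$train, maps)
  model <- trainModel(st, pr$trainLabels, trainConfig(epochs = 2, lr = 0.01),
                      buildStacks(pr$validation, maps), pr$valLabels,
                      normalizer = pr$normalizer)

  x <- featureValues(pr$train)[, 7]
  imgs <- transformTestSample(x, model)
  expect_length(imgs, 3L)                       # count equals m
  for (r in 1:3)
    expect_identical(imgs[[r]], stackImages(st[[r]])[, , 7])

  expect_error(transformTestSample(rep(0.5, 5), model), "trained on 8")

  # m = 1 limit: single image, the original single-representation path
  model1 <- trainModel(st[1], pr$trainLabels,
                       trainConfig(epochs = 2, lr = 0.01),
                       buildStacks(pr$validation, maps[1]), pr$valLabels,
                       normalizer = pr$normalizer)
  expect_length(transformTestSample(x, model1), 1L)
})

test_that("a degenerate ensemble reduces exactly to the single-representation rule", {
  ds <- blobsFixture(60, d = 8, seed = 4)
  pr <- preparedSplit(ds, seed = 4)
  map <- computePixelMap(pr$train, representationSpec("tsne", seed = 1L), 9, 9)
  maps3 <- list(map, map, map)                  # identical representations
  st <- buildStacks(pr$train, maps3)
  model <- trainModel(st, pr$trainLabels, trainConfig(epochs = 3, lr = 0.01),
                      buildStacks(pr$validation, maps3), pr$valLabels,
                      normalizer = pr$normalizer)
  preds <- predictBatch(pr$test, model)
  perRep <- preds@perRep
  for (r in 2:3) expect_equal(perRep[, , r], perRep[, , 1])
  expect_equal(averagedProbabilities(preds), perRep[, , 1])
  single <- apply(perRep[, , 1], 1, which.max)
  expect_equal(unname(predictedLabels(preds)), unname(single))
})

test_that("prediction order-invariance and accuracy bookkeeping hold", {
  ds <- blobsFixture(80, d = 8, seed = 6)
  pr <- preparedSplit(ds, seed = 6)
  specs <- list(representationSpec("pca"),
                representationSpec("tsne", seed = 2L))
  maps <- lapply(specs, function(s) computePixelMap(pr$train, s, 9, 9))
  mk <- function(mps) trainModel(buildStacks(pr$train, mps), pr$trainLabels,
                                 trainConfig(epochs = 12, lr = 0.01,
                                             seed = 3L),
                                 buildStacks(pr$validation, mps),
                                 pr$valLabels, normalizer = pr$normalizer)
  mA <- mk(maps)
  pA <- predictBatch(pr$test, mA)
  # permuting representation order after training leaves soft voting alone
  mB <- mA
  mB@maps <- rev(mA@maps)
  pB <- predictBatch(pr$test, mB)
  expect_equal(averagedProbabilities(pB), averagedProbabilities(pA))
  expect_identical(predictedLabels(pB), predictedLabels(pA))

  # accuracy equals the confusion-matrix trace ratio
  cm <- table(factor(predictedLabels(pA), levels = 1:2),
              factor(pA@truth, levels = 1:2))
  expect_equal(accuracy(pA), 100 * sum(diag(cm)) / sum(cm))
  expect_equal(accuracy(pA), 100)               # separable fixture

  expect_error(predictBatch(subsetSamples(ds, integer()), mA), "empty")
})

test_that("the ensemble is no worse than its weakest member on ringnorm", {
  diffs <- vapply(1:5, function(seed) {
    ds <- ringnormFixture(500, seed = seed)
    pr <- preparedSplit(ds, seed = seed)
    maps <- lapply(ringnormRepresentations(seed),
                   function(s) computePixelMap(pr$train, s, 12, 12))
    model <- trainModel(buildStacks(pr$train, maps), pr$trainLabels,
                        trainConfig(epochs = 8, lr = 0.01, seed = seed),
                        buildStacks(pr$validation, maps), pr$valLabels,
                        normalizer = pr$normalizer)
    preds <- predictBatch(pr$test, model)
    single <- vapply(1:3, function(r)
      100 * mean(apply(preds@perRep[, , r], 1, which.max) == preds@truth),
      numeric(1))
    accuracy(preds) - min(single)
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
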