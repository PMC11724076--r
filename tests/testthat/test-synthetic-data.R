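test_that("ringnorm draws match the stated class distributions", {
  n <- 100000L
  d <- 20L
  ds <- generateRingnorm(generatorConfig("ringnorm", nSamples = n,
                                         nFeatures = d, seed = 11L))
  v <- featureValues(ds)
  lab <- sampleLabels(ds)
  n1 <- sum(lab == 1L); n2 <- sum(lab == 2L)
  expect_equal(n1, n2)

  m1 <- rowMeans(v[, lab == 1L])
  m2 <- rowMeans(v[, lab == 2L])
  var1 <- apply(v[, lab == 1L], 1, var)
  # class 1: mean 0, covariance 4 I  (sd 2); 3-SE bands per coordinate
  expect_true(all(abs(m1) < 3 * 2 / sqrt(n1)))
  seVar <- sqrt(2 / (n1 - 1)) * 4        # SE of a normal sample variance
  expect_true(all(abs(var1 - 4) < 3 * seVar))
  # class 2: every coordinate has mean 2/sqrt(d) = 0.4472, unit variance
  expect_true(all(abs(m2 - 2 / sqrt(d)) < 3 / sqrt(n2)))
  expect_true(all(abs(apply(v[, lab == 2L], 1, var) - 1) <
                    3 * sqrt(2 / (n2 - 1))))
})

test_that("generators are deterministic and handle edge configs", {
  cfg <- generatorConfig("ringnorm", nSamples = 50, seed = 5L)
  expect_identical(featureValues(generateRingnorm(cfg)),
                   featureValues(generateRingnorm(cfg)))

  empty <- generateRingnorm(generatorConfig("ringnorm", nSamples = 0,
                                            seed = 1L))
  expect_equal(dim(featureValues(empty)), c(20L, 0L))

  expect_error(generatorConfig("ringnorm", nSamples = -5), "non-negative")
  expect_error(generatorConfig("ringnorm", nSamples = 10,
                               classFractions = c(0.6, 0.6)), "sum to 1")

  # rounding rule: class 1 takes the ceiling of its share
  ds7 <- generateRingnorm(generatorConfig("ringnorm", nSamples = 7, seed = 2L))
  expect_equal(unname(table(sampleLabels(ds7))[c("1", "2")]), c(4L, 3L),
               ignore_attr = TRUE)

  b <- generateBlobs(generatorConfig("gaussian_blobs", nSamples = 30,
                                     nFeatures = 4, seed = 9L))
  b2 <- generateBlobs(generatorConfig("gaussian_blobs", nSamples = 30,
                                      nFeatures = 4, seed = 9L))
  expect_identical(featureValues(b), featureValues(b2))
})

test_that("madelon-style structure is recoverable from metadata", {
  cfg <- generatorConfig("madelon_style", nSamples = 2000, nFeatures = 12,
                         seed = 21L,
                         params = list(nInformative = 2L, nRedundant = 4L,
                                       nClustersPerClass = 2L,
                                       flipFraction = 0))
  ds <- generateMadelonStyle(cfg)
  md <- S4Vectors::metadata(ds)$generator
  v <- featureValues(ds)
  unperm <- v[order(md$featurePermutation), , drop = FALSE]
  inf <- unperm[1:2, , drop = FALSE]
  red <- unperm[3:6, , drop = FALSE]
  # redundant features are exact linear combinations of informative ones
  expect_lt(max(abs(red - t(md$redundantWeights) %*% inf)), 1e-10)

  # 4 cluster centers on hypercube vertices recoverable by k-means
  km <- kmeans(t(inf), centers = 4, nstart = 20)
  matched <- apply(t(md$centers), 1, function(ctr)
    min(sqrt(colSums((t(km$centers) - ctr)^2))))
  expect_true(all(matched < 0.5))

  expect_error(
    generateMadelonStyle(generatorConfig("madelon_style", nSamples = 10,
                                         nFeatures = 5, seed = 1L,
                                         params = list(nInformative = 4L,
                                                       nRedundant = 4L))),
    "must equal nFeatures")
})

test_that("signal-free generators give chance-level held-out accuracy", {
  # irrelevant-only madelon and zero-separation blobs carry no signal
  nTr <- 400L; nTe <- 400L
  chanceBand <- function(acc, nTest) {
    ci <- 2.576 * sqrt(0.25 / nTest)
    abs(acc - 0.5) < ci + 0.05
  }
  for (mk in list(
    function(n, seed) generateMadelonStyle(
      generatorConfig("madelon_style", nSamples = n, nFeatures = 10,
                      seed = seed,
                      params = list(nInformative = 0L, nRedundant = 0L))),
    function(n, seed) generateBlobs(
      generatorConfig("gaussian_blobs", nSamples = n, nFeatures = 10,
                      seed = seed, params = list(separation = 0))))) {
    tr <- mk(nTr, 31L); te <- mk(nTe, 32L)
    pred <- class::knn(t(featureValues(tr)), t(featureValues(te)),
                       factor(sampleLabels(tr)), k = 9)
    expect_true(chanceBand(mean(as.integer(pred) == sampleLabels(te)), nTe))
  }

  # and well-separated blobs are perfectly classifiable
  tr <- blobsFixture(200, seed = 41); te <- blobsFixture(200, seed = 42)
  pred <- class::knn(t(featureValues(tr)), t(featureValues(te)),
                     factor(sampleLabels(tr)), k = 3)
  expect_equal(mean(as.integer(pred) == sampleLabels(te)), 1)
})
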