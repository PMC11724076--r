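test_that("rendering paints values at pixel locations with collision rules", {
  map <- toyPixelMap(rbind(c(0, 0), c(1, 2), c(1, 2), c(2, 1), c(0, 3)),
                     p = 3, q = 4)
  x <- c(0.5, 0.2, 0.6, 1, 0.1)
  imgMean <- renderSample(x, map, "mean")
  imgMax <- renderSample(x, map, "max")
  # hand-written expectation (1-based rows a+1, cols b+1)
  want <- matrix(0, 3, 4)
  want[1, 1] <- 0.5; want[2, 3] <- 0.4; want[3, 2] <- 1; want[1, 4] <- 0.1
  expect_equal(imgMean, want)
  want[2, 3] <- 0.6
  expect_equal(imgMax, want)

  expect_equal(renderSample(rep(0, 5), map), matrix(0, 3, 4))
  expect_error(renderSample(rep(0.5, 4), map), "expects 5")
  expect_error(renderSample(c(0.5, 2, 0, 0, 0), map), "normalized")
})

test_that("collision aggregation matches a grouping oracle and is monotone", {
  set.seed(7)
  map <- toyPixelMap(cbind(sample(0:5, 30, TRUE), sample(0:5, 30, TRUE)),
                     p = 6, q = 6)
  x <- runif(30)
  img <- renderSample(x, map, "mean")
  key <- pixelCoords(map)[, 1] * 6 + pixelCoords(map)[, 2]
  oracle <- tapply(x, key, mean)                    # independent grouping
  expect_equal(sum(img), sum(oracle), tolerance = 1e-12)
  for (k in names(oracle)) {
    ki <- as.integer(k)
    expect_equal(img[ki %/% 6 + 1, ki %% 6 + 1], unname(oracle[k]))
  }

  # permuting features together with their map rows changes nothing
  perm <- sample(30)
  mapP <- toyPixelMap(pixelCoords(map)[perm, ], 6, 6)
  expect_equal(renderSample(x[perm], mapP, "mean"), img)

  # raising one feature's value never lowers its pixel
  for (rule in c("mean", "max")) {
    x2 <- x; x2[4] <- min(1, x[4] + 0.3)
    a <- pixelCoords(map)[4, 1] + 1; b <- pixelCoords(map)[4, 2] + 1
    expect_gte(renderSample(x2, map, rule)[a, b],
               renderSample(x, map, rule)[a, b])
  }
})

test_that("Gaussian blur conserves mass, has an identity limit and a semigroup", {
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  raw <- applyBlur(imp, 1.2, renormalize = FALSE)
  expect_equal(sum(raw), 1, tolerance = 1e-6)       # impulse mass conserved
  expect_equal(raw[8, 8], max(raw))

  expect_lt(max(abs(applyBlur(imp, 0.1, renormalize = FALSE) - imp)), 1e-6)

  # semigroup of the sampled kernel (sigmas >= 1, where sampling aliasing
  # of the continuous Gaussian is negligible)
  set.seed(3)
  img <- applyBlur(matrix(runif(225), 15, 15), 1, renormalize = FALSE)
  two <- applyBlur(applyBlur(img, 1.5, renormalize = FALSE), 1,
                   renormalize = FALSE)
  one <- applyBlur(img, sqrt(1.5^2 + 1^2), renormalize = FALSE)
  expect_lt(max(abs(two - one)), 1e-4)

  # renormalized output keeps the input maximum
  norm <- applyBlur(imp, 1.2)
  expect_equal(max(norm), 1)
  expect_error(applyBlur(imp, 0), "positive")
})

test_that("Gabor bank responds to matching orientations and stays in [0,1]", {
  expect_equal(applyGabor(matrix(0, 12, 12)), matrix(0, 12, 12))

  # horizontal grating at a bank frequency (0.25 cycles/px, period 4 rows)
  g <- expand.grid(r = 1:24, c = 1:24)
  grating <- matrix(0.5 + 0.5 * sin(2 * pi * 0.25 * g$r), 24, 24)
  bank <- gaborBank(orientations = 4, frequencies = 0.25)
  # oracle: direct quadrature convolution per filter
  resp <- vapply(bank, function(f)
    mean(mrep:::gaborEnergy(grating, f)[9:16, 9:16]), numeric(1))
  thetas <- vapply(bank, `[[`, numeric(1), "theta")
  vertIdx <- which.min(abs(thetas - pi / 2))   # varies along rows
  horIdx <- which.min(abs(thetas))
  expect_gt(resp[vertIdx], resp[horIdx])

  set.seed(11)
  out <- applyGabor(matrix(runif(144), 12, 12))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(applyGabor(matrix(0, 5, 5), list()), "empty")
  expect_error(gaborBank(frequencies = numeric()), "empty")
})

test_that("stacks pool n x m images sharing one grid", {
  ds <- blobsFixture(10, d = 6, seed = 5)
  nm <- fitNorm2(ds)
  dsN <- applyNorm2(nm, ds)
  maps <- list(computePixelMap(dsN, representationSpec("pca"), 8, 8),
               computePixelMap(dsN, representationSpec("tsne", seed = 1L,
                                                       filter = "blur"),
                               8, 8),
               computePixelMap(dsN, representationSpec("umap", seed = 1L,
                                                       filter = "gabor"),
                               8, 8))
  stacks <- buildStacks(dsN, maps)
  expect_length(stacks, 3L)
  total <- sum(vapply(stacks, function(s) dim(stackImages(s))[3], integer(1)))
  expect_equal(total, 30L)                          # n * m images
  for (s in stacks) {
    im <- stackImages(s)
    expect_true(all(im >= 0 & im <= 1))
  }

  one <- buildStacks(dsN, maps[1])
  expect_length(one, 1L)
  expect_equal(dim(stackImages(one[[1]])), c(8L, 8L, 10L))

  mapBig <- computePixelMap(dsN, representationSpec("pca"), 9, 8)
  expect_error(buildStacks(dsN, list(maps[[1]], mapBig)),
               "share one grid size")
})
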