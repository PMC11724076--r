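test_that("PCA embedding matches a dense eigensolver oracle up to sign", {
  ds <- ringnormFixture(80, seed = 4)
  emb <- embedFeatures(ds, representationSpec("pca"))
  P <- featureValues(ds)                     # feature points, d x n
  C <- cov(P)                                # oracle: full eigendecomposition
  eg <- eigen(C, symmetric = TRUE)
  centered <- sweep(P, 2, colMeans(P))
  oracle <- centered %*% eg$vectors[, 1:2]
  for (k in 1:2) {
    s <- sign(sum(emb[, k] * oracle[, k]))
    expect_lt(max(abs(emb[, k] - s * oracle[, k])), 1e-8)
  }
})

test_that("embedding degenerate cases behave as documented", {
  # features on a line: second PCA coordinate carries no variance
  t_ <- seq(0, 1, length.out = 8)
  line <- tabularDataset(outer(t_, c(2, -1, 0.5)), rep(1L, 3),
                         classLevels = "1")
  emb <- embedFeatures(line, representationSpec("pca"))
  expect_lt(var(emb[, 2]), 1e-10 * var(emb[, 1]))

  # duplicated feature rows embed to identical points
  v <- matrix(rnorm(5 * 20), 5, 20)
  v <- rbind(v, v[2, ])
  dup <- tabularDataset(v, rep(1L, 20), classLevels = "1")
  embd <- embedFeatures(dup, representationSpec("pca"))
  expect_equal(embd[2, ], embd[6, ], ignore_attr = TRUE)

  # fewer than 3 features: neighbour embeddings fall back to PCA
  two <- tabularDataset(matrix(rnorm(2 * 15), 2, 15), rep(1L, 15),
                        classLevels = "1")
  expect_warning(e2 <- embedFeatures(two, representationSpec("tsne")),
                 "falling back to PCA")
  expect_equal(dim(e2), c(2L, 2L))
})

test_that("all t-SNE metrics and other techniques produce finite maps", {
  ds <- ringnormFixture(60, seed = 6)
  specs <- c(lapply(c("euclidean", "cosine", "hamming", "chebychev",
                      "mahalanobis"),
                    function(m) representationSpec("tsne", metric = m,
                                                   seed = 3L)),
             list(representationSpec("umap", seed = 3L),
                  representationSpec("kpca", seed = 3L)))
  for (spec in specs) {
    emb <- suppressWarnings(embedFeatures(ds, spec))
    expect_true(all(is.finite(emb)), info = spec@technique)
    expect_equal(nrow(emb), 20L)
  }
  expect_error(representationSpec("umap", metric = "cosine"),
               "only be set when technique")
})

test_that("minimum-area rectangle matches a fine rotation-sweep oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- minAreaRectangle(sq)
  expect_equal(r$area, 1, tolerance = 1e-12)
  expect_equal(r$rotationDeg %% 90, 0)

  set.seed(99)
  for (i in 1:100) {
    pts <- matrix(rnorm(2 * sample(3:40, 1)), ncol = 2)
    got <- minAreaRectangle(pts)$area
    expect_lte(got, sweepRectArea(pts) + 1e-9)
    # never larger than the axis-aligned bounding box
    expect_lte(got, diff(range(pts[, 1])) * diff(range(pts[, 2])) + 1e-12)
  }

  # rotation invariance of the reported area
  pts <- matrix(rnorm(40), ncol = 2)
  a0 <- minAreaRectangle(pts)$area
  for (ang in c(13.3, 45, 77.7)) {
    th <- ang * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(minAreaRectangle(pts %*% t(R))$area, a0,
                 tolerance = 1e-6)
  }

  # collinear points: zero-height rectangle, one occupied row
  lin <- cbind(1:5, 2 * (1:5))
  rl <- minAreaRectangle(lin)
  expect_equal(rl$area, 0)
  cl <- discretizePoints(lin, rl$rotationDeg, 10, 10)
  expect_equal(length(unique(cl[, 1])), 1L)
})

test_that("discretization anchors corners and matches a histogram oracle", {
  co <- discretizePoints(rbind(c(0, 0), c(1, 1)), 0, 10, 10)
  expect_equal(unname(co), rbind(c(0L, 0L), c(9L, 9L)))

  expect_equal(unname(discretizePoints(rbind(c(3, 4)), 0, 7, 5)),
               rbind(c(0L, 0L)))                      # single point

  set.seed(12)
  pts <- matrix(runif(2000), ncol = 2)
  co <- discretizePoints(pts, 0, 50, 50)
  expect_true(all(co[, 1] >= 0 & co[, 1] < 50 & co[, 2] >= 0 & co[, 2] < 50))
  # occupied-cell count equals an independent 2-D histogram
  s <- max(diff(range(pts[, 1])) / 50, diff(range(pts[, 2])) / 50)
  ax <- pmin(floor((pts[, 2] - min(pts[, 2])) / s), 49)
  bx <- pmin(floor((pts[, 1] - min(pts[, 1])) / s), 49)
  expect_equal(nrow(unique(co)), nrow(unique(cbind(ax, bx))))
})

test_that("pixel maps respect bounds, determinism and injected embeddings", {
  ds <- ringnormFixture(50, seed = 9)
  for (spec in list(representationSpec("pca"),
                    representationSpec("tsne", seed = 2L),
                    representationSpec("umap", seed = 2L))) {
    map <- computePixelMap(ds, spec, 16, 16)
    co <- pixelCoords(map)
    expect_true(all(co[, 1] >= 0 & co[, 1] < 16 &
                    co[, 2] >= 0 & co[, 2] < 16))
    map2 <- computePixelMap(ds, spec, 16, 16)
    expect_identical(pixelCoords(map), pixelCoords(map2))
  }

  # hand-planted embedding: grid cells computable by hand
  hand <- rbind(c(0, 0), c(4, 0), c(4, 2), c(2, 1))
  ds4 <- tabularDataset(matrix(rnorm(4 * 6), 4, 6), rep(1L, 6),
                        classLevels = "1")
  map <- computePixelMap(ds4, representationSpec("pca"), p = 2, q = 4,
                         embedding = hand)
  # extent 4 x 2, scale max(4/4, 2/2) = 1; half-open cells, far edge closes
  expect_equal(unname(pixelCoords(map)),
               rbind(c(0L, 0L), c(0L, 3L), c(1L, 3L), c(1L, 2L)))
})

test_that("pixel distances form the diagnostic metric the ensemble relies on", {
  map <- toyPixelMap(rbind(c(0, 0), c(3, 4), c(3, 4)), 10, 10)
  expect_equal(pixelDistance(map, 1, 1), 0)
  expect_equal(pixelDistance(map, 1, 2), 5)            # 3-4-5 triangle
  expect_equal(pixelDistance(map, 2, 1), pixelDistance(map, 1, 2))
  expect_error(pixelDistance(map, 1, 7), "out of range")

  # representation diversity: two distinct manifolds place at least one
  # feature pair at differing distances
  ds <- ringnormFixture(60, seed = 13)
  m1 <- computePixelMap(ds, representationSpec("pca"), 16, 16)
  m2 <- computePixelMap(ds, representationSpec("tsne", seed = 4L), 16, 16)
  pairs <- combn(20, 2)
  d1 <- apply(pairs, 2, function(ij) pixelDistance(m1, ij[1], ij[2]))
  d2 <- apply(pairs, 2, function(ij) pixelDistance(m2, ij[1], ij[2]))
  expect_true(any(abs(d1 - d2) > 0))
})

test_that("pixel maps survive a JSON round trip", {
  ds <- ringnormFixture(40, seed = 17)
  map <- computePixelMap(ds, representationSpec("tsne", metric = "hamming",
                                                filter = "blur", seed = 5L),
                         12, 12)
  path <- withr::local_tempfile(fileext = ".json")
  writePixelMap(map, path)
  back <- readPixelMap(path)
  expect_identical(pixelCoords(back), pixelCoords(map))
  expect_equal(back@rotationDeg, map@rotationDeg)
  expect_identical(back@spec@technique, map@spec@technique)
  expect_identical(back@spec@metric, map@spec@metric)
  expect_identical(back@spec@filter, map@spec@filter)
})
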