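# shared fixtures, all generated in code

blobsFixture <- function(n = 120, d = 12, seed = 3, separation = 10) {
  generateBlobs(generatorConfig("gaussian_blobs", nSamples = n,
                                nFeatures = d, seed = seed,
                                params = list(separation = separation)))
}

ringnormFixture <- function(n = 600, seed = 1) {
  generateRingnorm(generatorConfig("ringnorm", nSamples = n, seed = seed))
}

# a PixelMap with hand-set coordinates (bypasses any embedding)
toyPixelMap <- function(coords, p, q, spec = representationSpec("pca")) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  new("PixelMap", p = as.integer(p), q = as.integer(q), coords = coords,
      rotationDeg = 0, spec = spec,
      embedding = matrix(0, nrow(coords), 2,
                         dimnames = list(NULL, c("x", "y"))),
      featureNames = paste0("f", seq_len(nrow(coords))))
}

# normalized split pieces of a dataset, ready for the image pipeline
preparedSplit <- function(ds, seed = 1) {
  sp <- splitDataset(ds, seed = seed)
  tr <- subsetSamples(ds, sp$train)
  nm <- fitNorm2(tr)
  list(split = sp,
       train = applyNorm2(nm, tr),
       validation = applyNorm2(nm, subsetSamples(ds, sp$validation)),
       test = subsetSamples(ds, sp$test),
       normalizer = nm,
       trainLabels = sampleLabels(tr),
       valLabels = sampleLabels(subsetSamples(ds, sp$validation)))
}

# brute-force rotation sweep oracle for the minimum-area rectangle
sweepRectArea <- function(points, stepDeg = 0.05) {
  angles <- seq(0, 90 - stepDeg, by = stepDeg)
  th <- angles * pi / 180
  x <- points[, 1]; y <- points[, 2]
  areas <- vapply(th, function(t) {
    xr <- x * cos(t) - y * sin(t)
    yr <- x * sin(t) + y * cos(t)
    diff(range(xr)) * diff(range(yr))
  }, numeric(1))
  min(areas)
}
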