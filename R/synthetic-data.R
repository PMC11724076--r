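#' Configuration for the synthetic dataset generators
#'
#' @slot family "ringnorm", "madelon_style" or "gaussian_blobs".
#' @slot nSamples number of samples (>= 0).
#' @slot nFeatures number of features (>= 1).
#' @slot classFractions class prior proportions, in (0,1], summing to 1.
#' @slot seed RNG seed; identical configs produce identical datasets.
#' @slot params family-specific settings, see the generator functions.
#' @export
setClass("GeneratorConfig",
  representation(family = "character", nSamples = "integer",
                 nFeatures = "integer", classFractions = "numeric",
                 seed = "integer", params = "list"))

setValidity("GeneratorConfig", function(object) {
  if (!object@family %in% c("ringnorm", "madelon_style", "gaussian_blobs"))
    return("family must be ringnorm/madelon_style/gaussian_blobs")
  if (object@nSamples < 0L) return("nSamples must be >= 0")
  if (object@nFeatures < 1L) return("nFeatures must be >= 1")
  fr <- object@classFractions
  if (any(fr <= 0) || any(fr > 1)) return("class fractions must lie in (0,1]")
  if (abs(sum(fr) - 1) > 1e-9) return("class fractions must sum to 1")
  TRUE
})

#' @rdname GeneratorConfig-class
#' @param family,nSamples,nFeatures,classFractions,seed,params see slots.
#' @export
generatorConfig <- function(family = c("ringnorm", "madelon_style",
                                       "gaussian_blobs"),
                            nSamples, nFeatures = 20L,
                            classFractions = c(0.5, 0.5), seed = 1L,
                            params = list()) {
  family <- match.arg(family)
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples < 0)
    stop("nSamples must be a single non-negative integer")
  methods::new("GeneratorConfig", family = family,
               nSamples = as.integer(nSamples),
               nFeatures = as.integer(nFeatures),
               classFractions = classFractions, seed = as.integer(seed),
               params = params)
}

# class counts under the documented rounding rule: classes in order receive
# the ceiling of their share first (largest-remainder, earlier class wins).
classCounts <- function(n, fractions) apportion(n, fractions)

#' Generate the ringnorm benchmark
#'
#' A 20-dimensional (by default) two-class problem: class 1 is drawn from
#' N(0, 4 I_d) and class 2 from N((2 / sqrt(d)) 1, I_d). The Bayes-optimal
#' boundary is quadratic (a "ring"), which linear classifiers cannot
#' represent -- the property the benchmark exists to probe. Class priors
#' default to 50/50 and are configurable through `classFractions`.
#'
#' @param config a [GeneratorConfig-class] with `family == "ringnorm"`.
#' @return a [TabularDataset-class] of shape d x n with labels 1/2 and the
#'   generating config recorded in its metadata.
#' @examples
#' ds <- generateRingnorm(generatorConfig("ringnorm", nSamples = 100, seed = 7))
#' ds
#' @export
generateRingnorm <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  if (config@family != "ringnorm") stop("config family is not 'ringnorm'")
  n <- config@nSamples; d <- config@nFeatures
  counts <- classCounts(n, config@classFractions)
  if (length(counts) != 2L) stop("ringnorm is a two-class problem")
  withSeed(config@seed, {
    x1 <- matrix(rnorm(d * counts[1], mean = 0, sd = 2), nrow = d)
    x2 <- matrix(rnorm(d * counts[2], mean = 2 / sqrt(d), sd = 1), nrow = d)
  })
  values <- cbind(x1, x2)
  labels <- rep.int(c(1L, 2L), counts)
  perm <- withSeed(deriveSeed(config@seed, "interleave"), sample.int(max(n, 1L)))
  if (n > 0) { values <- values[, perm, drop = FALSE]; labels <- labels[perm] }
  tabularDataset(values, labels, classLevels = c("1", "2"),
                 metadata = list(generator = list(family = "ringnorm",
                                                  seed = config@seed,
                                                  counts = counts)))
}

#' Generate a Madelon-style nonlinear benchmark
#'
#' Emulates the structure of the NIPS-2003 Madelon generator: informative
#' features place per-class Gaussian clusters on the vertices of a scaled
#' hypercube, redundant features are exact linear combinations of the
#' informative ones, irrelevant features are pure noise, and a small
#' fraction of labels is flipped. The byte-exact original file is a
#' non-goal; what matters is the redundant/irrelevant/nonlinear structure.
#'
#' `config@params` recognises: `nInformative` (default 5), `nRedundant`
#' (default 5; the rest are irrelevant), `nClustersPerClass` (default 2),
#' `clusterSd` (default 1), `hypercubeScale` (default 3), `flipFraction`
#' (default 0.01).
#'
#' @param config a [GeneratorConfig-class] with `family == "madelon_style"`.
#' @return a [TabularDataset-class]; metadata records the feature
#'   permutation (`featurePermutation`, mapping output row -> generated row),
#'   the cluster centers in informative space and the linear combination
#'   weights, so tests can invert the construction.
#' @export
generateMadelonStyle <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  if (config@family != "madelon_style") stop("config family is not 'madelon_style'")
  p <- modifyList(list(nInformative = 5L, nRedundant = 5L,
                       nClustersPerClass = 2L, clusterSd = 1,
                       hypercubeScale = 3, flipFraction = 0.01),
                  config@params)
  n <- config@nSamples; d <- config@nFeatures
  nInf <- as.integer(p$nInformative); nRed <- as.integer(p$nRedundant)
  nIrr <- d - nInf - nRed
  if (nIrr < 0 || (nRed > 0 && nInf == 0))
    stop("informative + redundant + irrelevant feature counts must equal nFeatures")
  c_ <- length(config@classFractions)
  counts <- classCounts(n, config@classFractions)
  nClust <- max(1L, as.integer(p$nClustersPerClass))
  withSeed(config@seed, {
    # hypercube vertices (+-scale per coordinate), distinct while the cube
    # has enough corners, assigned cyclically to classes so neighbouring
    # vertices belong to different classes (nonlinearity)
    nVert <- c_ * nClust
    nd <- max(nInf, 1L)
    if (nd <= 25L && 2^nd >= nVert) {
      corner <- sample.int(2^nd, nVert) - 1L
      verts <- vapply(corner, function(ix)
        p$hypercubeScale * (2 * (bitwAnd(ix, bitwShiftL(1L, 0:(nd - 1L))) > 0) - 1),
        numeric(nd))
      verts <- matrix(verts, nrow = nd)
    } else {
      verts <- matrix(sample(c(-1, 1) * p$hypercubeScale, nVert * nd,
                             replace = TRUE), nrow = nd)
    }
    vertClass <- rep_len(seq_len(c_), nVert)
    labels <- rep.int(seq_len(c_), counts)
    inf <- matrix(0, nrow = max(nInf, 1L), ncol = max(n, 0L))
    clusterOf <- integer(max(n, 0L))
    for (k in seq_len(c_)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      vk <- which(vertClass == k)
      cl <- vk[sample.int(length(vk), length(idx), replace = TRUE)]
      clusterOf[idx] <- cl
      inf[, idx] <- verts[, cl, drop = FALSE] +
        matrix(rnorm(max(nInf, 1L) * length(idx), sd = p$clusterSd),
               nrow = max(nInf, 1L))
    }
    if (nInf == 0L) inf <- inf[0, , drop = FALSE]
    redW <- matrix(rnorm(nInf * nRed), nrow = max(nInf, 1L))[seq_len(nInf), ,
                                                             drop = FALSE]
    red <- if (nRed > 0) t(redW) %*% inf else
      matrix(0, 0, max(n, 0L))
    irr <- matrix(rnorm(nIrr * max(n, 0L)), nrow = nIrr)
    values <- rbind(inf, red, irr)
    nFlip <- floor(p$flipFraction * n)
    if (nFlip > 0) {
      fi <- sample.int(n, nFlip)
      labels[fi] <- 1L + (labels[fi] %% c_)   # rotate to another class
    }
    perm <- sample.int(d)
  })
  values <- values[perm, , drop = FALSE]
  roles <- rep(c("informative", "redundant", "irrelevant"),
               c(nInf, nRed, nIrr))[perm]
  tabularDataset(values, labels, classLevels = as.character(seq_len(c_)),
                 metadata = list(generator = list(
                   family = "madelon_style", seed = config@seed,
                   featurePermutation = perm, featureRoles = roles,
                   centers = verts, vertexClass = vertClass,
                   redundantWeights = redW, clusterOf = clusterOf)))
}

#' Generate isotropic Gaussian blobs
#'
#' One spherical Gaussian cluster per class, centers `separation` apart
#' along the unit diagonal. A tiny, fully controllable fixture: at large
#' separation the classes are perfectly separable, at separation 0 there is
#' no signal. `config@params`: `separation` (default 6), `sd` (default 1).
#'
#' @param config a [GeneratorConfig-class] with `family == "gaussian_blobs"`.
#' @return a [TabularDataset-class].
#' @export
generateBlobs <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  if (config@family != "gaussian_blobs") stop("config family is not 'gaussian_blobs'")
  p <- modifyList(list(separation = 6, sd = 1), config@params)
  n <- config@nSamples; d <- config@nFeatures
  c_ <- length(config@classFractions)
  counts <- classCounts(n, config@classFractions)
  u <- rep(1 / sqrt(d), d)
  labels <- rep.int(seq_len(c_), counts)
  withSeed(config@seed, {
    values <- matrix(rnorm(d * max(n, 0L), sd = p$sd), nrow = d)
  })
  if (n > 0)
    values <- values + outer(u, (labels - 1) * p$separation)
  tabularDataset(values, labels, classLevels = as.character(seq_len(c_)),
                 metadata = list(generator = list(family = "gaussian_blobs",
                                                  seed = config@seed,
                                                  separation = p$separation)))
}

#' Dispatch a GeneratorConfig to its family's generator
#'
#' @param config a [GeneratorConfig-class].
#' @return a [TabularDataset-class].
#' @export
generateDataset <- function(config) {
  switch(config@family,
         ringnorm       = generateRingnorm(config),
         madelon_style  = generateMadelonStyle(config),
         gaussian_blobs = generateBlobs(config))
}
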