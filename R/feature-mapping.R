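#' Embed the features of a dataset into the plane
#'
#' The manifold technique is applied to the TRANSPOSED data matrix: each of
#' the d features, seen as a point in the n-dimensional sample space,
#' receives a 2-D coordinate. This is the location function L(g | lambda_r)
#' that downstream stages discretise into pixel positions. Only training
#' samples should ever be passed here; test samples reuse the frozen map.
#'
#' Technique notes:
#' \itemize{
#'   \item \code{pca}: top-2 principal component scores of the feature
#'     points (centered, unscaled).
#'   \item \code{kpca}: kernel PCA (RBF by default; `params$sigma` sets the
#'     kernel width, default 1/n).
#'   \item \code{tsne}: exact t-SNE (theta = 0 unless `params$theta` says
#'     otherwise), PCA initialisation, perplexity
#'     `min(30, (d - 1) / 3)` unless overridden. Non-Euclidean metrics are
#'     fed in as precomputed feature-feature distance matrices. The
#'     `hamming` metric binarises each feature at its own median first
#'     (raw hamming on continuous values is degenerate); `mahalanobis` with
#'     a singular sample covariance falls back to a ridge-regularised
#'     covariance with a warning.
#'   \item \code{umap}: `n_neighbors = max(2, min(15, d - 1))` unless
#'     overridden; single-threaded SGD so results are reproducible from the
#'     spec seed.
#' }
#' With fewer than 3 features a 2-D neighbour embedding is meaningless, so
#' t-SNE/UMAP/kPCA fall back to PCA with a warning.
#'
#' @param ds a [TabularDataset-class] (training partition).
#' @param spec a [RepresentationSpec-class].
#' @return d x 2 numeric matrix of feature coordinates.
#' @export
embedFeatures <- function(ds, spec) {
  X <- t(featureValues(ds))               # samples x features
  P <- t(X)                               # feature points: d x n
  d <- nrow(P)
  if (d < 2L) stop("need at least 2 features to embed")
  tech <- spec@technique
  if (d < 3L && tech != "pca") {
    warning("fewer than 3 features; falling back to PCA embedding")
    tech <- "pca"
  }
  emb <- switch(tech,
    pca  = embedPCA(P),
    kpca = embedKPCA(P, spec),
    umap = embedUMAP(P, spec),
    tsne = embedTSNE(P, spec))
  dimnames(emb) <- list(rownames(P), c("x", "y"))
  emb
}

embedPCA <- function(P) {
  pc <- prcomp(P, center = TRUE, scale. = FALSE)
  sc <- pc$x
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  sc[, 1:2, drop = FALSE]
}

embedKPCA <- function(P, spec) {
  sigma <- spec@params$sigma
  if (is.null(sigma)) sigma <- 1 / ncol(P)
  kp <- withSeed(spec@seed,
    kernlab::kpca(P, kernel = "rbfdot", kpar = list(sigma = sigma),
                  features = 2))
  rot <- kernlab::rotated(kp)
  if (ncol(rot) < 2L) rot <- cbind(rot, 0)
  rot[, 1:2, drop = FALSE]
}

embedUMAP <- function(P, spec) {
  d <- nrow(P)
  nn <- spec@params$n_neighbors
  if (is.null(nn)) nn <- max(2L, min(15L, d - 1L))
  withSeed(spec@seed,
    uwot::umap(P, n_neighbors = nn, n_components = 2, min_dist = 0.1,
               n_sgd_threads = 1L, n_threads = 1L, init = "spca",
               verbose = FALSE))
}

embedTSNE <- function(P, spec) {
  d <- nrow(P)
  perp <- spec@params$perplexity
  if (is.null(perp)) perp <- min(30, (d - 1) / 3)
  perp <- max(perp, 0.5)
  theta <- spec@params$theta
  if (is.null(theta)) theta <- 0            # exact t-SNE by default
  init <- embedPCA(P)
  init <- init * 1e-4 / max(sd(init[, 1]), 1e-12)
  run <- function(obj, isDist) withSeed(spec@seed,
    Rtsne::Rtsne(obj, dims = 2, perplexity = perp, theta = theta,
                 is_distance = isDist, pca = FALSE,
                 check_duplicates = FALSE, Y_init = init,
                 max_iter = 500, verbose = FALSE, num_threads = 1L))
  res <- if (spec@metric == "euclidean") run(P, FALSE)
         else run(featureDistances(P, spec@metric), TRUE)
  res$Y
}

# feature-feature distance matrix for the non-Euclidean t-SNE variants;
# P is d features x n samples
featureDistances <- function(P, metric) {
  switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(P^2)); nrm[nrm == 0] <- 1
      S <- (P / nrm) %*% t(P / nrm)
      D <- 1 - S; D[D < 0] <- 0; diag(D) <- 0
      as.dist(D)
    },
    chebychev = {
      d <- nrow(P)
      D <- matrix(0, d, d)
      for (i in seq_len(d - 1)) for (j in (i + 1):d)
        D[i, j] <- D[j, i] <- max(abs(P[i, ] - P[j, ]))
      as.dist(D)
    },
    hamming = {
      med <- apply(P, 1, median)
      B <- (P > med) * 1                   # binarise each feature at its median
      n <- ncol(B)
      cross <- B %*% t(B)
      ones <- rowSums(B)
      mism <- outer(ones, ones, "+") - 2 * cross
      as.dist(mism / n)
    },
    mahalanobis = {
      S <- cov(P)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10 * max(ev, 1e-300)) {
        warning("singular covariance for mahalanobis metric; ",
                "adding ridge regularisation")
        S <- S + diag(1e-6 * max(ev, 1e-12), ncol(S))
      }
      Sinv <- solve(S)
      d <- nrow(P)
      D <- matrix(0, d, d)
      for (i in seq_len(d - 1)) for (j in (i + 1):d) {
        dv <- P[i, ] - P[j, ]
        D[i, j] <- D[j, i] <- sqrt(drop(t(dv) %*% Sinv %*% dv))
      }
      as.dist(D)
    },
    stop("unsupported metric: ", metric))
}

rotatePoints <- function(points, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  points %*% t(R)
}

#' Minimum-area bounding rectangle of a point set
#'
#' Rotating-calipers over the convex hull: the minimum-area enclosing
#' rectangle has a side collinear with a hull edge, so only hull-edge
#' angles need be examined. Returns the counter-clockwise rotation (in
#' degrees, in [0, 180)) that makes the optimal rectangle
#' axis-parallel; when several rotations tie in area, orientations whose
#' height does not exceed their width are preferred (so degenerate point
#' sets land in a single row) and among those the smallest
#' non-negative angle wins. Degenerate inputs are handled: collinear points
#' give a zero-height rectangle aligned with the line, a single point a
#' zero-size rectangle at rotation 0.
#'
#' @param points k x 2 numeric matrix.
#' @return list with `rotationDeg`, `area`, `width` (x extent after
#'   rotation), `height` (y extent), and `corners` (4 x 2, the rectangle in
#'   the original frame).
#' @export
minAreaRectangle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point")
  pts <- unique(points)
  boxAt <- function(deg) {
    rp <- rotatePoints(pts, deg)
    w <- diff(range(rp[, 1])); h <- diff(range(rp[, 2]))
    c(area = w * h, w = w, h = h)
  }
  if (nrow(pts) == 1L) {
    best <- 0
  } else {
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    k <- nrow(hp)
    edges <- hp[c(seq_len(k)[-1], 1L), , drop = FALSE] - hp
    angs <- atan2(edges[, 2], edges[, 1]) * 180 / pi
    base <- unique(round((-angs) %% 90, 12))
    cand <- sort(unique(c(base, base + 90)))   # both side orientations
    boxes <- vapply(cand, boxAt, numeric(3))
    aMin <- min(boxes["area", ])
    tied <- which(boxes["area", ] <= aMin + 1e-12 * max(aMin, 1))
    # ties: prefer landscape orientation (height <= width), then the
    # smallest non-negative angle
    flat <- tied[boxes["h", tied] <= boxes["w", tied] + 1e-12]
    best <- cand[if (length(flat)) flat[1] else tied[1]]
  }
  bb <- boxAt(best)
  rp <- rotatePoints(pts, best)
  xr <- range(rp[, 1]); yr <- range(rp[, 2])
  corners <- rotatePoints(cbind(xr[c(1, 2, 2, 1)], yr[c(1, 1, 2, 2)]), -best)
  list(rotationDeg = best, area = unname(bb["area"]),
       width = unname(bb["w"]), height = unname(bb["h"]), corners = corners)
}

#' Discretise embedded points onto a pixel grid
#'
#' The point cloud is rotated by `rotationDeg` (axis-aligning its bounding
#' rectangle) and mapped onto a p x q grid of half-open cells [k, k+1). A
#' single isotropic scale is used for both axes (the rectangle's aspect
#' ratio is preserved; the shorter dimension simply occupies fewer cells),
#' anchored at cell (0, 0). Points on the far boundary close the last cell.
#' Degenerate extents collapse onto row or column 0, so collinear inputs
#' occupy a single row.
#'
#' @param points k x 2 matrix of embedded coordinates.
#' @param rotationDeg rotation from [minAreaRectangle()].
#' @param p,q grid rows / columns.
#' @return k x 2 integer matrix of 0-based (row, col) = (a, b) pairs.
#' @export
discretizePoints <- function(points, rotationDeg, p, q) {
  if (p < 1L || q < 1L) stop("grid dimensions must be >= 1")
  points <- as.matrix(points)
  rp <- rotatePoints(points, rotationDeg)
  x <- rp[, 1] - min(rp[, 1])
  y <- rp[, 2] - min(rp[, 2])
  w <- max(x); h <- max(y)
  s <- max(w / q, h / p)
  if (s == 0) {                            # single point (or all coincident)
    coords <- matrix(0L, nrow(points), 2)
  } else {
    a <- pmin(as.integer(floor(y / s)), p - 1L)
    b <- pmin(as.integer(floor(x / s)), q - 1L)
    coords <- cbind(a, b)
  }
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("a", "b")
  coords
}

#' Compute the frozen pixel map of one representation
#'
#' Composes [embedFeatures()], [minAreaRectangle()] and
#' [discretizePoints()]: the DeepInsight transform P = H(M) that assigns
#' every feature its pixel location under the representation's manifold
#' technique. Deterministic given the same data, spec and grid.
#'
#' @param ds training [TabularDataset-class].
#' @param spec a [RepresentationSpec-class].
#' @param p,q grid rows / columns (default 50 x 50).
#' @param embedding optional pre-computed d x 2 embedding (testing hook /
#'   diagnostics); when supplied the manifold step is skipped.
#' @return a [PixelMap-class].
#' @export
computePixelMap <- function(ds, spec, p = 50L, q = 50L, embedding = NULL) {
  if (is.null(embedding)) {
    embedding <- embedFeatures(ds, spec)
  } else {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nFeatures(ds))
      stop("injected embedding must have one row per feature")
  }
  rect <- minAreaRectangle(embedding)
  coords <- discretizePoints(embedding, rect$rotationDeg, p, q)
  fn <- rownames(featureValues(ds))
  methods::new("PixelMap", p = as.integer(p), q = as.integer(q),
               coords = coords, rotationDeg = rect$rotationDeg, spec = spec,
               embedding = embedding,
               featureNames = if (is.null(fn)) idSeq("f", nrow(coords)) else fn)
}

#' Pixel distance between two features under one representation
#'
#' Euclidean distance between the pixel coordinates of features i and j --
#' the per-representation distance D_r whose variation across
#' representations is the premise of the multi-representation ensemble.
#'
#' @param map a [PixelMap-class].
#' @param i,j feature indices (1-based).
#' @return non-negative numeric distance in pixel units.
#' @export
pixelDistance <- function(map, i, j) {
  d <- nrow(map@coords)
  if (any(c(i, j) < 1L) || any(c(i, j) > d))
    stop("feature index out of range 1..", d)
  sqrt(sum((map@coords[i, ] - map@coords[j, ])^2))
}

#' Persist / restore a PixelMap as JSON
#'
#' The JSON artifact (spec, grid, rotation, integer coordinates) is what
#' ships with a trained model so test-time samples can be mapped without
#' re-fitting any embedding.
#'
#' @param map a [PixelMap-class].
#' @param path output / input file path.
#' @return `writePixelMap`: the path, invisibly; `readPixelMap`: the
#'   restored [PixelMap-class].
#' @export
writePixelMap <- function(map, path) {
  obj <- list(p = map@p, q = map@q, rotationDeg = map@rotationDeg,
              coords = unname(map@coords),
              embedding = unname(map@embedding),
              featureNames = map@featureNames,
              spec = list(technique = map@spec@technique,
                          metric = map@spec@metric, filter = map@spec@filter,
                          params = map@spec@params, seed = map@spec@seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePixelMap
#' @export
readPixelMap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- methods::new("RepresentationSpec", technique = obj$spec$technique,
                       metric = obj$spec$metric, filter = obj$spec$filter,
                       params = as.list(obj$spec$params),
                       seed = as.integer(obj$spec$seed))
  coords <- matrix(as.integer(obj$coords), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  methods::new("PixelMap", p = as.integer(obj$p), q = as.integer(obj$q),
               coords = coords, rotationDeg = obj$rotationDeg, spec = spec,
               embedding = matrix(as.numeric(obj$embedding), ncol = 2,
                                  dimnames = list(NULL, c("x", "y"))),
               featureNames = obj$featureNames)
}
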