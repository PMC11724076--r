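#' Render one sample as an image
#'
#' Paints the normalized feature values of a sample at their frozen pixel
#' locations. Background pixels are 0; when several features collide on one
#' pixel their values are combined with the `collision` rule (`"mean"`,
#' the default, preserves the average intensity of the colliding features;
#' `"max"` keeps the strongest).
#'
#' @param x numeric vector of length d with values in [0,1] (apply the
#'   training normalizer first).
#' @param map a [PixelMap-class].
#' @param collision "mean" or "max".
#' @return a p x q numeric matrix.
#' @export
renderSample <- function(x, map, collision = c("mean", "max")) {
  collision <- match.arg(collision)
  d <- nrow(map@coords)
  if (length(x) != d)
    stop("sample has ", length(x), " values but the map expects ", d)
  if (anyNA(x) || min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop("sample values must be normalized into [0,1]")
  img <- matrix(0, map@p, map@q)
  key <- map@coords[, 1] * map@q + map@coords[, 2] + 1
  agg <- if (collision == "mean") tapply(x, key, mean) else tapply(x, key, max)
  k <- as.integer(names(agg)) - 1L
  img[cbind(k %/% map@q + 1L, k %% map@q + 1L)] <- as.numeric(agg)
  img
}

# Gaussian kernel, separable, truncated at 5 sigma, unit mass (wide enough
# that two successive blurs compose like a single one to ~1e-6)
gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# half-sample symmetric reflection indices covering positions (1-r)..(n+r)
reflectIdx <- function(n, r) {
  t <- (1 - r):(n + r)
  m <- (t - 1) %% (2 * n)
  ifelse(m >= n, 2 * n - 1 - m, m) + 1
}

# 2-D convolution with reflective border handling, built on EBImage's
# filter2 (which only offers circular/replicate boundaries): reflect-pad,
# convolve, crop. Half-sample reflection keeps Gaussian smoothing an exact
# semigroup up to kernel truncation.
convolveReflect <- function(img, kernel) {
  kr <- (dim(kernel) - 1L) %/% 2L
  ri <- reflectIdx(nrow(img), kr[1])
  ci <- reflectIdx(ncol(img), kr[2])
  pad <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(pad, kernel, boundary = "circular")
  out[kr[1] + seq_len(nrow(img)), kr[2] + seq_len(ncol(img)), drop = FALSE]
}

#' Gaussian blurring enhancement
#'
#' Convolves the rendered image with an isotropic Gaussian (truncated at 5
#' sigma, reflective borders), spreading each feature's intensity over its
#' pixel neighbourhood. By default the output is rescaled so its maximum
#' equals the input maximum, keeping values in [0,1]; pass `renormalize =
#' FALSE` to obtain the raw mass-conserving convolution.
#'
#' @param image p x q numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param renormalize rescale the output maximum back to the input maximum.
#' @return blurred p x q matrix.
#' @export
applyBlur <- function(image, sigma, renormalize = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  k <- gaussKernel1d(sigma)
  out <- convolveReflect(image, outer(k, k))
  if (min(image) >= 0) out[out < 0] <- 0   # clip FFT round-off noise
  if (renormalize && max(out) > 0)
    out <- out * (max(image) / max(out))
  out
}

#' Construct a Gabor filter bank
#'
#' Quadrature (even cosine / odd sine) Gabor pairs over a grid of
#' orientations and spatial frequencies. The even kernel is made zero-mean
#' so flat regions give no response. Bandwidth follows the common
#' sigma = 0.56 / frequency rule.
#'
#' @param orientations number of evenly spaced orientations in [0, pi)
#'   (default 4).
#' @param frequencies spatial frequencies in cycles/pixel (default
#'   c(0.25, 0.5)).
#' @return list of filters, each with elements `even`, `odd`, `theta`,
#'   `frequency`.
#' @export
gaborBank <- function(orientations = 4L, frequencies = c(0.25, 0.5)) {
  if (orientations < 1L || !length(frequencies)) stop("empty Gabor bank")
  thetas <- (seq_len(orientations) - 1L) * pi / orientations
  bank <- list()
  for (th in thetas) for (f in frequencies) {
    sigma <- 0.56 / f
    r <- max(2L, ceiling(3 * sigma))
    g <- expand.grid(y = -r:r, x = -r:r)
    xr <- g$x * cos(th) + g$y * sin(th)
    yr <- -g$x * sin(th) + g$y * cos(th)
    env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
    even <- matrix(env * cos(2 * pi * f * xr), 2 * r + 1)
    odd  <- matrix(env * sin(2 * pi * f * xr), 2 * r + 1)
    even <- even - mean(even)               # kill DC response
    bank[[length(bank) + 1L]] <- list(even = even, odd = odd, theta = th,
                                      frequency = f)
  }
  bank
}

# quadrature energy of one Gabor filter
gaborEnergy <- function(image, filt) {
  sqrt(convolveReflect(image, filt$even)^2 +
       convolveReflect(image, filt$odd)^2)
}

#' Gabor filtering enhancement
#'
#' Computes the quadrature energy of every filter in the bank and keeps,
#' per pixel, the maximum response across the bank, rescaled to [0,1].
#' Texture-like arrangements of features light up the orientations and
#' scales they align with.
#'
#' @param image p x q numeric matrix.
#' @param bank a filter bank from [gaborBank()].
#' @return filtered p x q matrix with values in [0,1].
#' @export
applyGabor <- function(image, bank = gaborBank()) {
  if (!length(bank)) stop("empty Gabor bank")
  resp <- matrix(0, nrow(image), ncol(image))
  for (filt in bank) resp <- pmax(resp, gaborEnergy(image, filt))
  m <- max(resp)
  if (m > 0) resp <- resp / m
  resp
}

# apply the enhancement filter named in a PixelMap's spec to one image
applyRepFilter <- function(image, map) {
  spec <- map@spec
  switch(spec@filter,
    none = image,
    blur = {
      sigma <- spec@params$blurSigma
      if (is.null(sigma)) sigma <- 1
      applyBlur(image, sigma)
    },
    gabor = {
      bank <- spec@params$gaborBank
      if (is.null(bank)) bank <- gaborBank()
      applyGabor(image, bank)
    })
}

#' Build the image stacks of all representations
#'
#' Renders every sample through every PixelMap and applies each
#' representation's enhancement filter, producing m stacks of n images --
#' n * m training images in total. All maps must share one grid size, since
#' a single CNN consumes the pooled stacks.
#'
#' @param ds a normalized [TabularDataset-class].
#' @param maps list of [PixelMap-class] (one per representation).
#' @param collision collision aggregation rule, see [renderSample()].
#' @return list of [ImageStack-class], one per representation.
#' @export
buildStacks <- function(ds, maps, collision = c("mean", "max")) {
  collision <- match.arg(collision)
  if (!length(maps)) stop("need at least one PixelMap")
  dims <- vapply(maps, function(m) c(m@p, m@q), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all representations must share one grid size (p x q); got ",
         paste(apply(dims, 2, paste, collapse = "x"), collapse = ", "))
  v <- featureValues(ds)
  n <- ncol(v)
  ids <- colnames(v)
  lapply(seq_along(maps), function(r) {
    map <- maps[[r]]
    imgs <- array(0, dim = c(map@p, map@q, n))
    for (j in seq_len(n))
      imgs[, , j] <- applyRepFilter(renderSample(v[, j], map, collision), map)
    methods::new("ImageStack", repIndex = as.integer(r), images = imgs,
                 map = map, sampleIds = if (is.null(ids)) idSeq("s", n) else ids)
  })
}
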