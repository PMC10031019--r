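#' Configuration for the speckle-phantom generator
#'
#' The generator stands in for multi-site clinical B-mode ultrasound data: it
#' renders hypoechoic (darker-than-background) nodules on a speckled tissue
#' background.  Both "sites" share the same anatomy statistics; only the
#' rendering style differs (see [domain_style()]), which is exactly the
#' premise a style-transfer domain-adaptation method needs.
#'
#' @param image_size Pixels per side (square images), at least 16.  64 is the
#'   desk-scale default; clinical-scale 400 is supported.
#' @param nodules_per_image Integer range `c(min, max)` of nodules per image.
#' @param nodule_radius Range `c(min, max)` of nodule semi-axis lengths as a
#'   fraction of `image_size`.
#' @param nodule_contrast Mean-intensity depression of a nodule relative to
#'   the surrounding tissue, in `[0, 1]`.  0 renders invisible nodules.
#' @param speckle_shape Concentration of the unit-mean multiplicative gamma
#'   speckle noise; larger is cleaner.  Must be positive.
#' @param boundary_irregularity Amplitude of the low-frequency radial
#'   perturbation of nodule boundaries; 0 gives exact ellipses.
#' @param seed Default seed used when generation functions are called without
#'   one.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L,
                           nodules_per_image = c(1L, 3L),
                           nodule_radius = c(0.08, 0.2),
                           nodule_contrast = 0.4,
                           speckle_shape = 6,
                           boundary_irregularity = 0.15,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 16L)
    stop_sym("image_size must be an integer >= 16")
  chk_range <- function(r, what) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2])
      stop_sym(what, " must be a nonempty range c(min, max) with min <= max")
  }
  chk_range(nodules_per_image, "nodules_per_image")
  chk_range(nodule_radius, "nodule_radius")
  if (nodules_per_image[1] < 0) stop_sym("nodules_per_image must be >= 0")
  if (nodule_radius[1] <= 0) stop_sym("nodule_radius must be positive")
  if (nodule_radius[2] >= 0.5)
    stop_sym("nodule_radius range exceeds image bounds (max must be < 0.5)")
  if (nodule_contrast < 0 || nodule_contrast > 1)
    stop_sym("nodule_contrast must lie in [0, 1]")
  if (!is.finite(speckle_shape) || speckle_shape <= 0)
    stop_sym("speckle_shape must be a positive real")
  if (boundary_irregularity < 0)
    stop_sym("boundary_irregularity must be non-negative")
  structure(list(image_size = image_size,
                 nodules_per_image = as.integer(nodules_per_image),
                 nodule_radius = as.numeric(nodule_radius),
                 nodule_contrast = nodule_contrast,
                 speckle_shape = speckle_shape,
                 boundary_irregularity = boundary_irregularity,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Site rendering style
#'
#' Parameterizes the appearance discrepancy between imaging sites: tone curve
#' (gamma), contrast and brightness, point-spread blur, a low-frequency
#' additive texture, and optional intensity inversion.  The neutral style
#' (all defaults) is the identity map up to clipping.
#'
#' @param gamma Positive tone-curve exponent.
#' @param brightness_shift Additive shift in `[-0.3, 0.3]`.
#' @param contrast_scale Positive multiplicative contrast about mid-gray 0.5.
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @param texture_amp Amplitude of the additive sinusoidal texture (>= 0).
#' @param texture_freq Texture frequency in cycles per image width (> 0).
#' @param invert If `TRUE`, intensities are inverted (`1 - x`) first.
#' @return An object of class `domain_style`.
#' @export
domain_style <- function(gamma = 1, brightness_shift = 0, contrast_scale = 1,
                         blur_sigma = 0, texture_amp = 0, texture_freq = 8,
                         invert = FALSE) {
  if (!is.finite(gamma) || gamma <= 0) stop_sym("gamma must be positive")
  if (abs(brightness_shift) > 0.3)
    stop_sym("brightness_shift must lie in [-0.3, 0.3]")
  if (!is.finite(contrast_scale) || contrast_scale <= 0)
    stop_sym("contrast_scale must be positive")
  if (blur_sigma < 0) stop_sym("blur_sigma must be non-negative")
  if (texture_amp < 0) stop_sym("texture_amp must be non-negative")
  if (texture_freq <= 0) stop_sym("texture_freq must be positive")
  structure(list(gamma = gamma, brightness_shift = brightness_shift,
                 contrast_scale = contrast_scale, blur_sigma = blur_sigma,
                 texture_amp = texture_amp, texture_freq = texture_freq,
                 invert = isTRUE(invert)),
            class = "domain_style")
}

#' One image with optional ground-truth mask
#'
#' @param image `H x W` matrix of intensities in `[0, 1]`.
#' @param mask Optional `H x W` binary (0/1) matrix of the same shape.
#' @param domain Domain tag, `"source"` or `"target"`.
#' @param id Sample identifier string.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image, mask = NULL, domain = "source", id = "s0001") {
  assert_image01(image)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(image)))
      stop_sym("mask shape ", paste(dim(mask), collapse = "x"),
               " does not match image shape ",
               paste(dim(image), collapse = "x"))
    assert_binary_mask(mask)
  }
  domain <- match.arg(domain, c("source", "target"))
  structure(list(image = image, mask = mask, domain = domain,
                 id = as.character(id)),
            class = "image_sample")
}

# ---- anatomy ----------------------------------------------------------------

# Renders the speckle-free tissue map and the exact binary nodule mask.
# Assumes the RNG state is already seeded by the caller.
gen_anatomy_impl <- function(config) {
  S <- config$image_size
  xs <- (seq_len(S) - 0.5) / S
  # slowly varying tissue background around mid-bright echogenicity
  bg <- matrix(0.55, S, S)
  for (k in 1:3) {
    fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2)
    ph <- runif(2, 0, 2 * pi)
    amp <- 0.03 / k
    bg <- bg + amp * outer(cos(2 * pi * fx * xs + ph[1]),
                           cos(2 * pi * fy * xs + ph[2]))
  }
  n_nod <- if (config$nodules_per_image[1] == config$nodules_per_image[2])
    config$nodules_per_image[1]
  else sample(seq(config$nodules_per_image[1], config$nodules_per_image[2]), 1L)
  mask <- matrix(0, S, S)
  img <- bg
  rmax <- config$nodule_radius[2]
  u <- matrix(xs, S, S)          # row coordinate
  v <- matrix(xs, S, S, byrow = TRUE)
  for (k in seq_len(n_nod)) {
    a <- runif(1, config$nodule_radius[1], config$nodule_radius[2])
    b <- runif(1, config$nodule_radius[1], config$nodule_radius[2])
    cx <- runif(1, rmax * 1.2, 1 - rmax * 1.2)
    cy <- runif(1, rmax * 1.2, 1 - rmax * 1.2)
    phi <- runif(1, 0, pi)
    du <- u - cx; dv <- v - cy
    ru <- cos(phi) * du + sin(phi) * dv
    rv <- -sin(phi) * du + cos(phi) * dv
    rho <- sqrt((ru / a)^2 + (rv / b)^2)
    # low-frequency radial perturbation of the boundary
    pert <- matrix(0, S, S)
    if (config$boundary_irregularity > 0) {
      th <- atan2(rv, ru)
      for (m in 2:4) {
        ab <- rnorm(2, 0, 1 / m)
        pert <- pert + ab[1] * cos(m * th) + ab[2] * sin(m * th)
      }
      pert <- config$boundary_irregularity * pert
    }
    edge <- 1 + pert
    inside <- rho <= edge
    mask[inside] <- 1
    # soft intensity depression so the lesion has an ultrasound-like halo
    soft <- 1 / (1 + exp((rho - edge) / 0.06))
    img <- img * (1 - config$nodule_contrast * soft)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate speckle-free anatomy and its ground-truth mask
#'
#' Draws `nodules_per_image` dark elliptical nodules (with optional radial
#' boundary perturbation) on a smooth tissue background and returns the clean
#' image together with the exact binary mask of the nodule union.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `image` and `mask` (both `S x S`).
#' @export
generate_anatomy <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, gen_anatomy_impl(config))
}

# ---- speckle ----------------------------------------------------------------

#' Apply multiplicative gamma speckle noise
#'
#' Multiplies the image pixelwise by unit-mean gamma noise with concentration
#' `speckle_shape` (a first-order B-mode speckle approximation) and clips the
#' result to `[0, 1]`.
#'
#' @param clean_image Matrix of intensities in `[0, 1]`.
#' @param speckle_shape Positive concentration; values above `1e6` are capped
#'   (the noise-free limit).
#' @param seed Integer seed.
#' @return The speckled image, same shape as the input.
#' @export
apply_speckle <- function(clean_image, speckle_shape, seed = 1L) {
  assert_image01(clean_image, "clean_image")
  if (!is.finite(speckle_shape) || speckle_shape <= 0)
    stop_sym("speckle_shape must be a positive real")
  k <- min(speckle_shape, 1e6)
  with_seed(seed, {
    noise <- rgamma(length(clean_image), shape = k, rate = k)
    out <- pmin(pmax(clean_image * noise, 0), 1)
    dim(out) <- dim(clean_image)
    out
  })
}

# ---- style ------------------------------------------------------------------

# Separable Gaussian blur via banded row/column operators with renormalized
# (replicate-like) edges.  Exact identity for sigma = 0.
blur_operator <- function(n, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - rad):(i + rad)
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- k[ok]
    B[i, ] <- B[i, ] / sum(B[i, ])
  }
  B
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  d <- dim(image)
  Br <- blur_operator(d[1], sigma)
  Bc <- if (d[2] == d[1]) Br else blur_operator(d[2], sigma)
  Br %*% image %*% t(Bc)
}

#' Render an image under a site style
#'
#' Applies, in order: optional inversion, gamma tone curve, contrast scaling
#' about 0.5, brightness shift, Gaussian blur, and an additive sinusoidal
#' texture with seeded random orientation and phase; the result is clipped to
#' `[0, 1]`.  With the neutral style this is the identity map.
#'
#' @param image Matrix of intensities in `[0, 1]`.
#' @param style A [domain_style()].
#' @param seed Integer seed (used only by the texture component).
#' @return The styled image, same shape as the input.
#' @export
apply_domain_style <- function(image, style, seed = 1L) {
  assert_image01(image)
  stopifnot(inherits(style, "domain_style"))
  x <- image
  if (style$invert) x <- 1 - x
  if (style$gamma != 1) x <- x^style$gamma
  if (style$contrast_scale != 1) x <- 0.5 + style$contrast_scale * (x - 0.5)
  if (style$brightness_shift != 0) x <- x + style$brightness_shift
  x <- pmin(pmax(x, 0), 1)
  if (style$blur_sigma > 0) x <- gaussian_blur(x, style$blur_sigma)
  if (style$texture_amp > 0) {
    d <- dim(x)
    x <- x + with_seed(seed, {
      phi <- runif(1, 0, 2 * pi)
      ph <- runif(1, 0, 2 * pi)
      u <- matrix((seq_len(d[1]) - 0.5) / d[1], d[1], d[2])
      v <- matrix((seq_len(d[2]) - 0.5) / d[2], d[1], d[2], byrow = TRUE)
      style$texture_amp *
        sin(2 * pi * style$texture_freq * (cos(phi) * u + sin(phi) * v) + ph)
    })
  }
  pmin(pmax(x, 0), 1)
}

# ---- datasets ---------------------------------------------------------------

new_domain_dataset <- function(samples, split, domain, config = NULL,
                               style = NULL) {
  stopifnot(length(samples) == length(split),
            all(split %in% c("train", "test")))
  structure(list(samples = samples, split = split, domain = domain,
                 config = config, style = style),
            class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> domain=%s  n=%d (train %d / test %d)\n",
              x$domain, length(x$samples), sum(x$split == "train"),
              sum(x$split == "test")))
  invisible(x)
}

#' Generate a full single-domain phantom dataset
#'
#' Renders `n` phantoms (anatomy + speckle + site style), attaches the exact
#' masks, and assigns a seeded train/test split.  The whole dataset is a pure
#' function of `(config, style, seed)`.
#'
#' @param config A [phantom_config()].
#' @param style A [domain_style()].
#' @param n Number of samples, at least 2.
#' @param test_fraction Fraction of samples held out as the test split
#'   (ignored when `test_count` is given).
#' @param test_count Optional explicit number of test samples.
#' @param seed Integer seed.
#' @param domain Domain tag for the samples.
#' @return A `domain_dataset`.
#' @export
generate_domain_dataset <- function(config, style, n, test_fraction = 0.2,
                                    test_count = NULL, seed = config$seed,
                                    domain = "source") {
  stopifnot(inherits(config, "phantom_config"), inherits(style, "domain_style"))
  n <- as.integer(n)
  if (n < 2L) stop_sym("n must be at least 2")
  if (is.null(test_count)) {
    if (test_fraction <= 0 || test_fraction >= 1)
      stop_sym("test_fraction must lie strictly between 0 and 1")
    test_count <- round(n * test_fraction)
  }
  test_count <- as.integer(test_count)
  if (test_count >= n)
    stop_sym("test count (", test_count, ") must be smaller than n (", n, ")")
  domain <- match.arg(domain, c("source", "target"))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s_anat <- derive_seed(seed, paste0("anatomy", i))
    anat <- with_seed(s_anat, gen_anatomy_impl(config))
    img <- apply_speckle(anat$image, config$speckle_shape,
                         derive_seed(seed, paste0("speckle", i)))
    img <- apply_domain_style(img, style,
                              derive_seed(seed, paste0("style", i)))
    samples[[i]] <- image_sample(img, anat$mask, domain,
                                 sprintf("%s_%05d", domain, i))
  }
  split <- rep("train", n)
  test_idx <- with_seed(derive_seed(seed, "split"), sample.int(n, test_count))
  split[test_idx] <- "test"
  new_domain_dataset(samples, split, domain, config, style)
}

# Helpers used across the package
dataset_images <- function(ds, split = NULL) {
  idx <- if (is.null(split)) seq_along(ds$samples) else which(ds$split == split)
  lapply(ds$samples[idx], `[[`, "image")
}

dataset_masks <- function(ds, split = NULL) {
  idx <- if (is.null(split)) seq_along(ds$samples) else which(ds$split == split)
  lapply(ds$samples[idx], `[[`, "mask")
}

#' Built-in style presets for the synthetic cross-site benchmark
#'
#' `"neutral"` is the identity; `"site_a"`/`"site_b"` differ by gamma, blur,
#' texture and contrast; `"site_inverted"` additionally inverts intensities,
#' producing the strongest shift (a source-only model fails on it, which is
#' what makes the adaptation benefit measurable).  The magnitudes are our
#' choice: the clinical inter-site shift is never quantified numerically in
#' multi-site ultrasound studies.
#'
#' @param name Preset name.
#' @return A [domain_style()].
#' @export
style_preset <- function(name = c("neutral", "site_a", "site_b",
                                  "site_inverted")) {
  switch(match.arg(name),
    neutral = domain_style(),
    site_a = domain_style(gamma = 0.8, contrast_scale = 1.1,
                          blur_sigma = 0.6, texture_amp = 0.03,
                          texture_freq = 6),
    site_b = domain_style(gamma = 1.4, brightness_shift = 0.05,
                          contrast_scale = 0.9, blur_sigma = 1.2,
                          texture_amp = 0.05, texture_freq = 10),
    site_inverted = domain_style(gamma = 1.3, blur_sigma = 1.0,
                                 invert = TRUE))
}
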